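feature,stroke_mean,stroke_sd,control_mean,control_sd,printed_d,n_stroke,n_control,rounding_dominated
acc_min,0.21,0.1,0.5,0.11,-2.81,20,10,FALSE
acc_median,2.04,0.52,3.1,0.39,-2.2,20,10,FALSE
acc_rms,2.87,0.58,4.14,0.59,-2.18,20,10,FALSE
acc_crossing_entropy,1.04,0.02,1,0.02,2.28,20,10,TRUE
vel_skewness,0.86,0.24,0.37,0.11,2.34,20,10,TRUE
vel_crossing_entropy,1.07,0.01,1.05,0.01,2.3,20,10,TRUE
vel_median,31.79,7.49,46.76,5.82,-2.14,20,10,FALSE
acc_entropy,6.55,0.44,5.87,0.18,1.84,20,10,TRUE
vel_rms,41.76,8.28,55.85,6.45,-1.82,20,10,FALSE
vel_entropy,6.59,0.46,5.89,0.17,1.81,20,10,FALSE
vel_kurtosis,0.53,0.77,-0.55,0.17,1.69,20,10,FALSE
vel_crossing_number,75.61,43.6,32.13,5.1,1.21,20,10,FALSE
vel_min,4.21,1.54,5.92,1.13,-1.2,20,10,FALSE
acc_crossing_avg_length,8.82,2.1,11.2,2.12,-1.13,20,10,FALSE
acc_crossing_number,494.36,376.97,159.91,26.59,1.08,20,10,FALSE
vel_corr_xz,-0.02,0.15,-0.17,0.14,1.02,20,10,FALSE
vel_max,96.22,13.46,107.81,11.65,-0.9,20,10,FALSE
acc_corr_xz,-0.03,0.09,-0.1,0.09,0.81,20,10,TRUE
acc_corr_yz,-0.31,0.11,-0.22,0.12,-0.81,20,10,FALSE
acc_max,10.78,2.09,12.47,2.17,-0.8,20,10,FALSE
acc_kurtosis,5.81,3.88,3.29,1.6,0.76,20,10,FALSE
acc_skewness,1.67,0.46,1.38,0.22,0.73,20,10,FALSE
vel_corr_yz,-0.55,0.21,-0.48,0.19,-0.37,20,10,TRUE
acc_dom_freq_over_energy,0.00013,0.00015,9.37e-05,2.78e-05,0.32,20,10,TRUE
acc_corr_xy,0.0137,0.08,0.00078,0.08,0.16,20,10,FALSE
vel_crossing_avg_length,44.83,2.82,45.27,3.6,-0.14,20,10,FALSE
vel_corr_xy,0.03,0.13,0.01,0.1,0.14,20,10,TRUE
vel_dom_freq_over_energy,5.6e-07,1.87e-07,5.7e-07,1.42e-07,-0.07,20,10,FALSE
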