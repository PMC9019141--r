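# Posterior means of the fitted biweekly survival model, usable as
# generating values for simulation (same numbers as theta_published()).
# Read with read_parameters().
det_intercept_2009: 1.189
det_intercept_rest: 2.322
det_male: 0.347
recovery_r: 0.623
surv_intercept_BS: 1.661
surv_intercept_REST: 2.649
male_BS: 0.668
male_REST: 0.148
feed_BS: 0.627
feed_REST: 0.517
habitat_BS: -0.177
habitat_REST: 0.210
habfeed_BS: 0.887
habfeed_REST: -0.658
clutch: 0.236
mass: 0.064
age_lin: 0.550
age_quad: -0.071
year_2009: 0.026
year_2011: 0.655
year_2012: 0.404
year_2013: 0.543
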