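analysis,arch,movement,tooth_group,n,mean_diff_deg,sd_diff_deg,printed_ci_low,printed_ci_high,printed_loa_low,printed_loa_high,printed_p,printed_dahlberg,check_ci_low,check_ci_high,check_loa_low,check_loa_high,check_dahlberg,check_p
validity,maxillary,rotation,incisors,56,0.4,1.57,-0.15,0.82,-2.67,3.11,0.06,1.13,FALSE,TRUE,TRUE,FALSE,TRUE,TRUE
validity,maxillary,rotation,canines,28,0.98,2.27,0.1,1.86,-3.47,5.43,0.03,1.72,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
validity,maxillary,rotation,premolars,54,0.19,0.91,-0.07,0.44,-1.59,1.98,0.15,0.82,TRUE,TRUE,TRUE,TRUE,FALSE,FALSE
validity,maxillary,rotation,molars,56,0.16,0.71,-0.03,0.36,-1.23,1.55,0.1,0.7,TRUE,TRUE,TRUE,TRUE,FALSE,TRUE
validity,maxillary,inclination,incisors,56,0.39,4.29,-0.85,1.45,-8.01,8.8,0.6,3.01,FALSE,FALSE,TRUE,TRUE,TRUE,FALSE
validity,maxillary,inclination,canines,28,-0.1,3.36,-1.4,1.2,-6.69,6.47,0.87,2.34,TRUE,TRUE,TRUE,FALSE,TRUE,FALSE
validity,maxillary,inclination,premolars,54,-0.003,1.5,-0.42,0.41,-2.94,2.94,0.99,1.47,TRUE,TRUE,TRUE,TRUE,FALSE,TRUE
validity,maxillary,inclination,molars,56,0.15,1.47,-0.25,0.54,-2.73,3.03,0.46,1.32,TRUE,TRUE,TRUE,TRUE,FALSE,FALSE
validity,maxillary,angulation,incisors,56,-0.29,2.34,-0.94,0.35,-4.88,4.3,0.36,2.08,FALSE,TRUE,TRUE,TRUE,FALSE,TRUE
validity,maxillary,angulation,canines,28,1.73,4.77,-0.11,3.58,-9.34,11.08,0.06,3.53,TRUE,TRUE,FALSE,TRUE,TRUE,FALSE
validity,maxillary,angulation,premolars,54,3.7,1.6,3.28,4.18,0.56,6.84,0.001,2.88,FALSE,FALSE,TRUE,TRUE,FALSE,TRUE
validity,maxillary,angulation,molars,56,3.55,1.7,3.1,4,0.22,6.88,0.001,2.83,TRUE,TRUE,TRUE,TRUE,FALSE,TRUE
validity,mandibular,rotation,incisors,56,-0.04,0.9,-0.28,0.2,-1.8,1.72,0.75,0.63,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE
validity,mandibular,rotation,canines,28,-0.14,1.45,-0.7,0.42,-2.98,2.7,0.62,1.01,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE
validity,mandibular,rotation,premolars,54,0.02,0.61,-0.15,0.18,-1.17,1.21,0.84,0.76,TRUE,TRUE,TRUE,TRUE,FALSE,FALSE
validity,mandibular,rotation,molars,54,-0.09,0.5,-0.23,0.04,-1.07,0.89,0.17,0.45,TRUE,TRUE,TRUE,TRUE,FALSE,FALSE
validity,mandibular,inclination,incisors,56,-0.62,3.63,-1.62,0.38,-7.73,6.49,0.22,3.58,FALSE,FALSE,TRUE,TRUE,FALSE,FALSE
validity,mandibular,inclination,canines,28,0.6,2.53,0.39,1.6,-4.35,5.55,0.22,3.08,FALSE,FALSE,TRUE,TRUE,FALSE,TRUE
validity,mandibular,inclination,premolars,54,0.05,1.45,-0.35,0.45,-2.79,2.89,0.8,2.92,TRUE,TRUE,TRUE,TRUE,FALSE,TRUE
validity,mandibular,inclination,molars,54,0.01,0.72,-0.18,0.21,-1.4,1.41,0.88,0.51,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE
validity,mandibular,angulation,incisors,56,-0.69,3.8,-1.7,0.33,-8.14,6.76,0.18,2.71,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
validity,mandibular,angulation,canines,28,0.23,2.59,-0.81,1.28,-4.84,5.3,0.65,2.19,FALSE,FALSE,TRUE,TRUE,FALSE,FALSE
validity,mandibular,angulation,premolars,54,0.79,2.17,0.18,1.39,-3.46,5.04,0.01,1.81,FALSE,TRUE,TRUE,TRUE,FALSE,TRUE
validity,mandibular,angulation,molars,54,1.13,1.82,0.64,1.63,-2.44,4.7,0.001,1.5,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
test_retest,both,rotation,all,196,-0.006,0.12,-0.02,0.01,-0.24,0.23,0.47,0.08,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE
test_retest,both,inclination,all,196,-0.016,0.23,-0.05,0.01,-0.47,0.43,0.32,0.16,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE
test_retest,both,angulation,all,196,0.003,0.43,-0.06,0.06,-0.84,0.84,0.91,0.55,TRUE,TRUE,TRUE,TRUE,FALSE,FALSE
inter_rater,both,rotation,all,196,0.009,0.22,-0.02,0.04,-0.42,0.44,0.54,0.15,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE
inter_rater,both,inclination,all,196,-0.002,0.68,-0.1,0.09,-1.33,1.33,0.96,0.61,TRUE,TRUE,TRUE,TRUE,FALSE,FALSE
inter_rater,both,angulation,all,196,-0.019,0.86,-0.14,0.1,-1.69,1.67,0.75,0.74,TRUE,TRUE,TRUE,TRUE,FALSE,FALSE
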