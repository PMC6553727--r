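# Reference summary: keratometric methods vs CHM, post-SMILE study cohort (n = 40)
method,mean_D,sd_D,bias_D,bias_sd_D,loa_low_D,loa_high_D,pearson_r
CHM,37.72,2.07,NA,NA,NA,NA,NA
Km,38.50,1.77,0.78,0.58,-0.35,1.91,0.967
TNP,36.79,1.86,-0.93,0.54,-1.99,0.13,0.967
EKR_4.0,37.69,1.90,-0.03,0.63,-1.27,1.22,0.952
EKR_4.5,37.69,1.90,-0.03,0.51,-1.04,0.98,0.970
TCRP_pupil_zone_2,37.00,1.86,-0.71,0.59,-1.86,0.44,0.961
TCRP_pupil_zone_4,37.01,1.88,-0.70,0.49,-1.66,0.25,0.974
TCRP_pupil_zone_6,37.51,1.77,-0.21,0.60,-1.38,0.96,0.964
TCRP_pupil_ring_2,36.96,1.88,-0.76,0.52,-1.77,0.26,0.970
TCRP_pupil_ring_4,37.20,1.86,-0.52,0.53,-1.55,0.51,0.969
TCRP_pupil_ring_6,38.70,1.56,0.99,1.03,-1.00,3.00,0.874
TCRP_apex_zone_2,37.03,1.85,-0.69,0.61,-1.88,0.50,0.958
TCRP_apex_zone_4,37.06,1.85,-0.66,0.51,-1.66,0.35,0.972
TCRP_apex_zone_6,37.56,1.74,-0.15,0.63,-1.39,1.08,0.960
TCRP_apex_ring_2,36.99,1.86,-0.73,0.54,-1.79,0.34,0.967
TCRP_apex_ring_4,37.26,1.83,-0.45,0.55,-1.53,0.63,0.967
TCRP_apex_ring_6,38.75,1.54,1.04,1.06,-1.00,3.10,0.868
K_Haigis,37.30,1.98,-0.42,0.53,-1.45,0.62,0.967
K_Shammas,37.09,2.02,-0.63,0.53,-1.66,0.41,0.967
modTCRP_pupil_zone_4,37.71,1.88,0.00,0.49,-0.96,0.95,0.974
modTCRP_apex_zone_4,37.76,1.85,0.04,0.51,-0.96,1.05,0.972
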