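# Reference summary: four TCRP variants by diameter, post-SMILE study cohort (n = 40)
diameter_mm,variant,mean_D,sd_D
1,TCRP_pupil_zone,37.04,1.85
1,TCRP_pupil_ring,37.03,1.85
1,TCRP_apex_zone,37.06,1.86
1,TCRP_apex_ring,37.04,1.85
2,TCRP_pupil_zone,37.00,1.86
2,TCRP_pupil_ring,36.96,1.88
2,TCRP_apex_zone,37.03,1.85
2,TCRP_apex_ring,36.99,1.86
3,TCRP_pupil_zone,36.97,1.88
3,TCRP_pupil_ring,36.97,1.91
3,TCRP_apex_zone,37.00,1.86
3,TCRP_apex_ring,36.97,1.88
4,TCRP_pupil_zone,37.01,1.88
4,TCRP_pupil_ring,37.20,1.86
4,TCRP_apex_zone,37.06,1.85
4,TCRP_apex_ring,37.26,1.83
5,TCRP_pupil_zone,37.17,1.85
5,TCRP_pupil_ring,37.73,1.73
5,TCRP_apex_zone,37.23,1.82
5,TCRP_apex_ring,37.81,1.69
6,TCRP_pupil_zone,37.51,1.77
6,TCRP_pupil_ring,38.70,1.56
6,TCRP_apex_zone,37.56,1.74
6,TCRP_apex_ring,38.75,1.54
7,TCRP_pupil_zone,38.03,1.66
7,TCRP_pupil_ring,40.08,1.50
7,TCRP_apex_zone,38.07,1.64
7,TCRP_apex_ring,40.10,1.49
8,TCRP_pupil_zone,38.82,1.62
8,TCRP_pupil_ring,41.79,1.64
8,TCRP_apex_zone,38.77,1.56
8,TCRP_apex_ring,41.85,1.61
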