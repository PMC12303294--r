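cancer,gender,curvature,a0,a1,a2,a3,r_squared,k_p,k_q,coef_consistent
Nasopharynx,male,convex,-0.54,2.797,0.73,0.14,0.9856,0.583,0.425,TRUE
Other pharynx,male,convex,-0.485,2.844,0.47,0.33,0.9923,0.616,0.763,FALSE
Nasopharynx,female,convex,-1.36,2.797,0.73,0.14,0.9756,0.257,0.187,TRUE
Other pharynx,female,convex,-0.642,2.5295,0.77,0.11,0.9838,0.526,1.464,FALSE
Nasopharynx,both,convex,-0.845,2.797,0.73,0.14,0.9847,0.429,0.313,TRUE
Other pharynx,both,convex,-0.277,2.814,0.69,0.16,0.9916,0.758,0.910,FALSE
Hodgkin lymphoma,male,concave,-0.036,0.1405,0.007,2.1,0.9956,0.964,0.007,TRUE
Leukemia,male,concave,1.15,-0.8291,0.09,2.75,0.9941,3.158,0.284,TRUE
Hodgkin lymphoma,female,concave,0.7843,-1.6493,0.039,2.9,0.9920,2.191,0.085,TRUE
Leukemia,female,concave,0.8742,-0.8291,0.11,2.75,0.9925,2.397,0.264,TRUE
Hodgkin lymphoma,both,concave,0.1634,-0.3739,0.025,2.1,0.9863,1.178,0.029,TRUE
Leukemia,both,concave,0.6742,-0.8291,0.11,2.75,0.9925,2.397,0.264,FALSE
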