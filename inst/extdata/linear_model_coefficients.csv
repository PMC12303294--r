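cancer,gender,intercept,slope,r_squared
Bladder,male,-1.236,2.644,0.999
Bladder,female,-1.713,2.114,0.995
Bladder,both,-1.457,2.499,0.998
"Brain, Nervous system",male,0.029,1.216,0.987
"Brain, Nervous system",female,-0.155,1.167,0.984
"Brain, Nervous system",both,-0.058,1.194,0.985
Colorectum,male,0.461,2.203,0.997
Colorectum,female,0.523,1.945,0.994
Colorectum,both,0.485,2.089,0.996
Gallbladder,male,-2.290,2.415,0.998
Gallbladder,female,-1.491,2.042,0.996
Gallbladder,both,-1.829,2.197,0.998
Kidney,male,-1.230,2.234,0.937
Kidney,female,-1.323,1.884,0.921
Kidney,both,-1.274,2.094,0.932
Larynx,male,-1.204,2.291,0.973
Larynx,female,-2.311,1.677,0.996
Larynx,both,-1.586,2.172,0.981
"Lip, Oral cavity",male,-1.745,2.540,0.956
"Lip, Oral cavity",female,-1.972,2.193,0.981
"Lip, Oral cavity",both,-1.839,2.405,0.966
Liver,male,-1.079,2.713,0.963
Liver,female,-2.080,2.642,0.987
Liver,both,-1.449,2.690,0.970
Lung,male,0.139,2.693,0.993
Lung,female,-0.129,2.319,0.992
Lung,both,0.006,2.565,0.993
Melanoma of skin,male,-0.370,1.598,0.991
Melanoma of skin,female,0.262,1.078,0.990
Melanoma of skin,both,-0.035,1.336,0.992
Multiple myeloma,male,-2.159,2.304,0.996
Multiple myeloma,female,-2.257,2.171,0.999
Multiple myeloma,both,-2.205,2.243,0.998
Non-Hodgkin lymphoma,male,-0.187,1.875,0.980
Non-Hodgkin lymphoma,female,-0.578,1.625,0.987
Non-Hodgkin lymphoma,both,-0.362,1.619,0.983
Oesophagus,male,-0.621,2.404,0.986
Oesophagus,female,-1.482,2.243,0.996
Oesophagus,both,-0.957,2.358,0.989
Pancreas,male,-1.438,2.476,0.996
Pancreas,female,-1.663,2.370,0.999
Pancreas,both,-1.536,2.427,0.999
Stomach,male,0.128,2.321,0.991
Stomach,female,0.046,1.843,0.990
Stomach,both,0.080,2.143,0.992
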