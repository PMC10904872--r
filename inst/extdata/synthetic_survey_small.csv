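site_id,x,y,metal,concentration_ug_L,censored,lod_ug_L
S001,87.75,0.19,Pb,17.379,FALSE,0.8
S002,76.85,74.28,Pb,2.97,FALSE,0.8
S003,27.9,19.24,Pb,8.49,FALSE,0.8
S004,52.92,45.21,Pb,6.158,FALSE,0.8
S005,96.29,32.21,Pb,13.582,FALSE,0.8
S006,98.04,10.91,Pb,8.195,FALSE,0.8
S007,9.13,28.93,Pb,3.882,FALSE,0.8
S008,7.07,81.95,Pb,9.014,FALSE,0.8
S009,32.76,49.2,Pb,11.038,FALSE,0.8
S010,37.01,3.03,Pb,2.817,FALSE,0.8
S011,71.55,44.02,Pb,16.023,FALSE,0.8
S012,75.78,7.73,Pb,16.023,FALSE,0.8
S001,87.75,0.19,Cr,50.344,FALSE,0.15
S002,76.85,74.28,Cr,23.539,FALSE,0.15
S003,27.9,19.24,Cr,50.052,FALSE,0.15
S004,52.92,45.21,Cr,29.088,FALSE,0.15
S005,96.29,32.21,Cr,47.648,FALSE,0.15
S006,98.04,10.91,Cr,26.763,FALSE,0.15
S007,9.13,28.93,Cr,45.27,FALSE,0.15
S008,7.07,81.95,Cr,32.927,FALSE,0.15
S009,32.76,49.2,Cr,48.423,FALSE,0.15
S010,37.01,3.03,Cr,32.713,FALSE,0.15
S011,71.55,44.02,Cr,49.64,FALSE,0.15
S012,75.78,7.73,Cr,42.767,FALSE,0.15
S001,87.75,0.19,Cd,2.836,FALSE,0.22
S002,76.85,74.28,Cd,3.419,FALSE,0.22
S003,27.9,19.24,Cd,2.991,FALSE,0.22
S004,52.92,45.21,Cd,2.72,FALSE,0.22
S005,96.29,32.21,Cd,2.967,FALSE,0.22
S006,98.04,10.91,Cd,2.879,FALSE,0.22
S007,9.13,28.93,Cd,2.577,FALSE,0.22
S008,7.07,81.95,Cd,3.057,FALSE,0.22
S009,32.76,49.2,Cd,2.448,FALSE,0.22
S010,37.01,3.03,Cd,2.844,FALSE,0.22
S011,71.55,44.02,Cd,2.67,FALSE,0.22
S012,75.78,7.73,Cd,3.505,FALSE,0.22
S001,87.75,0.19,Ni,60.406,FALSE,0.3
S002,76.85,74.28,Ni,66.348,FALSE,0.3
S003,27.9,19.24,Ni,76.953,FALSE,0.3
S004,52.92,45.21,Ni,62.488,FALSE,0.3
S005,96.29,32.21,Ni,59.971,FALSE,0.3
S006,98.04,10.91,Ni,74.613,FALSE,0.3
S007,9.13,28.93,Ni,60.891,FALSE,0.3
S008,7.07,81.95,Ni,74.262,FALSE,0.3
S009,32.76,49.2,Ni,55.545,FALSE,0.3
S010,37.01,3.03,Ni,82.117,FALSE,0.3
S011,71.55,44.02,Ni,58.461,FALSE,0.3
S012,75.78,7.73,Ni,72.877,FALSE,0.3
S001,87.75,0.19,As,4.731,FALSE,2
S002,76.85,74.28,As,6.061,FALSE,2
S003,27.9,19.24,As,8.811,FALSE,2
S004,52.92,45.21,As,9.893,FALSE,2
S005,96.29,32.21,As,3.018,FALSE,2
S006,98.04,10.91,As,4.845,FALSE,2
S007,9.13,28.93,As,2.919,FALSE,2
S008,7.07,81.95,As,10.019,FALSE,2
S009,32.76,49.2,As,3.265,FALSE,2
S010,37.01,3.03,As,7.563,FALSE,2
S011,71.55,44.02,As,2.994,FALSE,2
S012,75.78,7.73,As,3.597,FALSE,2
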