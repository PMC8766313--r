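scan_id,days,cat1,cat2,cat3,cat4,cat5,cat6,cat7,cat8,cat9,cat10
scan01,7,41.70,36.36,21.55,9.59,6.46,4.16,1.76,0.43,0.09,0.05
scan02,34,0.41,17.96,45.77,29.79,12.76,5.81,3.50,1.66,0.64,0.04
scan03,83,17.96,36.52,33.79,13.93,6.27,3.33,2.04,1.07,0.21,0.05
scan04,138,1.10,31.22,39.06,26.28,12.03,6.50,3.46,1.60,0.60,0.08
scan05,250,2.50,36.33,37.25,25.14,12.16,7.42,4.34,2.11,0.68,0.20
scan06,446,3.43,40.58,37.42,25.22,12.50,7.85,4.45,3.32,1.45,0.35
scan07,656,3.04,36.20,31.18,28.78,15.85,9.15,4.76,3.61,2.47,0.98
scan08,1027,3.22,38.04,30.87,23.40,12.87,8.97,5.53,5.01,4.34,1.94
scan09,1384,3.89,39.48,34.27,25.99,15.22,10.69,6.74,4.65,4.21,1.90
scan10,1734,4.73,38.00,33.79,25.83,15.32,10.51,7.54,4.81,4.17,2.38
scan11,1937,4.38,39.47,32.04,26.55,15.70,11.24,7.59,5.49,3.63,1.79
scan12,2112,3.45,35.72,36.63,27.69,15.52,9.97,7.92,6.10,4.01,2.31
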