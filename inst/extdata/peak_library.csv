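name,ppm,rel_area
Phenylpyruvic acid,7.49,1
Phenylpyruvic acid,3.85,0.4
D-Mandelic acid,5,0.2
D-Mandelic acid,7.4,1
2-Furoylglycine,7.65,1
2-Furoylglycine,6.6,0.5
Tartaric acid,4.34,1
Phenylacetic acid,7.3,1
Phenylacetic acid,3.55,0.6
Glycine,3.56,1
Methionine,2.13,1
Methionine,2.64,0.6
Acetic acid,1.92,1
Phenylalanine,7.37,1
Phenylalanine,3.28,0.3
Neopterin,8.78,1
2PY and 4PY,8.33,1
2PY and 4PY,6.66,0.6
L-Citramalic acid,1.32,1
L-Citramalic acid,2.55,0.5
Maleic acid,6.26,1
Adenine,8.19,1
Adenine,8.22,0.9
1-Methylnicotinamide,9.27,1
1-Methylnicotinamide,4.47,0.8
2-Hydroxyisovaleric acid,0.84,1
2-Hydroxyisovaleric acid,0.97,0.9
Oxaloacetic acid,2.38,1
3-Methylglutaconic acid,2.16,1
Valine,0.98,1
Valine,1.04,0.9
Acetoacetic acid,2.27,1
Acetoacetic acid,3.43,0.5
Guanidinoacetic acid,3.79,1
Creatine,3.93,1
Dimethylamine,2.72,1
Allantoin,6.05,0.2
Allantoin,8,1
Null metabolite 01,4.236,1
Null metabolite 02,8.714,1
Null metabolite 02,8.965,0.88
Null metabolite 03,2.864,1
Null metabolite 04,8.669,1
Null metabolite 04,6.529,0.87
Null metabolite 05,6.5,1
Null metabolite 06,0.777,1
Null metabolite 06,7.593,0.63
Null metabolite 07,8.806,1
Null metabolite 08,7.943,1
Null metabolite 09,1.595,1
Null metabolite 10,0.962,1
Null metabolite 11,3.928,1
Null metabolite 11,2.746,0.42
Null metabolite 12,9,1
Null metabolite 12,9.299,0.78
Null metabolite 13,6.563,1
Null metabolite 14,3.168,1
Null metabolite 15,8.649,1
Null metabolite 16,6.387,1
Null metabolite 16,6.609,0.64
Null metabolite 17,9.027,1
Null metabolite 18,1.262,1
Null metabolite 18,4.201,0.89
Null metabolite 19,1.681,1
Null metabolite 19,8.792,0.59
Null metabolite 20,8.963,1
Null metabolite 20,3.627,0.46
Null metabolite 21,3.323,1
Null metabolite 22,1.401,1
Null metabolite 23,2.822,1
Null metabolite 24,8.505,1
Null metabolite 24,6.742,0.9
Null metabolite 25,1.938,1
Null metabolite 26,7.478,1
Null metabolite 26,2.052,0.87
Null metabolite 27,6.234,1
Null metabolite 28,1.817,1
Null metabolite 29,8.007,1
Null metabolite 30,2.8,1
Null metabolite 30,6.766,0.56
Null metabolite 31,7.503,1
Null metabolite 32,2.654,1
Null metabolite 32,3.361,0.47
Null metabolite 33,1.946,1
Null metabolite 34,2.704,1
Null metabolite 35,3.335,1
Null metabolite 36,2.003,1
Null metabolite 37,8.534,1
Null metabolite 37,3.732,0.64
Null metabolite 38,6.458,1
Null metabolite 39,2.759,1
Null metabolite 39,1.706,0.37
Null metabolite 40,8.015,1
Null metabolite 40,3.736,0.69
Null metabolite 41,7.361,1
Null metabolite 42,8.614,1
Null metabolite 43,8.458,1
Null metabolite 44,0.709,1
Null metabolite 44,7.884,0.57
Null metabolite 45,8.815,1
Null metabolite 46,3.402,1
Null metabolite 46,9.001,0.49
Null metabolite 47,4.043,1
Null metabolite 47,7.826,0.46
Null metabolite 48,1.813,1
Null metabolite 49,4.139,1
Null metabolite 49,1.238,0.59
Null metabolite 50,2.782,1
Null metabolite 50,2.836,0.85
Null metabolite 51,1.179,1
Null metabolite 52,2.709,1
Null metabolite 52,3.532,0.69
Null metabolite 53,8.751,1
Null metabolite 54,8.75,1
Null metabolite 55,0.703,1
Null metabolite 56,3.54,1
Null metabolite 56,2.766,0.33
Null metabolite 57,2.31,1
Null metabolite 57,8.528,0.55
Null metabolite 58,0.77,1
Null metabolite 58,8.963,0.74
Null metabolite 59,7.748,1
Null metabolite 60,4.339,1
Null metabolite 61,0.779,1
Null metabolite 61,3.654,0.67
Null metabolite 62,8.827,1
Null metabolite 63,3.376,1
Null metabolite 64,0.94,1
Null metabolite 64,6.166,0.36
Null metabolite 65,6.304,1
Null metabolite 65,8.661,0.8
Null metabolite 66,7.554,1
Null metabolite 67,9.283,1
Null metabolite 68,7.123,1
Null metabolite 69,7.974,1
Null metabolite 70,1.949,1
Null metabolite 71,2.659,1
Null metabolite 72,9.293,1
Null metabolite 72,6.759,0.61
Null metabolite 73,6.405,1
Null metabolite 73,8.234,0.69
Null metabolite 74,1.363,1
Null metabolite 74,3.362,0.56
Creatinine,3.05,1
Creatinine,4.06,0.67
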