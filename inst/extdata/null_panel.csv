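name,n_control,mean_control,sd_control,n_case,mean_case,sd_case,lod
Null metabolite 01,51,16.749,37.145,51,16.749,37.145,0
Null metabolite 02,51,3.443,6.391,51,3.443,6.391,0
Null metabolite 03,51,2.378,2.06,51,2.378,2.06,0
Null metabolite 04,51,2.418,3.357,51,2.418,3.357,0
Null metabolite 05,51,12.738,9.01,51,12.738,9.01,0
Null metabolite 06,51,4.624,10.86,51,4.624,10.86,0
Null metabolite 07,51,7.371,10.009,51,7.371,10.009,0
Null metabolite 08,51,124.462,285.092,51,124.462,285.092,0
Null metabolite 09,51,1.54,3.373,51,1.54,3.373,0
Null metabolite 10,51,3.764,7.843,51,3.764,7.843,0
Null metabolite 11,51,1.115,1.67,51,1.115,1.67,0
Null metabolite 12,51,23.385,27.022,51,23.385,27.022,0
Null metabolite 13,51,10.468,18.256,51,10.468,18.256,0
Null metabolite 14,51,24.373,33.478,51,24.373,33.478,0
Null metabolite 15,51,1.159,2.079,51,1.159,2.079,0
Null metabolite 16,51,3.155,7.287,51,3.155,7.287,0
Null metabolite 17,51,1.404,0.87,51,1.404,0.87,0
Null metabolite 18,51,2.282,3.409,51,2.282,3.409,0
Null metabolite 19,51,9.62,21.823,51,9.62,21.823,0
Null metabolite 20,51,28.428,61.97,51,28.428,61.97,0
Null metabolite 21,51,42.71,56.91,51,42.71,56.91,0
Null metabolite 22,51,4.482,8.848,51,4.482,8.848,0
Null metabolite 23,51,6.406,8.471,51,6.406,8.471,0
Null metabolite 24,51,2.433,1.382,51,2.433,1.382,0
Null metabolite 25,51,17.788,14.636,51,17.788,14.636,0
Null metabolite 26,51,115.549,156.127,51,115.549,156.127,0
Null metabolite 27,51,68.784,119.36,51,68.784,119.36,0
Null metabolite 28,51,3.083,3.167,51,3.083,3.167,0
Null metabolite 29,51,192.34,364.252,51,192.34,364.252,0
Null metabolite 30,51,7.926,5.389,51,7.926,5.389,0
Null metabolite 31,51,6.492,9.121,51,6.492,9.121,0
Null metabolite 32,51,153.982,357.022,51,153.982,357.022,0
Null metabolite 33,51,6.178,8.827,51,6.178,8.827,0
Null metabolite 34,51,12.004,9.129,51,12.004,9.129,0
Null metabolite 35,51,5.786,7.308,51,5.786,7.308,0
Null metabolite 36,51,15.768,8.198,51,15.768,8.198,0
Null metabolite 37,51,63.551,97.08,51,63.551,97.08,0
Null metabolite 38,51,103.628,208.43,51,103.628,208.43,0
Null metabolite 39,51,180.287,289.255,51,180.287,289.255,0
Null metabolite 40,51,69.998,158.681,51,69.998,158.681,0
Null metabolite 41,51,65.685,69.03,51,65.685,69.03,0
Null metabolite 42,51,9.259,19.379,51,9.259,19.379,0
Null metabolite 43,51,144.844,319.065,51,144.844,319.065,0
Null metabolite 44,51,164.207,105.164,51,164.207,105.164,0
Null metabolite 45,51,1.75,1.669,51,1.75,1.669,0
Null metabolite 46,51,67.663,116.405,51,67.663,116.405,0
Null metabolite 47,51,97.779,45.926,51,97.779,45.926,0
Null metabolite 48,51,143.926,167.512,51,143.926,167.512,0
Null metabolite 49,51,7.928,16.184,51,7.928,16.184,0
Null metabolite 50,51,166.03,153.443,51,166.03,153.443,0
Null metabolite 51,51,76.446,35.758,51,76.446,35.758,0
Null metabolite 52,51,6.024,12.027,51,6.024,12.027,0
Null metabolite 53,51,71.58,110.424,51,71.58,110.424,0
Null metabolite 54,51,151.753,99.84,51,151.753,99.84,0
Null metabolite 55,51,10.096,16.999,51,10.096,16.999,0
Null metabolite 56,51,134.592,107.225,51,134.592,107.225,0
Null metabolite 57,51,46.032,28.747,51,46.032,28.747,0
Null metabolite 58,51,74.426,38.448,51,74.426,38.448,0
Null metabolite 59,51,116.316,155.186,51,116.316,155.186,0
Null metabolite 60,51,2.154,2.177,51,2.154,2.177,0
Null metabolite 61,51,153.684,86.016,51,153.684,86.016,0
Null metabolite 62,51,2.093,0.924,51,2.093,0.924,0
Null metabolite 63,51,29.491,52.967,51,29.491,52.967,0
Null metabolite 64,51,6.923,14.056,51,6.923,14.056,0
Null metabolite 65,51,2.531,3.862,51,2.531,3.862,0
Null metabolite 66,51,2.051,1.859,51,2.051,1.859,0
Null metabolite 67,51,2.47,2.978,51,2.47,2.978,0
Null metabolite 68,51,1.529,1.538,51,1.529,1.538,0
Null metabolite 69,51,184.361,163.941,51,184.361,163.941,0
Null metabolite 70,51,30.592,31.482,51,30.592,31.482,0
Null metabolite 71,51,137.567,211.812,51,137.567,211.812,0
Null metabolite 72,51,38.534,49.018,51,38.534,49.018,0
Null metabolite 73,51,13.704,16.034,51,13.704,16.034,0
Null metabolite 74,51,20.347,45.235,51,20.347,45.235,0
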