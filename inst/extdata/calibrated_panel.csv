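name,n_control,mean_control,sd_control,n_case,mean_case,sd_case,lod
Phenylpyruvic acid,42,10.8,10.2,46,73.9,126.6,0
D-Mandelic acid,10,2.1,2.2,8,9.9,8.2,0
2-Furoylglycine,21,12.7,17.7,20,37.5,39.8,0
Tartaric acid,51,10.3,24.2,51,27.3,26.9,0
Phenylacetic acid,42,5.5,5.6,38,13.9,14.7,0
Glycine,51,117.8,124.1,51,282.6,342.2,0
Methionine,13,3.6,1.4,12,8.4,8.6,0
Acetic acid,51,8.9,7.2,51,17.2,13.3,0
Phenylalanine,42,21.0,18.3,47,39.7,21.4,0
Neopterin,51,3.0,5.3,51,5.2,7.6,0
2PY and 4PY,51,5.9,3.5,51,10.1,5.3,0
L-Citramalic acid,51,18.5,12.0,51,31.8,24.9,0
Maleic acid,50,1.1,1.9,51,1.7,2.2,0
Adenine,45,2.0,2.0,50,3.2,3.7,0
1-Methylnicotinamide,51,9.4,9.0,51,13.6,16.0,0
2-Hydroxyisovaleric acid,36,1.2,0.7,31,1.7,1.1,0
Oxaloacetic acid,50,27.8,26.9,47,38.8,25.1,0
3-Methylglutaconic acid,51,5.6,2.9,51,7.8,4.4,0
Valine,51,4.6,2.9,51,6.4,5.2,0
Acetoacetic acid,46,11.8,9.9,48,16.1,8.5,0
Guanidinoacetic acid,51,93.1,71.5,50,74.1,67.7,0
Creatine,49,201.4,370.1,49,160.2,269.7,0
Dimethylamine,51,40.2,27.2,51,30.3,20.6,0
Allantoin,51,16.2,11.3,48,7.1,5.9,0
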