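"feature","circle2d","sphere3d"
"Global Variance",191.134375,122.94266756499
"Skewness",0.213003864729341,-0.0259520687601775
"Kurtosis",2.77251171571019,2.92217271591378
"Energy",0.00313150424380367,0.000891059116087966
"Contrast",276.982293767214,180.949281845872
"Entropy",8.52410850207288,10.5591092136805
"Homogeneity",0.151138863209354,0.169858329643744
"Correlation",0.276798817645773,0.254248192960365
"Sum Average",53.5363586854056,67.2844861972902
"Variance",191.497401086623,121.320042497903
"Dissimilarity",13.2922371446488,10.6373940244489
"Autocorrelation",769.541679526116,1162.6459222833
"SRE",0.975806451612903,0.98085273764992
"LRE",1.09677419354839,1.07871060328139
"GLN",2.50161290322581,13.4872351665465
"RLN",72.6612903225806,476.158122583997
"RP",0.96875,0.974736169319675
"LGRE",0.0326279586216121,0.00396116865987104
"HGRE",909.332258064516,1255.43272105907
"SRLGE",0.0324762740411541,0.00393782446367791
"SRHGE",894.537903225806,1232.77288210706
"LRLGE",0.0332346969434441,0.00405704634084806
"LRHGE",968.509677419355,1348.22696936401
"GLV",193.683465140479,124.368714291139
"RLV",0.0312174817898023,0.0262015583011966
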