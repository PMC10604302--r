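dataset,n,indicator,mu0,mu1,m0,m1,s0,s1,p_wmw
cleveland,282,ALPHA,0.0038,0.0040,0.0029,0.0033,0.0029,0.0033,0.4837
cleveland,282,ALPHA2,5.8280,5.7834,5.8284,5.7121,0.7035,0.7473,0.4837
cleveland,282,HM,88.2808,79.0296,51.6722,42.4812,118.2997,94.5672,0.3004
cleveland,282,MAP,105.1306,108.0998,105.9115,107.8869,11.6754,11.6864,0.0793
cleveland,282,PBPI,0.5439,0.5692,0.5294,0.5556,0.1824,0.1760,0.2434
cleveland,282,PBPIRC,19.3680,19.8608,15.7457,17.3187,12.5346,11.7759,0.5273
cleveland,282,RC,0.0339,0.0340,0.0329,0.0325,0.0115,0.0113,0.9683
hungarian,294,ALPHA,0.0048,0.0047,0.0039,0.0038,0.0043,0.0035,0.7747
hungarian,294,ALPHA2,5.5739,5.5588,5.5552,5.5628,0.6453,0.6335,0.7747
hungarian,294,HM,53.8264,55.4877,38.9873,37.2640,51.6480,77.3438,0.2751
hungarian,294,MAP,105.4446,108.6070,102.9850,108.0512,11.4091,12.3450,0.0262
hungarian,294,PBPI,0.5639,0.5971,0.5500,0.5556,0.1502,0.2195,0.1196
hungarian,294,PBPIRC,21.7992,22.9755,18.6552,19.2456,13.1868,18.9023,0.6145
hungarian,294,RC,0.0295,0.0300,0.0280,0.0291,0.0081,0.0080,0.5268
longbeach,200,ALPHA,0.0038,0.0044,0.0029,0.0039,0.0030,0.0028,0.1033
longbeach,200,ALPHA2,5.8083,5.8785,5.8440,5.5574,0.6754,3.0681,0.1033
longbeach,200,HM,67.7813,47.4181,44.0492,34.3783,69.1907,49.5149,0.0886
longbeach,200,MAP,102.7137,106.1425,99.0182,104.4601,13.1111,11.7342,0.1067
longbeach,200,PBPI,0.6404,0.6842,0.6085,0.6500,0.2085,0.2005,0.2863
longbeach,200,PBPIRC,23.5717,25.9667,20.7905,21.8479,15.9530,13.7833,0.2079
longbeach,200,RC,0.0327,0.0299,0.0307,0.0288,0.0106,0.0083,0.1720
switzerland,123,ALPHA,0.0039,0.0038,0.0042,0.0026,0.0031,0.0036,0.9293
switzerland,123,ALPHA2,5.9888,5.9288,5.4949,5.9362,1.1305,0.8388,0.9293
switzerland,123,HM,197.6817,112.8445,33.3719,56.5868,285.4129,166.4005,0.9293
switzerland,123,MAP,98.9302,104.4039,102.2406,102.0779,16.6840,14.5477,0.5347
switzerland,123,PBPI,0.5972,0.5976,0.6587,0.5714,0.2409,0.2411,0.7942
switzerland,123,PBPIRC,22.1667,21.8520,26.9187,15.5101,13.9135,19.4161,0.6276
switzerland,123,RC,0.0355,0.0358,0.0247,0.0341,0.0161,0.0134,0.5839
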