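# synthetic_vcg_loop.csv - synthetic vectorcardiogram-like loop
# columns: x,y,z (mV); generated by the package authors, not real data
0,0,0
0.191,0.1474,-0.0028
0.3776,0.2846,-0.0113
0.5558,0.4022,-0.0253
0.7216,0.4925,-0.0447
0.8716,0.5498,-0.0692
1.0029,0.5711,-0.0986
1.113,0.556,-0.1326
1.2004,0.507,-0.1707
1.2642,0.4289,-0.2126
1.304,0.3284,-0.2577
1.3205,0.2138,-0.3056
1.3147,0.0935,-0.3557
1.2885,-0.0239,-0.4074
1.2439,-0.1307,-0.4601
1.1836,-0.2207,-0.5133
1.1105,-0.2895,-0.5664
1.0274,-0.335,-0.6187
0.9374,-0.3568,-0.6696
0.8432,-0.3569,-0.7187
0.7475,-0.3385,-0.7652
0.6524,-0.3059,-0.8088
0.5599,-0.2642,-0.8488
0.4711,-0.2181,-0.8849
0.387,-0.172,-0.9167
0.3078,-0.1291,-0.9437
0.2335,-0.0915,-0.9657
0.1634,-0.0598,-0.9824
0.0967,-0.0334,-0.9936
0.032,-0.0107,-0.9993
-0.032,0.0107,-0.9993
-0.0967,0.0334,-0.9936
-0.1634,0.0598,-0.9824
-0.2335,0.0915,-0.9657
-0.3078,0.1291,-0.9437
-0.387,0.172,-0.9167
-0.4711,0.2181,-0.8849
-0.5599,0.2642,-0.8488
-0.6524,0.3059,-0.8088
-0.7475,0.3385,-0.7652
-0.8432,0.3569,-0.7187
-0.9374,0.3568,-0.6696
-1.0274,0.335,-0.6187
-1.1105,0.2895,-0.5664
-1.1836,0.2207,-0.5133
-1.2439,0.1307,-0.4601
-1.2885,0.0239,-0.4074
-1.3147,-0.0935,-0.3557
-1.3205,-0.2138,-0.3056
-1.304,-0.3284,-0.2577
-1.2642,-0.4289,-0.2126
-1.2004,-0.507,-0.1707
-1.113,-0.556,-0.1326
-1.0029,-0.5711,-0.0986
-0.8716,-0.5498,-0.0692
-0.7216,-0.4925,-0.0447
-0.5558,-0.4022,-0.0253
-0.3776,-0.2846,-0.0113
-0.191,-0.1474,-0.0028
-0,-0,0
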