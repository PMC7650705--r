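trait,method,ability,accuracy
BW6,GBLUP,0.164,0.277
BW6,BayesA,0.171,0.289
BW6,BayesB,0.194,0.328
BW6,BayesC,0.177,0.299
BW6,BayesLasso,0.164,0.277
WH6,GBLUP,0.295,0.391
WH6,BayesA,0.255,0.338
WH6,BayesB,0.268,0.355
WH6,BayesC,0.243,0.322
WH6,BayesLasso,0.286,0.379
BL6,GBLUP,0.198,0.265
BL6,BayesA,0.205,0.274
BL6,BayesB,0.237,0.317
BL6,BayesC,0.246,0.329
BL6,BayesLasso,0.219,0.293
CG6,GBLUP,0.146,0.234
CG6,BayesA,0.201,0.322
CG6,BayesB,0.207,0.331
CG6,BayesC,0.210,0.336
CG6,BayesLasso,0.179,0.287
BW12,GBLUP,0.097,0.198
BW12,BayesA,0.094,0.192
BW12,BayesB,0.104,0.212
BW12,BayesC,0.103,0.210
BW12,BayesLasso,0.161,0.329
WH12,GBLUP,0.112,0.239
WH12,BayesA,0.079,0.168
WH12,BayesB,0.083,0.177
WH12,BayesC,0.097,0.207
WH12,BayesLasso,0.132,0.281
BL12,GBLUP,0.044,0.166
BL12,BayesA,0.044,0.166
BL12,BayesB,0.041,0.155
BL12,BayesC,0.039,0.147
BL12,BayesLasso,0.043,0.163
CG12,GBLUP,0.129,0.220
CG12,BayesA,0.110,0.220
CG12,BayesB,0.163,0.326
CG12,BayesC,0.106,0.212
CG12,BayesLasso,0.110,0.220
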