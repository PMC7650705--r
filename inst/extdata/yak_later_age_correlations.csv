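method,pearson_r
GBLUP,0.407
BayesA,0.422
BayesB,0.403
BayesC,0.405
BayesLasso,0.374
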