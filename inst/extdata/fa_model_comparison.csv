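model,n_vc,logLik
fa1,24,-214.93
fa2,35,-194.68
fa3,43,-187.81
fa4,51,-180.11
fa5,59,-174.09
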