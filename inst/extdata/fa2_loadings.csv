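location,year,fa1,fa2,cum_pct
BM,2017,0.61,0.34,56.01
BM,2018,1.05,-0.22,78.87
KUT,2017,0.41,0.28,38.15
KUT,2018,0.79,-0.25,57.45
OSK,2017,1.09,0.21,49.10
OSK,2018,0.77,-0.38,75.76
RUG,2017,0.92,0.65,90.35
RUG,2018,1.04,-0.62,80.88
SAS,2017,1.07,0.37,72.08
SAS,2018,1.14,-0.40,29.92
TOV,2017,0.85,0.51,72.77
TOV,2018,0.65,-0.22,45.05
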