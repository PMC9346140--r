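condition,aoi,observed_fixation_prob
TOV,SVS,0.66
TOV,IP,0
TOV,ND,0.18
TOV,DL,0.03
TOV,OW,0.12
TOI,SVS,0.8
TOI,IP,0
TOI,ND,0.14
TOI,DL,0.04
TOI,OW,0.02
TSV,SVS,0.68
TSV,IP,0.05
TSV,ND,0.15
TSV,DL,0.04
TSV,OW,0.07
TSI,SVS,0.71
TSI,IP,0.07
TSI,ND,0.12
TSI,DL,0.04
TSI,OW,0.06
DOV,SVS,0.65
DOV,IP,0
DOV,ND,0.17
DOV,DL,0.09
DOV,OW,0.1
DOI,SVS,0.68
DOI,IP,0
DOI,ND,0.18
DOI,DL,0.11
DOI,OW,0.03
DSV,SVS,0.29
DSV,IP,0.28
DSV,ND,0.24
DSV,DL,0.11
DSV,OW,0.07
DSI,SVS,0.33
DSI,IP,0.27
DSI,ND,0.26
DSI,DL,0.09
DSI,OW,0.06
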