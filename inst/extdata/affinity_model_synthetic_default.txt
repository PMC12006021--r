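# Synthetic default coefficients for the linear contact-based affinity
# model (kcal/mol; one coefficient per element-pair contact class at the
# 10.5 A cutoff). These are illustrative values chosen by the package
# authors so the predictor is usable out of the box; they are NOT a
# published calibration. Replace this file (read_affinity_model) with a
# fitted model for quantitative work.
intercept = -2.0
CC = -0.020
CN = -0.013
CO = -0.016
CX = -0.010
NN = -0.009
NO = -0.012
NX = -0.007
OO = -0.008
OX = -0.006
XX = -0.005
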