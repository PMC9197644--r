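model,accuracy,recall
svm,0.6275,0.6515
linear_svm,0.6598,0.6702
rbfnn,0.7609,0.7122
rf,0.7567,0.6547
elm,0.7912,0.7687
ielm,0.8728,0.8913
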