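taxon	diploid_number	formula
caroni_Capri	48	19M, 4sM, 1sT
caroni_Palermo	48	19M, 5sM
elegans	48	16M, 6sM, 2T
pyramidata	48	20M, 4sM
trochoides	48	16M, 7sM, 1T
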