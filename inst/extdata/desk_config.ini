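# Desk-scale end-to-end run: seven-generation crossing plan with a
# bulk-segregant F1 pool experiment (10,000 segregants, 1% survival).
# Trait loci default to the packaged two-locus architecture
# (major chrIV ~530 kbp, minor chrIX ~115 kbp).

[genome]
n_markers = 2000
recomb_rate = 0.35

[trait]
noise_sd = 0.1

[plan]
steps = F1:founder:10000:1.5;F2:CENPK:1232:1.5;F3:BY:1232:1.5;F4:BY:1232:1.5;F5:BY:1232:1.5;F6:BY:1232:1.5;F7:BY:1232:1.5

[sequencing]
depth = 100
survival_fraction = 0.01
selection_conc = 1.5

[seed]
seed = 1
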