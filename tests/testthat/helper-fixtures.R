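# Shared fixtures: the model genes used throughout the suite.

# two-intron gene with a cassette exon flanked by long introns; with speed
# 6 kb/min its first phase lasts 0.55 min, with 1.5 kb/min 2.2 min
two_intron_gene <- function()
  gene_structure(c(300, 300, 300), c(3000, 3000), "model2i")

# cassette exon with a short downstream intron: the regulatable configuration
short_down_gene <- function()
  gene_structure(c(300, 150, 300), c(3000, 300), "shortdown")

three_intron_gene <- function()
  gene_structure(c(200, 100, 100, 200), c(500, 800, 500), "model3i")

# closed-form skipping probability of the two-intron gene in the
# pairing-only model: only the constitutive excision of intron 1 (rate k)
# runs during phase I of length T1; afterwards the three equal-rate pairings
# compete, skipping with probability 1/3
skip_closed_form <- function(k, T1) exp(-k * T1) / 3
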