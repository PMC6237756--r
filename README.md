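# ctsplice

Kinetic Markov-chain modeling of co-transcriptional alternative splicing.

Cassette exons — internal exons that are either included in or skipped from
the mature mRNA — are decided by a race: the 5′ splice site of an upstream
intron can pair constitutively with its own 3′ site, or pair across the exon
with a downstream 3′ site, skipping it. Because splicing starts while RNA
polymerase II is still elongating, downstream splice sites do not exist yet
when upstream ones become reactive, and the elongation rate sets how long
the constitutive reaction runs unopposed. `ctsplice` turns this picture into
a continuous-time Markov chain with absorbing states and computes exact
isoform probabilities for it.

## The model

A gene is just its exon/intron lengths. For `N` introns the chain's
reactions are:

- availability of the 5′/3′ splice sites of intron *i*, rates *k₅′(i)*,
  *k₃′(i)* (min⁻¹) — the full engine, up to 3 introns;
- pairing of an available 5′ site of intron *i* with an available 3′ site of
  intron *j ≥ i*, rate *k_p(i,j)*, excising everything in between — the
  simple engine keeps only these and scales to 9 introns.

Transcription is split into phases whose durations are segment lengths over
the elongation speed (kb/min); within a phase the state distribution is
propagated as β·e^{GT} (matrix exponential of the phase generator), and
after the final phase the chain is solved to its absorbing limit. The
`2^(N−1)` fully spliced isoforms are recovered by collapsing absorbing
microstates. Optional rate rules encode intron definition
(*k_p(L) = k_p0·(200/max(L,200))^{1/2}*, penalizing pairing across segments
longer than 200 nt) and exon definition (a 3′ availability that switches
fast once the 5′ site across the exon is available), plus polymerase pauses
with phase-local rate overrides. A seeded Gillespie simulator of the same
reaction system serves as an independent stochastic oracle.

## Worked example

The two-intron model gene — a 300 nt cassette exon flanked by 3 kb introns,
all pairing rates 1 min⁻¹:

```r
library(ctsplice)
g   <- gene_structure(c(300, 300, 300), c(3000, 3000), "model2i")
r   <- splice_rates(2, kp0 = 1)

fit <- ctsplice(g, r, elongation = elongation_profile(6))   # 6 kb/min
fit
#> Co-transcriptional splicing fit (simple model)
#> Gene 'model2i': 2 introns; speed 6 kb/min
#> Isoform probabilities:
#>   1          (0 skipped)  0.8077
#>   0          (1 skipped)  0.1923

sapply(c(Inf, 6, 1.5), function(speed)
  1 - inclusion(ctsplice(g, r, elongation = elongation_profile(speed)), 2))
#> [1] 0.33333333 0.19231665 0.03693439
```

With instantaneous elongation (pure post-transcriptional splicing) the three
equal-rate pairings compete symmetrically and the exon is skipped 33% of the
time. Co-transcriptional elongation protects the exon: at 6 kb/min the
first phase (3.3 kb → 0.55 min) is reserved for the constitutive excision of
intron 1 and skipping falls to 19%; at 1.5 kb/min (2.2 min) it falls to 4%.
These match the closed form skip = ⅓·e^(−kp·T₁).

`simulate(fit, nsim = 1e5, seed = 1)` replays the same system stochastically;
`run_batch(sample_genes(species_length_profile("fly-like"), 100, 6, seed = 1))`
scores fidelity across a synthetic cohort under PTS/CTS with and without
intron definition. A shell entry point with `simulate`, `sweep`, `batch` and
`fixtures` subcommands is installed at `inst/cli/ctsplice.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ctsplice.R", package = "ctsplice"))')" \
  simulate --exons 300,300,300 --introns 3000,3000 --kp0 1 --speed 6 --out-dir out/
```

See the vignette (`vignettes/splicing-kinetics.Rmd`) for the model's
assumptions, parameter defaults, and numerical choices.

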