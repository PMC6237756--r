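---
title: "Kinetic modeling of co-transcriptional alternative splicing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modeling of co-transcriptional alternative splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctsplice)
```

## The model

Splicing of a pre-mRNA with $N$ introns is modeled as a continuous-time
Markov chain on a directed acyclic graph. The root node is the unspliced
transcript; every other node is a unique splicing intermediate; the absorbing
nodes are the fully spliced products. Two reaction classes connect the nodes:

* **Availability reactions.** The 5′ and 3′ splice sites of intron $i$
  become competent to react at rates $k_{5'}(i)$ and $k_{3'}(i)$ (min⁻¹).
  These lump snRNP recruitment and spliceosomal rearrangement, i.e. splice
  site commitment without choosing a partner.
* **Pairing reactions.** An available 5′ site of intron $i$ joins an
  available 3′ site of intron $j \ge i$ at rate $k_p(i,j)$, excising
  everything in between. $i = j$ is constitutive excision of one intron;
  $i < j$ skips the internal exons $i{+}1, \dots, j$.

Because each of the $N-1$ internal exons is either included or skipped, a
gene has $2^{N-1}$ possible fully spliced isoforms. Executed pairings occupy
disjoint intron intervals: a pairing may not straddle a region that has
already been excised. Availability flags of splice sites consumed or removed
by a pairing are frozen, so an isoform that skipped $n$ exons is represented
by $4^n$ absorbing microstates (each skipped exon leaves two flanking sites
whose availability flags may hold either value). Exhaustive enumeration
confirms $4^n$; the collapse step sums microstates into isoforms, so the
distinction never reaches the user.

Transcription couples to this chain through **phases**: intervals during
which a fixed set of splice sites exists. A phase's duration is the length
of the gene segment transcribed during it divided by the elongation speed
(kb/min). Within a phase the chain evolves as $\beta \, e^{G T}$, where $G$
is the infinitesimal generator restricted to the enabled reactions (rows sum
to zero; in the transition-matrix notation $\beta e^{-QT}$ this is $Q = -G$
— building the standard generator removes the sign ambiguity and makes
probability conservation checkable). After the last phase the chain runs to
its absorbing limit. Instantaneous elongation (speed `Inf`) makes every
finite phase vanish: purely post-transcriptional splicing (PTS).

Two engines share this machinery:

* the **full model** keeps availability and pairing reactions; its state
  count grows combinatorially and it is restricted to 3 introns (6 splice
  sites). Its phase schedule splits at every splice-site synthesis point,
  starting when the 5′ site of intron 1 is made.
* the **simple model** treats availability as instantaneous and keeps only
  pairings; it scales to 9 introns. Its schedule starts when intron 1 is
  fully transcribed; phase $i < N$ spans exon $i{+}1$ plus intron $i{+}1$.
  The final-exon phase enables nothing new, so it only shifts time between
  the last finite phase and the infinite one and is folded into the
  absorbing solve — a documented no-op for results.

The full model provably reduces to the simple model as
$k_{5'}, k_{3'} \to \infty$; the suite checks this at $10^6$ min⁻¹ to a
$10^{-6}$ tolerance.

## The two-intron benchmark

For the classic cassette-exon gene (two introns, one internal exon) with all
three pairing rates equal, the simple model has a closed form. During phase
I (duration $T_1$) only intron 1 can be excised, at rate $k$; afterwards the
three pairings compete symmetrically, and a third of the transcripts that
still contain intron 1 skip the exon:

$$P(\text{skip}) = \tfrac{1}{3} e^{-k T_1}.$$

```{r benchmark}
g <- gene_structure(c(300, 300, 300), c(3000, 3000), "model2i")
r <- splice_rates(2, kp0 = 1)
sapply(c(Inf, 6, 1.5), function(speed)
  1 - inclusion(ctsplice(g, r, elongation = elongation_profile(speed)), 2))
```

Instantaneous elongation skips 33% (exactly $1/3$); with phase I lasting
0.55 min (3.3 kb at 6 kb/min) skipping drops to 19%, and at 2.2 min
(1.5 kb/min) to 4%. The default pairing rate $k_{p0} = 1$ min⁻¹ is fixed by
this benchmark: it is the rate at which the closed form reproduces both
co-transcriptional skipping percentages at the fast/slow phase times.

## Parameters and defaults

| parameter | units | default | role |
|---|---|---|---|
| `kp0` | min⁻¹ | 1 | default pairing (joining) rate, all $(i,j)$ |
| `k5` | min⁻¹ | 2 | 5′ availability, per intron (full model) |
| `k3` | min⁻¹ | 1 | 3′ availability, per intron (full model) |
| `k3_fast` | min⁻¹ | 4 | stimulated 3′ rate under exon definition |
| `speed` | kb/min | 3 | polymerase elongation speed (`Inf` = PTS) |

The availability defaults encode a 5′ commitment step faster than the
rate-limiting 3′ step, consistent with rapid U1 recruitment versus slow,
ATP-dependent U2 recruitment. No published rate constants exist for the
availability reactions, so every full-model result in this package is a
*property* (an ordering or monotonicity), never a numeric reproduction; the
tests assert them as such.

Pauses are first-class: a `pol_pause()` anchors a zero-elongation phase
immediately after a named splice site is synthesized (or inside an exon or
intron) and may override rates for its duration — e.g. a 1-s pause after the
internal 3′ splice site with an elevated $k_{3'}(1)$ markedly increases
inclusion, while the matching 5′-side pause is insensitive to $k_{5'}(2)$
because nothing the 5′ site gates can fire until the downstream 3′ site
exists.

## Intron and exon definition

**Intron definition** (co-operativity across short introns) replaces the
pairing rate by a length law

$$k_p(L) = k_{p0}\,\Bigl(\frac{200}{\max(L, 200)}\Bigr)^{1/2},$$

flat up to 200 nt and decaying as the square root of length beyond —
kinetic rates of looping are linear in distance through the free energy,
and the square root accounts for the compaction of structured RNA. For a
skipping pairing the penalized length $L(i,j)$ spans the whole excised
lariat — introns $i..j$ plus the skipped internal exons — since that is the
region that must loop out. `span_mode = "introns"` restricts it to the
intron lengths alone for comparison.

**Exon definition** (co-operativity across a short exon) makes the 3′
availability of intron $i$ conditional: once the 5′ site of intron $i{+}1$
is available, $k_{3'}(i)$ switches from its slow baseline to `k3_fast`.
Setting `k3_fast` equal to the baseline reproduces the unconditional model
bitwise, which the suite checks end to end. The effect on inclusion is
never negative, and `exon_definition_scan()` shows the gain is largest for
weak exons (very slow baseline $k_{3'}$): it grows with downstream intron
length, peaking around 5–10 kb before declining gently — the long-intron
regime where human weak cassette exons actually reside.

## The synthetic cohorts

`sample_genes()` draws exon and intron lengths from log-normal profiles:
fly-like introns (median 70 nt, log-sd 0.8, putting ~90% under the 200 nt
intron-definition threshold), human-like introns (median 1.5 kb, log-sd
1.2), exons median 140 nt (log-sd 0.6) in both. These reproduce the
qualitative short- versus long-intron contrast between the two genomes, and
nothing else: real length distributions are heavier-tailed and correlated
along genes, and real splice sites differ in strength, none of which the
sampler emulates. Cohort-level results are therefore ordering properties of
the model under these profiles, not genome estimates.

`run_batch()` simulates each gene (simple engine) under PTS and CTS, with
and without intron definition. On fly-like cohorts (100 genes, 6 introns)
perfect fidelity — the isoform including every exon — obeys
CTS+ID ≥ CTS ≥ PTS, and the fidelity gain from intron definition under CTS
exceeds the human-like cohort's (which is near zero or negative, since the
length penalty also slows the constitutive excisions that CTS relies on).
Under PTS, where only rate *ratios* matter, the square-root penalty helps
the long-intron human-like cohort at least as much as the fly-like one:
with unimodal kb-scale introns the skip-to-constitutive rate ratio drops to
~0.7 versus ~0.85 for fly-like lengths. The co-transcriptional contrast is
the one the tests assert.

## Numerical choices

* Matrix exponentials are dense Padé with scaling and squaring
  (`Matrix::expm`); the state spaces are small (≤ 181 states for the full
  model at $N=3$; 4181 for the simple model at $N=9$, of which propagation
  only ever touches the prefix reachable with the introns synthesized so
  far, ≤ 1597 states).
* The absorbing limit is a transient-block linear solve
  $\beta_a + \beta_t(-G_{tt})^{-1}G_{ta}$, restricted to states reachable
  from the support of $\beta$. The spectral construction (zeroing the
  non-null eigenvalues) is kept as a test-only cross-check; the linear
  solve needs no eigen-decomposition of a defective matrix.
* Probability conservation is asserted to $10^{-9}$ after every phase and
  the absorbing solve; collapse refuses residual transient mass above
  $10^{-6}$.
* A transient state with no outgoing rate (possible only when a user sets a
  rate to zero) is a *trap*: the transcript can never finish splicing.
  `absorb()` reports it by name rather than renormalizing it away. One
  consequence worth knowing: disabling only $k_{3'}(1)$ in the two-intron
  gene does not force skipping — if intron 2 is excised first the skipping
  pairing is interval-blocked and the transcript is stuck, which the engine
  reports as an error.
* State order is deterministic (root first, then lexicographic within
  progress level), so equal seeds give byte-identical outputs.
* The Gillespie oracle re-enumerates enabled reactions directly from the
  state tuple, independently of the generator matrices, and redraws waiting
  times at phase boundaries (exact for exponential clocks). At $10^5$
  trajectories it agrees with the matrix engine within three binomial
  standard errors on every fixture gene.

## Problem sizes used by the test suite

Deterministic checks run on one- to three-intron model genes; the fidelity-
decay property uses chains of 2–6 introns; cohort properties use 100 genes
of 6 introns per species profile; stochastic validation uses $10^5$
trajectories. These sizes make every headline quantity reproducible on a
single CPU in a few minutes while keeping the binomial error of the
stochastic checks well below the effects being asserted.

## Limitations

* No recursive, multi-step intron excision: a pairing removes its whole
  span at once, so iterative removal of one intron through cryptic internal
  sites is out of scope.
* No sequence features: lengths are the only genomic input; splice-site
  strength enters solely through user-set rates.
* The full engine stops at 3 introns and the simple engine at 9; genes
  beyond that are rejected rather than approximated.
* Rates are piecewise-constant per phase; there is no continuous
  rate modulation along the gene beyond pauses and their overrides.
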