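---
title: "Detecting faster-X evolution: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting faster-X evolution: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fasterx)
```

# The scientific problem

In *Drosophila* and many other taxa the X chromosome contributes
disproportionately to hybrid male sterility, and one candidate
explanation is that the X experiences more frequent and stronger
positive selection than the autosomes (the faster-X effect). Testing
that hypothesis from a population sample of sequenced haplotypes takes
a chain of analyses: windowed summaries of polymorphism and divergence;
polymorphism stratified by functional sequence class, with a
minimally-constrained neutral class; McDonald–Kreitman (MK) style
estimates of the fraction of adaptive fixations; a genome scan for
recent hard selective sweeps; and an estimate of how strong the
selection behind a particular sweep must have been. `fasterx`
implements that chain end to end, together with seeded synthetic-data
generators so every stage can be validated against known truth.

# Summary statistics

**Nucleotide diversity.** Per window,
$\pi = \frac{1}{A}\sum_i 2\hat p_i(1-\hat p_i)\frac{n_i}{n_i-1}$
where $A$ is the number of callable sites, $n_i$ the callable ingroup
haplotypes at site $i$ and $\hat p_i$ the sample allele fraction; the
$n_i/(n_i-1)$ factor makes the estimator unbiased for small samples.
This equals the mean pairwise Hamming distance per site, and the test
suite asserts that equality against a brute-force pairwise oracle on
randomized instances.

**Tajima's D** uses the standard 1989 normalization; windows without
segregating sites return `NA` rather than zero. **Kelly's
$Z_{nS}$** averages $r^2$ over all pairs of biallelic, non-singleton
sites, reflecting the inbred, effectively haploid design of the data it
is meant for. **Divergence** is a Hamming proportion against a single
outgroup haplotype, with a strict $>10\%$ aligned-fraction window
filter, and a Jukes–Cantor correction
$d = -\tfrac34\ln(1-\tfrac{4p}{3})$ for class-level comparisons.

Missing-data policy: a site counts only when at least 4 ingroup
haplotypes are callable; triallelic sites are dropped everywhere. This
is a transparent replacement for read-level quality filtering, which is
out of scope here — inputs are already-called haplotypes.

# Sequence classes and the short-intron standard

`classify_sites()` labels every base with one class under the
precedence CDS > UTR > intron > intergenic (conservative for
constrained classes when genes overlap). Bases 8–30 of introns shorter
than 70 bp — the genome-wide median intron length in the system this
pipeline targets — form the `SI8_30` class, the least constrained
sequence available and therefore the neutral standard for $\alpha^*$
and for the mutation-rate contrast. Two boundary decisions are ours:
SI bases are counted from the intron's 5' end on the transcript strand,
and introns shorter than 30 bp contribute nothing (a partial window of
unknown neutrality is worse than no window). Ties in longest-transcript
selection break toward the lexicographically smallest transcript id,
for determinism.

# MK tests, alpha and alpha*

Counts of synonymous and nonsynonymous polymorphisms and fixations come
from direct codon comparison against the standard genetic code; codons
with more than one variable position or missing data are dropped and
counted, rather than path-enumerated. The 2x2 test is Fisher's exact
test. The adaptive proportion is
$\alpha = 1 - \frac{D_s P_n}{D_n P_s}$, computed on counts pooled over
genes with singleton polymorphisms excluded — segregating deleterious
amino-acid variants inflate $P_n$ at low frequency, and dropping
singletons removes most of that downward bias (the test suite
demonstrates the effect on data simulated with planted deleterious
singletons). $\alpha^*$ replaces the synonymous reference with SI8–30
counts and may legally be negative. Confidence intervals are percentile
bootstrap over genes (B = 1000); the gene is the resampling unit
because counts within a gene are correlated. Lineage polarization uses
two outgroups and strict parsimony: a change is assigned to the ingroup
branch only when both outgroups agree on the ancestral state.

# The sweep scan

Windows of 10 kb with at least 5,000 aligned sites contribute a
polarized unfolded SFS: a site enters only when its derived state is
present in the ingroup and absent from both outgroups. The composite
likelihood ratio contrasts the chromosome-wide background spectrum
against a complete-sweep alternative in which each lineage escapes the
sweep with probability $p_e = 1 - e^{-\alpha_s d}$; escaped lineages
draw ancestry from the background, trapped lineages coalesce through
the sweep into a single lineage. $\Lambda$ is maximized over 30
log-spaced $\alpha_s$ values spanning $[10^{-2}, 10^{2}]$ per window
span and floored at zero.

Three choices here are pinned variants of the cited scan method and
deserve emphasis:

* Because the window SFS aggregates sites, each site enters at the
  representative distance of a uniformly placed site from the window
  midpoint ($d = \mathrm{span}/4$); $\alpha_s$ and $d$ act only through
  $p_e$, so this costs one effective degree of freedom, not accuracy in
  the maximized statistic.
* Conditioning on polymorphism happens on the *mixture* over escape
  counts, not per escape count: a fully trapped site is monomorphic
  with certainty and must carry zero polymorphic mass, otherwise the
  alternative collapses toward the null exactly where a sweep erased
  variation.
* By default the likelihood also models the per-window *density* of
  polymorphic sites (`include_invariant = TRUE`): trapped lineages lose
  their polymorphism, so a sweep predicts fewer sites as well as a
  distorted spectrum. The shape-only statistic is available and is the
  one for which "window SFS proportional to background implies
  $\Lambda = 0$" holds exactly. On forward-simulated data the density
  term is what separates the valley core (few, young, low-frequency
  variants) from neutral windows; a shape-only scan is nearly blind
  there.

P-values use an upper-tail $\chi^2$ with 9 degrees of freedom. That
reference is nonstandard for a composite likelihood over linked sites
and is retained deliberately; its calibration is *measured* on neutral
forward simulations (the acceptance suite reports the realized
false-positive rate and requires it $\le 0.10$) rather than assumed.

**Segmentation.** Significant windows are grouped by a two-state HMM:
observations are binarized significance indicators, emissions
$P(\text{sig}\mid\text{sweep}) = 0.95$ and
$P(\text{sig}\mid\text{nonsweep}) = 0.05$ by default, and the
switching probability between adjacent windows is $f(1-f)$ with $f$
the marginal frequency of significant windows. The Viterbi path is
decoded with ties broken toward nonsweep; ineligible windows are
skipped as missing observations. Binarization is the minimal reading
of "emissions derived from the P-values"; the emission pair is
configurable. Region lengths convert to centimorgans by linear
interpolation of a marker map, refusing extrapolation.

**Randomization test.** Candidate (significant) windows are compared
with 1,000 arm-matched draws without replacement; directions are
one-sided where the sweep prediction is directional (lower $\pi$,
higher $Z_{nS}$, higher var $T_D$) and two-sided for mean Tajima's D.
The empirical P-value uses the add-one rule, so it is never zero.

# The hard-sweep fit

Diversity around a completed sweep follows
$\pi_c = \pi_0(1 - \gamma^{-4c/s})$ with $c$ the per-generation
recombination distance from the sweep center and $\gamma = 2N_e s$.
`fit_gamma()` minimizes squared error over 1-kb windows with a
deterministic log-grid search plus local refinement, and certifies the
optimum against the returned grid trace. The model depends on
$(\gamma, s)$ only through $\ln(\gamma)/s$, so the unconstrained
two-parameter fit sits on a ridge: the ratio is identified but
$\gamma$ alone is not. The fit object reports that ratio, and the two
anchored modes — $s$ fixed, or $s = \gamma/(2N_e)$ coupled — are the
ones used for point estimation. Which anchoring stands behind any given
published point estimate of $\gamma$ is usually not stated; both are
provided and the mode is recorded in the output.

# Synthetic data: what it emulates and what it does not

Two generator mechanisms are deliberate:

* a **spectrum sampler** draws segregating sites independently with
  derived-allele count $i$ at probability $\propto 1/i$ and
  $E[S] = \theta L a_1(n)$ — exact for SFS-level expectations
  ($E[\pi] = \theta$, $E[T_D] \approx 0$) but with no linkage;
* a **forward haploid Wright–Fisher simulator** with recombination,
  infinite sites on the integer grid, fitness $1+s$ at a selected
  site, conditioning on fixation by restart, and a configurable
  post-fixation recovery time $\tau$ (units of $2N$ generations). The
  population initializes at the equilibrium $1/i$ spectrum and burns in
  for $4N$ generations to build linkage before any sampling.

The CLR scan, HMM and $\gamma$ fit are validated only against the
forward mechanism — the scan must never be checked against its own
spectrum transformation. Outgroups are independent star branches
accumulating substitutions at a fixed rate with no polymorphism,
matching the single-genome outgroup usage of the target analysis;
consequently outgroup divergence is symmetric across chromosomes, and
the male-driven mutation-ratio inversion, while implemented and tested
on its closed form, has no planted signal to recover in the bundled
simulated genome (the analysis driver says so when the ratio falls
outside $(2/3, 4/3)$).

Desk-scale study conditions (chosen once; all seeded): populations are
rescaled to $N \le 500$ haploids with $\theta = 2N\mu$ and
$\rho = 2Nr$ held at their target per-bp values, recorded in each
bundle's truth sidecar. Sweep experiments use $\gamma = 2Ns \ge 600$
on 120–240 kb arms; for the scan-calibration contrast the swept arm is
long relative to the diversity valley, so that its own chromosome-wide
background spectrum remains representative, as it is in a whole-arm
scan. At this scale single recombination-escape events
are visible as asymmetric valley edges — real data at large $N$ are
smoother — which is why $\gamma$-recovery is asserted within a factor
of 2 (closed-form profiles with noise) or 3 (forward simulations), not
tighter. Simulated sample sizes (10 ingroup haplotypes, 2 outgroups)
match the target study design. What passing tests show is that the
estimators are correct and the scan is calibrated *under the model
assumptions*; they do not show robustness to demography, gene
conversion, variable mutation rate, alignment error or soft sweeps,
none of which the generators emulate.

# Numerical and degenerate-input policy

Probabilities are floored at $10^{-300}$ inside log-likelihoods;
$\Lambda$ is floored at 0. Windows with no callable sites, no
segregating sites, or fewer than two eligible LD sites return `NA`
sentinels and are excluded from summaries, never imputed. Jukes–Cantor
is undefined at $p \ge 0.75$ and warns. A sweep allele that fails to
fix within the attempt budget raises a classed error
(`fasterx_sweep_not_fixed`). Flat diversity profiles are flagged
unidentifiable rather than fitted. The repeat-density heterogeneity
test reports $df = \text{arms} - 1$ and says so in its output
metadata.

# Known limitations

* The $\chi^2_9$ reference for $\Lambda$ is approximate; use the
  measured neutral false-positive rate, or permutation calibration,
  for decision thresholds on real data.
* Codons with multiple segregating positions are dropped, slightly
  undercounting changes in fast-evolving genes.
* The forward simulator is $O(N \cdot S)$ per generation in R; it is
  sized for validation, not for large-scale power studies.
* The HMM's binarized emissions discard the magnitude of sub-threshold
  P-values; a continuous-emission reading is configurable only through
  the emission pair.
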