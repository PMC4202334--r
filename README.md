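# fasterx

Population-genomic detection of faster-X evolution from multi-sample
haplotype data: windowed diversity/divergence scans, sequence-class
stratified polymorphism with a short-intron neutral standard,
McDonald–Kreitman α/α* estimation with bootstrap confidence intervals,
a composite-likelihood selective-sweep scan with HMM segmentation and an
arm-matched randomization test, hard-sweep selection-intensity fitting,
and X-versus-autosome contrast statistics — all validated end to end on
synthetic data with known truth.

## Who this is for

Population geneticists analysing a phased (or effectively haploid)
population sample of one species plus one or two single-genome
outgroups — the classic *Drosophila* resequencing design of ~10 inbred
lines — who want the faster-X analysis chain as tested, reusable
functions rather than one-off scripts.

## The statistics at the core

* Unbiased nucleotide diversity per window,
  `pi = (1/A) Σ 2p̂(1−p̂)·n_i/(n_i−1)`; Tajima's D; Kelly's Z_nS
  (average pairwise r², singletons excluded); Hamming and Jukes–Cantor
  divergence with a >10% aligned-fraction window filter.
* MK tests (pooled unpolarized, and lineage-polarized via two-outgroup
  parsimony) and the adaptive proportion
  `α = 1 − (Ds·Pn)/(Dn·Ps)` on singleton-excluded pooled counts, with
  `α*` using bases 8–30 of introns < 70 bp as the neutral standard and
  percentile bootstrap CIs over genes.
* A sweep scan on polarized unfolded site-frequency spectra: per 10-kb
  window, a composite likelihood ratio Λ contrasts the chromosome-wide
  background SFS against a complete-sweep escape model (lineages escape
  with probability `1 − exp(−α_s·d)`), with upper-tail χ²(df = 9)
  P-values, two-state HMM segmentation of significant windows into
  regions, genetic-map lengths in cM, and a randomization test of
  candidate windows.
* The hard-sweep diversity profile `π_c = π0(1 − γ^(−4c/s))`, fit by
  deterministic least squares to estimate the population-scaled
  selection intensity γ = 2Nₑs.
* Seeded generators: a fast neutral spectrum sampler, a forward
  Wright–Fisher simulator with recombination and selection (the
  independent mechanism the sweep scan is validated against), MK count
  tables with tunable adaptive fraction, and complete on-disk fixture
  bundles (FASTA/VCF/GFF3/BED/genetic-map TSV/JSON truth sidecar).

## Worked example

Simulate a completed hard sweep (γ = 2Ns = 1000 in a rescaled
population of 400 haploids), scan it, and segment the significant
windows:

```r
library(fasterx)

cfg <- sim_config(seed = 63001, L = 1.4e5, theta = 0.002, rho = 2e-3,
                  n_pop = 400, chrom = "X",
                  sweep = list(position = 7e4, gamma = 1000, tau = 0.05))
aln <- simulate_sweep(cfg)
aln
#> haplotype_alignment: X (140,000 bp), 12 samples (10 ingroup), 14657 variable sites

clr <- clr_scan(polarized_sfs(aln))
subset(clr, significant, select = c(start, end, n_sites, lambda, p_value))
#>   start   end n_sites   lambda     p_value
#> 8 70000 80000       5 40.92383 5.16416e-06
```

The window holding the planted sweep carries only 5 polarized variants
where its neighbours carry dozens — the diversity valley — and the
composite likelihood ratio flags exactly that window (Λ = 40.9,
P ≈ 5 × 10⁻⁶ against χ²(9)). Fitting the hard-sweep model to the 1-kb
diversity profile around the planted center recovers the selection
intensity to within a factor of two:

```r
w <- make_windows(aln$L, 1000)
prof <- data.frame(position = (w$start + w$end) / 2, pi = window_pi(aln, w))
fit_gamma(subset(prof, abs(position - 7e4) <= 5.5e4),
          pi0 = 0.002, c_rate = 2e-3 / 800, Ne = 400, center = 7e4)
#> hard-sweep fit (Ne_coupled): gamma = 1786, s = 2.232, center = 70,000, rss = 0.000115 over 110 windows
```

A fitted γ of 1.8 × 10³ against a planted 1.0 × 10³ — typical of the
factor-3 recovery the validation suite asserts for single forward
simulations at this rescaled population size. The `analysis/`
directory chains the full study on a five-arm synthetic genome:
`01_simulate.R` writes per-arm fixture bundles, `02`–`07` scan windows,
stratify by sequence class, run MK/α, scan and segment sweeps, fit γ
and contrast repeat densities, writing their tables under `results/`.

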