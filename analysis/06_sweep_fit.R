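#!/usr/bin/env Rscript
# Fit the hard-sweep diversity-reduction model around the planted X sweep
# and estimate the population-scaled selection intensity gamma = 2Ns.
# Writes results/sweep_fit.json.

suppressPackageStartupMessages(library(fasterx))

aln <- read_haplotype_fasta("results/data/X/X.fa", chrom = "X")
truth <- jsonlite::read_json("results/data/X/truth.json")
center <- truth$sweep$position
r_bp <- truth$rho / (2 * truth$n_pop)  # per-bp per-generation crossover

w <- make_windows(aln$L, size = 1000)
prof <- data.frame(position = (w$start + w$end) / 2,
                   pi = window_pi(aln, w))
d <- abs(prof$position - center)
pi0_hat <- mean(prof$pi[d > 45000], na.rm = TRUE)

fit <- fit_gamma(prof[d <= 45000, ], pi0 = pi0_hat, c_rate = r_bp,
                 Ne = truth$n_pop, center = center)
print(fit)
cat(sprintf("true gamma = %g; fitted/true = %.2f\n", truth$sweep$gamma,
            fit$gamma / truth$sweep$gamma))

jsonlite::write_json(list(gamma_hat = fit$gamma, s_hat = fit$s,
                          gamma_true = truth$sweep$gamma,
                          pi0 = pi0_hat, c_rate = r_bp,
                          center = center, rss = fit$rss,
                          mode = fit$mode, n_windows = fit$n_windows),
                     "results/sweep_fit.json", auto_unbox = TRUE,
                     digits = NA)
cat("wrote results/sweep_fit.json\n")
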