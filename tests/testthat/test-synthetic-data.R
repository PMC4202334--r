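test_that("zero mutation rate yields no ingroup segregating sites", {
  cfg <- sim_config(seed = 1, L = 1e4, theta = 0, rho = 0.002,
                    outgroup_divergence = 0.02)
  aln <- simulate_neutral(cfg, "sfs")
  ing <- ingroup_alleles(aln)
  poly <- apply(ing, 2, function(col) length(unique(col)) > 1)
  expect_equal(sum(poly), 0)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- tiny_forward_cfg(7)
  a <- simulate_neutral(cfg, "forward")
  b <- simulate_neutral(cfg, "forward")
  expect_identical(a$alleles, b$alleles)
  expect_identical(a$positions, b$positions)
  s1 <- simulate_sweep(tiny_forward_cfg(8, sweep = list(position = 15000,
                                                        gamma = 300,
                                                        tau = 0.02)))
  s2 <- simulate_sweep(tiny_forward_cfg(8, sweep = list(position = 15000,
                                                        gamma = 300,
                                                        tau = 0.02)))
  expect_identical(s1$alleles, s2$alleles)
  # and the seed is restored, not clobbered, for the caller
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(simulate_neutral(cfg, "sfs")); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("neutral spectrum sampler matches coalescent expectations", {
  # E[pi] = theta and E[TD] = 0, averaged over 200 seeded replicates
  theta <- 0.01
  pis <- tds <- numeric(200)
  for (i in seq_len(200)) {
    cfg <- sim_config(seed = 5000 + i, L = 2e4, theta = theta, rho = 0,
                      n_ingroup = 10)
    aln <- simulate_neutral(cfg, "sfs")
    w <- data.frame(start = 0, end = cfg$L)
    pis[i] <- window_pi(aln, w)
    tds[i] <- tajima_d(aln)
  }
  expect_lt(abs(mean(pis) - theta), 3 * sd(pis) / sqrt(200))
  expect_lt(abs(mean(tds)), 3 * sd(tds) / sqrt(200))
})

test_that("forward simulator holds diversity near theta at equilibrium", {
  pis <- numeric(12)
  for (i in seq_len(12)) {
    cfg <- tiny_forward_cfg(6000 + i)
    aln <- simulate_neutral(cfg, "forward")
    pis[i] <- window_pi(aln, data.frame(start = 0, end = cfg$L))
  }
  expect_lt(abs(mean(pis) - 0.004), 3 * sd(pis) / sqrt(12))
})

test_that("a strong sweep carves a local diversity valley", {
  # center window pi below edge pi in (almost) all replicates, and below
  # the 5th percentile of matched neutral center windows; recombination
  # fast enough that the 5-kb edge window sits outside the valley
  n_rep <- 12
  centers <- edges <- neutral_centers <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    cfg <- sim_config(seed = 7000 + i, L = 6e4, theta = 0.004, rho = 0.005,
                      n_pop = 60, n_ingroup = 8,
                      sweep = list(position = 3e4, gamma = 1200,
                                   tau = 0.01))
    sw <- simulate_sweep(cfg)
    w <- data.frame(start = c(27500, 0), end = c(32500, 5000))
    p <- window_pi(sw, w)
    centers[i] <- p[1]; edges[i] <- p[2]
    neu <- simulate_neutral(sim_config(seed = 7100 + i, L = 6e4,
                                       theta = 0.004, rho = 0.005,
                                       n_pop = 60, n_ingroup = 8),
                            "forward")
    neutral_centers[i] <- window_pi(neu, w[1, , drop = FALSE])
  }
  expect_gte(mean(centers < edges), 0.95)
  expect_lt(median(centers), quantile(neutral_centers, 0.05))
})

test_that("a sweep allele that cannot fix is flagged, not silent", {
  cfg <- tiny_forward_cfg(9, sweep = list(position = 15000, gamma = 1,
                                          tau = 0))
  expect_error(simulate_sweep(cfg, max_attempts = 3),
               class = "fasterx_sweep_not_fixed")
})

test_that("MK count generator hits its target adaptive fraction", {
  # alpha_true = 0: pooled estimate centered on zero
  d0 <- simulate_mk_counts(mk_sim_spec(1000, alpha_true = 0, seed = 21))
  expect_lt(abs(alpha_estimate(d0)$alpha), 0.05)
  # alpha_true = 0.5 over 2000 genes: within +-0.05
  d5 <- simulate_mk_counts(mk_sim_spec(2000, alpha_true = 0.5, seed = 22))
  expect_lt(abs(alpha_estimate(d5)$alpha - 0.5), 0.05)
  # realized truth column agrees with the nominal rate
  expect_lt(abs(sum(d5$Dn_adaptive) / sum(d5$Dn) - 0.5), 0.05)
  # degenerate case
  expect_equal(nrow(simulate_mk_counts(mk_sim_spec(0, seed = 1))), 0)
})

test_that("pi profile generator evaluates the sweep model exactly", {
  pr <- make_pi_profile(gamma = 7.05e5, s = 1, pi0 = 0.0082,
                        c_rate = 7.91e-6, center = 0, span = 2000,
                        window = 1000, noise_sd = 0)
  # windows sit at +-500 and +-1500 bp; exact model values
  m <- list(gamma = 7.05e5, s = 1, pi0 = 0.0082, c_rate = 7.91e-6,
            center = 0)
  expect_equal(pr$pi, predict_pi(m, pr$position))
  # distal limit: far windows approach pi0
  far <- make_pi_profile(gamma = 100, s = 1e-4, pi0 = 0.01, c_rate = 1e-5,
                         center = 0, span = 5e4, window = 1000,
                         noise_sd = 0)
  expect_lt(abs(max(far$pi) - 0.01), 1e-8)
  expect_error(make_pi_profile(gamma = 10, s = 1, pi0 = 0.01,
                               c_rate = 1e-6, center = 0, noise_sd = -1))
})

test_that("fixture bundle round-trips through the package readers", {
  cfg <- sim_config(seed = 42, L = 3e4, theta = 0.004, rho = 0.002,
                    n_pop = 60, chrom = "X")
  out <- write_fixture_bundle(file.path(tempdir(), "bundle42"), cfg)
  a <- out$alignment
  expect_identical(unname(read_haplotype_fasta(out$fasta)$alleles),
                   unname(a$alleles))
  v <- read_haplotype_vcf(out$vcf)
  expect_identical(unname(v$alleles), unname(a$alleles))
  expect_identical(v$positions, a$positions)
  m <- read_gff_models(out$gff)
  expect_setequal(unique(m$type),
                  c("exon", "CDS", "five_prime_UTR", "three_prime_UTR"))
  # CDS length divisible by 3 per transcript
  cds <- m[m$type == "CDS", ]
  lens <- tapply(cds$end - cds$start, cds$transcript_id, sum)
  expect_true(all(lens %% 3 == 0))
  truth <- jsonlite::read_json(out$truth)
  expect_equal(truth$theta, cfg$theta)
  map <- read_genetic_map(out$map)
  expect_true(all(diff(map$cM) >= 0))
})

test_that("sweep truth sidecar records the planted sweep", {
  cfg <- tiny_forward_cfg(77, L = 3e4,
                          sweep = list(position = 15000, gamma = 400,
                                       tau = 0.02))
  out <- write_fixture_bundle(file.path(tempdir(), "bundle77"), cfg)
  truth <- jsonlite::read_json(out$truth)
  expect_equal(truth$sweep$gamma, 400)
  expect_lt(abs(truth$sweep$position - 15000), 100)
})
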