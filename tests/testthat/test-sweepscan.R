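# direct re-derivation of the CLR for one window, written with plain
# loops from the model description (escape-probability mixture over a
# background spectrum, optional invariant-site density term)
oracle_clr <- function(xi, bg_counts, start, end, aligned_all, S_all,
                       grid_size = 30, grid_range = c(1e-2, 1e2),
                       include_invariant = TRUE) {
  n <- length(xi) + 1
  bg <- bg_counts / sum(bg_counts)
  span <- end - start
  agrid <- exp(seq(log(grid_range[1] / span), log(grid_range[2] / span),
                   length.out = grid_size))
  q0 <- S_all / aligned_all
  A <- span
  S <- sum(xi)
  lnull <- sum(xi * log(pmax(bg, 1e-300)))
  if (include_invariant)
    lnull <- lnull + S * log(q0) + (A - S) * log(1 - q0)
  best <- -Inf
  for (a in agrid) {
    pe <- 1 - exp(-a * span / 4)
    pj <- rep(0, n - 1)
    for (E in 0:n) {
      wE <- choose(n, E) * pe^E * (1 - pe)^(n - E)
      if (E == n) { pj <- pj + wE * bg; next }
      m <- E + 1
      for (k in seq_len(n - 1)) for (i in 0:m) {
        hyp <- dhyper(i, k, n - k, m)
        if (hyp == 0) next
        # block lineage derived with probability i/m
        if (i >= 1) {
          j <- (i - 1) + (n - E)
          if (j >= 1 && j <= n - 1)
            pj[j] <- pj[j] + wE * bg[k] * hyp * (i / m)
        }
        if (i <= E && i >= 1)
          pj[i] <- pj[i] + wE * bg[k] * hyp * (1 - i / m)
      }
    }
    retained <- sum(pj)
    lalt <- sum(xi * log(pmax(pj / retained, 1e-300)))
    if (include_invariant)
      lalt <- lalt + S * log(pmax(q0 * retained, 1e-300)) +
        (A - S) * log(1 - q0 * retained)
    best <- max(best, lalt)
  }
  max(0, 2 * (best - lnull))
}

make_sfs_df <- function(xi_list, span = 10000, chrom = "c") {
  n1 <- length(xi_list[[1]]) + 1
  df <- data.frame(chrom = chrom,
                   start = (seq_along(xi_list) - 1) * span,
                   end = seq_along(xi_list) * span,
                   aligned_sites = span,
                   eligible = TRUE)
  xi <- do.call(rbind, xi_list)
  colnames(xi) <- paste0("xi", seq_len(n1 - 1))
  cbind(df, as.data.frame(xi))
}

test_that("polarized SFS applies the strict outgroup filter", {
  # 10 ingroup: site with T x3, A x7, both outgroups A -> xi3
  m <- matrix("A", 12, 3)
  m[1:3, 1] <- "T"                        # polarizable, derived count 3
  m[1:5, 2] <- "G"; m[11, 2] <- "G"       # near outgroup carries derived
  m[1:2, 3] <- "C"; m[12, 3] <- "C"       # far outgroup carries derived
  aln <- haplotype_alignment("c", 10000, c(100, 200, 300), m,
                             c(rep("ingroup", 10), "outgroup_near",
                               "outgroup_far"))
  sfs <- polarized_sfs(aln, data.frame(start = 0, end = 10000))
  xi <- as.numeric(sfs[1, grep("^xi", names(sfs))])
  expect_equal(xi[3], 1)
  expect_equal(sum(xi), 1)  # the two outgroup-contaminated sites dropped
  # monomorphic window: all-zero SFS
  aln0 <- haplotype_alignment("c", 10000, integer(0),
                              matrix(character(0), 12, 0),
                              c(rep("ingroup", 10), "outgroup_near",
                                "outgroup_far"))
  sfs0 <- polarized_sfs(aln0, data.frame(start = 0, end = 10000))
  expect_equal(sum(sfs0[1, grep("^xi", names(sfs0))]), 0)
  # eligibility threshold on aligned sites
  sfs_small <- polarized_sfs(aln, data.frame(start = 0, end = 4000))
  expect_false(sfs_small$eligible[1])
})

test_that("CLR is zero on background-proportional windows", {
  base <- c(40, 20, 13, 10, 8, 6, 5, 4, 3)
  # identical windows: spectrum and density both match the background
  sfs_eq <- make_sfs_df(list(base, base, base))
  for (inv in c(TRUE, FALSE)) {
    cr <- clr_scan(sfs_eq, include_invariant = inv)
    expect_true(all(cr$lambda < 1e-6))
  }
  # proportional counts: the spectrum shape matches the background, so
  # the shape-only statistic is exactly null; the density-aware variant
  # is free to respond to the per-window site density
  sfs_prop <- make_sfs_df(list(base, base * 2L, base * 3L))
  cr2 <- clr_scan(sfs_prop, include_invariant = FALSE)
  expect_true(all(cr2$lambda < 1e-6))
})

test_that("CLR matches the brute-force likelihood oracle", {
  # small-n windows with hand-enumerable likelihoods, both model variants
  xi_list <- list(c(3, 1, 2), c(1, 0, 1), c(8, 3, 2))
  sfs <- make_sfs_df(xi_list, span = 10000)
  bg <- colSums(do.call(rbind, xi_list))
  for (inv in c(TRUE, FALSE)) {
    cr <- clr_scan(sfs, include_invariant = inv)
    for (w in 1:3) {
      lam <- oracle_clr(xi_list[[w]], bg, sfs$start[w], sfs$end[w],
                        aligned_all = sum(sfs$aligned_sites),
                        S_all = sum(bg), include_invariant = inv)
      expect_equal(cr$lambda[w], lam, tolerance = 1e-8,
                   info = paste("window", w, "invariant", inv))
    }
  }
})

test_that("CLR is invariant to scaling all counts by a common factor", {
  xi_list <- list(c(12, 5, 3, 2, 1), c(30, 2, 1, 0, 9), c(7, 7, 7, 7, 7))
  sfs1 <- make_sfs_df(xi_list)
  sfs4 <- make_sfs_df(lapply(xi_list, `*`, 4L))
  sfs4$aligned_sites <- sfs1$aligned_sites * 4L
  sfs4$end <- sfs4$start + 10000  # same span; only counts scale
  c1 <- clr_scan(sfs1, include_invariant = FALSE)
  c4 <- clr_scan(sfs4, include_invariant = FALSE)
  expect_equal(c4$lambda, c1$lambda * 4, tolerance = 1e-8)
  expect_true(all(c1$lambda >= 0))
})

test_that("chi-squared reference gives the standard tail probabilities", {
  expect_equal(clr_pvalue(0), 1)
  expect_equal(clr_pvalue(16.919), 0.05, tolerance = 1e-3)
  expect_equal(chisq_pvalue(54.68, df = 1), 1.4e-13, tolerance = 0.05)
  expect_error(clr_pvalue(-1))
})

test_that("Viterbi segmentation handles trivial observation patterns", {
  mk_clr <- function(p) data.frame(chrom = "X",
                                   start = (seq_along(p) - 1) * 1e4,
                                   end = seq_along(p) * 1e4,
                                   eligible = TRUE, p_value = p)
  expect_equal(nrow(hmm_segment(mk_clr(rep(0.5, 50)))), 0)
  r_all <- hmm_segment(mk_clr(rep(0.001, 50)))
  expect_equal(nrow(r_all), 1)
  expect_equal(r_all$start, 0); expect_equal(r_all$end, 5e5)
  # planted block of 10 significant among 200
  p <- rep(0.6, 200); p[101:110] <- 1e-4
  r <- hmm_segment(mk_clr(p))
  expect_equal(nrow(r), 1)
  expect_equal(r$start, 100 * 1e4)
  expect_equal(r$end, 110 * 1e4)
  expect_equal(r$n_windows, 10)
})

test_that("the decoded path is a maximum-probability path", {
  # certificate against exhaustive enumeration of all 2^m state paths
  path_logprob <- function(state, obs, e_s, e_n, f) {
    t_sw <- f * (1 - f)
    em <- ifelse(state, ifelse(obs, e_s, 1 - e_s),
                 ifelse(obs, e_n, 1 - e_n))
    tr <- ifelse(diff(state) != 0, t_sw, 1 - t_sw)
    log(0.5) + sum(log(em)) + sum(log(tr))
  }
  set.seed(55)
  for (trial in 1:20) {
    m <- sample(8:12, 1)
    obs <- runif(m) < 0.3
    if (!any(obs) || all(obs)) next
    dec <- fasterx:::.viterbi_sweep(obs, 0.9, 0.1)
    f <- mean(obs)
    lp_dec <- path_logprob(dec, obs, 0.9, 0.1, f)
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), m))
    best <- max(apply(combos, 1, path_logprob, obs = obs, e_s = 0.9,
                      e_n = 0.1, f = f))
    expect_equal(lp_dec, best, tolerance = 1e-10)
  }
})

test_that("region arithmetic and map interpolation are exact", {
  reg <- data.frame(chrom = "X", start = 8500000, end = 9050000)
  expect_equal((reg$end - reg$start) / 1000, 550)
  # linear map: region spanning half the marker interval = half the cM
  map1 <- data.frame(chrom = "X", bp = c(0, 1e6), cM = c(0, 1))
  half <- data.frame(chrom = "X", start = 25e4, end = 75e4)
  expect_equal(region_cM(half, map1), 0.5)
  zero <- data.frame(chrom = "X", start = 5e5, end = 5e5)
  expect_equal(region_cM(zero, map1), 0)
  # synthetic map at the local rate of the large X sweep region
  rate <- 3.008 / 550000
  map2 <- data.frame(chrom = "X", bp = c(8.4e6, 9.1e6),
                     cM = c(0, rate * 7e5))
  expect_equal(region_cM(reg, map2), 3.008, tolerance = 1e-6)
  # extrapolation refused
  outside <- data.frame(chrom = "X", start = 0, end = 100)
  expect_warning(cm <- region_cM(outside, map2))
  expect_true(is.na(cm))
})

test_that("randomization test is seeded and detects planted shifts", {
  set.seed(202)
  aw <- data.frame(chrom = rep(c("X", "2L", "2R"), each = 120),
                   pi = rnorm(360, 0.01, 0.002),
                   znS = runif(360, 0.1, 0.5),
                   tajima_d = rnorm(360, 0, 0.6))
  cand_idx <- c(sample(1:120, 6), sample(121:240, 4), sample(241:360, 5))
  cand <- aw[cand_idx, ]
  r1 <- randomization_test(cand, aw, R = 500, seed = 9)
  r2 <- randomization_test(cand, aw, R = 500, seed = 9)
  expect_identical(r1$p_value, r2$p_value)
  expect_true(all(r1$p_value > 0 & r1$p_value <= 1))
  # planted low-pi candidates: one-sided P small
  shifted <- cand
  shifted$pi <- shifted$pi - 3 * sd(aw$pi)
  r3 <- randomization_test(shifted, aw, R = 500, seed = 9)
  expect_lte(r3$p_value[r3$stat == "pi"], 0.05)
  # arm with more candidates than windows errors
  tiny <- aw[1:3, ]
  expect_error(randomization_test(aw[1:10, ], tiny))
})

test_that("scan summary reports window bookkeeping", {
  clr <- data.frame(chrom = "X", start = 0, end = 1,
                    eligible = c(rep(TRUE, 8), FALSE, FALSE),
                    significant = c(TRUE, TRUE, rep(FALSE, 8)))
  s <- scan_summary(clr)
  expect_equal(s$n_eligible, 8)
  expect_equal(s$n_significant, 2)
  expect_equal(s$pct_significant, 25)
})
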