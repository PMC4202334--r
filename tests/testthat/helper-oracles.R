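# Brute-force oracles, written independently of the package internals:
# direct enumeration / pairwise definitions, no shared code paths.

# mean pairwise Hamming distance per site over all ingroup pairs;
# per pair, only jointly callable sites count (here: complete data)
oracle_pi <- function(ing, n_sites_total) {
  n <- nrow(ing)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(ing[i, ]) & !is.na(ing[j, ])
    tot <- tot + sum(ing[i, ok] != ing[j, ok])
  }
  tot / choose(n, 2) / n_sites_total
}

# Tajima's D from the 1989 definitions: pi_total by explicit pairwise
# averaging, S by counting, constants spelled out
oracle_tajima_d <- function(ing) {
  n <- nrow(ing)
  poly <- apply(ing, 2, function(col) length(unique(col[!is.na(col)])) > 1)
  S <- sum(poly)
  if (S == 0) return(NA_real_)
  k <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    k <- k + sum(ing[i, ] != ing[j, ], na.rm = TRUE)
  k <- k / choose(n, 2)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# average r^2 over pairs of biallelic non-singleton sites, from explicit
# 2x2 haplotype counts
oracle_zns <- function(ing) {
  elig <- which(apply(ing, 2, function(col) {
    tab <- table(col[!is.na(col)])
    length(tab) == 2 && min(tab) >= 2
  }))
  if (length(elig) < 2) return(NA_real_)
  r2s <- c()
  for (a in seq_len(length(elig) - 1)) for (b in (a + 1):length(elig)) {
    ca <- ing[, elig[a]]; cb <- ing[, elig[b]]
    ok <- !is.na(ca) & !is.na(cb)
    ca <- ca[ok]; cb <- cb[ok]
    A <- sort(unique(ca))[1]; B <- sort(unique(cb))[1]
    pA <- mean(ca == A); pB <- mean(cb == B)
    if (pA %in% c(0, 1) || pB %in% c(0, 1)) next
    pAB <- mean(ca == A & cb == B)
    r2s <- c(r2s, (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB)))
  }
  if (!length(r2s)) NA_real_ else mean(r2s)
}

# two-sided Fisher exact P by enumerating all tables with the observed
# margins; tables with probability <= observed (up to R's tie tolerance)
# are summed
oracle_fisher <- function(tab) {
  m <- sum(tab[, 1]); nn <- sum(tab[, 2]); kk <- sum(tab[1, ])
  x <- tab[1, 1]
  lo <- max(0, kk - nn); hi <- min(kk, m)
  probs <- dhyper(lo:hi, m, nn, kk)
  obs <- dhyper(x, m, nn, kk)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# two-sided Mann-Whitney exact P by enumerating all assignments of the
# pooled tie-free sample
oracle_mw <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  U_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  obs <- U_of(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  Us <- apply(combos, 2, U_of)
  mu <- n1 * n2 / 2
  # two-sided: double the smaller tail (capped), matching wilcox.test
  lo <- mean(Us <= obs); hi <- mean(Us >= obs)
  min(1, 2 * min(lo, hi))
}

# random small ingroup-only alignment for oracle equivalence checks
random_alignment <- function(seed, n = NULL, n_sites = NULL, L = 1000) {
  set.seed(seed)
  if (is.null(n)) n <- sample(4:10, 1)
  if (is.null(n_sites)) n_sites <- sample(5:200, 1)
  pos <- sort(sample.int(L, n_sites)) - 1L
  M <- matrix("A", n, n_sites)
  for (j in seq_len(n_sites)) {
    alt <- sample(c("C", "G", "T"), 1)
    carriers <- sample.int(n, sample.int(n - 1, 1))
    M[carriers, j] <- alt
  }
  haplotype_alignment("chr", L, pos, M, rep("ingroup", n))
}

# small sim config used across tests (desk-scale forward runs)
tiny_forward_cfg <- function(seed, L = 3e4, sweep = NULL) {
  sim_config(seed = seed, L = L, theta = 0.004, rho = 0.002, n_pop = 60,
             n_ingroup = 8, sweep = sweep)
}
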