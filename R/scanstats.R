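#' Nucleotide diversity per window
#'
#' Per-site nucleotide diversity \eqn{\pi} in each window, computed as the
#' sum over usable sites of \eqn{2\hat p(1-\hat p)\, n_i/(n_i-1)} divided
#' by the number of callable sites in the window, where \eqn{n_i} is the
#' number of callable ingroup haplotypes at site \eqn{i} and \eqn{\hat p}
#' the sample allele fraction. The \eqn{n_i/(n_i-1)} factor is the
#' unequal-sample-size correction; the result equals the mean pairwise
#' Hamming distance per callable site.
#'
#' Sites with fewer than `min_called` callable haplotypes or more than two
#' alleles are dropped from all statistics. Windows with zero callable
#' sites return `NA`.
#'
#' @param aln A [haplotype_alignment()].
#' @param windows data.frame with `start`, `end` (half-open bp), e.g. from
#'   [make_windows()].
#' @param min_called Minimum callable ingroup haplotypes for a site to
#'   count (default 4).
#' @return Numeric vector of per-window \eqn{\pi}.
#' @export
window_pi <- function(aln, windows, min_called = 4L) {
  ss <- .site_summary(aln, min_called)
  contrib <- .pi_site_contrib(ss)
  vapply(seq_len(nrow(windows)), function(w) {
    ncall <- windows$end[w] - windows$start[w]
    if (ncall <= 0) return(NA_real_)
    j <- .sites_in(aln, windows$start[w], windows$end[w])
    sum(contrib[j]) / ncall
  }, numeric(1))
}

# indices of variable sites inside [start, end)
.sites_in <- function(aln, start, end) {
  which(aln$positions >= start & aln$positions < end)
}

# per-site pi contribution (0 for unusable or monomorphic sites)
.pi_site_contrib <- function(ss) {
  p <- ss$count1 / ss$n_called
  out <- ifelse(ss$polymorphic,
                2 * p * (1 - p) * ss$n_called / (ss$n_called - 1), 0)
  out[!is.finite(out)] <- 0
  out
}

# Tajima (1989) normalizing constants for sample size n
.tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D in a window
#'
#' Standard normalized difference between the pairwise-diversity and
#' segregating-sites estimators of \eqn{\theta}. Returns `NA` when the
#' window has no usable segregating sites or fewer than 4 ingroup
#' haplotypes. The sample size entering the constants is the number of
#' ingroup haplotypes.
#'
#' @inheritParams window_pi
#' @param window Optional single window (list/row with `start`, `end`);
#'   default spans the whole chromosome.
#' @return Tajima's D (scalar) or per-window vector when `windows` given.
#' @export
tajima_d <- function(aln, window = NULL, windows = NULL, min_called = 4L) {
  n <- sum(aln$roles == "ingroup")
  if (n < 4L) return(NA_real_)
  k <- .tajima_constants(n)
  ss <- .site_summary(aln, min_called)
  contrib <- .pi_site_contrib(ss)
  one <- function(start, end) {
    j <- .sites_in(aln, start, end)
    S <- sum(ss$polymorphic[j])
    if (S < 1L) return(NA_real_)
    pi_total <- sum(contrib[j])
    (pi_total - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  }
  if (!is.null(windows))
    return(vapply(seq_len(nrow(windows)),
                  function(w) one(windows$start[w], windows$end[w]),
                  numeric(1)))
  if (is.null(window)) window <- list(start = 0L, end = aln$L)
  one(window$start, window$end)
}

#' Kelly's Z_nS in a window
#'
#' Unweighted average pairwise \eqn{r^2} over all unordered pairs of
#' eligible sites: biallelic, usable, and non-singleton (minor or derived
#' allele count of 1 excluded). \eqn{r^2} is computed on haplotypes
#' callable at both sites. Windows with fewer than two eligible sites
#' return `NA`.
#'
#' @inheritParams tajima_d
#' @return Z_nS value in `[0, 1]`, or per-window vector.
#' @export
znS <- function(aln, window = NULL, windows = NULL, min_called = 4L) {
  ss <- .site_summary(aln, min_called)
  minor <- pmin(ss$count1, ss$count2)
  eligible <- ss$polymorphic & minor >= 2L
  ing <- ingroup_alleles(aln)
  one <- function(start, end) {
    j <- intersect(.sites_in(aln, start, end), which(eligible))
    if (length(j) < 2L) return(NA_real_)
    # indicator matrix: carrier of allele1 at each eligible site
    X <- ing[, j, drop = FALSE] == matrix(ss$allele1[j], nrow(ing),
                                          length(j), byrow = TRUE)
    if (!anyNA(X)) {
      # complete data: all pairwise r2 in one crossproduct
      nh <- nrow(X)
      p <- colMeans(X)
      keep <- p > 0 & p < 1
      X <- X[, keep, drop = FALSE]; p <- p[keep]
      if (ncol(X) < 2L) return(NA_real_)
      pab <- crossprod(X) / nh
      D <- pab - tcrossprod(p)
      r2m <- D^2 / tcrossprod(p * (1 - p))
      ut <- upper.tri(r2m)
      return(mean(r2m[ut]))
    }
    r2 <- 0; np <- 0L
    for (a in seq_len(length(j) - 1L)) for (b in (a + 1L):length(j)) {
      ok <- !is.na(X[, a]) & !is.na(X[, b])
      pa <- mean(X[ok, a]); pb <- mean(X[ok, b])
      if (pa %in% c(0, 1) || pb %in% c(0, 1)) next
      pab <- mean(X[ok, a] & X[ok, b])
      r2 <- r2 + (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
      np <- np + 1L
    }
    if (np == 0L) NA_real_ else r2 / np
  }
  if (!is.null(windows))
    return(vapply(seq_len(nrow(windows)),
                  function(w) one(windows$start[w], windows$end[w]),
                  numeric(1)))
  if (is.null(window)) window <- list(start = 0L, end = aln$L)
  one(window$start, window$end)
}

#' Windowed divergence from an outgroup
#'
#' Proportion of differing sites (Hamming distance per jointly callable
#' site) between an ingroup sequence and one outgroup, per window. Windows
#' in which the jointly aligned fraction does not exceed
#' `min_aligned_fraction` of the window are excluded (`NA`, flagged in the
#' `excluded` attribute).
#'
#' @inheritParams window_pi
#' @param outgroup Outgroup role, `"outgroup_far"` (default) or
#'   `"outgroup_near"`.
#' @param ingroup `"consensus"` (majority-rule, default) or the name of a
#'   single ingroup sample.
#' @param min_aligned_fraction Required aligned fraction (default 0.10,
#'   strict: a window is kept only if the fraction is strictly greater).
#' @return Numeric vector of per-window Hamming divergence, with attribute
#'   `excluded` (logical) marking filtered windows.
#' @export
window_divergence <- function(aln, windows, outgroup = "outgroup_far",
                              ingroup = "consensus",
                              min_aligned_fraction = 0.10) {
  og <- outgroup_alleles(aln, outgroup)
  ing <- if (identical(ingroup, "consensus")) .ingroup_consensus(aln)
         else {
           if (!ingroup %in% rownames(aln$alleles))
             .stopf("no sample named '%s'", ingroup)
           aln$alleles[ingroup, ]
         }
  joint <- !is.na(ing) & !is.na(og)
  diffs <- joint & ing != og
  d <- rep(NA_real_, nrow(windows))
  excluded <- rep(FALSE, nrow(windows))
  for (w in seq_len(nrow(windows))) {
    width <- windows$end[w] - windows$start[w]
    j <- .sites_in(aln, windows$start[w], windows$end[w])
    # every position absent from the variable-site list is aligned and equal
    aligned <- width - sum(!joint[j])
    if (width <= 0 || aligned <= min_aligned_fraction * width) {
      excluded[w] <- TRUE
      next
    }
    d[w] <- sum(diffs[j]) / aligned
  }
  attr(d, "excluded") <- excluded
  d
}

#' Jukes--Cantor distance
#'
#' Corrects a raw proportion of differing sites for multiple hits:
#' \eqn{d = -\frac{3}{4}\ln(1 - \frac{4p}{3})}. Defined for
#' \eqn{0 \le p < 0.75}; larger values return `NA` with a warning.
#'
#' @param p Proportion of differing sites (vectorized).
#' @return Corrected distance, always `>= p`.
#' @export
jukes_cantor <- function(p) {
  if (any(p < 0, na.rm = TRUE)) .stopf("p must be non-negative")
  out <- ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
  if (any(p >= 0.75, na.rm = TRUE))
    warning("Jukes-Cantor distance undefined for p >= 0.75; returning NA")
  out
}

#' Windowed polymorphism/divergence scan
#'
#' One row per window: callable sites, segregating sites, \eqn{\pi},
#' Tajima's D, Z_nS, Hamming divergence to the far outgroup and its
#' Jukes--Cantor correction.
#'
#' @inheritParams window_divergence
#' @param windows Window grid; defaults to nonoverlapping 10-kb windows.
#' @return data.frame of per-window statistics (class `window_stats`).
#' @export
window_scan <- function(aln, windows = NULL, min_called = 4L,
                        min_aligned_fraction = 0.10) {
  if (is.null(windows)) windows <- make_windows(aln$L, chrom = aln$chrom)
  ss <- .site_summary(aln, min_called)
  S <- vapply(seq_len(nrow(windows)), function(w)
    sum(ss$polymorphic[.sites_in(aln, windows$start[w], windows$end[w])]),
    numeric(1))
  out <- data.frame(
    chrom = if ("chrom" %in% names(windows)) windows$chrom else aln$chrom,
    start = windows$start, end = windows$end,
    n_callable_sites = windows$end - windows$start,
    S = as.integer(S),
    pi = window_pi(aln, windows, min_called),
    tajima_d = tajima_d(aln, windows = windows, min_called = min_called),
    znS = znS(aln, windows = windows, min_called = min_called))
  if (any(aln$roles == "outgroup_far")) {
    dh <- window_divergence(aln, windows,
                            min_aligned_fraction = min_aligned_fraction)
    out$d_hamming <- as.numeric(dh)
    out$d_jc <- jukes_cantor(out$d_hamming)
    out$divergence_excluded <- attr(dh, "excluded")
  }
  class(out) <- c("window_stats", "data.frame")
  out
}

#' Per-sequence-class summaries
#'
#' Recomputes \eqn{\pi}, Tajima's D and divergence restricted to each
#' sequence class of a per-site class map (see [classify_sites()]).
#' Classes with zero sites are omitted.
#'
#' @param aln A [haplotype_alignment()].
#' @param classmap Either a `site_class_map` or a character/factor vector
#'   of length `aln$L` giving each position's class.
#' @param min_called Minimum callable haplotypes per site.
#' @return data.frame with one row per class: `class`, `n_sites`, `S`,
#'   `pi`, `tajima_d`, `d_hamming`, `d_jc`.
#' @export
class_summaries <- function(aln, classmap, min_called = 4L) {
  labels <- if (inherits(classmap, "site_class_map")) classmap$class
            else as.character(classmap)
  if (length(labels) != aln$L)
    .stopf("classmap must label all %d positions", aln$L)
  n <- sum(aln$roles == "ingroup")
  k <- if (n >= 4L) .tajima_constants(n) else NULL
  ss <- .site_summary(aln, min_called)
  contrib <- .pi_site_contrib(ss)
  og <- if (any(aln$roles == "outgroup_far"))
    outgroup_alleles(aln, "outgroup_far") else NULL
  cons <- if (!is.null(og)) .ingroup_consensus(aln) else NULL
  site_class <- labels[aln$positions + 1L]
  rows <- lapply(sort(unique(labels)), function(cl) {
    n_sites <- sum(labels == cl)
    if (n_sites == 0L) return(NULL)
    j <- which(site_class == cl)
    S <- sum(ss$polymorphic[j])
    pi <- sum(contrib[j]) / n_sites
    td <- NA_real_
    if (!is.null(k) && S >= 1L) {
      pt <- sum(contrib[j])
      td <- (pt - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
    }
    dh <- NA_real_
    if (!is.null(og)) {
      joint <- !is.na(cons[j]) & !is.na(og[j])
      aligned <- n_sites - sum(!joint)
      dh <- sum(joint & cons[j] != og[j]) / aligned
    }
    data.frame(class = cl, n_sites = n_sites, S = as.integer(S), pi = pi,
               tajima_d = td, d_hamming = dh, d_jc = jukes_cantor(dh))
  })
  do.call(rbind, rows)
}
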