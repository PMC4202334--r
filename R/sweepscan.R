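#' Polarized unfolded site frequency spectra per window
#'
#' For each window, counts \eqn{\xi_1 \ldots \xi_{n-1}} of derived-allele
#' frequencies among the \eqn{n} ingroup haplotypes, polarized by strict
#' outgroup agreement: a site enters only when a derived state is present
#' in at least one ingroup sample but absent from both outgroups (both
#' outgroups callable and carrying the same ingroup allele, taken as
#' ancestral). Windows with fewer than `min_aligned` aligned sites are
#' flagged ineligible.
#'
#' @param aln A [haplotype_alignment()] with both outgroups.
#' @param windows Window grid (default nonoverlapping 10 kb).
#' @param min_aligned Eligibility threshold on aligned sites per window
#'   (default 5000).
#' @param min_called Minimum callable ingroup haplotypes per site.
#' @return data.frame (class `window_sfs`): `chrom`, `start`, `end`,
#'   `aligned_sites`, `eligible`, plus columns `xi1` ... `xi(n-1)`.
#' @export
polarized_sfs <- function(aln, windows = NULL, min_aligned = 5000L,
                          min_called = 4L) {
  if (!all(c("outgroup_near", "outgroup_far") %in% aln$roles))
    .stopf("polarization requires both outgroups")
  if (is.null(windows)) windows <- make_windows(aln$L, chrom = aln$chrom)
  n <- sum(aln$roles == "ingroup")
  ss <- .site_summary(aln, min_called)
  near <- outgroup_alleles(aln, "outgroup_near")
  far <- outgroup_alleles(aln, "outgroup_far")
  # derived count per polarizable site (NA where the filter rejects)
  dc <- rep(NA_integer_, length(aln$positions))
  pol <- which(ss$polymorphic & !is.na(near) & !is.na(far) & near == far)
  for (j in pol) {
    anc <- near[j]
    if (anc == ss$allele1[j]) dc[j] <- ss$count2[j]
    else if (anc == ss$allele2[j]) dc[j] <- ss$count1[j]
    # else: outgroup allele absent from the ingroup -> unusable
  }
  xi <- matrix(0L, nrow(windows), n - 1L,
               dimnames = list(NULL, paste0("xi", seq_len(n - 1L))))
  aligned <- integer(nrow(windows))
  for (w in seq_len(nrow(windows))) {
    width <- windows$end[w] - windows$start[w]
    aligned[w] <- width  # simulated alignments are fully callable
    j <- .sites_in(aln, windows$start[w], windows$end[w])
    cnt <- dc[j]
    cnt <- cnt[!is.na(cnt) & cnt >= 1L & cnt <= n - 1L]
    if (length(cnt)) {
      tb <- tabulate(cnt, nbins = n - 1L)
      xi[w, ] <- tb
    }
  }
  out <- data.frame(chrom = if ("chrom" %in% names(windows)) windows$chrom
                            else aln$chrom,
                    start = windows$start, end = windows$end,
                    aligned_sites = aligned,
                    eligible = aligned >= min_aligned)
  out <- cbind(out, as.data.frame(xi))
  class(out) <- c("window_sfs", "data.frame")
  out
}

# sweep-transformed spectra: T[E+1, j] proportional to P(derived count j
# and site still polymorphic | E of n lineages escaped the sweep), for a
# site that was polymorphic (background-distributed) before the sweep.
# Escaped lineages draw ancestry from the background spectrum; the trapped
# lineages coalesce into one lineage through the sweep, so a site with E
# escapees behaves as a background draw of m = E + 1 exchangeable lineages,
# one of which is then expanded to n - E copies. Rows are NOT renormalized:
# a fully trapped site (E = 0) is monomorphic with certainty and carries no
# polymorphic mass. Conditioning on observing a polymorphic site happens on
# the mixture over E, in the caller.
.sweep_transform_table <- function(bg, n) {
  stopifnot(length(bg) == n - 1L)
  bg <- bg / sum(bg)
  TT <- matrix(0, n + 1L, n - 1L)
  for (E in 0:n) {
    if (E == n) { TT[E + 1L, ] <- bg; next }
    m <- E + 1L
    # downsampled background: derived count i among m of the n lineages
    q <- numeric(m + 1L)
    for (k in seq_len(n - 1L)) {
      i <- 0:m
      q <- q + bg[k] * stats::dhyper(i, k, n - k, m)
    }
    pj <- numeric(n + 1L)  # index = j + 1, j in 0..n
    for (i in 0:m) {
      if (q[i + 1L] == 0) next
      p_block_derived <- i / m
      # block ancestral: the i derived alleles sit on escaped lineages
      if (i <= E) pj[i + 1L] <- pj[i + 1L] + q[i + 1L] * (1 - p_block_derived)
      # block derived: n - E copies of the derived allele plus i - 1 escapees
      j <- (i - 1L) + (n - E)
      if (i >= 1L) pj[j + 1L] <- pj[j + 1L] + q[i + 1L] * p_block_derived
    }
    TT[E + 1L, ] <- pj[2:n]  # j = 1 .. n-1; mass < 1 is monomorphic loss
  }
  TT
}

#' Composite-likelihood sweep scan
#'
#' For each eligible window, contrasts the composite likelihood of the
#' polarized SFS under the chromosome-wide background spectrum against a
#' complete-sweep alternative centred on the window midpoint. Under the
#' alternative each lineage escapes the sweep with probability
#' \eqn{p_e = 1 - \exp(-\alpha_s d)} (\eqn{d} = distance from the site to
#' the window midpoint); escaped lineages draw from the background
#' spectrum while trapped lineages coalesce through the sweep. The
#' statistic \eqn{\Lambda = 2(\ln L_{alt} - \ln L_{null})}, maximized
#' over a log-spaced grid of \eqn{\alpha_s} and floored at 0, is referred
#' to a chi-squared distribution with `df` degrees of freedom (default 9,
#' an acknowledged approximation whose calibration should be measured on
#' neutral data).
#'
#' @param sfs A `window_sfs` data.frame from [polarized_sfs()].
#' @param background Optional background spectrum (length n-1); default
#'   the normalized sum of the eligible windows' spectra, per chromosome.
#' @param grid_size Number of \eqn{\alpha_s} grid points (default 30).
#' @param grid_range Range of \eqn{\alpha_s} in units of 1/window-span
#'   (default `c(1e-2, 1e2)`).
#' @param df Degrees of freedom for the reference distribution.
#' @param alpha_level Significance threshold on the P-value (default 0.05).
#' @param include_invariant Model the per-window density of polymorphic
#'   sites as well as the spectrum shape (default TRUE). Trapped lineages
#'   lose their polymorphism, so a sweep predicts both a distorted
#'   spectrum and fewer polymorphic sites; the invariant-site term
#'   carries the second signal. `FALSE` gives the shape-only statistic.
#' @return data.frame (class `clr_result`): window coordinates, `n_sites`,
#'   `lambda`, `alpha_s` at the maximum, `p_value`, `significant`,
#'   `eligible`.
#' @export
clr_scan <- function(sfs, background = NULL, grid_size = 30L,
                     grid_range = c(1e-2, 1e2), df = 9, alpha_level = 0.05,
                     include_invariant = TRUE) {
  xi_cols <- grep("^xi", names(sfs))
  n <- length(xi_cols) + 1L
  out <- sfs[, c("chrom", "start", "end", "eligible")]
  out$n_sites <- as.integer(rowSums(sfs[, xi_cols, drop = FALSE]))
  out$lambda <- NA_real_
  out$alpha_s <- NA_real_
  for (ch in unique(sfs$chrom)) {
    rows <- which(sfs$chrom == ch & sfs$eligible)
    if (!length(rows)) next
    bg <- colSums(sfs[rows, xi_cols, drop = FALSE])
    if (!is.null(background)) bg <- background
    if (sum(bg) == 0) .stopf("empty background SFS on chromosome %s", ch)
    bg <- bg / sum(bg)
    span <- stats::median(sfs$end[rows] - sfs$start[rows])
    alpha_grid <- exp(seq(log(grid_range[1] / span),
                          log(grid_range[2] / span),
                          length.out = grid_size))
    # The window SFS aggregates sites by frequency class, so sites enter
    # the likelihood at the representative distance of a uniformly placed
    # site from the window midpoint, d = span/4; alpha_s and d act only
    # through p_e = 1 - exp(-alpha_s d).
    TT <- .sweep_transform_table(bg, n)
    pe_grid <- 1 - exp(-alpha_grid * span / 4)
    WE <- t(vapply(pe_grid, function(pe) stats::dbinom(0:n, n, pe),
                   numeric(n + 1L)))
    mix <- WE %*% TT  # grid x (n-1), polymorphic mass retained post-sweep
    retained <- rowSums(mix)  # <= 1; the rest went monomorphic
    shape <- log(pmax(mix / retained, 1e-300))
    logbg <- log(pmax(bg, 1e-300))
    # background per-site polymorphism rate (for the density term)
    q0 <- sum(sfs[rows, xi_cols]) / sum(sfs$aligned_sites[rows])
    for (w in rows) {
      xi <- as.numeric(sfs[w, xi_cols])
      S <- sum(xi)
      A <- sfs$aligned_sites[w]
      if (S == 0 && !include_invariant) { out$lambda[w] <- 0; next }
      lnull <- sum(xi * logbg)
      scores <- as.numeric(shape %*% xi)
      if (include_invariant) {
        lnull <- lnull + S * log(q0) + (A - S) * log(1 - q0)
        scores <- scores + S * log(pmax(q0 * retained, 1e-300)) +
          (A - S) * log(1 - q0 * retained)
      }
      best <- which.max(scores)
      out$lambda[w] <- max(0, 2 * (scores[best] - lnull))
      out$alpha_s[w] <- alpha_grid[best]
    }
  }
  out$p_value <- ifelse(is.na(out$lambda), NA_real_,
                        chisq_pvalue(pmax(out$lambda, 0), df))
  out$significant <- !is.na(out$p_value) & out$p_value < alpha_level
  class(out) <- c("clr_result", "data.frame")
  out
}

#' Composite-likelihood P-value
#'
#' Upper-tail chi-squared probability of a CLR statistic with `df`
#' degrees of freedom (default 9, matching the windowed sweep scan).
#'
#' @param lambda Non-negative CLR statistic (vectorized).
#' @param df Degrees of freedom.
#' @return P-value in (0, 1].
#' @export
clr_pvalue <- function(lambda, df = 9) {
  if (any(lambda < 0, na.rm = TRUE)) .stopf("lambda must be >= 0")
  chisq_pvalue(lambda, df)
}

#' Window bookkeeping summary of a sweep scan
#'
#' Counts eligible and significant windows and their percentage.
#'
#' @param clr A `clr_result` data.frame (needs `eligible` and either
#'   `significant` or `p_value`).
#' @param alpha_level Threshold used when only `p_value` is present.
#' @return list: `n_eligible`, `n_significant`, `pct_significant`.
#' @export
scan_summary <- function(clr, alpha_level = 0.05) {
  elig <- if ("eligible" %in% names(clr)) clr$eligible else rep(TRUE, nrow(clr))
  sig <- if ("significant" %in% names(clr)) clr$significant
         else clr$p_value < alpha_level
  n_el <- sum(elig, na.rm = TRUE)
  n_sig <- sum(sig & elig, na.rm = TRUE)
  list(n_eligible = n_el, n_significant = n_sig,
       pct_significant = 100 * n_sig / n_el)
}

# Viterbi decoding for the two-state sweep/nonsweep chain. Observations
# are per-window significance indicators; emissions P(sig | sweep) = e_s,
# P(sig | nonsweep) = e_n; the probability of switching state between
# adjacent windows is f(1 - f) with f the marginal frequency of
# significant windows. Ties break toward nonsweep.
.viterbi_sweep <- function(obs, e_s, e_n) {
  f <- mean(obs)
  if (f == 0) return(rep(FALSE, length(obs)))
  if (f == 1) return(rep(TRUE, length(obs)))
  t_sw <- f * (1 - f)
  lt <- log(c(stay = 1 - t_sw, switch = t_sw))
  le <- rbind(nonsweep = log(c(`FALSE` = 1 - e_n, `TRUE` = e_n)),
              sweep = log(c(`FALSE` = 1 - e_s, `TRUE` = e_s)))
  m <- length(obs)
  delta <- matrix(-Inf, 2, m)  # rows: nonsweep, sweep
  psi <- matrix(1L, 2, m)
  o1 <- as.character(obs[1])
  delta[, 1] <- log(0.5) + le[, o1]
  for (t in 2:m) {
    ot <- as.character(obs[t])
    for (s in 1:2) {
      cand <- delta[, t - 1] + ifelse(1:2 == s, lt["stay"], lt["switch"])
      # tie toward nonsweep (state 1)
      best <- which.max(cand)
      if (cand[1] == cand[2]) best <- 1L
      delta[s, t] <- cand[best] + le[s, ot]
      psi[s, t] <- best
    }
  }
  path <- integer(m)
  path[m] <- if (delta[2, m] > delta[1, m]) 2L else 1L
  for (t in (m - 1L):1L) path[t] <- psi[path[t + 1L], t + 1L]
  path == 2L
}

#' Segment a sweep scan into candidate sweep regions
#'
#' Groups contiguous windows into putative sweep regions with a two-state
#' ("sweep"/"nonsweep") hidden Markov model. The observation for each
#' eligible window is its significance indicator (P < `alpha_level`);
#' emission probabilities of a significant window are `e_s` under sweep
#' and `e_n` under nonsweep; the probability of switching state between
#' adjacent windows is \eqn{f(1-f)} with \eqn{f} the marginal frequency
#' of significant windows. The Viterbi path is decoded (ties toward
#' nonsweep) and maximal runs of the sweep state become regions.
#' Ineligible windows are skipped (treated as missing observations).
#'
#' @param clr A `clr_result` data.frame, ordered along the chromosome.
#' @param e_s,e_n Emission probabilities (defaults 0.95 / 0.05).
#' @param alpha_level Significance threshold (default 0.05).
#' @param min_region_bp Minimum reported region length (default 0; use
#'   20000 for a Table-4-style list).
#' @return data.frame (class `sweep_regions`): `chrom`, `start`, `end`,
#'   `n_windows`, `length_bp`, `length_kb`.
#' @export
hmm_segment <- function(clr, e_s = 0.95, e_n = 0.05, alpha_level = 0.05,
                        min_region_bp = 0) {
  stopifnot(e_s > e_n)
  regions <- list()
  for (ch in unique(clr$chrom)) {
    sub <- clr[clr$chrom == ch & clr$eligible & !is.na(clr$p_value), ]
    if (!nrow(sub)) next
    sub <- sub[order(sub$start), ]
    obs <- sub$p_value < alpha_level
    state <- .viterbi_sweep(obs, e_s, e_n)
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      regions[[length(regions) + 1L]] <-
        data.frame(chrom = ch, start = sub$start[starts[i]],
                   end = sub$end[ends[i]],
                   n_windows = r$lengths[i])
    }
  }
  if (!length(regions)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0),
                      length_bp = integer(0), length_kb = numeric(0))
  } else {
    out <- do.call(rbind, regions)
    out$length_bp <- out$end - out$start
    out$length_kb <- out$length_bp / 1000
    out <- out[out$length_bp >= min_region_bp, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("sweep_regions", "data.frame")
  out
}

#' Genetic-map length of regions
#'
#' Converts physical region spans to centimorgans by linear interpolation
#' of a marker map. Regions extending beyond the mapped span are refused
#' (NA, with a warning) rather than extrapolated.
#'
#' @param regions `sweep_regions` data.frame (or any with `chrom`,
#'   `start`, `end`).
#' @param genetic_map data.frame with columns `chrom`, `bp`, `cM`
#'   (monotone in `bp` within a chromosome).
#' @return Numeric vector of cM spans, one per region.
#' @export
region_cM <- function(regions, genetic_map) {
  vapply(seq_len(nrow(regions)), function(i) {
    m <- genetic_map[genetic_map$chrom == regions$chrom[i], ]
    if (nrow(m) < 2L) {
      warning("genetic map has < 2 markers on ", regions$chrom[i])
      return(NA_real_)
    }
    m <- m[order(m$bp), ]
    if (regions$start[i] < min(m$bp) || regions$end[i] > max(m$bp)) {
      warning("region outside genetic map span; extrapolation refused")
      return(NA_real_)
    }
    cm <- stats::approx(m$bp, m$cM, xout = c(regions$start[i],
                                             regions$end[i]))$y
    cm[2] - cm[1]
  }, numeric(1))
}

#' Arm-matched randomization test for candidate windows
#'
#' Compares summary statistics of a candidate window set (e.g. the
#' significant sweep-scan windows) with sets of the same per-arm sizes
#' drawn at random without replacement from all windows. The empirical
#' P-value is \eqn{(1 + \#\{\text{replicates at least as extreme}\})/(R + 1)}.
#' Directions: lower-tail for mean \eqn{\pi}, upper-tail for mean Z_nS
#' and for the variance of Tajima's D, two-sided for mean Tajima's D.
#'
#' @param candidates data.frame of candidate windows (must carry `chrom`
#'   and the statistic columns).
#' @param all_windows data.frame of all eligible windows (superset).
#' @param stats Statistic columns to test (subset of `pi`, `znS`,
#'   `tajima_d`; `var_tajima_d` is always added when `tajima_d` is
#'   present).
#' @param R Number of replicates (default 1000).
#' @param seed Integer seed.
#' @return data.frame: `stat`, `observed`, `p_value`, `direction`.
#' @export
randomization_test <- function(candidates, all_windows,
                               stats = c("pi", "znS", "tajima_d"),
                               R = 1000L, seed = 1L) {
  stats <- intersect(stats, names(all_windows))
  if (!length(stats)) .stopf("no requested statistic column present")
  arms <- table(candidates$chrom)
  for (a in names(arms)) {
    avail <- sum(all_windows$chrom == a)
    if (arms[[a]] > avail)
      .stopf("arm %s has %d candidates but only %d windows", a, arms[[a]], avail)
  }
  smean <- function(df) vapply(stats, function(s)
    mean(df[[s]], na.rm = TRUE), numeric(1))
  svar <- function(df) if ("tajima_d" %in% stats)
    stats::var(df$tajima_d, na.rm = TRUE) else NULL
  obs_mean <- smean(candidates)
  obs_var <- svar(candidates)
  arm_rows <- lapply(names(arms), function(a) which(all_windows$chrom == a))
  names(arm_rows) <- names(arms)
  reps_mean <- matrix(NA_real_, R, length(stats),
                      dimnames = list(NULL, stats))
  reps_var <- numeric(R)
  .with_seed(seed, {
    for (r in seq_len(R)) {
      idx <- unlist(lapply(names(arms), function(a)
        arm_rows[[a]][sample.int(length(arm_rows[[a]]), arms[[a]])]))
      sub <- all_windows[idx, , drop = FALSE]
      reps_mean[r, ] <- smean(sub)
      if (!is.null(obs_var)) reps_var[r] <- svar(sub)
    }
  })
  emp <- function(extreme) (1 + sum(extreme, na.rm = TRUE)) / (R + 1)
  rows <- lapply(stats, function(s) {
    if (s == "pi") {
      p <- emp(reps_mean[, s] <= obs_mean[s]); dir <- "lower"
    } else if (s == "znS") {
      p <- emp(reps_mean[, s] >= obs_mean[s]); dir <- "higher"
    } else {
      lo <- emp(reps_mean[, s] <= obs_mean[s])
      hi <- emp(reps_mean[, s] >= obs_mean[s])
      p <- min(1, 2 * min(lo, hi)); dir <- "two-sided"
    }
    data.frame(stat = s, observed = unname(obs_mean[s]), p_value = p,
               direction = dir)
  })
  out <- do.call(rbind, rows)
  if (!is.null(obs_var)) {
    out <- rbind(out, data.frame(stat = "var_tajima_d", observed = obs_var,
                                 p_value = emp(reps_var >= obs_var),
                                 direction = "higher"))
  }
  rownames(out) <- NULL
  out
}
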