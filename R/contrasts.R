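#' X-versus-autosome contrast of a window statistic
#'
#' Mean of the statistic over X-linked and autosomal windows, their
#' ratio, and a two-sided Mann--Whitney U test comparing the two window
#' distributions (exact enumeration for small tie-free samples, normal
#' approximation with tie correction otherwise, as provided by
#' [stats::wilcox.test()]).
#'
#' @param window_stats data.frame of per-window statistics with a `chrom`
#'   column.
#' @param stat Name of the statistic column.
#' @param x_chroms Chromosome names counted as X-linked (default `"X"`).
#' @param exact_max Use exact enumeration when both sample sizes are at
#'   most this (default 20); larger samples use the normal approximation.
#' @return list of class `chrom_contrast`: `stat`, `x_value`, `a_value`,
#'   `ratio`, `p_value`, `n_x`, `n_a`.
#' @export
xa_contrast <- function(window_stats, stat, x_chroms = "X",
                        exact_max = 20L) {
  if (!stat %in% names(window_stats)) .stopf("no column '%s'", stat)
  is_x <- window_stats$chrom %in% x_chroms
  xv <- window_stats[[stat]][is_x]
  av <- window_stats[[stat]][!is_x]
  xv <- xv[is.finite(xv)]; av <- av[is.finite(av)]
  if (!length(xv) || !length(av))
    .stopf("both X and autosome window sets must be non-empty")
  exact <- length(xv) <= exact_max && length(av) <= exact_max
  p <- suppressWarnings(
    stats::wilcox.test(xv, av, exact = exact)$p.value)
  structure(list(stat = stat, x_value = mean(xv), a_value = mean(av),
                 ratio = if (mean(av) != 0) mean(xv) / mean(av) else NA_real_,
                 p_value = p, n_x = length(xv), n_a = length(av)),
            class = "chrom_contrast")
}

#' @export
print.chrom_contrast <- function(x, ...) {
  cat(sprintf("%s: X = %.4g, A = %.4g, X/A = %.3f, P_MWU = %.3g (n = %d/%d)\n",
              x$stat, x$x_value, x$a_value, x$ratio, x$p_value, x$n_x, x$n_a))
  invisible(x)
}

#' Male:female mutation-rate ratio from X/A neutral divergence
#'
#' Under male-driven evolution the X/A ratio of neutral divergence is
#' \eqn{d_X/d_A = \frac{2}{3}\,(2 + \alpha_m)/(1 + \alpha_m)} with
#' \eqn{\alpha_m} the male:female mutation-rate ratio (the X spends 1/3
#' of its history in males versus 1/2 for autosomes). This function
#' inverts the relation:
#' \eqn{\alpha_m = (3 d - 4)/(2 - 3 d)}, defined for
#' \eqn{d \in (2/3, 4/3)}; `d = 1` gives symmetric rates and `d = 4/3`
#' the female-only limit.
#'
#' @param d_ratio X/A ratio of divergence at a putatively neutral
#'   sequence class.
#' @return list of class `mutation_ratio`: `alpha_m`, `d_ratio`.
#' @export
male_driven_alpha <- function(d_ratio) {
  .check_scalar(d_ratio, "d_ratio")
  if (d_ratio <= 2 / 3 || d_ratio >= 4 / 3)
    .stopf("d_ratio must lie in the open interval (2/3, 4/3); got %g", d_ratio)
  structure(list(alpha_m = (3 * d_ratio - 4) / (2 - 3 * d_ratio),
                 d_ratio = d_ratio),
            class = "mutation_ratio")
}

#' @export
print.mutation_ratio <- function(x, ...) {
  cat(sprintf("male:female mutation-rate ratio alpha_m = %.3f (d_X/d_A = %.3f)\n",
              x$alpha_m, x$d_ratio))
  invisible(x)
}

#' Repeat density per arm and class, with X/A fold-excess
#'
#' Computes the masked fraction of each chromosome arm for each repeat
#' class from a BED-style interval table (intervals are merged before
#' counting, so fragmented annotations give identical results), the X/A
#' fold-excess per class (autosomal reference = masked bp summed over all
#' autosomal arms), and a heterogeneity chi-squared across arms on
#' masked-bp counts (expected proportional to arm length; df = arms - 1).
#'
#' @param repeat_bed data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and `class`.
#' @param arm_lengths data.frame with `chrom` and `length`.
#' @param x_chroms Chromosome names counted as X-linked.
#' @return list of class `repeat_density`: `fractions` (arm x class
#'   matrix), `fold_excess` (per class), `heterogeneity` (per class:
#'   `chisq`, `df`, `p_value`).
#' @export
repeat_density <- function(repeat_bed, arm_lengths, x_chroms = "X") {
  arms <- arm_lengths$chrom
  classes <- sort(unique(repeat_bed$class))
  masked <- matrix(0, length(arms), length(classes),
                   dimnames = list(arms, classes))
  for (a in arms) for (cl in classes) {
    b <- repeat_bed[repeat_bed$chrom == a & repeat_bed$class == cl, ]
    if (!nrow(b)) next
    ir <- IRanges::reduce(IRanges::IRanges(start = b$start + 1L,
                                           end = b$end))
    masked[a, cl] <- sum(IRanges::width(ir))
  }
  lens <- setNames(arm_lengths$length, arms)
  fractions <- masked / lens
  is_x <- arms %in% x_chroms
  if (!any(is_x) || all(is_x))
    .stopf("need at least one X and one autosomal arm")
  fold <- vapply(classes, function(cl) {
    fx <- sum(masked[is_x, cl]) / sum(lens[is_x])
    fa <- sum(masked[!is_x, cl]) / sum(lens[!is_x])
    if (fa == 0) NA_real_ else fx / fa
  }, numeric(1))
  het <- lapply(classes, function(cl) {
    obs <- masked[, cl]
    if (sum(obs) == 0) return(list(chisq = 0, df = length(arms) - 1L,
                                   p_value = 1))
    expd <- sum(obs) * lens / sum(lens)
    chisq <- sum((obs - expd)^2 / expd)
    list(chisq = chisq, df = length(arms) - 1L,
         p_value = chisq_pvalue(chisq, length(arms) - 1L))
  })
  names(het) <- classes
  structure(list(fractions = fractions, fold_excess = fold,
                 heterogeneity = het,
                 note = paste("heterogeneity df = n_arms - 1; computed on",
                              "merged masked-bp counts")),
            class = "repeat_density")
}
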