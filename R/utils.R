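# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. `seed = NULL` leaves the RNG alone.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stopf("'%s' must be a finite numeric scalar", name)
  if (positive && x <= 0) .stopf("'%s' must be > 0", name)
  if (nonneg && x < 0) .stopf("'%s' must be >= 0", name)
  invisible(x)
}

#' Upper-tail chi-squared probability
#'
#' Tail probability \eqn{P(X^2 \ge stat)} for a chi-squared reference
#' distribution. Used for the composite-likelihood sweep scan (df = 9),
#' the X/autosome window-count contrast (df = 1), and repeat-density
#' heterogeneity tests.
#'
#' @param stat Non-negative chi-squared statistic (vectorized).
#' @param df Degrees of freedom.
#' @return Upper-tail probability in (0, 1].
#' @examples
#' chisq_pvalue(16.919, df = 9)  # ~0.05
#' @export
chisq_pvalue <- function(stat, df) {
  if (any(!is.finite(stat)) || any(stat < 0))
    .stopf("chi-squared statistic must be finite and non-negative")
  .check_scalar(df, "df", positive = TRUE)
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

#' Tiling window grid over a chromosome
#'
#' Half-open, base-pair windows `[start, end)` tiling `[0, L)`. The default
#' grid is nonoverlapping; a `stride` smaller than `size` yields sliding
#' windows.
#'
#' @param L Chromosome length in bp.
#' @param size Window size in bp (default 10 kb).
#' @param stride Step between window starts (defaults to `size`).
#' @param chrom Chromosome name attached to each window.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
make_windows <- function(L, size = 10000L, stride = size, chrom = "chr") {
  .check_scalar(L, "L", positive = TRUE)
  .check_scalar(size, "size", positive = TRUE)
  .check_scalar(stride, "stride", positive = TRUE)
  starts <- seq(0L, max(0L, as.integer(L) - 1L), by = as.integer(stride))
  starts <- starts[starts < L]
  data.frame(chrom = chrom, start = starts,
             end = pmin(starts + as.integer(size), as.integer(L)))
}
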