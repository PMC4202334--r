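#' Specification for synthetic MK count tables
#'
#' Parameters for a per-gene generator of fixed/polymorphic,
#' synonymous/nonsynonymous count tables with a known adaptive fraction.
#' Nonsynonymous mutation pressure is the synonymous pressure thinned by
#' the `constraint` fraction; adaptive nonsynonymous fixations are added
#' so that their expected share of all nonsynonymous fixations is
#' `alpha_true`. Neutral singletons arise in both polymorphism classes at
#' the neutral-spectrum rate for `n` haplotypes; additional segregating
#' deleterious nonsynonymous singletons (rate `deleterious_singleton`)
#' let the singleton-exclusion estimator be exercised.
#'
#' @param n_genes Number of genes.
#' @param mean_Ds,mean_Ps Expected synonymous fixations / polymorphisms
#'   per gene (> 0).
#' @param constraint Fraction of nonsynonymous mutations removed by
#'   purifying selection, in `[0, 1)`.
#' @param alpha_true True proportion of nonsynonymous fixations that are
#'   adaptive, in `[0, 1)`.
#' @param n Ingroup sample size governing the neutral singleton fraction
#'   \eqn{1/a_1(n)} (default 10).
#' @param deleterious_singleton Expected extra deleterious nonsynonymous
#'   singletons per gene (default 0).
#' @param seed Integer seed.
#' @return A `mk_sim_spec` list.
#' @export
mk_sim_spec <- function(n_genes, mean_Ds = 8, mean_Ps = 8, constraint = 0.7,
                        alpha_true = 0, n = 10L, deleterious_singleton = 0,
                        seed = 1L) {
  .check_scalar(n_genes, "n_genes", nonneg = TRUE)
  .check_scalar(mean_Ds, "mean_Ds", positive = TRUE)
  .check_scalar(mean_Ps, "mean_Ps", positive = TRUE)
  .check_scalar(constraint, "constraint", nonneg = TRUE)
  if (constraint >= 1) .stopf("constraint must be < 1")
  .check_scalar(alpha_true, "alpha_true", nonneg = TRUE)
  if (alpha_true >= 1) .stopf("alpha_true must be < 1")
  .check_scalar(deleterious_singleton, "deleterious_singleton", nonneg = TRUE)
  structure(list(n_genes = as.integer(n_genes), mean_Ds = mean_Ds,
                 mean_Ps = mean_Ps, constraint = constraint,
                 alpha_true = alpha_true, n = as.integer(n),
                 deleterious_singleton = deleterious_singleton,
                 seed = as.integer(seed)),
            class = "mk_sim_spec")
}

#' Simulate per-gene MK count tables with known truth
#'
#' Draws, for each gene, Poisson counts of synonymous fixations and
#' polymorphisms, constraint-thinned neutral nonsynonymous counts,
#' adaptive nonsynonymous fixations at the rate implied by `alpha_true`,
#' and singleton sub-counts. The realized number of adaptive fixations
#' per gene is recorded in the `Dn_adaptive` column, so the true pooled
#' adaptive fraction of any simulated data set is observable.
#'
#' @param spec A [mk_sim_spec()].
#' @return data.frame with one row per gene: `gene`, `Dn`, `Ds`, `Pn`,
#'   `Ps`, `Pn_singleton`, `Ps_singleton`, `Dn_adaptive`.
#' @export
simulate_mk_counts <- function(spec) {
  stopifnot(inherits(spec, "mk_sim_spec"))
  ng <- spec$n_genes
  if (ng == 0L)
    return(data.frame(gene = character(0), Dn = integer(0), Ds = integer(0),
                      Pn = integer(0), Ps = integer(0),
                      Pn_singleton = integer(0), Ps_singleton = integer(0),
                      Dn_adaptive = integer(0)))
  .with_seed(spec$seed, {
    omega0 <- 1 - spec$constraint
    q_singleton <- 1 / sum(1 / seq_len(spec$n - 1))  # neutral spectrum share
    Ds <- stats::rpois(ng, spec$mean_Ds)
    Ps <- stats::rpois(ng, spec$mean_Ps)
    Dn_neutral <- stats::rpois(ng, spec$mean_Ds * omega0)
    lam_adp <- spec$mean_Ds * omega0 * spec$alpha_true / (1 - spec$alpha_true)
    Dn_adp <- stats::rpois(ng, lam_adp)
    Pn_neutral <- stats::rpois(ng, spec$mean_Ps * omega0)
    Ps_sing <- stats::rbinom(ng, Ps, q_singleton)
    Pn_sing_neutral <- stats::rbinom(ng, Pn_neutral, q_singleton)
    Pn_del <- stats::rpois(ng, spec$deleterious_singleton)
    data.frame(gene = sprintf("g%05d", seq_len(ng)),
               Dn = Dn_neutral + Dn_adp, Ds = Ds,
               Pn = Pn_neutral + Pn_del, Ps = Ps,
               Pn_singleton = Pn_sing_neutral + Pn_del,
               Ps_singleton = Ps_sing,
               Dn_adaptive = Dn_adp)
  })
}
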