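#' Classify codon changes in a CDS alignment
#'
#' Walks an in-frame CDS alignment of ingroup haplotypes plus outgroup(s)
#' codon by codon and tabulates synonymous/nonsynonymous polymorphisms and
#' fixed differences against the standard genetic code. A fixed difference
#' requires all callable ingroup haplotypes to share one allele and the
#' outgroup another; a polymorphism requires at least two ingroup alleles.
#' Codons with more than one variable position, or containing missing
#' data, are dropped (count reported). Singleton polymorphisms (minor
#' ingroup allele carried by exactly one haplotype) are sub-counted so the
#' singleton-exclusion estimator can be applied downstream.
#'
#' @param cds Character matrix (rows = samples, columns = nucleotide
#'   positions; length divisible by 3) or a vector of equal-length
#'   strings. Row names identify samples.
#' @param ingroup Row indices or names of the ingroup haplotypes.
#' @param outgroup Row index or name of the outgroup used for fixed
#'   differences (the far outgroup in the pooled, unpolarized design).
#' @return list of class `mk_counts`: `Dn`, `Ds`, `Pn`, `Ps`,
#'   `Pn_singleton`, `Ps_singleton`, `n_codons_dropped`.
#' @export
classify_codon_changes <- function(cds, ingroup, outgroup) {
  if (!is.matrix(cds)) {
    cds <- do.call(rbind, strsplit(toupper(as.character(cds)), ""))
  }
  cds <- toupper(cds)
  if (ncol(cds) %% 3L != 0L) .stopf("CDS alignment length not divisible by 3")
  ing <- cds[ingroup, , drop = FALSE]
  og <- cds[outgroup, , drop = FALSE]
  if (nrow(og) != 1L) .stopf("exactly one outgroup row required")
  code <- Biostrings::GENETIC_CODE
  counts <- c(Dn = 0L, Ds = 0L, Pn = 0L, Ps = 0L,
              Pn_singleton = 0L, Ps_singleton = 0L)
  dropped <- 0L
  for (c0 in seq(1L, ncol(cds), by = 3L)) {
    cols <- c0:(c0 + 2L)
    block <- rbind(ing[, cols, drop = FALSE], og[, cols, drop = FALSE])
    if (any(is.na(block)) || any(!block %in% c("A", "C", "G", "T"))) {
      dropped <- dropped + 1L
      next
    }
    nvar <- sum(vapply(1:3, function(k) length(unique(block[, k])) > 1L,
                       logical(1)))
    if (nvar == 0L) next
    if (nvar > 1L) { dropped <- dropped + 1L; next }
    k <- which(vapply(1:3, function(k) length(unique(block[, k])) > 1L,
                      logical(1)))
    ing_al <- ing[, cols[k]]
    og_al <- og[1, cols[k]]
    ing_tab <- table(ing_al)
    base_codon <- paste(block[1, ], collapse = "")
    variant <- function(al) {
      cc <- block[1, ]; cc[k] <- al; paste(cc, collapse = "")
    }
    syn <- function(a, b) code[[variant(a)]] == code[[variant(b)]]
    if (length(ing_tab) >= 2L) {
      # ingroup polymorphism (biallelic by the nvar==1 guard)
      a <- names(ing_tab)[1]; b <- names(ing_tab)[2]
      s <- syn(a, b)
      counts[if (s) "Ps" else "Pn"] <- counts[if (s) "Ps" else "Pn"] + 1L
      if (min(ing_tab) == 1L) {
        key <- if (s) "Ps_singleton" else "Pn_singleton"
        counts[key] <- counts[key] + 1L
      }
    } else if (ing_al[1] != og_al) {
      s <- syn(ing_al[1], og_al)
      counts[if (s) "Ds" else "Dn"] <- counts[if (s) "Ds" else "Dn"] + 1L
    }
  }
  structure(c(as.list(counts), list(n_codons_dropped = dropped)),
            class = "mk_counts")
}

#' Polarize a biallelic site onto the ingroup lineage
#'
#' Parsimony assignment of a change to the ingroup (\emph{mauritiana})
#' branch: usable only when both outgroups agree on an allele; the
#' agreed-upon allele is taken as ancestral, so an ingroup-private state
#' is derived on the ingroup lineage. Sites where the outgroups disagree,
#' are missing, or the configuration needs more than one change are
#' unusable; triallelic configurations are unusable.
#'
#' @param ingroup Character vector of ingroup alleles (`NA` = missing).
#' @param near,far Single alleles of the near and far outgroup.
#' @return list with `status` (`"mau_derived_fixation"`,
#'   `"mau_polymorphism"`, `"other"`, `"unusable"`) and `derived` (the
#'   derived allele on the ingroup lineage, or `NA`).
#' @export
polarize_mau_lineage <- function(ingroup, near, far) {
  ingroup <- ingroup[!is.na(ingroup)]
  un <- unique(ingroup)
  bad <- list(status = "unusable", derived = NA_character_)
  if (!length(un) || length(un) > 2L) return(bad)
  if (is.na(near) || is.na(far)) return(bad)
  if (near != far) {
    # outgroups disagree: nothing is assignable to the ingroup branch,
    # but a fixed ingroup matching one outgroup places the change on a
    # deeper branch
    if (length(un) == 1L && un %in% c(near, far))
      return(list(status = "other", derived = NA_character_))
    return(bad)
  }
  anc <- near
  if (length(unique(c(un, anc))) > 2L) return(bad)  # triallelic overall
  if (length(un) == 1L) {
    if (un == anc) return(list(status = "other", derived = NA_character_))
    return(list(status = "mau_derived_fixation", derived = un))
  }
  derived <- setdiff(un, anc)
  if (length(derived) != 1L) return(bad)
  list(status = "mau_polymorphism", derived = derived)
}

#' McDonald--Kreitman test
#'
#' Two-sided Fisher exact test of the 2x2 contrast of fixed versus
#' polymorphic, nonsynonymous versus synonymous counts, with the
#' direction of departure read off the ratio of fixation to polymorphism
#' odds. A zero margin gives `p = 1` with undefined direction.
#'
#' @param counts An `mk_counts` list, or a numeric vector/list with
#'   elements `Dn`, `Ds`, `Pn`, `Ps`.
#' @return list: `p_value`, `direction` (`"excess_fixations"`,
#'   `"excess_polymorphisms"` or `NA`), `table` (the 2x2 matrix).
#' @export
mk_test <- function(counts) {
  tab <- matrix(as.numeric(c(counts$Dn, counts$Ds, counts$Pn, counts$Ps)),
                2L, 2L, byrow = TRUE,
                dimnames = list(c("fixed", "polymorphic"),
                                c("nonsyn", "syn")))
  if (any(tab < 0) || any(!is.finite(tab))) .stopf("invalid MK counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(p_value = 1, direction = NA_character_, table = tab))
  p <- stats::fisher.test(tab)$p.value
  ratio_fix <- tab[1, 1] / tab[1, 2]
  ratio_poly <- tab[2, 1] / tab[2, 2]
  dir <- if (ratio_fix > ratio_poly) "excess_fixations"
         else if (ratio_fix < ratio_poly) "excess_polymorphisms"
         else NA_character_
  list(p_value = min(1, p), direction = dir, table = tab)
}

# pooled counts (optionally singleton-excluded) from a list of mk_counts
# or a data.frame with the count columns
.pool_counts <- function(counts, exclude_singletons = TRUE) {
  if (inherits(counts, "mk_counts")) counts <- list(counts)
  if (is.data.frame(counts)) {
    df <- counts
  } else {
    df <- do.call(rbind, lapply(counts, function(x)
      as.data.frame(x[c("Dn", "Ds", "Pn", "Ps",
                        "Pn_singleton", "Ps_singleton")])))
  }
  if (!all(c("Pn_singleton", "Ps_singleton") %in% names(df))) {
    df$Pn_singleton <- 0; df$Ps_singleton <- 0
  }
  pn <- df$Pn; ps <- df$Ps
  if (exclude_singletons) {
    pn <- pn - df$Pn_singleton
    ps <- ps - df$Ps_singleton
  }
  c(Dn = sum(df$Dn), Ds = sum(df$Ds), Pn = sum(pn), Ps = sum(ps))
}

#' Proportion of fixations driven by positive selection (alpha)
#'
#' Pooled estimator
#' \eqn{\alpha = 1 - (D_s P_n)/(D_n P_s)} over a gene set, with
#' polymorphism singletons excluded by default (divergence counts cannot
#' contain singletons by construction). Undefined (with a diagnostic)
#' when `Dn = 0` or `Ps = 0` after pooling.
#'
#' @param counts A list of `mk_counts` (one per gene), a single
#'   `mk_counts`, or a data.frame with columns `Dn`, `Ds`, `Pn`, `Ps` and
#'   optionally `Pn_singleton`, `Ps_singleton`.
#' @param exclude_singletons Drop singleton polymorphisms (default TRUE).
#' @return list of class `alpha_estimate`: `alpha`, pooled `counts`,
#'   `neutral_class = "synonymous"`, `exclude_singletons`.
#' @export
alpha_estimate <- function(counts, exclude_singletons = TRUE) {
  p <- .pool_counts(counts, exclude_singletons)
  if (p["Dn"] <= 0 || p["Ps"] <= 0)
    return(structure(list(alpha = NA_real_, counts = p,
                          neutral_class = "synonymous",
                          exclude_singletons = exclude_singletons,
                          note = "undefined: Dn = 0 or Ps = 0 after pooling"),
                     class = "alpha_estimate"))
  a <- 1 - (p["Ds"] * p["Pn"]) / (p["Dn"] * p["Ps"])
  structure(list(alpha = unname(a), counts = p,
                 neutral_class = "synonymous",
                 exclude_singletons = exclude_singletons),
            class = "alpha_estimate")
}

#' @export
print.alpha_estimate <- function(x, ...) {
  cat(sprintf("alpha = %.4f (neutral class: %s%s)\n",
              x$alpha, x$neutral_class,
              if (isTRUE(x$exclude_singletons)) ", singletons excluded" else ""))
  if (!is.null(x$ci)) cat(sprintf("  95%% CI [%.4f, %.4f] (%d bootstrap reps)\n",
                                  x$ci[1], x$ci[2], x$n_bootstrap))
  invisible(x)
}

#' Alpha with a short-intron neutral standard (alpha*)
#'
#' Same estimator as [alpha_estimate()] with the synonymous reference
#' replaced by short-intron (SI8--30) fixation and polymorphism counts:
#' \eqn{\alpha^* = 1 - (D_{SI} P_c)/(D_c P_{SI})} for a focal class
#' \eqn{c} (nonsynonymous, synonymous, UTR or intron). Negative values
#' are legal and indicate relatively fewer fixations in the focal class
#' than in the neutral standard.
#'
#' @param class_counts list/vector with `D` and `P` for the focal class
#'   (already singleton-handled as desired).
#' @param si_counts list/vector with `D` and `P` for SI8--30 sites.
#' @return list of class `alpha_estimate` with `neutral_class = "SI8_30"`.
#' @export
alpha_star <- function(class_counts, si_counts) {
  Dc <- as.numeric(class_counts[["D"]]); Pc <- as.numeric(class_counts[["P"]])
  Ds <- as.numeric(si_counts[["D"]]); Ps <- as.numeric(si_counts[["P"]])
  if (any(c(Dc, Pc, Ds, Ps) < 0)) .stopf("negative counts")
  if (Dc <= 0 || Ps <= 0)
    return(structure(list(alpha = NA_real_, neutral_class = "SI8_30",
                          note = "undefined: zero focal fixations or SI polymorphisms"),
                     class = "alpha_estimate"))
  structure(list(alpha = 1 - (Ds * Pc) / (Dc * Ps),
                 counts = c(D = Dc, P = Pc, D_SI = Ds, P_SI = Ps),
                 neutral_class = "SI8_30"),
            class = "alpha_estimate")
}

#' Bootstrap confidence interval for a pooled estimator
#'
#' Percentile 95% interval over `B` resamples of genes with replacement
#' (the resampling unit is the gene, respecting between-gene count
#' correlation). Seeded and deterministic. The interval is flagged
#' unstable when the estimator is undefined in more than 10% of
#' replicates.
#'
#' @param counts data.frame of per-gene counts (columns `Dn`, `Ds`, `Pn`,
#'   `Ps`, optional singleton columns) or list of `mk_counts`.
#' @param estimator Function mapping a pooled count vector
#'   (`Dn`,`Ds`,`Pn`,`Ps`) to a scalar; default the alpha estimator.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param exclude_singletons Passed to the pooling step.
#' @return list: `ci` (2.5/97.5 percentiles), `point`, `B`, `unstable`,
#'   `prop_undefined`.
#' @export
bootstrap_ci <- function(counts, estimator = NULL, B = 1000L, seed = 1L,
                         exclude_singletons = TRUE) {
  if (inherits(counts, "mk_counts")) counts <- list(counts)
  if (!is.data.frame(counts)) {
    counts <- do.call(rbind, lapply(counts, function(x)
      as.data.frame(x[intersect(names(x),
                                c("Dn", "Ds", "Pn", "Ps",
                                  "Pn_singleton", "Ps_singleton"))])))
  }
  ng <- nrow(counts)
  if (ng < 2L) .stopf("bootstrap needs at least 2 genes")
  if (is.null(estimator))
    estimator <- function(p) 1 - (p["Ds"] * p["Pn"]) / (p["Dn"] * p["Ps"])
  pn <- counts$Pn; ps <- counts$Ps
  if (exclude_singletons && all(c("Pn_singleton", "Ps_singleton") %in%
                                names(counts))) {
    pn <- pn - counts$Pn_singleton
    ps <- ps - counts$Ps_singleton
  }
  M <- rbind(Dn = counts$Dn, Ds = counts$Ds, Pn = pn, Ps = ps)
  point <- estimator(rowSums(M))
  vals <- .with_seed(seed, {
    # gene resampling with replacement == multinomial gene weights
    W <- stats::rmultinom(B, ng, rep(1 / ng, ng))
    reps <- M %*% W
    apply(reps, 2L, function(col) estimator(setNames(col, rownames(M))))
  })
  vals[!is.finite(vals)] <- NA_real_
  prop_undef <- mean(is.na(vals))
  ci <- unname(stats::quantile(vals, c(0.025, 0.975), na.rm = TRUE))
  list(ci = ci, point = unname(point), B = as.integer(B),
       unstable = prop_undef > 0.10, prop_undefined = prop_undef)
}
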