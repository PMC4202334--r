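#' Haplotype alignment over one chromosome arm
#'
#' Container for a set of haploid sequences (an ingroup population plus up
#' to two single-haplotype outgroups) reduced to their variable sites.
#' Positions are 0-based base pairs on `[0, L)`; every position not listed
#' in `positions` is assumed monomorphic across all samples and callable.
#' Missing calls at variable sites are `NA`.
#'
#' @param chrom Chromosome name.
#' @param L Chromosome length in bp.
#' @param positions Strictly increasing integer vector of 0-based variable
#'   site positions.
#' @param alleles Character matrix (samples x sites) over
#'   `A`,`C`,`G`,`T`,`NA`; rows named by sample.
#' @param roles Character vector per sample: `"ingroup"`,
#'   `"outgroup_near"` or `"outgroup_far"`.
#' @param ancestral Optional character vector of ancestral alleles per site
#'   (known truth in simulations; `NA` where unknown).
#' @return An object of class `haplotype_alignment`.
#' @export
haplotype_alignment <- function(chrom, L, positions, alleles, roles,
                                ancestral = NULL) {
  .check_scalar(L, "L", positive = TRUE)
  positions <- as.integer(positions)
  if (is.unsorted(positions, strictly = TRUE))
    .stopf("positions must be strictly increasing")
  if (length(positions) && (positions[1] < 0 || positions[length(positions)] >= L))
    .stopf("positions must lie in [0, L)")
  alleles <- as.matrix(alleles)
  if (ncol(alleles) != length(positions))
    .stopf("alleles must have one column per position")
  ok <- alleles %in% c("A", "C", "G", "T") | is.na(alleles)
  if (!all(ok)) .stopf("alleles must be A/C/G/T or NA")
  roles <- match.arg(roles, c("ingroup", "outgroup_near", "outgroup_far"),
                     several.ok = TRUE)
  if (length(roles) != nrow(alleles))
    .stopf("one role per sample required")
  if (is.null(rownames(alleles)))
    rownames(alleles) <- sprintf("hap%02d", seq_len(nrow(alleles)))
  if (!is.null(ancestral) && length(ancestral) != length(positions))
    .stopf("ancestral must have one allele per position")
  structure(list(chrom = chrom, L = as.integer(L), positions = positions,
                 alleles = alleles, roles = roles, ancestral = ancestral),
            class = "haplotype_alignment")
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat(sprintf("haplotype_alignment: %s (%s bp), %d samples (%d ingroup), %d variable sites\n",
              x$chrom, format(x$L, big.mark = ","), nrow(x$alleles),
              sum(x$roles == "ingroup"), length(x$positions)))
  invisible(x)
}

#' Ingroup allele matrix
#' @param aln A `haplotype_alignment`.
#' @return Character matrix restricted to ingroup rows.
#' @export
ingroup_alleles <- function(aln) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  aln$alleles[aln$roles == "ingroup", , drop = FALSE]
}

#' Outgroup allele vector
#' @param aln A `haplotype_alignment`.
#' @param role `"outgroup_far"` or `"outgroup_near"`.
#' @return Character vector of the outgroup's alleles at the variable sites.
#' @export
outgroup_alleles <- function(aln, role = "outgroup_far") {
  stopifnot(inherits(aln, "haplotype_alignment"))
  i <- which(aln$roles == role)
  if (!length(i)) .stopf("alignment has no sample with role '%s'", role)
  aln$alleles[i[1], ]
}

# Per-site summary of the ingroup at the variable sites: number of callable
# haplotypes, number of distinct alleles, derived/minor counts. Sites with
# fewer than `min_called` callable haplotypes or more than two alleles are
# flagged unusable (dropped from all statistics downstream).
.site_summary <- function(aln, min_called = 4L) {
  ing <- ingroup_alleles(aln)
  n_called <- colSums(!is.na(ing))
  nal <- integer(ncol(ing))
  a1 <- a2 <- rep(NA_character_, ncol(ing))
  c1 <- c2 <- integer(ncol(ing))
  for (j in seq_len(ncol(ing))) {
    tab <- table(ing[, j], useNA = "no")
    nal[j] <- length(tab)
    if (length(tab) >= 1L) { a1[j] <- names(tab)[1]; c1[j] <- tab[[1]] }
    if (length(tab) >= 2L) { a2[j] <- names(tab)[2]; c2[j] <- tab[[2]] }
  }
  usable <- n_called >= min_called & nal <= 2L
  poly <- usable & nal == 2L
  list(n_called = n_called, n_alleles = nal,
       allele1 = a1, allele2 = a2, count1 = c1, count2 = c2,
       usable = usable, polymorphic = poly)
}

# Majority-rule ingroup consensus at the variable sites (ties broken toward
# the alphabetically smallest allele, for determinism).
.ingroup_consensus <- function(aln) {
  ing <- ingroup_alleles(aln)
  apply(ing, 2L, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(NA_character_)
    tab <- sort(table(col), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    sort(top)[1]
  })
}
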