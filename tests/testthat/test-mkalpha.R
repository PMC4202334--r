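test_that("codon changes are classified against the genetic code", {
  # GGA/GGG segregating: synonymous polymorphism (Gly 4-fold)
  cds <- rbind(mau1 = c("G", "G", "A"), mau2 = c("G", "G", "G"),
               mau3 = c("G", "G", "A"), out = c("G", "G", "A"))
  ct <- classify_codon_changes(cds, ingroup = 1:3, outgroup = 4)
  expect_equal(ct$Ps, 1L); expect_equal(ct$Pn, 0L)
  expect_equal(ct$Ps_singleton, 1L)  # minor allele count 1
  # AAA vs AAG outgroup: synonymous fixation; AAA vs GAA: nonsynonymous
  cds2 <- rbind(m1 = c("A", "A", "A", "A", "A", "A"),
                m2 = c("A", "A", "A", "A", "A", "A"),
                out = c("A", "A", "G", "G", "A", "A"))
  ct2 <- classify_codon_changes(cds2, 1:2, 3)
  expect_equal(ct2$Ds, 1L); expect_equal(ct2$Dn, 1L)
  # codons with two variable positions are dropped, with a count
  cds3 <- rbind(m1 = c("A", "A", "A"), m2 = c("A", "C", "A"),
                out = c("A", "A", "G"))
  ct3 <- classify_codon_changes(cds3, 1:2, 3)
  expect_equal(ct3$n_codons_dropped, 1L)
  expect_equal(ct3$Dn + ct3$Ds + ct3$Pn + ct3$Ps, 0L)
})

test_that("planted per-gene counts are recovered exactly", {
  # build a gene of 60 codons with known planted changes
  set.seed(77)
  base <- t(replicate(6, rep(c("G", "C", "T"), 60)))  # GCT = Ala, 60 codons
  rownames(base) <- c(paste0("m", 1:5), "out")
  # codon 3: synonymous polymorphism GCT/GCC carried by 2 samples
  base[1:2, 9] <- "C"
  # codon 10: nonsynonymous polymorphism GCT -> GAT (Asp), singleton
  base[4, 29] <- "A"
  # codon 20: synonymous fixation in outgroup (GCT -> GCA)
  base[6, 60] <- "A"
  # codon 30: nonsynonymous fixation (GCT -> CCT, Pro, outgroup differs)
  base[6, 88] <- "C"
  ct <- classify_codon_changes(base, 1:5, 6)
  expect_equal(ct$Ps, 1L); expect_equal(ct$Pn, 1L)
  expect_equal(ct$Ds, 1L); expect_equal(ct$Dn, 1L)
  expect_equal(ct$Pn_singleton, 1L); expect_equal(ct$Ps_singleton, 0L)
})

test_that("lineage polarization follows two-outgroup parsimony", {
  expect_equal(polarize_mau_lineage(rep("T", 5), "A", "A")$status,
               "mau_derived_fixation")
  expect_equal(polarize_mau_lineage(rep("T", 5), "T", "A")$status, "other")
  p <- polarize_mau_lineage(c("T", "T", "A", "A", "A"), "A", "A")
  expect_equal(p$status, "mau_polymorphism")
  expect_equal(p$derived, "T")
  # outgroup disagreement, missing data, triallelic: unusable
  expect_equal(polarize_mau_lineage(rep("T", 4), "A", "G")$status,
               "unusable")
  expect_equal(polarize_mau_lineage(rep("T", 4), NA, "A")$status,
               "unusable")
  expect_equal(polarize_mau_lineage(c("T", "G"), "A", "A")$status,
               "unusable")
  # enumerated biallelic configurations against a direct parsimony rule
  bases <- c("A", "C")
  for (n_derived in 0:4) for (anc in bases) {
    ing <- c(rep(setdiff(bases, anc), n_derived),
             rep(anc, 4 - n_derived))
    got <- polarize_mau_lineage(ing, anc, anc)
    expected <- if (n_derived == 0) "other"
                else if (n_derived == 4) "mau_derived_fixation"
                else "mau_polymorphism"
    expect_equal(got$status, expected)
  }
})

test_that("MK test equals exact enumeration and handles degeneracies", {
  expect_equal(mk_test(list(Dn = 5, Ds = 5, Pn = 5, Ps = 5))$p_value, 1)
  expect_equal(mk_test(list(Dn = 0, Ds = 0, Pn = 3, Ps = 7))$p_value, 1)
  t1 <- mk_test(list(Dn = 10, Ds = 2, Pn = 2, Ps = 10))
  expect_equal(t1$p_value,
               oracle_fisher(matrix(c(10, 2, 2, 10), 2, byrow = TRUE)),
               tolerance = 1e-9)
  expect_equal(t1$direction, "excess_fixations")
  # randomized tables with total <= 40
  set.seed(909)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 5), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    got <- mk_test(list(Dn = tab[1, 1], Ds = tab[1, 2],
                        Pn = tab[2, 1], Ps = tab[2, 2]))$p_value
    expect_equal(got, oracle_fisher(tab), tolerance = 1e-9,
                 info = paste(tab, collapse = ","))
  }
})

test_that("alpha estimator closed forms and invariances hold", {
  # neutral expectation: Pn/Ps = Dn/Ds gives alpha = 0
  expect_equal(alpha_estimate(data.frame(Dn = 10, Ds = 20, Pn = 5,
                                         Ps = 10))$alpha, 0)
  # no nonsynonymous polymorphism: alpha = 1
  expect_equal(alpha_estimate(data.frame(Dn = 10, Ds = 20, Pn = 0,
                                         Ps = 10))$alpha, 1)
  expect_equal(alpha_estimate(data.frame(Dn = 40, Ds = 60, Pn = 20,
                                         Ps = 60))$alpha, 0.5)
  # scaling all four counts leaves alpha unchanged
  a1 <- alpha_estimate(data.frame(Dn = 8, Ds = 12, Pn = 5, Ps = 9))$alpha
  a2 <- alpha_estimate(data.frame(Dn = 80, Ds = 120, Pn = 50,
                                  Ps = 90))$alpha
  expect_equal(a1, a2)
  # undefined cases flagged
  expect_true(is.na(alpha_estimate(data.frame(Dn = 0, Ds = 5, Pn = 2,
                                              Ps = 5))$alpha))
})

test_that("alpha* sign convention follows the short-intron standard", {
  expect_equal(alpha_star(c(D = 10, P = 5), c(D = 20, P = 10))$alpha, 0)
  expect_gt(alpha_star(c(D = 20, P = 5), c(D = 20, P = 10))$alpha, 0)
  expect_lt(alpha_star(c(D = 10, P = 10), c(D = 20, P = 10))$alpha, 0)
  # planted truth: simulated counts, SI standard from the same generator
  d <- simulate_mk_counts(mk_sim_spec(3000, alpha_true = 0.4, seed = 5))
  si <- simulate_mk_counts(mk_sim_spec(3000, alpha_true = 0, seed = 6))
  a <- alpha_star(
    c(D = sum(d$Dn), P = sum(d$Pn - d$Pn_singleton)),
    c(D = sum(si$Ds), P = sum(si$Ps - si$Ps_singleton)))
  expect_lt(abs(a$alpha - 0.4), 0.05)
})

test_that("singleton exclusion removes deleterious-polymorphism bias", {
  d <- simulate_mk_counts(mk_sim_spec(2000, alpha_true = 0.3, seed = 31,
                                      deleterious_singleton = 1.5))
  with_ex <- alpha_estimate(d, exclude_singletons = TRUE)$alpha
  without <- alpha_estimate(d, exclude_singletons = FALSE)$alpha
  expect_gt(with_ex, without)
  expect_lt(abs(with_ex - 0.3), 0.05)
})

test_that("bootstrap CI is seeded, stable and degenerate-safe", {
  d <- simulate_mk_counts(mk_sim_spec(300, alpha_true = 0.25, seed = 41))
  b1 <- bootstrap_ci(d, seed = 11)
  b2 <- bootstrap_ci(d, seed = 11)
  expect_identical(b1$ci, b2$ci)
  expect_true(b1$ci[1] <= b1$point && b1$point <= b1$ci[2])
  # identical genes: zero-width interval at the point estimate
  same <- data.frame(Dn = rep(10, 20), Ds = rep(10, 20), Pn = rep(5, 20),
                     Ps = rep(10, 20))
  b3 <- bootstrap_ci(same, seed = 1)
  expect_equal(b3$ci[1], b3$ci[2])
  expect_equal(b3$ci[1], b3$point)
})
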