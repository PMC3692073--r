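unit_setup <- function(seqs, ids = sprintf("s%d", seq_along(seqs))) {
  a <- new_alignment(ids, seqs)
  list(a = a, m = mask_columns(a, 1 - 1e-9), w = rep(1, length(seqs)))
}

test_that("pair frequencies: counting, pseudocount, gap skipping", {
  s <- unit_setup(c("AC", "AC", "CD", "CD"))
  pf <- pair_frequencies(s$a, s$m, s$w, 1, 2, pseudocount = 0)
  expect_equal(pf$joint["A", "C"], 0.5)
  expect_equal(pf$joint["C", "D"], 0.5)
  expect_equal(sum(pf$joint), 1)
  expect_equal(pf$effective_count, 4)

  pf2 <- pair_frequencies(s$a, s$m, s$w, 1, 2, pseudocount = 0.05)
  expect_true(all(pf2$joint > 0))
  expect_equal(sum(pf2$joint), 1)
  expect_equal(pf2$marginal_i, rowSums(pf2$joint))
  expect_equal(pf2$marginal_j, colSums(pf2$joint))

  # gapped rows are skipped; a pair with < 2 contributing rows is degenerate
  s3 <- unit_setup(c("AC", "CD", "A-"))
  pf3 <- pair_frequencies(s3$a, s3$m, s3$w, 1, 2, pseudocount = 0)
  expect_equal(pf3$effective_count, 2)  # row 3 has a gap and is skipped
  s4 <- unit_setup(c("AC", "A-"))
  expect_error(pair_frequencies(s4$a, s4$m, s4$w, 1, 2, 0), "degenerate")
})

test_that("mutual information: closed forms and oracle equivalence", {
  # perfectly covarying two-state pair -> ln 2
  s <- unit_setup(c("AC", "AC", "CD", "CD"))
  pf <- pair_frequencies(s$a, s$m, s$w, 1, 2, pseudocount = 0)
  expect_equal(mutual_information(pf), log(2), tolerance = 1e-12)

  # independent uniform pair over {A,C} x {C,D} -> 0
  si <- unit_setup(c("AC", "AD", "CC", "CD"))
  pfi <- pair_frequencies(si$a, si$m, si$w, 1, 2, pseudocount = 0)
  expect_equal(mutual_information(pfi), 0, tolerance = 1e-12)

  # random pair vs brute-force recomputation
  a <- random_alignment(10, 4, seed = 21)
  m <- mask_columns(a, 0.5)
  set.seed(22); w <- runif(10, 0.2, 2)
  pfr <- pair_frequencies(a, m, w, 2, 4, pseudocount = 0.05)
  expect_equal(mutual_information(pfr),
               oracle_pair_mi(aln_chars(a), w, 2, 4, 0.05),
               tolerance = 1e-12)
})

test_that("mi_matrix agrees with the single-pair path and the oracle", {
  a <- random_alignment(9, 6, seed = 31, gap_rate = 0.15)
  m <- mask_columns(a, 0.5)
  set.seed(32); w <- runif(9, 0.1, 1.5)
  kept <- which(m$keep)
  mm <- mi_matrix(a, m, w, pseudocount = 0.05)
  expect_true(isSymmetric(unname(mm)))
  expect_true(all(is.na(diag(mm))))
  for (i in 1:2) for (j in 3:4) {
    pf <- pair_frequencies(a, m, w, kept[i], kept[j], 0.05)
    expect_equal(mm[i, j], mutual_information(pf), tolerance = 1e-12)
  }
  expect_equal(mm, oracle_mi_matrix(a, kept, w, 0.05),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("a duplicated column attains the maximal MI of its row", {
  a <- random_alignment(12, 5, seed = 41)
  dup <- new_alignment(a$id, paste0(a$seq, substr(a$seq, 2, 2)))
  m <- mask_columns(dup, 0.5)
  mm <- mi_matrix(dup, m, rep(1, 12), pseudocount = 0)
  # column 6 is the copy of column 2: its MI is the column's self-MI, the
  # maximum of the row (ties with accidentally bijective columns allowed)
  expect_equal(mm[2, 6], max(mm[2, ], na.rm = TRUE))
})

test_that("all-conserved alignment has (near) zero MI as pseudocount -> 0", {
  a <- new_alignment(c("a", "b", "c"), rep("AAAA", 3))
  m <- mask_columns(a, 0.5)
  mm <- mi_matrix(a, m, rep(1, 3), pseudocount = 1e-14)
  expect_true(all(abs(mm[upper.tri(mm)]) <= 1e-9))
})

test_that("MI is invariant to weight scaling and consistent relabeling", {
  a <- random_alignment(10, 4, seed = 51)
  m <- mask_columns(a, 0.5)
  set.seed(52); w <- runif(10, 0.5, 2)
  mm1 <- mi_matrix(a, m, w, 0.05)
  mm2 <- mi_matrix(a, m, w * 7.3, 0.05)
  expect_equal(mm1, mm2, tolerance = 1e-12)

  # swap two amino-acid labels consistently in every column
  relabeled <- chartr("AC", "CA", a$seq)
  ar <- new_alignment(a$id, relabeled)
  mr <- mi_matrix(ar, mask_columns(ar, 0.5), w, 0.05)
  expect_equal(unname(mr), unname(mm1), tolerance = 1e-12)
})

test_that("APC: all-equal matrix, hand-computed 3x3, symmetry, NA handling", {
  allc <- matrix(0.7, 4, 4); diag(allc) <- NA
  expect_true(all(abs(apc_correct(allc)[upper.tri(allc)]) < 1e-12))

  mi3 <- matrix(c(NA, 2, 1, 2, NA, 1, 1, 1, NA), 3, 3)
  apc3 <- apc_correct(mi3)
  expect_equal(apc3[1, 2], 2 - 1.5 * 1.5 / (4 / 3), tolerance = 1e-12)
  expect_equal(apc3[1, 2], 0.3125)
  expect_true(isSymmetric(unname(apc3)))

  a <- random_alignment(8, 7, seed = 61)
  mm <- mi_matrix(a, mask_columns(a, 0.5), rep(1, 8), 0.05)
  expect_equal(unname(apc_correct(mm)), oracle_apc(unname(mm)),
               tolerance = 1e-10)

  zero <- matrix(0, 3, 3); diag(zero) <- NA
  expect_warning(out <- apc_correct(zero), "zero")
  expect_equal(out, zero)
})

test_that("permutation z-scores are seed-reproducible and find the planted pair", {
  g <- generate_msa(60, 8, planted_pairs = list(c(2, 6, 1)), seed = 71)
  a <- g$alignment
  m <- mask_columns(a, 0.5)
  w <- rep(1, 60)
  s1 <- permutation_zscores(a, m, w, 0.05, n_permutations = 15, seed = 9)
  s2 <- permutation_zscores(a, m, w, 0.05, n_permutations = 15, seed = 9)
  expect_identical(s1$z, s2$z)  # bitwise reproducible
  s3 <- permutation_zscores(a, m, w, 0.05, n_permutations = 15, seed = 10)
  expect_false(identical(s1$z, s3$z))

  # the planted coupling-1 pair dominates
  ut <- which(upper.tri(s1$z), arr.ind = TRUE)
  best <- ut[which.max(s1$z[ut]), ]
  expect_equal(sort(s1$positions[best]), c(2, 6))
  expect_gt(max(s1$z[ut]), 6.5)
})

test_that("a permutation-invariant alignment gets z = 0, flagged degenerate", {
  # every column fully conserved: shuffling changes nothing, the null has
  # zero spread, and z is defined as 0 rather than 0/0
  a <- new_alignment(c("a", "b", "c", "d"), rep("WKR", 4))
  m <- mask_columns(a, 0.5)
  s <- permutation_zscores(a, m, rep(1, 4), 0.05, n_permutations = 5,
                           seed = 2)
  expect_true(all(s$z[upper.tri(s$z)] == 0))
  expect_true(all(s$degenerate[upper.tri(s$degenerate)]))
})

test_that("pooled null is available and differs from per-pair", {
  a <- random_alignment(30, 6, seed = 81)
  m <- mask_columns(a, 0.5)
  w <- rep(1, 30)
  sp <- permutation_zscores(a, m, w, 0.05, 10, seed = 3, null = "per-pair")
  sg <- permutation_zscores(a, m, w, 0.05, 10, seed = 3, null = "pooled")
  expect_false(identical(sp$z, sg$z))
  expect_true(isSymmetric(unname(sg$z)))
})

test_that("the significant-pair table applies a strict threshold", {
  sc <- fake_scores(c(7.0, 6.5, 6.4))
  tab <- zscore_table(sc, 6.5)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$z, 7.0)
  expect_equal(nrow(zscore_table(sc, 6.5, all = TRUE)), 3)
})
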