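paralog_fixture <- function() {
  ids <- c("TFA", "TFB", "TFC")
  seqs <- setNames(c("MKRLVNQ", "MARLVNE", "AKRQVGQ"), ids)
  compendium <- lapply(seq_along(ids), function(i) {
    w <- matrix(0.1 * i, 2, 4)
    w[, i] <- 1
    psam(w, tf_id = ids[i], positions = c("1", "2"))
  })
  names(compendium) <- ids
  list(compendium = compendium, seqs = seqs,
       fam = aligned_family(ids, unname(seqs)))
}

test_that("closest paralog transfers the minimal-Levenshtein model", {
  fix <- paralog_fixture()
  # identical to a training TF: that TF's model comes back
  hit <- closest_paralog("MARLVNE", fix$compendium, fix$seqs)
  expect_equal(attr(hit, "donor"), "TFB")
  expect_equal(attr(hit, "distance"), 0)
  # hand-computed distances pick the nearest neighbor
  d <- vapply(fix$seqs, function(s) levenshtein_dist("MKRLVNE", s),
              numeric(1))
  hit2 <- closest_paralog("MKRLVNE", fix$compendium, fix$seqs)
  expect_equal(attr(hit2, "donor"), names(which.min(d)))
  expect_error(closest_paralog("MKR", list(), fix$seqs), "empty|must")
})

test_that("closest-paralog distance ties break lexicographically", {
  ids <- c("ZTF", "ATF")
  seqs <- setNames(c("MKRL", "MKRV"), ids)
  compendium <- lapply(ids, function(id) {
    psam(rbind(c(1, 0.5, 0.2, 0.1)), tf_id = id)
  })
  names(compendium) <- ids
  # query equidistant (1 edit) from both -> lexicographically smaller id
  hit <- closest_paralog("MKRW", compendium, seqs)
  expect_equal(attr(hit, "donor"), "ATF")
})

test_that("similarity regression reduces to minimal hamming under uniform
           weights and follows single-position weights", {
  fix <- paralog_fixture()
  w_uniform <- rep(1, 7)
  hit <- similarity_regression("MKRLVNE", fix$compendium, fix$fam, w_uniform)
  h <- vapply(fix$fam$tf_ids, function(id) {
    sum(strsplit("MKRLVNE", "")[[1]] != fix$fam$rows[id, ])
  }, numeric(1))
  expect_equal(attr(hit, "donor"), names(which.min(h)))
  # training TF queried against itself returns itself
  self <- similarity_regression(unname(fix$seqs["TFC"]), fix$compendium,
                                fix$fam, w_uniform)
  expect_equal(attr(self, "donor"), "TFC")
  # zero weight everywhere but position 2: neighbor chosen by that position
  w2 <- c(0, 1, 0, 0, 0, 0, 0)
  hit2 <- similarity_regression("MARLVNQ", fix$compendium, fix$fam, w2)
  expect_equal(attr(hit2, "donor"), "TFB")  # only TFB shares A at position 2
  # all-zero score ties resolve lexicographically
  hit3 <- similarity_regression("MWRLVNQ", fix$compendium, fix$fam, w2)
  expect_equal(attr(hit3, "donor"), "TFA")
  expect_error(similarity_regression("MKRLVNE", fix$compendium, fix$fam,
                                     rep(1, 9)), "gap_insert")
})

test_that("gap-column insertion reconciles weight coordinate systems", {
  fix <- paralog_fixture()
  w9 <- rep(1, 9)
  hit <- similarity_regression("MKRLVNE", fix$compendium, fix$fam, w9,
                               gap_insert = c(4, 4))
  expect_equal(attr(hit, "donor"), "TFA")
})

test_that("R^2 and RMSD follow their defining formulas", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rmsd(c(1, 2, 3), c(1, 2, 3)), 0)
  # constant offset: RMSD 1, R^2 0 for obs (0, 2)
  expect_equal(rmsd(c(1, 3), c(0, 2)), 1)
  expect_equal(r_squared(c(1, 3), c(0, 2)), 0)
  # hand-decomposed sums of squares
  obs <- c(0, 1, 2, 3)
  pred <- c(0.5, 1, 1.5, 3.5)
  expect_equal(r_squared(pred, obs), 1 - 0.75 / 5)
  expect_equal(rmsd(pred, obs), sqrt(0.75 / 4))
  expect_true(is.na(r_squared(c(1, 2), c(5, 5))))
  expect_error(r_squared(1, 1), "n >= 2")
})

test_that("replicate concordance pools all position/base energies", {
  fix <- identical_family(n = 2)
  E <- energy_from_psam(fix$compendium[[1]])
  res <- replicate_concordance(E, E)
  expect_equal(res$r_squared, 1)
  expect_equal(res$rmsd, 0)
  expect_equal(res$n_entries, 16L)
  Eb <- energy_matrix(unclass(E), tf_id = "B",
                      positions = c("9", "10", "11", "12"))
  expect_error(replicate_concordance(E, Eb), "position labels")
})

test_that("replicate noise follows the sqrt(2) * sd law", {
  synth <- simulate_family(synthetic_family_spec(n_tfs = 50, seed = 31))
  reps <- simulate_replicates(synth$compendium, 0.2, seed = 32)
  per <- vapply(names(reps$rep1), function(id) {
    replicate_concordance(reps$rep1[[id]], reps$rep2[[id]])$rmsd
  }, numeric(1))
  expect_equal(mean(per), 0.2 * sqrt(2), tolerance = 0.2)
  # zero noise: perfect concordance
  reps0 <- simulate_replicates(synth$compendium, 0, seed = 1)
  res0 <- replicate_concordance(reps0$rep1[[1]], reps0$rep2[[1]])
  expect_equal(res0$r_squared, 1)
  expect_equal(res0$rmsd, 0)
  expect_error(simulate_replicates(synth$compendium, -0.1), "non-negative")
})

test_that("dddG range is the spread over all entries", {
  expect_equal(dddg_range(matrix(0, 3, 4)), 0)
  expect_equal(dddg_range(rbind(c(-1.2, 0, 0.3, 0.8))), 2)
  m <- rbind(c(0.1, -0.4, 0.2, 0), c(1.3, 0, -0.2, 0.6))
  expect_equal(dddg_range(m), 1.3 - (-0.4))
  expect_error(dddg_range(numeric(0)), "empty")
})

test_that("effect enrichment is hypergeometric with the stated tail", {
  # perfect separation, 10 vs 10: p = 1 / choose(20, 10)
  cls <- rep(c("change", "no-change"), each = 10)
  rng <- rep(c(2, 0.1), each = 10)
  expect_equal(effect_enrichment(cls, rng, threshold = 1),
               1 / choose(20, 10))
  # no association: p well away from significance
  set.seed(2)
  rng2 <- runif(20, 0, 2)
  expect_gt(effect_enrichment(sample(cls), rng2), 0.05)
  # threshold above every range: degenerate, p = 1
  expect_equal(effect_enrichment(cls, rng, threshold = 10), 1)
  expect_equal(effect_enrichment(rep("change", 5), runif(5)), 1)
})

test_that("method comparisons: Wilcoxon matches the tabulated 6-pair value and
           the bootstrap is seeded and calibrated", {
  base <- c(5, 3, 8, 6, 7, 4)
  d <- c(0.3, 0.5, 0.9, 1.1, 1.4, 2.0)
  # all six signed ranks positive: exact two-sided p = 2/64
  expect_equal(compare_methods(base + d, base, mode = "wilcoxon"), 2 / 64)
  expect_equal(compare_methods(base, base, mode = "wilcoxon"), 1)

  set.seed(1)
  errsA <- rnorm(100, sd = 0.2)
  errsB <- rnorm(100, sd = 2)
  p1 <- compare_methods(errsA, errsB, mode = "bootstrap-t", seed = 1)
  expect_lt(p1, 0.001)
  # bit-exact reproducibility under a fixed seed
  expect_identical(p1, compare_methods(errsA, errsB, mode = "bootstrap-t",
                                       seed = 1))
  expect_equal(compare_methods(errsA, errsA, mode = "bootstrap-t"), 1)
  expect_error(compare_methods(1:3, 1:3), "n >= 5")
})

test_that("EMSA band-intensity ratios convert to ddG/RT", {
  expect_equal(emsa_ddg(2, 1, 2, 1), 0)
  expect_equal(emsa_ddg(exp(1), 1, 1, 1), 1)
  expect_equal(emsa_ddg(3, 2, 5, 4), -emsa_ddg(5, 4, 3, 2))
  expect_error(emsa_ddg(0, 1, 1, 1), "positive")
})

test_that("LOOCV on the identical family is perfect for every method", {
  fix <- identical_family(n = 6)
  for (method in c("familycode", "closest_paralog",
                   "similarity_regression")) {
    cv <- fc_loocv(fix$compendium, fix$fam, method)
    agg <- glance(cv)
    expect_equal(agg$r_squared, 1, tolerance = 1e-9)
    expect_equal(agg$rmsd, 0, tolerance = 1e-6)
  }
})

test_that("distance thresholds exclude leaky neighbors or flag NA", {
  fix <- identical_family(n = 6)
  # identical sequences: any positive threshold removes all training TFs
  cv <- fc_loocv(fix$compendium, fix$fam, "closest_paralog", threshold = 1)
  expect_true(all(is.na(cv$r_squared)))
  expect_true(all(cv$n_train == 0))

  synth <- simulate_family(synthetic_family_spec(n_tfs = 12, length = 8,
                                                 n_dna_positions = 2,
                                                 determinants = list(
                                                   list(r = 3L, j = 1L,
                                                        targets = list(
                                                          R = c(-0.5, 0.3, -0.5),
                                                          V = c(0.55, -0.55, -0.55)))),
                                                 seed = 41))
  cv0 <- fc_loocv(synth$compendium, synth$fam, "closest_paralog")
  cv1 <- fc_loocv(synth$compendium, synth$fam, "closest_paralog",
                  threshold = 2)
  expect_true(all(cv1$n_train <= cv0$n_train))
})

test_that("FamilyCode generalizes across distant sequences better than
           paralog transfer", {
  # determinant groups span distant background sequences: the family-level
  # model shares strength across them while the nearest paralog does not
  synth <- simulate_family(synthetic_family_spec(n_tfs = 40, length = 16,
                                                 seed = 51))
  cv_fc <- glance(fc_loocv(synth$compendium, synth$fam, "familycode"))
  cv_cp <- glance(fc_loocv(synth$compendium, synth$fam, "closest_paralog"))
  expect_gt(cv_fc$r_squared, cv_cp$r_squared)
})
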