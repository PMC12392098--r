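make_cloud <- function(n, seed = 1) {
  set.seed(seed)
  matrix(runif(n * 3, -0.4, 0.4), ncol = 3)
}

test_that("centered SVD reconstructs the cloud and fixes signs", {
  M <- make_cloud(10)
  sv <- center_and_svd(M)
  expect_equal(sweep(M, 2, sv$mu),
               sv$u %*% diag(sv$d) %*% t(sv$v), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(crossprod(sv$v), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(sv$d) <= 1e-12))
  expect_true(all(sv$d >= 0))
  # sign convention: the largest-magnitude entry of each V column positive
  for (k in 1:3) expect_gt(sv$v[which.max(abs(sv$v[, k])), k], 0)
  # reverse transformation reproduces every training point
  S <- sweep(M, 2, sv$mu) %*% sv$v
  back <- sweep(S %*% t(sv$v), 2, sv$mu, "+")
  expect_equal(back, M, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("degenerate clouds are handled: identical points and a line", {
  M0 <- matrix(0.2, 5, 3)
  sv <- center_and_svd(M0)
  expect_equal(sv$d, rep(0, 3))
  expect_equal(unname(sv$mu), rep(0.2, 3))
  dirv <- c(1, 2, -1) / sqrt(6)
  M1 <- outer(seq(-1, 1, length.out = 6), dirv)
  sv1 <- center_and_svd(M1)
  expect_equal(sv1$d[2:3], c(0, 0), tolerance = 1e-10)
  expect_gt(sv1$d[1], 0)
})

test_that("forward selection finds the planted determinant and only it", {
  synth <- simulate_family(synthetic_family_spec(seed = 6))
  det <- synth$truth$determinants[[1]]
  model <- fc_fit(synth$compendium, synth$fam)
  sel <- tidy(model)
  at_det <- sel[sel$dna_position == as.character(det$j), ]
  # the determinant residue is selected for the planted DNA position
  expect_true(det$r %in% at_det$residue)
  # and it carries the dominant ANOVA evidence there
  expect_equal(at_det$residue[which.min(at_det$anova_p)], det$r)
})

test_that("perfectly linked duplicate features are skipped, not selected twice", {
  synth <- simulate_family(synthetic_family_spec(
    n_tfs = 30, length = 10,
    determinants = list(list(r = 3L, j = 2L,
                             targets = list(R = c(-0.5, 0.3, -0.5),
                                            V = c(0.55, -0.55, -0.55)))),
    n_dna_positions = 3, seed = 8))
  # copy the determinant column to create perfect linkage disequilibrium
  rows <- synth$fam$rows
  rows[, 7] <- rows[, 3]
  fam2 <- aligned_family(synth$fam$tf_ids,
                         apply(rows, 1, paste, collapse = ""))
  model <- fc_fit(synth$compendium, fam2)
  sel <- tidy(model)
  for (pos in unique(sel$dna_position)) {
    for (pc in unique(sel$pc[sel$dna_position == pos])) {
      chosen <- sel$residue[sel$dna_position == pos & sel$pc == pc]
      expect_false(all(c(3, 7) %in% chosen))
      # the better-ranked copy (tie -> lower r) is the one chosen
      if (any(chosen %in% c(3, 7))) expect_true(3 %in% chosen)
    }
  }
})

test_that("selection alpha -> 0 empties the model and predicts the centroid", {
  synth <- simulate_family(synthetic_family_spec(n_tfs = 20, length = 8,
                                                 n_dna_positions = 2, seed = 2,
                                                 determinants = list(
                                                   list(r = 3L, j = 1L,
                                                        targets = list(
                                                          R = c(-0.5, 0.3, -0.5),
                                                          V = c(0.55, -0.55, -0.55))))))
  model <- fc_fit(synth$compendium, synth$fam, selection_alpha = 1e-300)
  expect_equal(nrow(tidy(model)), 0L)
  P <- predict(model, paste(synth$fam$rows[1, ], collapse = ""))
  for (j in seq_along(model$positions)) {
    centroid <- psam_column_from_tetra(model$positions[[j]]$mu)
    expect_equal(unname(unclass(P)[j, ]), unname(centroid), tolerance = 1e-12)
  }
  # all-gap query also falls back to the centroid
  Pg <- predict(model, strrep("-", 8))
  expect_equal(unclass(Pg), unclass(P), ignore_attr = TRUE)
})

test_that("group-mean encoding retrieves exact means and BLOSUM-weights unseen
           amino acids", {
  y <- c(1, 3, 2, 6, 4, 5)
  aa <- c("R", "R", "R", "V", "V", "V")
  gm <- vapply(split(y, aa), mean, numeric(1))
  blosum <- read_blosum()
  expect_equal(encode_residue_fixture("R", gm, blosum), 2)
  expect_equal(encode_residue_fixture("V", gm, blosum), 5)
  # unseen K: weights 1/(B[K,K]-B[K,R]) and 1/(B[K,K]-B[K,V]) by hand
  wr <- 1 / (blosum["K", "K"] - blosum["K", "R"])
  wv <- 1 / (blosum["K", "K"] - blosum["K", "V"])
  expect_equal(encode_residue_fixture("K", gm, blosum),
               (wr * 2 + wv * 5) / (wr + wv))
  # gap: unweighted mean of observed group means
  expect_equal(encode_residue_fixture("-", gm, blosum), 3.5)
})

test_that("an identical-TF family reproduces its shared PSAM for any query", {
  fix <- identical_family()
  model <- fc_fit(fix$compendium, fix$fam)
  shared <- unclass(fix$compendium[[1]])
  for (q in c(fix$fam$tf_ids[1], "MKRVANQLE", "AAAAAAAAA")) {
    P <- predict(model, q)
    expect_equal(unclass(P), shared, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("held-out synthetic TFs are predicted accurately", {
  synth <- simulate_family(synthetic_family_spec(seed = 12))
  tfs <- names(synth$compendium)
  held <- tfs[1]
  model <- fc_fit(synth$compendium[tfs[-1]], synth$fam)
  pred <- predict(model, paste(synth$fam$rows[held, ], collapse = ""),
                  type = "energy")
  obs <- synth$compendium[[held]]
  expect_lt(rmsd(as.vector(unclass(pred)), as.vector(unclass(obs))), 0.3)
})

test_that("models serialize to JSON and reproduce predictions byte-identically", {
  synth <- simulate_family(synthetic_family_spec(n_tfs = 20, length = 8,
                                                 n_dna_positions = 2, seed = 3,
                                                 determinants = list(
                                                   list(r = 3L, j = 1L,
                                                        targets = list(
                                                          R = c(-0.5, 0.3, -0.5),
                                                          V = c(0.55, -0.55, -0.55))))))
  model <- fc_fit(synth$compendium, synth$fam)
  f <- withr::local_tempfile(fileext = ".json")
  write_fc_model(model, f)
  m2 <- read_fc_model(f)
  carrier <- names(which(synth$truth$assignments[[1]] == "R"))[1]
  q <- paste(synth$fam$rows[carrier, ], collapse = "")
  expect_identical(as.vector(unclass(predict(model, q))),
                   as.vector(unclass(predict(m2, q))))
  expect_identical(predict_dddg(model, q, "R3V"),
                   predict_dddg(m2, q, "R3V"))
  expect_error(read_fc_model(withr::local_tempfile(fileext = ".json",
                                                   lines = "{}")),
               "not a familycode model")
})

test_that("prediction is invariant to training-set order", {
  synth <- simulate_family(synthetic_family_spec(n_tfs = 24, length = 8,
                                                 n_dna_positions = 2, seed = 5,
                                                 determinants = list(
                                                   list(r = 3L, j = 1L,
                                                        targets = list(
                                                          R = c(-0.5, 0.3, -0.5),
                                                          V = c(0.55, -0.55, -0.55))))))
  m1 <- fc_fit(synth$compendium, synth$fam)
  set.seed(99)
  m2 <- fc_fit(synth$compendium[sample(names(synth$compendium))], synth$fam)
  q <- strrep("A", 8)
  expect_equal(unclass(predict(m1, q)), unclass(predict(m2, q)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("mutant predictions recover planted shifts and validate inputs", {
  synth <- simulate_family(synthetic_family_spec(seed = 14))
  model <- fc_fit(synth$compendium, synth$fam)
  det <- synth$truth$determinants[[1]]
  carrier <- names(which(synth$truth$assignments[[1]] == "R"))[1]
  mut <- simulate_mutant(synth, carrier, sprintf("R%dV", det$r))

  pred <- predict_dddg(model, mut$wt_seq, sprintf("R%dV", det$r))
  expect_lt(rmsd(as.vector(pred), as.vector(mut$true_dddg)), 0.3)

  # empty mutation list: all-zero shift
  expect_equal(predict_dddg(model, mut$wt_seq, character(0)),
               matrix(0, 6, 4, dimnames = list(as.character(1:6),
                                               c("A", "C", "G", "T"))))
  # wild-type residue mismatch is rejected
  expect_error(predict_dddg(model, mut$wt_seq, sprintf("W%dV", det$r)),
               "mismatch")
  expect_error(predict_dddg(model, mut$wt_seq, "R999V"), "outside")
})

test_that("background-position mutations predict near-zero shifts", {
  synth <- simulate_family(synthetic_family_spec(seed = 15))
  model <- fc_fit(synth$compendium, synth$fam)
  det <- synth$truth$determinants[[1]]
  bg <- setdiff(seq_len(synth$truth$spec$length), det$r)[1]
  id <- synth$fam$tf_ids[1]
  from <- synth$fam$rows[id, bg]
  to <- setdiff(c("A", "E", "K", "L"), from)[1]
  mut <- simulate_mutant(synth, id, sprintf("%s%d%s", from, bg, to))
  expect_equal(mut$true_dddg, matrix(0, 6, 4,
                                     dimnames = dimnames(mut$true_dddg)))
  pred <- predict_dddg(model, mut$wt_seq,
                       sprintf("%s%d%s", from, bg, to))
  expect_lt(max(abs(pred)), 0.5)   # no planted effect to recover
})

test_that("additively planted double mutants shift like the sum of singles", {
  targets <- list(R = c(-0.4, 0.2, -0.4), V = c(0.5, -0.5, -0.5),
                  K = c(0.0, 0.5, -0.3), L = c(-0.2, -0.4, 0.4))
  synth <- simulate_family(synthetic_family_spec(
    n_tfs = 48, length = 12, n_dna_positions = 3,
    determinants = list(list(r = 3L, j = 1L,
                             targets = targets[c("R", "V")]),
                        list(r = 8L, j = 3L,
                             targets = targets[c("K", "L")])),
    noise_sd = 0.05, seed = 21))
  model <- fc_fit(synth$compendium, synth$fam)
  id <- names(which(synth$truth$assignments[[1]] == "R" &
                      synth$truth$assignments[[2]] == "K"))[1]
  wt <- paste(synth$fam$rows[id, ], collapse = "")
  d1 <- predict_dddg(model, wt, "R3V")
  d2 <- predict_dddg(model, wt, "K8L")
  d12 <- predict_dddg(model, wt, c("R3V", "K8L"))
  # effects planted at disjoint DNA positions combine additively in the
  # embedding; the energy-space comparison inherits the log nonlinearity
  # and the joint refit shares two key features, so agreement is approximate
  expect_lt(rmsd(as.vector(d12), as.vector(d1 + d2)), 0.3)
  # and each single-position effect is recovered where it was planted
  expect_lt(rmsd(as.vector(d1[1, ]), as.vector(d12[1, ])), 0.3)
  expect_lt(rmsd(as.vector(d2[3, ]), as.vector(d12[3, ])), 0.3)
})

test_that("tidy and glance summarize fitted models", {
  synth <- simulate_family(synthetic_family_spec(n_tfs = 20, length = 8,
                                                 n_dna_positions = 2, seed = 2,
                                                 determinants = list(
                                                   list(r = 3L, j = 1L,
                                                        targets = list(
                                                          R = c(-0.5, 0.3, -0.5),
                                                          V = c(0.55, -0.55, -0.55))))))
  model <- fc_fit(synth$compendium, synth$fam)
  td <- tidy(model)
  expect_true(all(c("dna_position", "pc", "residue", "beta", "anova_p")
                  %in% names(td)))
  gl <- glance(model)
  expect_equal(gl$n_tfs, 20L)
  expect_equal(gl$n_features, nrow(td))
})
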