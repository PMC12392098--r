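#' Closest-paralog baseline
#'
#' Transfers the binding model of the training TF whose (unaligned)
#' protein sequence has the smallest Levenshtein distance to the test
#' sequence.  Distance ties are broken by lexicographic tf_id.
#'
#' @param test_seq residue string of the query protein.
#' @param compendium named list of training binding models.
#' @param sequences named character vector of training protein
#'   sequences (names = tf_ids).
#' @return The chosen training model, with attributes `donor` and
#'   `distance`.
#' @export
closest_paralog <- function(test_seq, compendium, sequences) {
  compendium <- as_compendium(compendium)
  tfs <- names(compendium)
  if (length(tfs) == 0L) abort("empty training set")
  if (!all(tfs %in% names(sequences))) {
    abort("every training TF needs a protein sequence")
  }
  d <- vapply(tfs, function(id) levenshtein_dist(test_seq, sequences[[id]]),
              numeric(1L))
  ord <- order(d, tfs)
  donor <- tfs[ord[1L]]
  out <- compendium[[donor]]
  attr(out, "donor") <- donor
  attr(out, "distance") <- unname(d[donor])
  out
}

#' Similarity-regression baseline
#'
#' Scores each training TF by a per-position identity profile against
#' the test sequence (1 where the aligned residues match, 0
#' otherwise) weighted by pretrained per-position coefficients, and
#' transfers the binding model of the best-scoring TF.  With uniform
#' weights this reduces to the minimal-Hamming neighbor.  Pretrained
#' weight vectors may use a different profile-HMM coordinate system;
#' `gap_insert` reconciles the alignments by inserting all-gap columns
#' (see [insert_gap_columns()]) before scoring.
#'
#' @param test_seq aligned residue string for the query (in the
#'   family's coordinate system, before `gap_insert`).
#' @param compendium named list of training binding models.
#' @param fam an `fc_family` containing the training TFs.
#' @param weights numeric vector of per-position weights, of the
#'   alignment length after gap-column insertion.
#' @param gap_insert integer vector of match positions after which a
#'   gap column is inserted (default none).
#' @param direction `"max"` (default) transfers the highest weighted
#'   identity; `"min"` the lowest.
#' @return The chosen training model, with attributes `donor` and
#'   `score`.
#' @export
similarity_regression <- function(test_seq, compendium, fam, weights,
                                  gap_insert = integer(0),
                                  direction = c("max", "min")) {
  direction <- match.arg(direction)
  compendium <- as_compendium(compendium)
  tfs <- names(compendium)
  if (length(tfs) == 0L) abort("empty training set")
  if (length(gap_insert) > 0L) fam <- insert_gap_columns(fam, gap_insert)
  test_chars <- strsplit(toupper(test_seq), "")[[1L]]
  if (length(gap_insert) > 0L) {
    tmp <- insert_gap_columns(
      aligned_family("query", paste(test_chars, collapse = "")), gap_insert)
    test_chars <- tmp$rows[1L, ]
  }
  if (length(weights) != fam$length) {
    abort(sprintf(paste0("weight vector length %d does not match alignment ",
                         "length %d; check the gap_insert configuration"),
                  length(weights), fam$length))
  }
  scores <- vapply(tfs, function(id) {
    sum(weights * (fam$rows[id, ] == test_chars))
  }, numeric(1L))
  ord <- if (direction == "max") order(-scores, tfs) else order(scores, tfs)
  donor <- tfs[ord[1L]]
  out <- compendium[[donor]]
  attr(out, "donor") <- donor
  attr(out, "score") <- unname(scores[donor])
  out
}

#' Leave-one-out cross-validation of family-level predictors
#'
#' Each TF is held out in turn; the remaining TFs (optionally minus
#' those within Hamming distance `threshold` of the held-out sequence,
#' to control information leakage) train the chosen predictor, and
#' predicted ddG/RT values at the evaluated DNA positions are compared
#' with the held-out TF's own model.  Held-out TFs whose training set
#' empties under the threshold are reported as `NA`.
#'
#' @param compendium named list of binding models (>= 5 TFs).
#' @param fam an `fc_family` covering the compendium.
#' @param method `"familycode"`, `"closest_paralog"` or
#'   `"similarity_regression"`.
#' @param threshold Hamming-distance exclusion threshold (`NULL` for
#'   plain LOOCV).
#' @param positions DNA position labels to evaluate (default: all).
#' @param weights,gap_insert passed to [similarity_regression()].
#' @param selection_alpha,floor passed to [fc_fit()].
#' @return A tibble (class `fc_eval`), one row per held-out TF:
#'   `tf_id`, `n_train`, `r_squared`, `rmsd`.  Attributes `aggregate`
#'   (pooled `r_squared`/`rmsd` over all entries), `method` and
#'   `threshold`.
#' @export
fc_loocv <- function(compendium, fam,
                     method = c("familycode", "closest_paralog",
                                "similarity_regression"),
                     threshold = NULL, positions = NULL,
                     weights = NULL, gap_insert = integer(0),
                     selection_alpha = 0.05, floor = 0.01) {
  method <- match.arg(method)
  compendium <- as_compendium(compendium)
  tfs <- names(compendium)
  if (length(tfs) < 5L) abort("LOOCV needs at least 5 TFs")
  positions <- positions %||% rownames(compendium[[1L]])
  seqs <- family_sequences(fam, tfs)

  per_tf <- list()
  pooled_pred <- list()
  pooled_obs <- list()
  for (id in tfs) {
    train <- setdiff(tfs, id)
    if (!is.null(threshold)) {
      d <- vapply(train, function(t) hamming_dist(fam, id, t), numeric(1L))
      train <- train[d >= threshold]
    }
    if (length(train) == 0L ||
        (method == "familycode" && length(train) < 4L)) {
      per_tf[[id]] <- tibble(tf_id = id, n_train = length(train),
                             r_squared = NA_real_, rmsd = NA_real_)
      next
    }
    pred <- loocv_predict(method, id, train, compendium, fam, seqs,
                          positions, weights, gap_insert,
                          selection_alpha, floor)
    obs <- energy_from_psam(compendium[[id]], floor = floor)
    pv <- as.vector(unclass(pred)[positions, , drop = FALSE])
    ov <- as.vector(unclass(obs)[positions, , drop = FALSE])
    per_tf[[id]] <- tibble(tf_id = id, n_train = length(train),
                           r_squared = r_squared(pv, ov),
                           rmsd = rmsd(pv, ov))
    pooled_pred[[id]] <- pv
    pooled_obs[[id]] <- ov
  }
  out <- dplyr::bind_rows(per_tf)
  pv <- unlist(pooled_pred, use.names = FALSE)
  ov <- unlist(pooled_obs, use.names = FALSE)
  attr(out, "aggregate") <-
    if (length(ov) > 1L) {
      tibble(r_squared = r_squared(pv, ov), rmsd = rmsd(pv, ov),
             n_entries = length(ov))
    } else {
      tibble(r_squared = NA_real_, rmsd = NA_real_, n_entries = 0L)
    }
  attr(out, "method") <- method
  attr(out, "threshold") <- threshold
  attr(out, "errors") <- if (length(ov)) pv - ov else numeric(0)
  class(out) <- c("fc_eval", class(out))
  out
}

loocv_predict <- function(method, id, train, compendium, fam, seqs,
                          positions, weights, gap_insert,
                          selection_alpha, floor) {
  training <- compendium[train]
  if (method == "familycode") {
    model <- fc_fit(training, fam, selection_alpha = selection_alpha,
                    floor = floor, positions = positions)
    predict(model, paste(fam$rows[id, ], collapse = ""), type = "energy",
            tf_id = id)
  } else if (method == "closest_paralog") {
    P <- closest_paralog(seqs[[id]], training, seqs[train])
    energy_from_psam(P, floor = floor)
  } else {
    if (is.null(weights)) {
      weights <- rep(1, fam$length + length(gap_insert))
    }
    P <- similarity_regression(paste(fam$rows[id, ], collapse = ""),
                               training, fam, weights, gap_insert)
    energy_from_psam(P, floor = floor)
  }
}

#' @export
print.fc_eval <- function(x, ...) {
  agg <- attr(x, "aggregate")
  cat("<cross-validation report> method=", attr(x, "method"),
      if (!is.null(attr(x, "threshold"))) {
        paste0(" threshold=", attr(x, "threshold"))
      },
      "\n  aggregate R^2 = ", signif(agg$r_squared, 4),
      ", RMSD = ", signif(agg$rmsd, 4),
      "  (", agg$n_entries, " entries)\n", sep = "")
  NextMethod()
}

#' @rdname fc_loocv
#' @param x an `fc_eval` report.
#' @param ... unused.
#' @return `glance()` returns the aggregate metrics as a one-row
#'   tibble.
#' @method glance fc_eval
#' @export
glance.fc_eval <- function(x, ...) {
  dplyr::bind_cols(attr(x, "aggregate"),
                   tibble(method = attr(x, "method"),
                          threshold = attr(x, "threshold") %||% NA_real_))
}

#' Per-TF prediction accuracy plot
#'
#' Dot plot of per-held-out-TF coefficients of determination from a
#' cross-validation report.
#'
#' @param object an `fc_eval` report.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot fc_eval
#' @export
autoplot.fc_eval <- function(object, ...) {
  df <- dplyr::arrange(as_tibble(object), .data$r_squared)
  df$tf_id <- factor(df$tf_id, levels = df$tf_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r_squared, y = .data$tf_id)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(R^2 ~ "(ddG/RT, held-out TF)"),
                  y = NULL,
                  title = paste("method:", attr(object, "method"))) +
    ggplot2::theme_minimal()
}
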