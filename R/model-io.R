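#' Serialize a fitted model to JSON
#'
#' The JSON file stores everything needed to reproduce predictions
#' byte-for-byte: the training alignment rows, per-position centering
#' vector, basis, singular values and scores, the selected features
#' with their coefficients and group-mean tables, and the
#' configuration.
#'
#' @param model an `fc_model`.
#' @param path file path.
#' @export
write_fc_model <- function(model, path) {
  pcs_out <- function(pc) {
    list(features = pc$features, beta = pc$beta,
         anova_p = pc$anova_p %||% numeric(0),
         group_means = purrr::map(pc$group_means, as.list))
  }
  obj <- list(
    format = "familycode-model-v1",
    family = model$family,
    tf_ids = model$tf_ids,
    rows = apply(model$rows, 1L, paste, collapse = ""),
    config = model$config,
    alignment_fingerprint = model$alignment_fingerprint,
    positions = purrr::map(model$positions, function(pm) {
      list(position = pm$position, mu = pm$mu,
           v = pm$v, d = pm$d, scores = pm$scores,
           pcs = purrr::map(pm$pcs, pcs_out))
    })
  )
  # I(17) significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fc_model
#' @param path file path of a model written by [write_fc_model()].
#' @return `read_fc_model()` returns the restored `fc_model`.
#' @export
read_fc_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = TRUE)
  if (!identical(obj$format, "familycode-model-v1")) {
    abort(paste0(path, ": not a familycode model file"))
  }
  tf_ids <- as.character(obj$tf_ids)
  rows <- do.call(rbind, strsplit(as.character(obj$rows), ""))
  rownames(rows) <- tf_ids
  restore_pc <- function(pc) {
    list(features = as.integer(pc$features),
         beta = as.numeric(pc$beta),
         anova_p = as.numeric(pc$anova_p),
         group_means = purrr::map(pc$group_means,
                                  ~ unlist(.x) %||% numeric(0)))
  }
  as_mat <- function(x) {
    if (is.list(x)) do.call(rbind, purrr::map(x, as.numeric))
    else {
      m <- as.matrix(x)
      storage.mode(m) <- "double"
      m
    }
  }
  positions <- purrr::map(obj$positions, function(pm) {
    list(position = pm$position,
         mu = as.numeric(pm$mu),
         v = as_mat(pm$v),
         d = as.numeric(pm$d),
         scores = as_mat(pm$scores),
         pcs = purrr::map(pm$pcs, restore_pc))
  })
  names(positions) <- purrr::map_chr(obj$positions, "position")
  structure(list(family = obj$family, tf_ids = tf_ids, rows = rows,
                 positions = positions,
                 config = obj$config,
                 alignment_fingerprint = obj$alignment_fingerprint),
            class = "fc_model")
}

#' Tidy a fitted family model
#'
#' One row per selected (DNA position, PC, residue) feature, with its
#' regression coefficient and ranking ANOVA p-value.
#'
#' @param x an `fc_model`.
#' @param ... unused.
#' @return A tibble: `dna_position`, `pc`, `residue`, `beta`,
#'   `anova_p`.
#' @method tidy fc_model
#' @export
tidy.fc_model <- function(x, ...) {
  rows <- list()
  for (pm in x$positions) {
    for (ci in 1:3) {
      pcm <- pm$pcs[[ci]]
      for (k in seq_along(pcm$features)) {
        r <- pcm$features[[k]]
        rows[[length(rows) + 1L]] <-
          tibble(dna_position = pm$position, pc = ci, residue = r,
                 beta = pcm$beta[[k]],
                 anova_p = pcm$anova_p[r] %||% NA_real_)
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble(dna_position = character(0), pc = integer(0),
                  residue = integer(0), beta = numeric(0),
                  anova_p = numeric(0)))
  }
  dplyr::bind_rows(rows)
}

#' @rdname tidy.fc_model
#' @return `glance()` returns a one-row tibble: `n_tfs`,
#'   `n_positions`, `n_features`, `selection_alpha`, `floor`.
#' @method glance fc_model
#' @export
glance.fc_model <- function(x, ...) {
  tibble(n_tfs = length(x$tf_ids),
         n_positions = length(x$positions),
         n_features = nrow(tidy(x)),
         selection_alpha = x$config$selection_alpha,
         floor = x$config$floor)
}
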