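#' Fit a family-level base-preference model
#'
#' For every DNA position the tetrahedral points of all training TFs
#' form an n x 3 cloud `M`.  The cloud is centered and decomposed by
#' SVD (`M - mu = U D V'`); the columns of `V` define a data-driven
#' coordinate frame inside the tetrahedron and the rows of
#' `S = (M - mu) V` are per-TF principal-component scores.  For each
#' PC, residue positions are ranked by one-way ANOVA of the scores
#' against amino-acid identity and added by forward selection: a
#' candidate enters the regression only while the nested-model F-test
#' (extra sum of squares) stays below `selection_alpha`, starting with
#' the top-ranked feature tested against the empty model.  Each
#' selected feature is encoded as the group-mean score of the TF's
#' amino acid (excluding the TF itself during fitting), and
#' coefficients are estimated by ordinary least squares without
#' intercept.
#'
#' @param compendium named list of `fc_psam`/`fc_energy` models with
#'   shared position labels (one per training TF).
#' @param fam an `fc_family` covering every TF in the compendium.
#' @param selection_alpha F-test threshold for forward feature
#'   selection (default 0.05).
#' @param floor relative-affinity floor used when inverse-mapping
#'   predictions (default 0.01).
#' @param family optional family tag stored in the model.
#' @param positions DNA position labels to model (default: all).
#' @return An object of class `fc_model`.
#' @seealso [predict.fc_model()], [predict_dddg()], [fc_loocv()]
#' @export
fc_fit <- function(compendium, fam, selection_alpha = 0.05, floor = 0.01,
                   family = NULL, positions = NULL) {
  compendium <- as_compendium(compendium)
  tfs <- names(compendium)
  if (length(tfs) < 4L) abort("at least 4 training TFs are required")
  missing <- setdiff(tfs, fam$tf_ids)
  if (length(missing) > 0L) {
    abort(paste0("TFs absent from the alignment: ",
                 paste(missing, collapse = ", ")))
  }
  positions <- positions %||% rownames(compendium[[1L]])
  rows <- fam$rows[tfs, , drop = FALSE]

  position_models <- purrr::map(positions, function(j) {
    fit_position_model(j, cloud_points(compendium, j), rows,
                       selection_alpha)
  })
  names(position_models) <- positions

  structure(list(family = family,
                 tf_ids = tfs,
                 rows = rows,
                 positions = position_models,
                 config = list(selection_alpha = selection_alpha,
                               floor = floor,
                               dddg_convention = "neg_log_4f"),
                 alignment_fingerprint =
                   sprintf("L=%d;n=%d", ncol(rows), nrow(rows))),
            class = "fc_model")
}

#' @export
print.fc_model <- function(x, ...) {
  nsel <- sum(purrr::map_int(x$positions, function(pm) {
    sum(purrr::map_int(pm$pcs, ~ length(.x$features)))
  }))
  cat("<familycode model> ", length(x$tf_ids), " TFs, ",
      length(x$positions), " DNA positions, ",
      nsel, " selected (PC, residue) features\n", sep = "")
  invisible(x)
}

#' Centered SVD of a tetrahedral cloud
#'
#' Centers the n x 3 cloud and returns its singular value
#' decomposition with a deterministic sign convention (each column of
#' `V` is flipped so that its largest-magnitude entry is positive).
#' A cloud of identical points is permitted and yields zero singular
#' values with `V = I`.
#'
#' @param M numeric n x 3 matrix (or `fc_cloud` tibble) of tetrahedral
#'   coordinates; at least 4 rows.
#' @return List with elements `u`, `d`, `v`, `mu` such that
#'   `M - mu = u diag(d) v'`.
#' @export
center_and_svd <- function(M) {
  M <- cloud_matrix(M)
  if (nrow(M) < 4L) abort("at least 4 TFs are required")
  mu <- colMeans(M)
  Xc <- sweep(M, 2L, mu)
  if (max(abs(Xc)) < 1e-14) {
    return(list(u = matrix(0, nrow(M), 3L), d = rep(0, 3L),
                v = diag(3L), mu = mu))
  }
  s <- svd(Xc)
  for (k in seq_along(s$d)) {
    i <- which.max(abs(s$v[, k]))
    if (s$v[i, k] < 0) {
      s$v[, k] <- -s$v[, k]
      s$u[, k] <- -s$u[, k]
    }
  }
  list(u = s$u, d = s$d, v = s$v, mu = mu)
}

fit_position_model <- function(label, M, rows, selection_alpha) {
  sv <- center_and_svd(M)
  S <- sweep(M, 2L, sv$mu) %*% sv$v   # scores = U D
  pcs <- purrr::map(1:3, function(c) {
    fit_pc(S[, c], rows, selection_alpha)
  })
  list(position = label, mu = sv$mu, v = sv$v, d = sv$d,
       scores = S, pcs = pcs)
}

# ANOVA p-value of y against the aa groups of each alignment column;
# columns with < 2 groups or no residual df give NA
rank_features <- function(y, rows) {
  vapply(seq_len(ncol(rows)), function(r) {
    aa <- rows[, r]
    g <- length(unique(aa))
    if (g < 2L || length(y) - g < 1L) return(NA_real_)
    anova_oneway(y, aa)[["p"]]
  }, numeric(1L))
}

# leave-self-out group-mean encoding of one residue column
loo_encoding <- function(y, aa) {
  x <- numeric(length(y))
  for (lev in unique(aa)) {
    idx <- which(aa == lev)
    if (length(idx) >= 2L) {
      x[idx] <- (sum(y[idx]) - y[idx]) / (length(idx) - 1L)
    } else {
      x[idx] <- 0 # singleton: no leave-one-out mean; fall back to grand mean
    }
  }
  x
}

full_group_means <- function(y, aa) {
  vapply(split(y, aa), mean, numeric(1L))
}

#' Rank and forward-select protein features for one response
#'
#' @param y numeric vector of per-TF scores (one PC).
#' @param rows character matrix of aligned residues, one row per TF in
#'   the same order as `y`.
#' @param alpha nested-model F-test threshold.
#' @return List: `features` (selected residue positions, in selection
#'   order), `beta` (OLS coefficients on the leave-self-out group-mean
#'   encodings), `anova_p` (ranking p-values for all positions),
#'   `group_means` (per selected feature, named vector of full-sample
#'   amino-acid group means).
#' @keywords internal
fit_pc <- function(y, rows, alpha) {
  p_rank <- rank_features(y, rows)
  order_r <- order(p_rank, seq_along(p_rank), na.last = NA)
  selected <- integer(0)
  X <- matrix(numeric(0), nrow = length(y), ncol = 0L)
  rss <- sum(y^2) # empty model predicts 0 (scores are centered)
  for (r in order_r) {
    x_new <- loo_encoding(y, rows[, r])
    Xc <- cbind(X, x_new)
    qr_c <- qr(Xc)
    if (qr_c$rank < ncol(Xc)) next # collinear with current design: skip
    fitc <- qr.coef(qr_c, y)
    rss_new <- sum((y - Xc %*% fitc)^2)
    df2 <- length(y) - ncol(Xc)
    if (df2 < 1L) break
    if (rss_new >= rss) break
    Fstat <- ((rss - rss_new) / 1) / (rss_new / df2)
    if (rss_new < 1e-12 * max(rss, 1)) Fstat <- Inf # essentially perfect fit
    p_F <- pf(Fstat, 1, df2, lower.tail = FALSE)
    if (is.na(p_F) || p_F >= alpha) break
    selected <- c(selected, r)
    X <- Xc
    rss <- rss_new
  }
  if (length(selected) == 0L) {
    return(list(features = integer(0), beta = numeric(0),
                anova_p = p_rank, group_means = list()))
  }
  beta <- qr.coef(qr(X), y)
  beta[is.na(beta)] <- 0
  gms <- purrr::map(selected, function(r) full_group_means(y, rows[, r]))
  names(gms) <- as.character(selected)
  list(features = selected, beta = unname(beta), anova_p = p_rank,
       group_means = gms)
}

#' Encode an aligned sequence into predicted PC scores
#'
#' For each selected feature of each PC, looks up the full-sample
#' group-mean score of the query's amino acid.  Amino acids unseen at
#' that position are encoded as a weighted mean over the observed
#' group means, with weight proportional to
#' `1 / (B[a, a] - B[a, a'])` under BLOSUM62 (non-positive
#' differences receive the largest finite positive weight).  Gaps use
#' the unweighted mean of the observed group means.
#'
#' @param pm one position model (internal structure of an `fc_model`).
#' @param seq_chars character vector of aligned residues.
#' @param blosum substitution matrix from [read_blosum()].
#' @return Numeric 3-vector of predicted PC scores.
#' @keywords internal
encode_sequence <- function(pm, seq_chars, blosum) {
  vapply(1:3, function(c) {
    pc <- pm$pcs[[c]]
    if (length(pc$features) == 0L) return(0)
    x <- vapply(seq_along(pc$features), function(k) {
      r <- pc$features[[k]]
      encode_residue(seq_chars[[r]], pc$group_means[[k]], blosum)
    }, numeric(1L))
    sum(pc$beta * x)
  }, numeric(1L))
}

encode_residue <- function(a, gm, blosum) {
  if (a %in% names(gm)) return(unname(gm[[a]]))
  observed <- setdiff(names(gm), "-")
  if (length(observed) == 0L) return(mean(gm))
  if (a == "-" || !a %in% rownames(blosum)) return(mean(gm[observed]))
  d <- blosum[a, a] - blosum[a, observed]
  w <- ifelse(d > 0, 1 / d, NA_real_)
  if (all(is.na(w))) {
    w <- rep(1, length(observed))
  } else {
    w[is.na(w)] <- max(w, na.rm = TRUE)
  }
  sum(w * gm[observed]) / sum(w)
}

#' Predict a binding model for an unseen family member
#'
#' Predicted PC scores are mapped back to tetrahedral coordinates via
#' the reverse SVD transformation (`v = mu + V s`) and inverse-mapped
#' to a PSAM column with the configured affinity floor.
#'
#' @param object an `fc_model`.
#' @param sequence aligned residue string of the model's alignment
#'   length (or the tf_id of a training TF).
#' @param type `"psam"` or `"energy"`.
#' @param tf_id identifier attached to the returned model.
#' @param ... unused.
#' @return An `fc_psam` (or `fc_energy`) over the model's DNA
#'   positions.
#' @export
predict.fc_model <- function(object, sequence, type = c("psam", "energy"),
                             tf_id = "prediction", ...) {
  type <- match.arg(type)
  chars <- model_sequence_chars(object, sequence)
  blosum <- read_blosum()
  w <- t(vapply(object$positions, function(pm) {
    s <- encode_sequence(pm, chars, blosum)
    v <- pm$mu + drop(pm$v %*% s)
    psam_column_from_tetra(v, floor = object$config$floor)
  }, numeric(4L)))
  rownames(w) <- names(object$positions)
  P <- psam(w, tf_id = tf_id, positions = rownames(w),
            family = object$family)
  if (type == "energy") energy_from_psam(P, floor = object$config$floor) else P
}

model_sequence_chars <- function(object, sequence) {
  sequence <- as.character(sequence)
  L <- ncol(object$rows)
  if (sequence %in% object$tf_ids) {
    return(unname(object$rows[sequence, ]))
  }
  if (nchar(sequence) != L) {
    abort(sprintf("sequence must be aligned to length %d", L))
  }
  strsplit(toupper(sequence), "")[[1L]]
}

#' Predict mutation-induced binding free-energy shifts
#'
#' For a set of missense mutations the regression is refit with the
#' mutated residue positions as the only, mandatory features (no
#' forward selection), the wild-type and mutant sequences are both
#' encoded and mapped into the tetrahedron, and the per-DNA-position
#' shift is converted to dddG/RT via [tetra_shift_dddg()].
#'
#' @param model an `fc_model`.
#' @param wt_seq aligned wild-type residue string (or training tf_id).
#' @param mutations mutations in `"R13V"` notation (from amino acid,
#'   standardized residue position, to amino acid), or a data frame
#'   with columns `r`, `from`, `to`.
#' @return Numeric matrix of dddG/RT values, one row per DNA position,
#'   columns A, C, G, T.
#' @export
predict_dddg <- function(model, wt_seq, mutations) {
  chars <- model_sequence_chars(model, wt_seq)
  muts <- parse_mutations(mutations)
  if (nrow(muts) == 0L) {
    out <- matrix(0, length(model$positions), 4L,
                  dimnames = list(names(model$positions), DNA_BASES))
    return(out)
  }
  if (any(muts$r < 1L | muts$r > length(chars))) {
    abort("mutated position outside the alignment")
  }
  bad <- muts$from != chars[muts$r]
  if (any(bad)) {
    abort(sprintf("wild-type residue mismatch at position %d: expected %s, found %s",
                  muts$r[bad][1L], muts$from[bad][1L], chars[muts$r[bad][1L]]))
  }
  mut_chars <- chars
  mut_chars[muts$r] <- muts$to
  blosum <- read_blosum()

  out <- t(vapply(model$positions, function(pm) {
    key <- refit_key_features(pm, model$rows, muts$r)
    s_wt <- encode_key(key, chars, blosum)
    s_mut <- encode_key(key, mut_chars, blosum)
    v_wt <- pm$mu + drop(pm$v %*% s_wt)
    v_mut <- pm$mu + drop(pm$v %*% s_mut)
    tetra_shift_dddg(v_wt, v_mut, floor = model$config$floor)
  }, numeric(4L)))
  rownames(out) <- names(model$positions)
  out
}

parse_mutations <- function(mutations) {
  if (is.null(mutations) || length(mutations) == 0L) {
    return(tibble(r = integer(0), from = character(0), to = character(0)))
  }
  if (is.data.frame(mutations)) {
    return(tibble(r = as.integer(mutations$r),
                  from = toupper(as.character(mutations$from)),
                  to = toupper(as.character(mutations$to))))
  }
  m <- regmatches(mutations,
                  regexec("^([A-Za-z\\-])(\\d+)([A-Za-z\\-])$", mutations))
  bad <- vapply(m, length, integer(1L)) != 4L
  if (any(bad)) {
    abort(paste0("cannot parse mutation: ", mutations[bad][1L]))
  }
  tibble(r = as.integer(vapply(m, `[`, character(1L), 3L)),
         from = toupper(vapply(m, `[`, character(1L), 2L)),
         to = toupper(vapply(m, `[`, character(1L), 4L)))
}

# refit one position model with the given residue positions as the only
# (mandatory) features; returns per-PC beta and group-mean tables
refit_key_features <- function(pm, rows, key_r) {
  key_r <- sort(unique(as.integer(key_r)))
  pcs <- purrr::map(1:3, function(c) {
    y <- pm$scores[, c]
    X <- vapply(key_r, function(r) loo_encoding(y, rows[, r]),
                numeric(nrow(rows)))
    X <- matrix(X, nrow = nrow(rows))
    beta <- qr.coef(qr(X), y)
    beta[is.na(beta)] <- 0
    gms <- purrr::map(key_r, function(r) full_group_means(y, rows[, r]))
    names(gms) <- as.character(key_r)
    list(features = key_r, beta = unname(beta), group_means = gms)
  })
  list(pcs = pcs)
}

encode_key <- function(key, chars, blosum) {
  vapply(1:3, function(c) {
    pc <- key$pcs[[c]]
    x <- vapply(seq_along(pc$features), function(k) {
      encode_residue(chars[[pc$features[[k]]]], pc$group_means[[k]], blosum)
    }, numeric(1L))
    sum(pc$beta * x)
  }, numeric(1L))
}
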