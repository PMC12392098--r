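#' Binding specificity models: energy matrices and PSAMs
#'
#' A binding model for one TF is stored either as an energy matrix of
#' ddG/RT penalties (dimensionless, one row per DNA position, columns
#' A, C, G, T; the preferred base of each row is exactly 0 and all
#' entries are >= 0) or as a position-specific affinity matrix (PSAM)
#' of relative affinities `w = exp(-ddG/RT)` (row maximum exactly 1,
#' all entries in \[0, 1\]).
#'
#' @param values numeric matrix, one row per DNA position, 4 columns in
#'   base order A, C, G, T.
#' @param tf_id character scalar identifying the TF.
#' @param positions optional character vector of DNA position labels
#'   (e.g. `"-3"..."+3"` for a palindromic frame, `"D1"..."D8"` for
#'   homeodomains).  Defaults to `"1"..."n"`.
#' @param family,platform,replicate,quality optional metadata tags
#'   (family name, assay platform, replicate tag, model-quality score).
#' @return An object of class `fc_energy` or `fc_psam`: the numeric
#'   matrix with position labels as rownames and metadata attributes.
#' @examples
#' E <- energy_matrix(rbind(c(0, 1.6, 4.6, 4.6), c(0.5, 0, 2, 2)),
#'                    tf_id = "TF1")
#' P <- psam_from_energy(E)
#' @name binding_models
NULL

new_binding_matrix <- function(values, tf_id, positions, class,
                               family = NULL, platform = NULL,
                               replicate = NULL, quality = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != 4L) {
    abort("binding model must have 4 base columns (A, C, G, T)")
  }
  if (!is.numeric(values) || anyNA(values)) {
    abort("binding model values must be numeric and non-missing")
  }
  if (is.null(positions)) {
    positions <- rownames(values) %||% as.character(seq_len(nrow(values)))
  }
  positions <- as.character(positions)
  if (length(positions) != nrow(values)) {
    abort("number of position labels must equal number of rows")
  }
  dimnames(values) <- list(positions, DNA_BASES)
  structure(values,
            tf_id = as.character(tf_id), family = family,
            platform = platform, replicate = replicate, quality = quality,
            class = c(class, "matrix", "array"))
}

#' @rdname binding_models
#' @export
energy_matrix <- function(values, tf_id = "TF", positions = NULL,
                          family = NULL, platform = NULL,
                          replicate = NULL, quality = NULL) {
  x <- new_binding_matrix(values, tf_id, positions, "fc_energy",
                          family, platform, replicate, quality)
  validate_energy(x)
}

#' @rdname binding_models
#' @export
psam <- function(values, tf_id = "TF", positions = NULL,
                 family = NULL, platform = NULL,
                 replicate = NULL, quality = NULL) {
  x <- new_binding_matrix(values, tf_id, positions, "fc_psam",
                          family, platform, replicate, quality)
  validate_psam(x)
}

validate_energy <- function(x, tol = 1e-8) {
  if (any(x < -tol)) abort("ddG/RT values must be non-negative")
  mins <- apply(x, 1L, min)
  if (any(abs(mins) > tol)) {
    abort("every row of an energy matrix must contain a 0 (preferred base)")
  }
  x[x < 0] <- 0
  x
}

validate_psam <- function(x, tol = 1e-8) {
  if (any(x < -tol) || any(x > 1 + tol)) {
    abort("relative affinities must lie in [0, 1]")
  }
  maxs <- apply(x, 1L, max)
  if (any(abs(maxs - 1) > tol)) {
    abort("every PSAM row must have maximum 1 (preferred base)")
  }
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' @export
print.fc_psam <- function(x, ...) {
  cat("<PSAM> ", attr(x, "tf_id"), "  (", nrow(x), " positions)\n", sep = "")
  print(round(unclass(strip_meta(x)), 4))
  invisible(x)
}

#' @export
print.fc_energy <- function(x, ...) {
  cat("<ddG/RT matrix> ", attr(x, "tf_id"), "  (", nrow(x),
      " positions)\n", sep = "")
  print(round(unclass(strip_meta(x)), 4))
  invisible(x)
}

strip_meta <- function(x) {
  attributes(x)[setdiff(names(attributes(x)), c("dim", "dimnames"))] <- NULL
  x
}

meta_of <- function(x) {
  list(tf_id = attr(x, "tf_id"), family = attr(x, "family"),
       platform = attr(x, "platform"), replicate = attr(x, "replicate"),
       quality = attr(x, "quality"))
}

with_meta <- function(values, template, class) {
  m <- meta_of(template)
  new_binding_matrix(values, m$tf_id, rownames(values) %||% rownames(template),
                     class, m$family, m$platform, m$replicate, m$quality)
}

#' Convert between energy matrices and PSAMs
#'
#' `psam_from_energy()` applies `w = exp(-ddG/RT)` elementwise;
#' `energy_from_psam()` applies `ddG/RT = -ln(w)` after flooring
#' relative affinities below `floor` (default 0.01) so the log is
#' finite; the row minimum is re-zeroed so the preferred-base
#' convention holds exactly.
#'
#' @param E an `fc_energy` matrix.
#' @param P an `fc_psam` matrix.
#' @param floor smallest relative affinity retained before taking logs.
#' @return The converted model (`fc_psam` or `fc_energy`).
#' @export
psam_from_energy <- function(E) {
  if (!inherits(E, "fc_energy")) E <- energy_matrix(E)
  with_meta(exp(-unclass(E)), E, "fc_psam")
}

#' @rdname psam_from_energy
#' @export
energy_from_psam <- function(P, floor = 0.01) {
  if (!inherits(P, "fc_psam")) P <- psam(P)
  w <- unclass(P)
  w[w < floor] <- floor
  G <- -log(w)
  G <- sweep(G, 1L, apply(G, 1L, min)) # re-zero rows (exact for floored rows)
  with_meta(G, P, "fc_energy")
}

#' Impose reverse-complement symmetry on a PSAM
#'
#' Palindromic binding frames (e.g. the bHLH E-box) are bound by
#' symmetric dimers, so the binding model should be invariant under
#' reverse complementation.  The symmetrized model is the geometric
#' mean, in affinity space, of the PSAM and its reverse complement
#' (equivalently the arithmetic mean of the two ddG/RT matrices,
#' matching the additive-energy convention), with each row re-scaled
#' to maximum 1.
#'
#' @param P an `fc_psam` with an even number of positions.
#' @return A reverse-complement symmetric `fc_psam`.
#' @export
rc_symmetrize <- function(P) {
  if (!inherits(P, "fc_psam")) P <- psam(P)
  if (nrow(P) %% 2L != 0L) {
    abort("reverse-complement symmetrization needs an even number of positions")
  }
  w <- unclass(P)
  s <- sqrt(w * revcomp_matrix(w))
  s <- s / apply(s, 1L, max)
  with_meta(s, P, "fc_psam")
}

revcomp_matrix <- function(w) {
  w[rev(seq_len(nrow(w))), REVCOMP_IDX, drop = FALSE]
}

#' Reverse-complement a PSAM
#'
#' @param P an `fc_psam`.
#' @return The PSAM of the reverse-complement binding frame (positions
#'   reversed, A/T and C/G columns swapped); position labels are kept
#'   in their new order.
#' @export
rc_psam <- function(P) {
  if (!inherits(P, "fc_psam")) P <- psam(P)
  w <- revcomp_matrix(unclass(P))
  rownames(w) <- rownames(P)
  with_meta(w, P, "fc_psam")
}
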