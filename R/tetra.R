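#' The tetrahedral embedding of base preference
#'
#' Each PSAM column (four relative affinities) is normalized to base
#' frequencies and mapped into a regular tetrahedron whose vertices
#' `t_A = (1,1,1)`, `t_C = (1,-1,-1)`, `t_G = (-1,1,-1)`,
#' `t_T = (-1,-1,1)` represent strict preference for a single base.
#' The mapping `v = f %*% T` (with `T` the 4 x 3 vertex matrix) is
#' exactly invertible on the probability simplex via
#' `f_b = (1 + <v, t_b>) / 4`.  Points near a face, edge or vertex are
#' insensitive to the precise (large) ddG/RT of strongly disfavored
#' bases, which is what makes the embedding robust to the noisy tail
#' of binding-model estimates.
#'
#' @return `tetra_vertices()` returns the constant 4 x 3 matrix of
#'   vertex coordinates, rows named A, C, G, T.
#' @examples
#' v <- tetra_from_freqs(c(1, 0, 0, 0))   # vertex t_A = (1, 1, 1)
#' freqs_from_tetra(c(0, 0, 0))           # uniform preference
#' @export
tetra_vertices <- function() {
  matrix(c(1, 1, 1,
           1, -1, -1,
           -1, 1, -1,
           -1, -1, 1),
         nrow = 4L, byrow = TRUE,
         dimnames = list(DNA_BASES, c("x", "y", "z")))
}

#' Normalize relative affinities to base frequencies
#'
#' @param w numeric 4-vector of relative affinities (A, C, G, T),
#'   all `>= 0`, not all zero.
#' @return Numeric 4-vector summing to 1.
#' @export
freqs_from_affinities <- function(w) {
  w <- as.numeric(w)
  if (length(w) != 4L || anyNA(w) || any(w < 0)) {
    abort("affinities must be 4 non-negative numbers")
  }
  s <- sum(w)
  if (s <= 0) abort("affinities must not all be zero")
  w / s
}

#' Map base frequencies to tetrahedral coordinates
#'
#' @param f numeric 4-vector of frequencies (sums to 1, all `>= 0`).
#' @return Numeric 3-vector `(x, y, z)` inside (or on) the tetrahedron.
#' @export
tetra_from_freqs <- function(f) {
  f <- as.numeric(f)
  if (length(f) != 4L || anyNA(f) || any(f < -1e-9) ||
      abs(sum(f) - 1) > 1e-6) {
    abort("frequencies must be 4 non-negative numbers summing to 1")
  }
  drop(f %*% tetra_vertices())
}

#' Recover base frequencies from a tetrahedral point
#'
#' Exact inverse of [tetra_from_freqs()] on the simplex.  Points
#' outside the tetrahedron yield one or more negative frequencies,
#' which is how exterior points are detected.
#'
#' @param v numeric 3-vector.
#' @return Numeric 4-vector summing to 1 (possibly with negative
#'   entries for exterior points).
#' @export
freqs_from_tetra <- function(v) {
  v <- as.numeric(v)
  if (length(v) != 3L || anyNA(v)) abort("point must be a numeric 3-vector")
  drop((1 + tetra_vertices() %*% v) / 4)
}

#' Is a tetrahedral point interior?
#'
#' A point is interior when all four reconstructed frequencies are
#' non-negative (within `tol`, to absorb float noise).
#'
#' @param v numeric 3-vector.
#' @param tol non-negativity tolerance.
#' @export
tetra_is_interior <- function(v, tol = 1e-12) {
  all(freqs_from_tetra(v) >= -tol)
}

#' Reconstruct a PSAM column from a tetrahedral point
#'
#' Frequencies are recovered by the inverse mapping, rescaled so the
#' preferred base has relative affinity 1, and entries below `floor`
#' (including any negatives from slightly exterior points) are set to
#' `floor`.
#'
#' @param v numeric 3-vector.
#' @param floor smallest relative affinity retained (default 0.01).
#' @return Numeric 4-vector of relative affinities with maximum 1.
#' @export
psam_column_from_tetra <- function(v, floor = 0.01) {
  f <- freqs_from_tetra(v)
  m <- max(f)
  if (m <= 0) {
    abort("degenerate exterior point: all frequencies non-positive; regularize first")
  }
  w <- f / m
  w[w < floor] <- floor
  names(w) <- DNA_BASES
  w
}

#' Pull an exterior point back inside the tetrahedron
#'
#' An exterior point (negative reconstructed frequency for at least
#' one base) is moved along the line connecting it to the vertex of
#' its least-preferred base, to the surface on which the reconstructed
#' relative affinity of that base equals `floor`.  If more than one
#' base is offending the step is repeated (most-negative frequency
#' first; ties broken in A, C, G, T order) until the point is interior.
#'
#' The relative affinity along the line is monitored directly
#' (`w_b = f_b / max(f)`, with the maximum taken pointwise) and the
#' crossing located by monotone bisection to `|w_b - floor| < 1e-10`.
#'
#' @param v numeric 3-vector.
#' @param floor target relative affinity for the moved base.
#' @param max_iter safety cap on the number of offending-base passes.
#' @return An interior 3-vector; `v` is returned unchanged if already
#'   interior.
#' @export
tetra_regularize <- function(v, floor = 0.01, max_iter = 10L) {
  v <- as.numeric(v)
  verts <- tetra_vertices()
  for (iter in seq_len(max_iter)) {
    f <- freqs_from_tetra(v)
    if (all(f >= -1e-12)) return(v) # interior points are never moved
    b <- which.min(f) # most negative frequency; ties -> A,C,G,T order
    v <- move_to_floor_plane(v, verts[b, ], b, floor)
  }
  abort("tetrahedral regularization did not converge (numeric fault)")
}

# bisection along v(lambda) = v + lambda * (vertex - v) for w_b = floor
move_to_floor_plane <- function(v, vertex, b, floor, tol = 1e-10) {
  vertex <- unname(as.numeric(vertex))
  wb <- function(lambda) {
    f <- freqs_from_tetra(v + lambda * (vertex - v))
    f[b] / max(f)
  }
  lo <- 0
  hi <- 1
  if (wb(lo) >= floor) return(v)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    val <- wb(mid)
    if (abs(val - floor) < tol) {
      return(v + mid * (vertex - v))
    }
    if (val < floor) lo <- mid else hi <- mid
  }
  v + ((lo + hi) / 2) * (vertex - v)
}

#' Binding free-energy shift between two tetrahedral points
#'
#' The shift vector `v_alt - v_ref` is placed at the origin and its
#' endpoint inverse-mapped to frequencies; if the endpoint falls
#' outside the tetrahedron it is first pulled back by
#' [tetra_regularize()].  The frequencies are converted to signed
#' energies as `dddG_b/RT = -ln(4 f_b)`, chosen so that a null shift
#' gives 0 for every base and reversing the shift flips every sign
#' (when neither endpoint needs regularization).  Estimating dddG/RT
#' through the embedding, rather than subtracting two ddG/RT matrices
#' directly, suppresses the large fluctuations of poorly determined
#' disfavored-base energies.
#'
#' @param v_ref,v_alt numeric 3-vectors (reference and alternative,
#'   e.g. wild-type and mutant).
#' @param floor relative-affinity floor used when the shift endpoint
#'   must be regularized.
#' @return Named numeric 4-vector of dddG/RT values (A, C, G, T).
#' @export
tetra_shift_dddg <- function(v_ref, v_alt, floor = 0.01) {
  e <- as.numeric(v_alt) - as.numeric(v_ref)
  if (!tetra_is_interior(e)) e <- tetra_regularize(e, floor = floor)
  f <- freqs_from_tetra(e)
  d <- -log(4 * f)
  names(d) <- DNA_BASES
  d
}

#' Embed a binding model in the tetrahedron
#'
#' Maps every row (DNA position) of a PSAM or energy matrix to its
#' tetrahedral point.
#'
#' @param x an `fc_psam` or `fc_energy`.
#' @return A tibble with columns `tf_id`, `position`, `x`, `y`, `z`.
#' @export
tetra_embed <- function(x) {
  if (inherits(x, "fc_energy")) x <- psam_from_energy(x)
  if (!inherits(x, "fc_psam")) x <- psam(x)
  w <- unclass(x)
  pts <- t(apply(w, 1L, function(row) {
    tetra_from_freqs(freqs_from_affinities(row))
  }))
  tibble(tf_id = attr(x, "tf_id"), position = rownames(w),
         x = pts[, 1L], y = pts[, 2L], z = pts[, 3L])
}

#' Tetrahedral cloud of a family compendium at one DNA position
#'
#' @param compendium named list of `fc_psam` or `fc_energy` models
#'   sharing position labels.
#' @param position DNA position label (or index) to extract.
#' @return A tibble (class `fc_cloud`) with columns `tf_id`, `x`, `y`,
#'   `z` and attribute `position`; one row per TF.
#' @export
tetra_cloud <- function(compendium, position) {
  compendium <- as_compendium(compendium)
  rows <- purrr::map(compendium, function(P) {
    w <- unclass(P)
    lab <- if (is.character(position)) position else rownames(w)[position]
    if (!lab %in% rownames(w)) {
      abort(paste0("DNA position '", lab, "' absent from model ",
                   attr(P, "tf_id")))
    }
    v <- tetra_from_freqs(freqs_from_affinities(w[lab, ]))
    tibble(tf_id = attr(P, "tf_id"), x = v[1L], y = v[2L], z = v[3L])
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "position") <-
    if (is.character(position)) position else rownames(compendium[[1L]])[position]
  class(out) <- c("fc_cloud", class(out))
  out
}

# fast path: n x 3 matrix of tetra points at one DNA position label,
# rownames = tf_ids (no tibble overhead; used by fit/scan internals)
cloud_points <- function(compendium, position) {
  verts <- tetra_vertices()
  pts <- t(vapply(compendium, function(P) {
    w <- unclass(P)[position, ]
    drop((w / sum(w)) %*% verts)
  }, numeric(3L)))
  dimnames(pts) <- list(names(compendium), c("x", "y", "z"))
  pts
}

# normalize a compendium: named list of fc_psam, names = tf_ids
as_compendium <- function(x) {
  if (inherits(x, "fc_psam") || inherits(x, "fc_energy")) x <- list(x)
  if (!is.list(x) || length(x) == 0L) abort("empty compendium")
  x <- purrr::map(x, function(m) {
    if (inherits(m, "fc_energy")) psam_from_energy(m)
    else if (inherits(m, "fc_psam")) m
    else abort("compendium entries must be fc_psam or fc_energy objects")
  })
  names(x) <- purrr::map_chr(x, attr, "tf_id")
  if (anyDuplicated(names(x))) abort("duplicate tf_id in compendium")
  labs <- rownames(x[[1L]])
  ok <- purrr::map_lgl(x, ~ identical(rownames(.x), labs))
  if (!all(ok)) abort("all models in a compendium must share position labels")
  x
}
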