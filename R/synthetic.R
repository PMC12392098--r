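#' Specification of a synthetic TF family
#'
#' The generator emulates the statistical structure that the
#' family-level model is built to exploit: at designated "determinant"
#' residue positions the amino-acid identity sets the tetrahedral
#' position of the binding-model column at a designated DNA position
#' (group target plus isotropic 3D noise, truncated to the
#' tetrahedron's interior), while all other residue columns are drawn
#' i.i.d. from a background alphabet and all other DNA positions
#' scatter around a per-position anchor point.
#'
#' @param n_tfs number of TFs in the family.
#' @param length alignment length L (standardized residue positions).
#' @param n_dna_positions number of DNA positions in each binding
#'   model.
#' @param determinants list of determinants; each a list with `r`
#'   (residue position), `j` (DNA position index) and `targets` (named
#'   list mapping amino acid to an interior 3-vector).  The default
#'   (`NULL`) plants one Arg/Val determinant at residue 13 (or the last
#'   residue of shorter alignments), mimicking the major-groove contact
#'   residue of bHLH proteins.
#' @param noise_sd within-group isotropic noise (tetrahedral units).
#' @param background_alphabet,background_freqs residue alphabet (and
#'   sampling weights) for non-determinant columns.
#' @param seed RNG seed; the same spec and seed give byte-identical
#'   families.
#' @return A list of class `fc_synth_spec`.
#' @export
synthetic_family_spec <- function(n_tfs = 50L, length = 20L,
                                  n_dna_positions = 6L,
                                  determinants = NULL,
                                  noise_sd = 0.05,
                                  background_alphabet = c("A", "E", "K", "L",
                                                          "N", "Q", "R", "S"),
                                  background_freqs = NULL,
                                  seed = 1L) {
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  determinants <- determinants %||%
    default_determinants(as.integer(length), as.integer(n_dna_positions))
  for (det in determinants) {
    stopifnot(is.numeric(det$r), is.numeric(det$j), is.list(det$targets))
    if (det$r < 1L || det$r > length) abort("determinant residue outside 1..L")
    if (det$j < 1L || det$j > n_dna_positions) {
      abort("determinant DNA position outside the model")
    }
    ok <- vapply(det$targets, tetra_is_interior, logical(1L))
    if (!all(ok)) abort("determinant targets must be interior points")
  }
  structure(list(n_tfs = as.integer(n_tfs), length = as.integer(length),
                 n_dna_positions = as.integer(n_dna_positions),
                 determinants = determinants, noise_sd = noise_sd,
                 background_alphabet = background_alphabet,
                 background_freqs = background_freqs %||%
                   rep(1 / base::length(background_alphabet),
                       base::length(background_alphabet)),
                 seed = as.integer(seed)),
            class = "fc_synth_spec")
}

default_determinants <- function(length = 20L, n_dna_positions = 6L) {
  list(list(r = min(13L, length), j = min(3L, n_dna_positions),
            targets = list(R = c(-0.5, 0.3, -0.5),   # G-preferring
                           V = c(0.55, -0.55, -0.55)))) # C-preferring
}

#' Generate a synthetic family with known ground truth
#'
#' @param spec an `fc_synth_spec`.
#' @return A list with elements `fam` (an `fc_family`), `compendium`
#'   (named list of `fc_energy` models) and `truth` (the spec plus the
#'   planted per-TF tetra points, determinant group assignments and
#'   non-determinant anchors).
#' @export
simulate_family <- function(spec) {
  stopifnot(inherits(spec, "fc_synth_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  n <- spec$n_tfs
  L <- spec$length
  tf_ids <- sprintf("TF%03d", seq_len(n))
  rows <- matrix(sample(spec$background_alphabet, n * L, replace = TRUE,
                        prob = spec$background_freqs),
                 nrow = n, dimnames = list(tf_ids, NULL))

  det_j <- vapply(spec$determinants, function(d) as.integer(d$j), integer(1L))
  assignments <- list()
  stride <- 1L
  for (d in seq_along(spec$determinants)) {
    det <- spec$determinants[[d]]
    aas <- names(det$targets)
    # balanced factorial assignment: each determinant cycles with a stride
    # equal to the product of earlier group counts, so determinants are
    # uncorrelated across TFs rather than perfectly linked
    aa_per_tf <- aas[(((seq_len(n) - 1L) %/% stride) %% length(aas)) + 1L]
    rows[, det$r] <- aa_per_tf
    assignments[[d]] <- setNames(aa_per_tf, tf_ids)
    stride <- stride * length(aas)
  }

  anchors <- purrr::map(seq_len(spec$n_dna_positions), function(j) {
    if (j %in% det_j) return(NULL)
    sample_interior_point(c(0, 0, 0), 0.25)
  })

  points <- purrr::map(seq_len(spec$n_dna_positions), function(j) {
    m <- matrix(NA_real_, n, 3L, dimnames = list(tf_ids, c("x", "y", "z")))
    m
  })
  for (j in seq_len(spec$n_dna_positions)) {
    d_idx <- match(j, det_j)
    for (i in seq_len(n)) {
      center <- if (!is.na(d_idx)) {
        det <- spec$determinants[[d_idx]]
        det$targets[[rows[i, det$r]]]
      } else {
        anchors[[j]]
      }
      points[[j]][i, ] <- sample_interior_point(center, spec$noise_sd)
    }
  }

  positions <- as.character(seq_len(spec$n_dna_positions))
  compendium <- purrr::map(seq_len(n), function(i) {
    w <- t(vapply(seq_len(spec$n_dna_positions), function(j) {
      psam_column_from_tetra(points[[j]][i, ], floor = 0.01)
    }, numeric(4L)))
    rownames(w) <- positions
    energy_from_psam(psam(w, tf_id = tf_ids[[i]], positions = positions,
                          family = "synthetic"))
  })
  names(compendium) <- tf_ids

  fam <- aligned_family(tf_ids, apply(rows, 1L, paste, collapse = ""))
  truth <- list(spec = spec, points = points, anchors = anchors,
                assignments = assignments,
                determinants = purrr::map(spec$determinants, function(det) {
                  list(r = det$r, j = det$j, targets = det$targets)
                }))
  list(fam = fam, compendium = compendium, truth = truth)
}

# rejection-sample an interior point around a center (up to 1000 tries)
sample_interior_point <- function(center, sd) {
  if (sd == 0) return(as.numeric(center))
  for (i in 1:1000) {
    v <- as.numeric(center) + rnorm(3L, sd = sd)
    if (tetra_is_interior(v)) return(v)
  }
  abort("could not sample an interior point: noise_sd too large")
}

#' Simulate replicate binding models
#'
#' Adds i.i.d. Gaussian noise (in energy space, mimicking assay noise)
#' to the ddG/RT entries of the non-preferred bases of every model,
#' re-zeroing each row minimum, and returns two independent replicate
#' compendia.
#'
#' @param compendium named list of `fc_energy` models.
#' @param energy_noise_sd noise standard deviation (ddG/RT units).
#' @param seed RNG seed.
#' @return List with elements `rep1` and `rep2`.
#' @export
simulate_replicates <- function(compendium, energy_noise_sd, seed = 1L) {
  if (energy_noise_sd < 0) abort("energy_noise_sd must be non-negative")
  compendium <- purrr::map(compendium, function(m) {
    if (inherits(m, "fc_psam")) energy_from_psam(m) else m
  })
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perturb <- function(E) {
    G <- unclass(E)
    for (i in seq_len(nrow(G))) {
      pref <- which.min(G[i, ])
      idx <- setdiff(1:4, pref)
      G[i, idx] <- G[i, idx] + rnorm(3L, sd = energy_noise_sd)
      G[i, ] <- G[i, ] - min(G[i, ])
    }
    with_meta(G, E, "fc_energy")
  }
  list(rep1 = purrr::map(compendium, perturb),
       rep2 = purrr::map(compendium, perturb))
}

#' Construct a mutant with known ground-truth effect
#'
#' Substitutes one residue of a synthetic TF and returns the mutant
#' aligned sequence together with the true dddG/RT matrix implied by
#' the planted determinant targets (zero at every DNA position for
#' background-position mutations).
#'
#' @param synth output of [simulate_family()].
#' @param tf_id TF to mutate.
#' @param mutation `"R13V"`-style string or data frame (see
#'   [predict_dddg()]); a single substitution.
#' @return List: `wt_seq`, `mut_seq` (aligned strings) and
#'   `true_dddg` (matrix, DNA positions x bases).
#' @export
simulate_mutant <- function(synth, tf_id, mutation) {
  fam <- synth$fam
  truth <- synth$truth
  check_member(fam, tf_id)
  mut <- parse_mutations(mutation)
  if (nrow(mut) != 1L) abort("exactly one substitution is required")
  if (mut$r < 1L || mut$r > fam$length) {
    abort("mutated position outside the alignment")
  }
  wt_chars <- fam$rows[tf_id, ]
  if (wt_chars[[mut$r]] != mut$from) {
    abort(sprintf("wild-type residue mismatch at %d: expected %s, found %s",
                  mut$r, mut$from, wt_chars[[mut$r]]))
  }
  mut_chars <- wt_chars
  mut_chars[[mut$r]] <- mut$to

  npos <- truth$spec$n_dna_positions
  dddg <- matrix(0, npos, 4L,
                 dimnames = list(as.character(seq_len(npos)), DNA_BASES))
  for (det in truth$determinants) {
    if (det$r == mut$r) {
      if (!mut$to %in% names(det$targets)) {
        abort(paste0("no planted target for amino acid ", mut$to,
                     " at determinant position ", det$r))
      }
      dddg[det$j, ] <- tetra_shift_dddg(det$targets[[mut$from]],
                                        det$targets[[mut$to]])
    }
  }
  list(wt_seq = paste(wt_chars, collapse = ""),
       mut_seq = paste(mut_chars, collapse = ""),
       true_dddg = dddg)
}

#' Write a simulated family to a fixture directory
#'
#' Emits the alignment (`alignment.fasta`), one PSAM TSV per TF under
#' `psams/`, and the ground truth (`truth.json`).
#'
#' @param synth output of [simulate_family()].
#' @param dir output directory (created if needed).
#' @export
write_synthetic_family <- function(synth, dir) {
  dir.create(file.path(dir, "psams"), recursive = TRUE, showWarnings = FALSE)
  write_family_alignment(synth$fam, file.path(dir, "alignment.fasta"))
  for (id in names(synth$compendium)) {
    write_psam(psam_from_energy(synth$compendium[[id]]),
               file.path(dir, "psams", paste0(id, ".tsv")))
  }
  truth <- synth$truth
  obj <- list(
    spec = unclass(truth$spec),
    determinants = truth$determinants,
    anchors = truth$anchors,
    points = purrr::map(truth$points, ~ unname(as.matrix(.x))),
    assignments = purrr::map(truth$assignments, as.list)
  )
  jsonlite::write_json(obj, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
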