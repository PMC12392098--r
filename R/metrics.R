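#' Coefficient of determination and root-mean-square deviation
#'
#' `r_squared()` computes `1 - SS_res / SS_tot` about the mean of the
#' observed values; `rmsd()` the root of the mean squared difference.
#' Observed vectors with zero variance give `NA` for R^2.
#'
#' @param pred,obs equal-length numeric vectors (n >= 2).
#' @return Numeric scalar.
#' @export
r_squared <- function(pred, obs) {
  check_paired(pred, obs)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot <= 0) return(NA_real_)
  1 - sum((obs - pred)^2) / ss_tot
}

#' @rdname r_squared
#' @export
rmsd <- function(pred, obs) {
  check_paired(pred, obs)
  sqrt(mean((pred - obs)^2))
}

check_paired <- function(pred, obs) {
  if (length(pred) != length(obs) || length(obs) < 2L) {
    abort("pred and obs must be equal-length vectors with n >= 2")
  }
  if (anyNA(pred) || anyNA(obs)) abort("missing values in metric input")
}

#' Concordance between replicate binding models
#'
#' Compares the ddG/RT entries of two models of the same TF (e.g. two
#' assay replicates) over all (position, base) cells, giving a
#' ceiling against which predictive performance can be judged.
#'
#' @param modelA,modelB `fc_energy` (or `fc_psam`) models with
#'   identical position labels.
#' @return A one-row tibble: `r_squared`, `rmsd`, `n_entries`.
#' @export
replicate_concordance <- function(modelA, modelB) {
  if (inherits(modelA, "fc_psam")) modelA <- energy_from_psam(modelA)
  if (inherits(modelB, "fc_psam")) modelB <- energy_from_psam(modelB)
  if (!identical(rownames(modelA), rownames(modelB))) {
    abort("replicate models must share position labels")
  }
  a <- as.vector(unclass(modelA))
  b <- as.vector(unclass(modelB))
  tibble(r_squared = r_squared(a, b), rmsd = rmsd(a, b),
         n_entries = length(a))
}

#' Range of a mutation-effect matrix
#'
#' The difference between the largest and smallest dddG/RT entry
#' across all DNA positions and bases: a scalar summary of how
#' strongly a mutation reshapes base preference.
#'
#' @param dddg numeric matrix of dddG/RT values.
#' @return Non-negative numeric scalar.
#' @export
dddg_range <- function(dddg) {
  if (length(dddg) == 0L) abort("empty dddG/RT matrix")
  max(dddg) - min(dddg)
}

#' Enrichment of large predicted effects among confirmed effects
#'
#' Hypergeometric tail test that mutants whose dddG/RT range exceeds
#' `threshold` are enriched among mutants independently classified as
#' changing specificity.
#'
#' @param classifications character/logical vector per mutant:
#'   `"change"`/`TRUE` versus `"no-change"`/`FALSE`.
#' @param ranges numeric vector of dddG/RT ranges, same length.
#' @param threshold range cutoff (default 1).
#' @return Hypergeometric p-value (1 for degenerate tables).
#' @export
effect_enrichment <- function(classifications, ranges, threshold = 1) {
  if (is.logical(classifications)) {
    change <- classifications
  } else {
    change <- tolower(as.character(classifications)) %in%
      c("change", "changed", "yes", "true")
  }
  if (length(change) != length(ranges) || length(change) == 0L) {
    abort("one classification per range is required")
  }
  N <- length(change)
  K <- sum(change)
  n <- sum(ranges > threshold)
  k <- sum(change & ranges > threshold)
  if (K == 0L || K == N || n == 0L) return(1)
  phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Compare the prediction errors of two methods
#'
#' `"bootstrap-t"` resamples the paired differences of squared errors
#' (B draws, seeded), forms the bootstrap null of the t statistic from
#' the centered differences, and reports a two-sided p-value.
#' `"wilcoxon"` is the paired Wilcoxon signed-rank test (as used for
#' comparing per-mutant R^2 values between predictors).
#'
#' @param errsA,errsB paired numeric error vectors (n >= 5).  For the
#'   bootstrap mode these are residuals whose squares are compared;
#'   for the Wilcoxon mode they are compared as given.
#' @param mode `"bootstrap-t"` or `"wilcoxon"`.
#' @param B bootstrap draws (default 10000).
#' @param seed RNG seed for the bootstrap.
#' @return Two-sided p-value.
#' @export
compare_methods <- function(errsA, errsB, mode = c("bootstrap-t", "wilcoxon"),
                            B = 10000L, seed = 1L) {
  mode <- match.arg(mode)
  if (length(errsA) != length(errsB) || length(errsA) < 5L) {
    abort("paired error vectors with n >= 5 are required")
  }
  if (mode == "wilcoxon") {
    if (all(errsA == errsB)) return(1)
    return(wilcox.test(errsA, errsB, paired = TRUE)$p.value)
  }
  d <- errsA^2 - errsB^2
  if (all(d == 0)) return(1)
  n <- length(d)
  t_obs <- mean(d) / (sd(d) / sqrt(n))
  d0 <- d - mean(d) # center to impose the null
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  t_boot <- vapply(seq_len(B), function(i) {
    s <- d0[sample.int(n, n, replace = TRUE)]
    se <- sd(s) / sqrt(n)
    if (se == 0) 0 else mean(s) / se
  }, numeric(1L))
  (1 + sum(abs(t_boot) >= abs(t_obs))) / (B + 1)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Binding free-energy difference from EMSA band intensities
#'
#' `ln[(bound_ref / unbound_ref) / (bound_alt / unbound_alt)]`: the
#' log ratio of bound/unbound band-intensity ratios between a
#' reference and an alternative probe, i.e. the ddG/RT of swapping
#' probes, estimated from a gel.
#'
#' @param bound_ref,unbound_ref,bound_alt,unbound_alt positive band
#'   intensities.
#' @return ddG/RT (dimensionless).
#' @export
emsa_ddg <- function(bound_ref, unbound_ref, bound_alt, unbound_alt) {
  vals <- c(bound_ref, unbound_ref, bound_alt, unbound_alt)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("band intensities must be positive")
  }
  log((bound_ref / unbound_ref) / (bound_alt / unbound_alt))
}
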