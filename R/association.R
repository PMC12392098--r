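#' MANOVA of tetrahedral position against amino-acid identity
#'
#' Tests the null hypothesis that the mean tetrahedral position is the
#' same for every amino-acid group, using the Pillai-Bartlett trace
#' `V = tr(H (H + E)^-1)` of the between-group (`H`) and within-group
#' (`E`) sums-of-squares-and-cross-products matrices, with the
#' standard F approximation (`s = min(p, g - 1)`).  If the total
#' scatter is rank-deficient (e.g. a cloud confined to a line or
#' plane) the test is carried out in the spanned subspace, so a 1-D
#' cloud reduces exactly to a one-way ANOVA.
#'
#' @param points an `fc_cloud` tibble from [tetra_cloud()], or a
#'   numeric matrix with one row per observation.
#' @param groups vector of group labels, one per row of `points`.
#' @return A one-row tibble: `pillai`, `statistic` (approximate F),
#'   `df1`, `df2`, `p_value`, `n`, `n_groups`.
#' @export
pillai_manova <- function(points, groups) {
  X <- cloud_matrix(points)
  groups <- as.character(groups)
  if (length(groups) != nrow(X)) {
    abort("one group label per observation is required")
  }
  g <- length(unique(groups))
  n <- nrow(X)
  if (g < 2L) abort("at least 2 distinct groups are required")
  if (n - g < 1L) abort("residual degrees of freedom must be positive")

  grand <- colMeans(X)
  Xc <- sweep(X, 2L, grand)
  Tm <- crossprod(Xc)                       # total SSCP
  H <- matrix(0, ncol(X), ncol(X))
  E <- matrix(0, ncol(X), ncol(X))
  for (lev in unique(groups)) {
    rows <- X[groups == lev, , drop = FALSE]
    d <- colMeans(rows) - grand
    H <- H + nrow(rows) * tcrossprod(d)
    rc <- sweep(rows, 2L, colMeans(rows))
    E <- E + crossprod(rc)
  }

  # restrict to the subspace actually spanned by the data
  eig <- eigen(Tm, symmetric = TRUE)
  keep <- eig$values > max(eig$values, 0) * 1e-10
  if (!any(keep)) abort("singular scatter: all observations identical")
  B <- eig$vectors[, keep, drop = FALSE]
  p <- ncol(B)
  Hs <- crossprod(B, H %*% B)
  Es <- crossprod(B, E %*% B)
  V <- sum(diag(Hs %*% solve(Hs + Es)))

  q <- g - 1
  v <- n - g
  s <- min(p, q)
  m <- (abs(p - q) - 1) / 2
  nn <- (v - p - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nn + s + 1)
  if (df2 <= 0) abort("residual degrees of freedom too small for the F approximation")
  Fstat <- (df2 / df1) * V / (s - V)
  tibble(pillai = V, statistic = Fstat, df1 = df1, df2 = df2,
         p_value = pf(Fstat, df1, df2, lower.tail = FALSE),
         n = n, n_groups = g)
}

cloud_matrix <- function(points) {
  if (inherits(points, "data.frame")) {
    as.matrix(points[, c("x", "y", "z")])
  } else {
    as.matrix(points)
  }
}

#' Per-group centroids of a tetrahedral cloud
#'
#' @param points an `fc_cloud` tibble or numeric matrix.
#' @param groups group label per row; rows with `NA` labels are
#'   dropped.
#' @return A tibble: `group`, `n`, `x`, `y`, `z`.
#' @export
group_centroids <- function(points, groups) {
  X <- cloud_matrix(points)
  keep <- !is.na(groups)
  X <- X[keep, , drop = FALSE]
  groups <- as.character(groups[keep])
  out <- purrr::map(sort(unique(groups)), function(lev) {
    rows <- X[groups == lev, , drop = FALSE]
    cm <- colMeans(rows)
    tibble(group = lev, n = nrow(rows), x = cm[1L], y = cm[2L], z = cm[3L])
  })
  dplyr::bind_rows(out)
}

#' One-way ANOVA of one principal-component score
#'
#' Closed-form sums-of-squares one-way ANOVA, used to rank protein
#' features by how strongly amino-acid identity at one residue
#' position structures the family's scores along one PC.
#'
#' @param u numeric vector of per-TF scores.
#' @param groups group label per score.
#' @return A one-row tibble: `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
anova_per_pc <- function(u, groups) {
  res <- anova_oneway(as.numeric(u), as.character(groups))
  tibble(statistic = res[["F"]], df1 = res[["df1"]], df2 = res[["df2"]],
         p_value = res[["p"]])
}

# scalar-returning one-way ANOVA used in feature-ranking hot loops
anova_oneway <- function(u, groups) {
  g <- length(unique(groups))
  n <- length(u)
  if (g < 2L) abort("at least 2 distinct groups are required")
  if (n - g < 1L) abort("residual degrees of freedom must be positive")
  grand <- mean(u)
  ns <- tabulate(factor(groups))
  means <- vapply(split(u, groups), mean, numeric(1L))
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((u - grand)^2) - ssb
  df1 <- g - 1
  df2 <- n - g
  if (ssw <= .Machine$double.eps * max(ssb, 1)) {
    Fstat <- if (ssb > 0) Inf else 0
  } else {
    Fstat <- (ssb / df1) / (ssw / df2)
  }
  c(F = Fstat, df1 = df1, df2 = df2,
    p = pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' Scan a family for sequence determinants of base preference
#'
#' Runs one MANOVA per (residue position, DNA position) pair: the
#' dependent variable is the tetrahedral position of each TF's
#' binding-model column at that DNA position, the independent variable
#' the amino-acid identity at that residue position.  Residue columns
#' with fewer than two groups (or no residual degrees of freedom)
#' yield `NA`.  Gap characters form a group of their own only when at
#' least `min_gap_group` TFs share the gap; otherwise gapped TFs are
#' excluded from that cell.
#'
#' @param compendium named list of `fc_psam`/`fc_energy` models with
#'   shared position labels.
#' @param fam an `fc_family` covering every TF in the compendium.
#' @param alpha Bonferroni-corrected significance level (default
#'   0.001).
#' @param positions DNA position labels to scan (default: all).
#' @param min_gap_group minimum number of gapped TFs for a gap group.
#' @return A tibble (class `fc_scan`), one row per (residue, DNA
#'   position): `residue`, `dna_position`, `n`, `n_groups`, `pillai`,
#'   `statistic`, `df1`, `df2`, `p_value`, `p_bonferroni`,
#'   `significant`.  Attributes `alpha` and `n_tests` record the
#'   correction.
#' @export
scan_associations <- function(compendium, fam, alpha = 0.001,
                              positions = NULL, min_gap_group = 2L) {
  compendium <- as_compendium(compendium)
  tfs <- names(compendium)
  missing <- setdiff(tfs, fam$tf_ids)
  if (length(missing) > 0L) {
    abort(paste0("TFs absent from the alignment: ",
                 paste(missing, collapse = ", ")))
  }
  positions <- positions %||% rownames(compendium[[1L]])

  clouds <- purrr::map(positions, function(j) cloud_points(compendium, j))
  names(clouds) <- positions

  rows <- list()
  for (r in seq_len(fam$length)) {
    aa <- fam$rows[tfs, r]
    keep <- aa != "-" | sum(aa == "-") >= min_gap_group
    for (j in positions) {
      res <- scan_cell(clouds[[j]][keep, , drop = FALSE], aa[keep])
      rows[[length(rows) + 1L]] <-
        dplyr::bind_cols(tibble(residue = r, dna_position = j), res)
    }
  }
  out <- dplyr::bind_rows(rows)
  n_tests <- sum(!is.na(out$p_value))
  out$p_bonferroni <- pmin(out$p_value * n_tests, 1)
  out$significant <- !is.na(out$p_bonferroni) & out$p_bonferroni < alpha
  attr(out, "alpha") <- alpha
  attr(out, "n_tests") <- n_tests
  class(out) <- c("fc_scan", class(out))
  out
}

scan_cell <- function(X, aa) {
  blank <- tibble(n = nrow(X), n_groups = length(unique(aa)),
                  pillai = NA_real_, statistic = NA_real_,
                  df1 = NA_real_, df2 = NA_real_, p_value = NA_real_)
  if (length(unique(aa)) < 2L || nrow(X) - length(unique(aa)) < 1L) {
    return(blank)
  }
  res <- tryCatch(pillai_manova(X, aa), error = function(e) NULL)
  if (is.null(res)) return(blank)
  res[, c("n", "n_groups", "pillai", "statistic", "df1", "df2", "p_value")]
}

#' Heatmap of an association scan
#'
#' Plots `-log10` Bonferroni-corrected p-values as a residue-position
#' by DNA-position heatmap, with significant cells outlined.
#'
#' @param object an `fc_scan` from [scan_associations()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot fc_scan
#' @export
autoplot.fc_scan <- function(object, ...) {
  df <- dplyr::mutate(
    as_tibble(object),
    dna_position = factor(.data$dna_position,
                          levels = unique(.data$dna_position)),
    neglogp = -log10(pmax(.data$p_bonferroni, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dna_position,
                                   y = .data$residue,
                                   fill = .data$neglogp)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = dplyr::filter(df, .data$significant),
                       fill = NA, colour = "black", linewidth = 0.4) +
    ggplot2::scale_fill_viridis_c(name = "-log10 p (Bonf.)",
                                  na.value = "grey90") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "DNA position", y = "residue position") +
    ggplot2::theme_minimal()
}
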