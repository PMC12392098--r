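# Shared fixtures, built in code at test time.

# a small hand-made PSAM with an exact CACGTG E-box core at offset 1
ebox_psam <- function(tf_id = "EBOX") {
  w <- rbind(c(0.4, 0.3, 0.2, 1),    # flank
             c(0.01, 1, 0.01, 0.01), # C
             c(1, 0.01, 0.01, 0.01), # A
             c(0.01, 1, 0.01, 0.01), # C
             c(0.01, 0.01, 1, 0.01), # G
             c(0.01, 0.01, 0.01, 1), # T
             c(0.01, 0.01, 1, 0.01), # G
             c(0.25, 1, 0.5, 0.8))   # flank
  psam(w, tf_id = tf_id)
}

# family of identical TFs sharing one PSAM (sequences also identical)
identical_family <- function(n = 6L, npos = 4L) {
  w <- rbind(c(1, 0.5, 0.2, 0.05),
             c(0.3, 1, 0.08, 0.6),
             c(0.02, 0.9, 1, 0.4),
             c(1, 1, 0.01, 0.25))[seq_len(npos), , drop = FALSE]
  ids <- sprintf("TF%02d", seq_len(n))
  compendium <- lapply(ids, function(id) {
    psam(w, tf_id = id, positions = as.character(seq_len(npos)))
  })
  names(compendium) <- ids
  fam <- aligned_family(ids, rep("MKRVANQLE", n))
  list(compendium = compendium, fam = fam)
}

# random interior tetra point (uniform over frequency simplex)
random_interior_point <- function() {
  f <- -log(runif(4))
  tetra_from_freqs(f / sum(f))
}

# independent textbook MANOVA oracle via stats::manova / summary.manova
manova_oracle <- function(X, groups) {
  fit <- stats::manova(X ~ factor(groups))
  tab <- summary(fit, test = "Pillai")$stats
  list(pillai = tab[1, "Pillai"], statistic = tab[1, "approx F"],
       df1 = tab[1, "num Df"], df2 = tab[1, "den Df"],
       p_value = tab[1, "Pr(>F)"])
}

# reverse complement of a PSAM matrix (independent of package internals)
revcomp_matrix_fixture <- function(w) {
  w[rev(seq_len(nrow(w))), c(4, 3, 2, 1), drop = FALSE]
}

encode_residue_fixture <- function(a, gm, blosum) {
  familycode:::encode_residue(a, gm, blosum)
}
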