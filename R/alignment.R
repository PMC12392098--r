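#' Aligned TF family
#'
#' A family alignment fixes a standardized residue coordinate system
#' (e.g. positions 1-53 for the bHLH domain aligned to its profile
#' HMM).  The alignment itself is produced outside this package (e.g.
#' with hmmalign); here it is consumed as equal-length gapped rows.
#'
#' @param tf_ids character vector of unique TF identifiers.
#' @param sequences character vector of gapped, equal-length residue
#'   strings (one per TF; `-` is the gap character).
#' @param raw_sequences optional named character vector of unaligned
#'   (cloned) protein sequences, used by Levenshtein-based baselines.
#' @return An object of class `fc_family`.
#' @export
aligned_family <- function(tf_ids, sequences, raw_sequences = NULL) {
  tf_ids <- as.character(tf_ids)
  sequences <- toupper(as.character(sequences))
  if (length(tf_ids) != length(sequences)) {
    abort("tf_ids and sequences must have the same length")
  }
  if (anyDuplicated(tf_ids)) abort("duplicate tf_id in alignment")
  L <- unique(nchar(sequences))
  if (length(L) != 1L || L == 0L) {
    abort("all aligned rows must have the same (positive) length")
  }
  rows <- do.call(rbind, strsplit(sequences, ""))
  rownames(rows) <- tf_ids
  structure(list(tf_ids = tf_ids, rows = rows, length = L,
                 raw_sequences = raw_sequences),
            class = "fc_family")
}

#' @export
print.fc_family <- function(x, ...) {
  cat("<aligned family> ", length(x$tf_ids), " TFs, ", x$length,
      " match positions\n", sep = "")
  invisible(x)
}

#' Load a family alignment from disk
#'
#' Supported formats: aligned FASTA, Stockholm, and A2M (in which the
#' match columns -- uppercase residues and `-` -- are extracted and
#' insert states dropped).
#'
#' @param path file path.
#' @param format `"fasta"`, `"stockholm"`, or `"a2m"`; guessed from
#'   the file extension by default.
#' @return An `fc_family`.
#' @export
read_family_alignment <- function(path,
                                  format = c("auto", "fasta", "stockholm",
                                             "a2m")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext,
                     sto = , stk = , stockholm = "stockholm",
                     a2m = "a2m",
                     "fasta")
  }
  if (format == "stockholm") {
    seqs <- read_stockholm(path)
  } else {
    # BStringSet preserves case (A2M marks insert states in lowercase)
    aa <- Biostrings::readBStringSet(path)
    seqs <- setNames(as.character(aa), sub("\\s.*", "", names(aa)))
  }
  if (format == "a2m") {
    seqs <- vapply(seqs, function(s) {
      chars <- strsplit(s, "")[[1L]]
      paste(chars[chars %in% c(LETTERS, "-")], collapse = "")
    }, character(1L))
  }
  aligned_family(names(seqs), unname(seqs))
}

read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^# STOCKHOLM", lines[[1L]])) {
    abort(paste0(path, ": missing '# STOCKHOLM' header"))
  }
  seqs <- list()
  for (ln in lines[-1L]) {
    if (grepl("^#", ln) || !nzchar(trimws(ln)) || grepl("^//", ln)) next
    fields <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(fields) != 2L) abort(paste0(path, ": malformed sequence line"))
    id <- fields[[1L]]
    seqs[[id]] <- paste0(seqs[[id]] %||% "", fields[[2L]])
  }
  if (length(seqs) == 0L) abort(paste0(path, ": no sequences"))
  vapply(seqs, gsub, character(1L), pattern = "\\.", replacement = "-")
}

#' Write a family alignment as aligned FASTA
#'
#' @param fam an `fc_family`.
#' @param path file path.
#' @export
write_family_alignment <- function(fam, path) {
  seqs <- apply(fam$rows, 1L, paste, collapse = "")
  writeLines(as.vector(rbind(paste0(">", fam$tf_ids), seqs)), path)
  invisible(path)
}

#' Residue lookup in a family alignment
#'
#' Returns the amino-acid identity (or `-`) of TF `tf_id` at
#' standardized residue position `r`.
#'
#' @param fam an `fc_family`.
#' @param tf_id TF identifier.
#' @param r residue position in `1..L`.
#' @return Single character.
#' @export
residue_at <- function(fam, tf_id, r) {
  check_member(fam, tf_id)
  r <- as.integer(r)
  if (is.na(r) || r < 1L || r > fam$length) {
    abort(sprintf("residue position %s outside 1..%d", r, fam$length))
  }
  unname(fam$rows[tf_id, r])
}

check_member <- function(fam, tf_id) {
  if (!tf_id %in% fam$tf_ids) {
    abort(paste0("unknown tf_id: ", tf_id))
  }
}

#' Sequence distances
#'
#' `hamming_dist()` counts aligned positions at which two family rows
#' differ (a gap counts as an ordinary character).  `levenshtein_dist()`
#' is the standard unit-cost edit distance between two plain residue
#' strings (via `utils::adist`).
#'
#' @param fam an `fc_family`.
#' @param id1,id2 TF identifiers.
#' @return Integer distance.
#' @export
hamming_dist <- function(fam, id1, id2) {
  check_member(fam, id1)
  check_member(fam, id2)
  sum(fam$rows[id1, ] != fam$rows[id2, ])
}

#' @rdname hamming_dist
#' @param s1,s2 residue strings.
#' @export
levenshtein_dist <- function(s1, s2) {
  drop(adist(as.character(s1), as.character(s2)))
}

#' Extract ungapped sequences from an alignment
#'
#' Uses `raw_sequences` when present, otherwise the aligned rows with
#' gaps removed.
#'
#' @param fam an `fc_family`.
#' @param ids TF identifiers (default: all).
#' @return Named character vector of residue strings.
#' @export
family_sequences <- function(fam, ids = fam$tf_ids) {
  vapply(ids, function(id) {
    check_member(fam, id)
    raw <- fam$raw_sequences[[id]]
    if (!is.null(raw) && !is.na(raw)) return(raw)
    paste(fam$rows[id, fam$rows[id, ] != "-"], collapse = "")
  }, character(1L))
}

#' Insert all-gap columns into an alignment
#'
#' Reconciles alignments produced with different profile HMMs (e.g.
#' inserting two gap columns after match position 34 to match the
#' coordinate system of pretrained similarity-regression weights).
#'
#' @param fam an `fc_family`.
#' @param after integer vector: a gap column is inserted after each
#'   listed match position (0 inserts at the front; repeats allowed).
#' @return An `fc_family` with `length + length(after)` columns.
#' @export
insert_gap_columns <- function(fam, after) {
  after <- as.integer(after)
  if (any(after < 0L | after > fam$length)) {
    abort("gap-column anchors must lie in 0..L")
  }
  idx <- seq_len(fam$length)
  # build the new column template: original indices with NA for gaps
  template <- integer(0)
  for (i in 0:fam$length) {
    if (i > 0L) template <- c(template, i)
    template <- c(template, rep(NA_integer_, sum(after == i)))
  }
  rows <- fam$rows[, ifelse(is.na(template), 1L, template), drop = FALSE]
  rows[, is.na(template)] <- "-"
  aligned_family(fam$tf_ids, apply(rows, 1L, paste, collapse = ""),
                 raw_sequences = fam$raw_sequences)
}

#' Export the residue lookup table
#'
#' @param fam an `fc_family`.
#' @return A tibble with one row per (TF, residue position):
#'   `tf_id`, `r`, `aa`.
#' @export
residue_table <- function(fam) {
  tibble(tf_id = rep(fam$tf_ids, each = fam$length),
         r = rep(seq_len(fam$length), times = length(fam$tf_ids)),
         aa = as.vector(t(fam$rows)))
}
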