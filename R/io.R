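#' Read and write binding models
#'
#' Two plain-text interchange formats are supported.  `"tsv"` is a
#' tab-separated table with header `pos A C G T` and one row per DNA
#' position (UTF-8, `.` decimal).  `"meme"` is the MEME minimal motif
#' format; its letter-probability rows are converted to a PSAM by
#' dividing each row by its maximum (and back to probabilities, by row
#' normalization, on write).
#'
#' @param path file path.
#' @param format `"tsv"` or `"meme"`.
#' @param tf_id TF identifier; defaults to the motif name (MEME) or
#'   the file name (TSV).
#' @return `read_psam()` / `read_energy()` return an `fc_psam` /
#'   `fc_energy`; the writers return `path` invisibly.
#' @export
read_psam <- function(path, format = c("tsv", "meme"), tf_id = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    m <- read_pos_table(path)
    psam(m$values, tf_id = tf_id %||% default_id(path), positions = m$pos)
  } else {
    m <- read_meme_minimal(path)
    w <- m$probs / apply(m$probs, 1L, max)
    psam(w, tf_id = tf_id %||% m$name)
  }
}

#' @rdname read_psam
#' @export
read_energy <- function(path, tf_id = NULL) {
  m <- read_pos_table(path)
  energy_matrix(m$values, tf_id = tf_id %||% default_id(path),
                positions = m$pos)
}

#' @rdname read_psam
#' @param P,E the model to write.
#' @export
write_psam <- function(P, path, format = c("tsv", "meme")) {
  format <- match.arg(format)
  if (!inherits(P, "fc_psam")) P <- psam(P)
  if (format == "tsv") {
    write_pos_table(unclass(P), path)
  } else {
    probs <- sweep(unclass(P), 1L, rowSums(unclass(P)), "/")
    lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
               paste("MOTIF", attr(P, "tf_id")),
               sprintf("letter-probability matrix: alphabet length= 4 w= %d nsites= 20 E= 0",
                       nrow(P)),
               apply(probs, 1L, function(r) paste(sprintf("%.6f", r),
                                                  collapse = "  ")))
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname read_psam
#' @export
write_energy <- function(E, path) {
  if (!inherits(E, "fc_energy")) E <- energy_matrix(E)
  write_pos_table(unclass(E), path)
  invisible(path)
}

default_id <- function(path) sub("\\.[^.]*$", "", basename(path))

read_pos_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) abort(paste0(path, ": no data rows"))
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  if (length(header) != 5L || !identical(toupper(header[2:5]), DNA_BASES)) {
    abort(paste0(path, ":1: expected header 'pos A C G T'"))
  }
  pos <- character(0)
  vals <- list()
  for (i in 2:length(lines)) {
    fields <- strsplit(trimws(lines[[i]]), "\\s+")[[1L]]
    if (length(fields) != 5L) {
      abort(sprintf("%s:%d: expected 5 fields, found %d", path, i,
                    length(fields)))
    }
    num <- suppressWarnings(as.numeric(fields[2:5]))
    if (anyNA(num)) abort(sprintf("%s:%d: non-numeric value", path, i))
    pos <- c(pos, fields[[1L]])
    vals[[length(vals) + 1L]] <- num
  }
  list(pos = pos, values = do.call(rbind, vals))
}

write_pos_table <- function(m, path) {
  lines <- c(paste(c("pos", DNA_BASES), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i], format(m[i, ], digits = 15)),
                     collapse = "\t")
             }, character(1L)))
  writeLines(lines, path)
}

read_meme_minimal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  motif_at <- grep("^MOTIF\\b", lines)
  if (length(motif_at) == 0L) {
    abort(paste0(path, ": no MOTIF record found"))
  }
  if (length(motif_at) > 1L) {
    abort(paste0(path, ": multiple motifs per file not supported"))
  }
  name <- strsplit(trimws(lines[[motif_at]]), "\\s+")[[1L]][2L]
  mat_at <- grep("^letter-probability matrix", lines)
  mat_at <- mat_at[mat_at > motif_at][1L]
  if (is.na(mat_at)) {
    abort(paste0(path, ": MOTIF without letter-probability matrix"))
  }
  width <- suppressWarnings(
    as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[[mat_at]])))
  rows <- list()
  i <- mat_at + 1L
  while (i <= length(lines) && length(rows) < (width %||% Inf)) {
    txt <- trimws(lines[[i]])
    if (!nzchar(txt)) {
      if (length(rows) > 0L) break
      i <- i + 1L
      next
    }
    num <- suppressWarnings(as.numeric(strsplit(txt, "\\s+")[[1L]]))
    if (anyNA(num) || length(num) != 4L) {
      if (is.na(width)) break
      abort(sprintf("%s:%d: expected 4 probabilities", path, i))
    }
    rows[[length(rows) + 1L]] <- num
    i <- i + 1L
  }
  if (!is.na(width) && length(rows) != width) {
    abort(sprintf("%s: expected %d matrix rows, found %d", path, width,
                  length(rows)))
  }
  probs <- do.call(rbind, rows)
  rownames(probs) <- as.character(seq_len(nrow(probs)))
  colnames(probs) <- DNA_BASES
  list(name = name %||% default_id(path), probs = probs)
}

#' Read a compendium of binding models from a directory
#'
#' Reads every `*.tsv` (or `*.meme`) model under `dir` into a named
#' list keyed by tf_id.
#'
#' @param dir directory of model files.
#' @param format file format, as in [read_psam()].
#' @param type `"psam"` or `"energy"` (TSV only).
#' @return Named list of binding models.
#' @export
read_compendium <- function(dir, format = c("tsv", "meme"),
                            type = c("psam", "energy")) {
  format <- match.arg(format)
  type <- match.arg(type)
  ext <- if (format == "meme") "\\.meme$" else "\\.tsv$"
  files <- sort(list.files(dir, pattern = ext, full.names = TRUE))
  if (length(files) == 0L) abort(paste0("no model files found under ", dir))
  models <- purrr::map(files, function(f) {
    if (type == "energy") read_energy(f) else read_psam(f, format)
  })
  names(models) <- purrr::map_chr(models, attr, "tf_id")
  models
}

#' Write a tetrahedral cloud to TSV
#'
#' @param cloud an `fc_cloud` tibble from [tetra_cloud()].
#' @param path file path.
#' @export
write_cloud <- function(cloud, path) {
  utils::write.table(as.data.frame(cloud), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an NCBI-format substitution matrix (e.g. BLOSUM62)
#'
#' Lines starting with `#` are comments; the first non-comment line
#' holds the column letters and each subsequent line a row letter and
#' its scores.
#'
#' @param path file path, or `NULL` (default) to return the BLOSUM62
#'   matrix shipped with Biostrings.
#' @return Integer matrix with amino-acid row/column names.
#' @export
read_blosum <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.fc_cache$blosum62)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      .fc_cache$blosum62 <- env$BLOSUM62
    }
    return(.fc_cache$blosum62)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  rows <- purrr::map(lines[-1L], ~ strsplit(trimws(.x), "\\s+")[[1L]])
  m <- do.call(rbind, purrr::map(rows, ~ as.numeric(.x[-1L])))
  rownames(m) <- purrr::map_chr(rows, 1L)
  colnames(m) <- cols
  m
}
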