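IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' IUPAC consensus seed for fixing a binding frame
#'
#' A seed like `"NCANNTGN"` (bHLH E-box) or `"NNTDAYNN"` (homeodomain)
#' is expanded into a 4 x L indicator matrix with a 1 wherever the
#' IUPAC symbol at that position covers the base.
#'
#' @param pattern character scalar over the IUPAC nucleotide alphabet.
#' @return An object of class `fc_seed`: the indicator matrix (rows
#'   A, C, G, T) with the pattern attached.
#' @examples
#' iupac_seed("NNTDAYNN")
#' @export
iupac_seed <- function(pattern) {
  pattern <- toupper(as.character(pattern))
  chars <- strsplit(pattern, "")[[1L]]
  if (length(chars) == 0L || !all(chars %in% names(IUPAC_CODES))) {
    abort("seed pattern must be a non-empty IUPAC nucleotide string")
  }
  ind <- vapply(chars, function(s) as.numeric(DNA_BASES %in% IUPAC_CODES[[s]]),
                numeric(4L))
  rownames(ind) <- DNA_BASES
  colnames(ind) <- chars
  structure(ind, pattern = pattern, class = c("fc_seed", "matrix", "array"))
}

#' @export
print.fc_seed <- function(x, ...) {
  cat("<IUPAC seed> ", attr(x, "pattern"), "\n", sep = "")
  invisible(x)
}

#' Motif matching score between a PSAM window and a seed
#'
#' `MMS = sqrt( (1/J) * sum_j min over covered b' of (1 - w_{j,b'})^2 )`
#' where `J` is the seed length: each seed position contributes the
#' squared distance from 1 of its best-matching covered base.  A score
#' of 0 means that at every position some base covered by the IUPAC
#' symbol has relative affinity exactly 1.
#'
#' @param P an `fc_psam`.
#' @param seed an `fc_seed` (or pattern string).
#' @param offset 0-based offset of the seed window within `P`.
#' @param strand `"+"` to score the window as-is, `"-"` to score its
#'   reverse complement.
#' @return Non-negative numeric scalar.
#' @export
mms_score <- function(P, seed, offset = 0L, strand = c("+", "-")) {
  strand <- match.arg(strand)
  if (!inherits(P, "fc_psam")) P <- psam(P)
  if (!inherits(seed, "fc_seed")) seed <- iupac_seed(seed)
  J <- ncol(seed)
  if (offset < 0L || offset + J > nrow(P)) {
    abort("seed window does not fit inside the PSAM at this offset")
  }
  w <- unclass(P)[offset + seq_len(J), , drop = FALSE]
  if (strand == "-") w <- revcomp_matrix(w)
  total <- 0
  for (j in seq_len(J)) {
    covered <- which(seed[, j] == 1)
    total <- total + min((1 - w[j, covered])^2)
  }
  sqrt(total / J)
}

#' Align a binding model to an IUPAC seed
#'
#' Scans all offsets on both strands, picks the window minimizing the
#' motif matching score, and returns the PSAM trimmed to the seed
#' length (reverse-complemented if the minus strand won).  This is a
#' pragmatic way of imposing a consistent binding frame on models fit
#' independently for different TFs.  Ties are broken deterministically:
#' smallest offset first, then the plus strand.
#'
#' @param P an `fc_psam` at least as long as the seed.
#' @param seed an `fc_seed` (or pattern string).
#' @param positions optional position labels for the trimmed frame
#'   (defaults to the seed symbols' 1-based indices).
#' @return The windowed `fc_psam`, with attributes `offset`, `strand`
#'   and `mms` recording the chosen frame.
#' @export
align_to_seed <- function(P, seed, positions = NULL) {
  if (!inherits(P, "fc_psam")) P <- psam(P)
  if (!inherits(seed, "fc_seed")) seed <- iupac_seed(seed)
  J <- ncol(seed)
  if (nrow(P) < J) abort("PSAM shorter than the seed")
  best <- NULL
  for (off in 0:(nrow(P) - J)) {
    for (strand in c("+", "-")) {
      s <- mms_score(P, seed, off, strand)
      if (is.null(best) || s < best$mms - 1e-12) {
        best <- list(offset = off, strand = strand, mms = s)
      }
    }
  }
  w <- unclass(P)[best$offset + seq_len(J), , drop = FALSE]
  if (best$strand == "-") w <- revcomp_matrix(w)
  rownames(w) <- positions %||% as.character(seq_len(J))
  out <- with_meta(w, P, "fc_psam")
  attr(out, "offset") <- best$offset
  attr(out, "strand") <- best$strand
  attr(out, "mms") <- best$mms
  out
}
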