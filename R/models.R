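#' Sequencing error model for the profile HMM
#'
#' Controls how tolerant the compiled model is to sequencing errors in the
#' fixed blocks of the architecture.
#'
#' @param base_error Per-base substitution probability assumed by match
#'   states: a match state for base `X` emits `X` with `1 - 3 * base_error`
#'   and each other base with `base_error`.
#' @param indel_open Probability of opening an insertion or deletion inside a
#'   fixed block. With `indel_open = 0` no insert/delete states are built.
#' @param indel_extend Self/extension probability of insert and delete
#'   states.
#' @return An `error_model` object.
#' @export
error_model <- function(base_error = 0.05, indel_open = 0.01,
                        indel_extend = 0.3) {
  stopifnot(base_error >= 0, base_error * 3 < 1,
            indel_open >= 0, indel_open < 0.5,
            indel_extend >= 0, indel_extend < 1)
  structure(list(base_error = base_error, indel_open = indel_open,
                 indel_extend = indel_extend), class = "error_model")
}

#' Zero-order background (null) model of nucleotide frequencies
#'
#' @param freqs Named numeric vector of A,C,G,T frequencies summing to 1.
#' @return A `background_model` object.
#' @export
background_model <- function(freqs = c(A = 0.25, C = 0.25, G = 0.25,
                                       T = 0.25)) {
  stopifnot(length(freqs) == 4L, all(freqs >= 0))
  if (abs(sum(freqs) - 1) > 1e-9) stop("background frequencies must sum to 1",
                                       call. = FALSE)
  if (is.null(names(freqs))) names(freqs) <- c("A", "C", "G", "T")
  freqs <- freqs[c("A", "C", "G", "T")]
  structure(list(freqs = freqs), class = "background_model")
}

#' Estimate background frequencies from a set of reads
#'
#' Counts A,C,G,T over at most `max_reads` reads (the default mirrors the
#' pipeline's use of the first 100,000 input reads); falls back to the
#' uniform model if no countable bases are present.
#'
#' @param seqs Character vector of nucleotide sequences.
#' @param max_reads Maximum number of reads used for the estimate.
#' @return A [background_model()].
#' @export
estimate_background <- function(seqs, max_reads = 100000L) {
  seqs <- utils::head(seqs, max_reads)
  if (length(seqs) == 0L) return(background_model())
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  tab <- table(strsplit(paste(seqs, collapse = ""), "")[[1L]])
  for (b in names(counts)) if (b %in% names(tab)) counts[b] <- tab[[b]]
  if (sum(counts) == 0) return(background_model())
  background_model(counts / sum(counts))
}

#' Zero-order background log-probability of a read
#'
#' Returns `sum(log(freqs[x_i]))`. An `N` scores as the background model's
#' maximum base frequency so that ambiguous bases are score-neutral between
#' the architecture model and the null.
#'
#' @param x Nucleotide string over `A,C,G,T,N`.
#' @param bg A [background_model()].
#' @return Log-probability (may be `-Inf` when a base has zero frequency).
#' @export
background_score <- function(x, bg = background_model()) {
  codes <- seq_to_int(x)
  lf <- log(bg$freqs)
  ln <- log(max(bg$freqs))
  sum(ifelse(codes == 4L, ln, lf[codes + 1L]))
}

# A,C,G,T,N -> 0..4 (input validation lives here)
seq_to_int <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  chars <- strsplit(toupper(x), "")[[1L]]
  codes <- match(chars, c("A", "C", "G", "T", "N")) - 1L
  if (anyNA(codes)) {
    stop("sequence contains characters outside {A,C,G,T,N}: '",
         paste(unique(chars[is.na(codes)]), collapse = ""), "'",
         call. = FALSE)
  }
  codes
}

int_to_seq <- function(codes) {
  paste(c("A", "C", "G", "T", "N")[codes + 1L], collapse = "")
}
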