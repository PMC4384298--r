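revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(s)), "")[[1L]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Bit-parallel semi-global approximate search of a read in a reference
#'
#' Computes the minimal edit distance (mismatches + insertions + deletions)
#' of the full read against any substring of the reference using the Myers
#' bit-vector recurrence over 64-bit machine words, with the standard block
#' extension for reads longer than 64 nt. `N` in the read matches nothing.
#'
#' @param read Pattern string (the read).
#' @param reference Text string.
#' @param max_k Maximum tolerated edit distance.
#' @return A `contaminant_hit` list (`distance`, `end` — 0-based reference
#'   offset of the best alignment end) or `NULL` if no alignment with at
#'   most `max_k` errors exists.
#' @export
bitvector_edit_search <- function(read, reference, max_k) {
  stopifnot(nchar(read) >= 1L, nchar(reference) >= 1L, max_k >= 0)
  res <- myers_search_cpp(seq_to_int(read), seq_to_int(reference))
  if (res$distance > max_k) return(NULL)
  structure(list(distance = res$distance, end = res$end),
            class = "contaminant_hit")
}

#' Remove reads matching known contaminant references
#'
#' Each read is searched against every reference sequence on both strands
#' (via the read's reverse complement); a read is removed when its best hit
#' is within `max_k` edits and is attributed to that single best reference
#' (first reference wins on ties).
#'
#' @param reads Named character vector of read sequences (names = read ids).
#' @param references Named character vector of reference sequences, or a
#'   path to a FASTA file (optionally gzipped).
#' @param max_k Maximum edit distance for a hit.
#' @return List with `kept` and `removed` (subsets of `reads`), `hits`
#'   (data.frame: id, reference, distance, end), and per-reference `counts`.
#' @export
filter_contaminants <- function(reads, references, max_k = 3L) {
  if (is.character(references) && length(references) == 1L &&
      file.exists(references)) {
    fa <- Biostrings::readDNAStringSet(references)
    references <- as.character(fa)
  }
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  if (length(references) == 0L) {
    return(list(kept = reads, removed = reads[0],
                hits = data.frame(id = character(), reference = character(),
                                  distance = integer(), end = integer()),
                counts = stats::setNames(integer(0), character(0))))
  }
  if (is.null(names(references)))
    names(references) <- paste0("ref", seq_along(references))
  counts <- stats::setNames(integer(length(references)), names(references))
  hit_id <- character(); hit_ref <- character()
  hit_d <- integer(); hit_end <- integer()
  removed <- logical(length(reads))
  for (i in seq_along(reads)) {
    rd <- reads[[i]]
    rc <- revcomp(rd)
    best_d <- .Machine$integer.max; best_ref <- NA_character_; best_e <- NA_integer_
    for (j in seq_along(references)) {
      for (pat in c(rd, rc)) {
        res <- myers_search_cpp(seq_to_int(pat),
                                seq_to_int(references[[j]]))
        if (res$distance < best_d) {
          best_d <- res$distance
          best_ref <- names(references)[[j]]
          best_e <- res$end
        }
      }
    }
    if (best_d <= max_k) {
      removed[[i]] <- TRUE
      counts[[best_ref]] <- counts[[best_ref]] + 1L
      hit_id <- c(hit_id, names(reads)[[i]])
      hit_ref <- c(hit_ref, best_ref)
      hit_d <- c(hit_d, best_d)
      hit_end <- c(hit_end, best_e)
    }
  }
  list(kept = reads[!removed], removed = reads[removed],
       hits = data.frame(id = hit_id, reference = hit_ref,
                         distance = hit_d, end = hit_end,
                         stringsAsFactors = FALSE),
       counts = counts)
}

#' Trinucleotide low-complexity (DUST-style) score
#'
#' Over the first 64 nucleotides of the read (or the whole read if shorter)
#' all overlapping 3-mers are counted and the score is
#' `100 * sum(c_t * (c_t - 1) / 2) / (w - 3)` with `w` the window length and
#' `c_t` the count of 3-mer `t`. A 64-nt homopolymer scores 3100; a sequence
#' with all-distinct 3-mers scores 0; uniform random sequence stays far
#' below the default threshold. Bases beyond position 64 never change the
#' score.
#'
#' @param seq Read sequence.
#' @param threshold Flagging threshold (`flagged` iff `score > threshold`).
#' @param window Window length in nucleotides.
#' @return A `dust_result` list: `score`, `flagged`.
#' @export
dust_score <- function(seq, threshold = 100, window = 64L) {
  w <- min(nchar(seq), window)
  if (w <= 3L) {
    return(structure(list(score = 0, flagged = FALSE), class = "dust_result"))
  }
  s <- substr(seq, 1L, w)
  kmers <- substring(s, seq_len(w - 2L), seq_len(w - 2L) + 2L)
  cnt <- table(kmers)
  score <- 100 * sum(cnt * (cnt - 1) / 2) / (w - 3)
  structure(list(score = score, flagged = score > threshold),
            class = "dust_result")
}
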