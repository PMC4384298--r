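hamming <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

random_dna <- function(n, len, freqs = c(0.25, 0.25, 0.25, 0.25)) {
  vapply(rep_len(len, n), function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE, prob = freqs),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Generate a maximally dissimilar barcode set
#'
#' Greedy random search: candidate barcodes are drawn uniformly and kept
#' when their Hamming distance to every retained barcode is at least
#' `min_distance`. Deterministic given the seed; errors out when the
#' request cannot be met within the attempt budget (e.g. beyond the
#' sphere-packing capacity of the sequence space).
#'
#' @param n Number of barcodes.
#' @param length Barcode length in nucleotides.
#' @param min_distance Minimum pairwise Hamming distance.
#' @param seed Random seed (`NULL`: current RNG state).
#' @param max_attempts Attempt budget.
#' @return Character vector of `n` barcodes.
#' @export
generate_barcode_set <- function(n, length, min_distance, seed = NULL,
                                 max_attempts = 10000L * n) {
  stopifnot(n >= 1, length >= 1, min_distance >= 0, min_distance <= length)
  with_seed(seed, {
    kept <- character()
    attempts <- 0L
    while (length(kept) < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      cand <- random_dna(1L, length)
      if (all(vapply(kept, hamming, 0L, cand) >= min_distance)) {
        kept <- c(kept, cand)
      }
    }
    if (length(kept) < n) {
      stop("could not find ", n, " barcodes of length ", length,
           " with pairwise distance >= ", min_distance, " in ",
           max_attempts, " attempts", call. = FALSE)
    }
    kept
  })
}

apply_substitutions <- function(seq, rate) {
  if (rate <= 0 || !nzchar(seq)) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(bases, b), 1L)
    }, "", USE.NAMES = FALSE)
  }
  paste(chars, collapse = "")
}

apply_indels <- function(seq, rate) {
  if (rate <= 0 || !nzchar(seq)) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  out <- character(0)
  for (ch in chars) {
    u <- stats::runif(1)
    if (u < rate / 2) next                       # deletion
    if (u < rate) out <- c(out, sample(c("A", "C", "G", "T"), 1L))  # insertion
    out <- c(out, ch)
  }
  paste(out, collapse = "")
}

#' Simulate a benchmark dataset with known ground truth
#'
#' `n_true` reads are rendered from the architecture (uniformly sampled
#' barcode alternative, random fingerprint, random read body of
#' `read_length` nt, full partial-adapter sequences) with per-base
#' substitutions at `error_rate` and optional indels at `indel_rate`;
#' errors are applied per block so block boundaries in the truth table stay
#' exact. `n_random` uniform i.i.d. decoy reads of matching lengths are
#' appended. Deterministic given the seed.
#'
#' @param arch A `read_architecture`; its barcode segment alternatives are
#'   the sample barcodes.
#' @param error_rate Per-base substitution probability in `[0, 0.5)`.
#' @param n_true,n_random Read counts of the two classes.
#' @param read_length Length of the random read body.
#' @param indel_rate Per-base indel probability (default 0: substitutions
#'   only).
#' @param seed Random seed.
#' @return A `simulated_dataset`: `records` (data.frame id, seq, qual) and
#'   `truth` (data.frame id, origin, barcode index & sequence, umi,
#'   read_start, read_end 0-based half-open).
#' @export
simulate_dataset <- function(arch, error_rate = 0, n_true = 90000L,
                             n_random = 10000L, read_length = 30L,
                             indel_rate = 0, seed = NULL) {
  stopifnot(error_rate >= 0, error_rate < 0.5, n_true >= 0, n_random >= 0)
  kinds <- arch_kinds(arch)
  barcode_seg <- which(kinds == "BARCODE")[1]
  with_seed(seed, {
    ids <- sprintf("read%06d", seq_len(n_true + n_random))
    seqs <- character(n_true + n_random)
    origin <- rep(c("true", "random"), c(n_true, n_random))
    bc_index <- rep(NA_integer_, n_true + n_random)
    bc_seq <- rep(NA_character_, n_true + n_random)
    umi <- rep(NA_character_, n_true + n_random)
    read_start <- rep(NA_integer_, n_true + n_random)
    read_end <- rep(NA_integer_, n_true + n_random)

    for (i in seq_len(n_true)) {
      parts <- character(length(arch$segments))
      umi_parts <- character(0)
      for (k in seq_along(arch$segments)) {
        seg <- arch$segments[[k]]
        block <- switch(seg$kind,
          BARCODE = {
            bi <- sample.int(length(seg$sequences), 1L)
            if (!is.na(barcode_seg) && k == barcode_seg) {
              bc_index[[i]] <- bi
              bc_seq[[i]] <- seg$sequences[[bi]]
            }
            seg$sequences[[bi]]
          },
          FINGERPRINT = {
            u <- random_dna(1L, seg$length)
            umi_parts <- c(umi_parts, u)
            u
          },
          SPACER = seg$sequences[[1L]],
          PARTIAL = seg$sequences[[1L]],
          READ = random_dna(1L, read_length))
        block <- apply_substitutions(block, error_rate)
        if (indel_rate > 0) block <- apply_indels(block, indel_rate)
        parts[[k]] <- block
      }
      umi[[i]] <- paste(umi_parts, collapse = "")
      lens <- nchar(parts)
      read_k <- which(kinds == "READ")
      read_start[[i]] <- sum(lens[seq_len(read_k - 1L)])
      read_end[[i]] <- read_start[[i]] + lens[[read_k]]
      seqs[[i]] <- paste(parts, collapse = "")
    }
    true_lens <- nchar(seqs[seq_len(n_true)])
    if (n_random > 0L) {
      rl <- if (n_true > 0L) sample(true_lens, n_random, replace = TRUE)
            else rep(read_length + arch_fixed_length(arch), n_random)
      seqs[n_true + seq_len(n_random)] <- random_dna(n_random, rl)
    }
    structure(list(
      records = data.frame(id = ids, seq = seqs,
                           qual = strrep("I", nchar(seqs)),
                           stringsAsFactors = FALSE),
      truth = data.frame(id = ids, origin = origin, barcode = bc_index,
                         barcode_seq = bc_seq, umi = umi,
                         read_start = read_start, read_end = read_end,
                         stringsAsFactors = FALSE),
      config = list(arch = arch, error_rate = error_rate,
                    indel_rate = indel_rate, n_true = n_true,
                    n_random = n_random, read_length = read_length,
                    seed = seed)),
      class = "simulated_dataset")
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("simulated_dataset:", x$config$n_true, "architecture reads +",
      x$config$n_random, "random reads, error rate", x$config$error_rate,
      "\n")
  invisible(x)
}

#' Recall and precision of an extraction run against the simulation truth
#'
#' A read counts as correctly assigned when it was accepted, originates
#' from the architecture, and its barcode call equals the planted barcode
#' (for barcode-free architectures, any accepted architecture read).
#' Recall divides by the number of architecture reads; precision by the
#' number of accepted-and-assigned reads (reported as 1 when nothing was
#' assigned: no assignments, no errors). Accepted decoy reads are the false
#' positives; accepted architecture reads with the wrong barcode are the
#' misassignments.
#'
#' @param labeled List of `labeled_read` objects (or the data.frame from
#'   [extract_reads()]).
#' @param truth Truth table from [simulate_dataset()].
#' @return An `eval_result`: `recall`, `precision`, `misassigned`,
#'   `false_positives`, `n_true`, `n_assigned`, `n_correct`.
#' @export
evaluate_extraction <- function(labeled, truth) {
  if (is.data.frame(labeled)) {
    df <- labeled
  } else {
    df <- data.frame(
      id = vapply(labeled, `[[`, "", "source"),
      accepted = vapply(labeled, `[[`, TRUE, "accepted"),
      barcode = vapply(labeled, function(l)
        if (is.null(l$barcode) || is.na(l$barcode)) NA_character_
        else l$barcode, ""),
      stringsAsFactors = FALSE)
  }
  m <- match(df$id, truth$id)
  stopifnot(!anyNA(m))
  tr <- truth[m, ]
  has_bc <- any(!is.na(tr$barcode_seq))
  correct <- df$accepted & tr$origin == "true" &
    (if (has_bc) !is.na(df$barcode) & df$barcode == tr$barcode_seq else TRUE)
  assigned <- df$accepted
  n_true <- sum(truth$origin == "true")
  n_correct <- sum(correct)
  n_assigned <- sum(assigned)
  structure(list(
    recall = if (n_true > 0) n_correct / n_true else 1,
    precision = if (n_assigned > 0) n_correct / n_assigned else 1,
    misassigned = sum(assigned & tr$origin == "true" & !correct),
    false_positives = sum(assigned & tr$origin == "random"),
    n_true = n_true, n_assigned = n_assigned, n_correct = n_correct),
    class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "eval_result: recall %.4f, precision %.4f (%d/%d correct; %d misassigned, %d false positives)\n",
    x$recall, x$precision, x$n_correct, x$n_assigned, x$misassigned,
    x$false_positives))
  invisible(x)
}
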