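#' Per-position posterior segment-label probabilities
#'
#' For each read position and each architecture segment, sums the posterior
#' probability `f * b / P(x|M)` over all emitting states belonging to that
#' segment. States of a barcode segment's competing background chain are
#' reported in their own pseudo-label column (named `background.seg<k>`).
#' Rows sum to 1 up to numerical precision.
#'
#' @param m A `scoring_matrices` object from [hmm_backward()].
#' @param hmm The `profile_hmm` the matrices were computed with.
#' @return Numeric matrix, read positions x labels.
#' @export
posterior_labels <- function(m, hmm) {
  if (is.null(m$b)) stop("posterior_labels needs backward matrices; ",
                         "use hmm_backward()", call. = FALSE)
  if (nrow(m$f) != hmm$n_states)
    stop("scoring matrices do not match the model", call. = FALSE)
  n_seg <- length(hmm$segments)
  label <- ifelse(hmm$silent, 0L, hmm$seg)
  cols <- paste0("seg", seq_len(n_seg))
  extra <- 0L
  for (info in hmm$barcode_info) {
    bg_chain <- info$chains$chain[info$chains$label == "background"]
    if (length(bg_chain)) {
      extra <- extra + 1L
      sel <- !hmm$silent & hmm$seg == info$seg & hmm$chain == bg_chain
      label[sel] <- n_seg + extra
      cols <- c(cols, paste0("background.seg", info$seg))
    }
  }
  post <- hmm_posterior_label_cpp(m$f, m$b, label, n_seg + extra, m$logPxM)
  colnames(post) <- cols
  attr(post, "background_of") <- if (extra > 0L)
    vapply(hmm$barcode_info, `[[`, 0L, "seg") else integer()
  post
}

#' Optimal-accuracy segment labeling of a read
#'
#' Dynamic program over (position, segment) that maximizes the summed
#' posterior label probability of the chosen labels, under the constraint
#' that labels traverse the architecture monotonically (each segment is one
#' contiguous, possibly empty, block in declared order). The posterior
#' columns act as a substitution matrix; skipping a segment other than a
#' partial adapter incurs a large fixed penalty so that mandatory blocks are
#' only empty when the posterior leaves them essentially no mass. Background
#' pseudo-label columns are folded into their barcode segment before
#' decoding (barcode identity is called from the entry posteriors, not from
#' the labeling). Ties are broken towards the earliest possible segment
#' transition.
#'
#' @param post Matrix from [posterior_labels()].
#' @param arch The `read_architecture` the model was compiled from.
#' @param skip_penalty Score penalty for leaving a mandatory segment empty.
#' @return Integer vector of segment indices, one per read position, with
#'   the achieved total posterior as attribute `score`.
#' @export
optimal_accuracy_decode <- function(post, arch, skip_penalty = 1000) {
  K <- length(arch$segments)
  stopifnot(ncol(post) >= K)
  bg_of <- attr(post, "background_of")
  mat <- post[, seq_len(K), drop = FALSE]
  if (length(bg_of)) {
    for (j in seq_along(bg_of)) {
      mat[, bg_of[[j]]] <- mat[, bg_of[[j]]] + post[, K + j]
    }
  }
  L <- nrow(mat)
  kinds <- arch_kinds(arch)
  pen <- ifelse(kinds == "PARTIAL", 0, skip_penalty)
  cumpen <- cumsum(pen)                     # cost of skipping segments 1..k
  cum0 <- c(0, cumpen)                      # cum0[k] = cost of skipping 1..k-1

  score_prev <- mat[1L, ] - cum0[seq_len(K)]
  ptr <- matrix(0L, L, K)
  if (L > 1L) {
    for (i in 2:L) {
      g <- score_prev + cumpen               # advance helper
      adv_val <- rep(-Inf, K); adv_arg <- integer(K)
      best <- -Inf; barg <- 0L
      for (k in seq_len(K)) {
        if (g[[k]] >= best) { best <- g[[k]]; barg <- k }
        adv_val[[k]] <- best; adv_arg[[k]] <- barg
      }
      sc <- numeric(K)
      for (k in seq_len(K)) {
        stay <- score_prev[[k]]
        adv <- if (k > 1L) adv_val[[k - 1L]] - cumpen[[k - 1L]] else -Inf
        if (stay >= adv) { sc[[k]] <- stay; ptr[i, k] <- k }
        else { sc[[k]] <- adv; ptr[i, k] <- adv_arg[[k - 1L]] }
      }
      score_prev <- sc + mat[i, ]
    }
  }
  final <- score_prev - (cumpen[[K]] - cumpen)  # skip segments k+1..K
  k <- max(which(final == max(final)))          # tie: end in latest segment
  labels <- integer(L)
  labels[[L]] <- k
  if (L > 1L) {
    for (i in L:2) {
      k <- ptr[i, k]
      labels[[i - 1L]] <- k
    }
  }
  attr(labels, "score") <- max(final)
  labels
}

#' Encode a fingerprint (UMI) as a unique integer
#'
#' Big-endian base-4 with `A=0, C=1, G=2, T=3`; e.g. `"ACGT"` encodes as 27.
#' Injective for a fixed length; [decode_umi()] inverts it.
#'
#' @param umi_seq Fingerprint string over `A,C,G,T`.
#' @return Non-negative number (exact for fingerprints up to 26 nt).
#' @export
encode_umi <- function(umi_seq) {
  codes <- seq_to_int(umi_seq)
  if (any(codes > 3L)) stop("ambiguous UMI: N in fingerprint", call. = FALSE)
  sum(codes * 4^(rev(seq_along(codes)) - 1))
}

#' Decode a fingerprint integer back to its sequence
#'
#' @param code Number from [encode_umi()].
#' @param length Fingerprint length in nucleotides.
#' @return Fingerprint string.
#' @export
decode_umi <- function(code, length) {
  digits <- integer(length)
  for (i in rev(seq_len(length))) {
    digits[[i]] <- code %% 4
    code <- code %/% 4
  }
  paste(c("A", "C", "G", "T")[digits + 1L], collapse = "")
}

#' Cut the labeled read into its mappable insert, barcode call and UMI
#'
#' Applies the segment labeling: positions labeled as the read segment
#' become the extracted read (with the matching quality substring),
#' fingerprint-labeled positions are concatenated into the UMI. The barcode
#' call is the [barcode_confidence()] winner. The read is rejected (with a
#' reason) when the extraction quality falls below the threshold, when the
#' background chain wins the barcode, when the decoded fingerprint length
#' differs from the declared total, when the fingerprint contains `N`, or
#' when no position is labeled as the read.
#'
#' @param record List or one-row data.frame with `id`, `seq`, `qual`.
#' @param labels Labeling from [optimal_accuracy_decode()].
#' @param arch The `read_architecture`.
#' @param score A `score_result` from [score_read()].
#' @param threshold Minimum extraction quality `q` for acceptance.
#' @return A `labeled_read`: `source`, `labels`, `read_seq`, `read_qual`,
#'   `barcode`, `umi_seq`, `umi_code`, `q`, `accepted`, `reason`.
#' @export
extract_read <- function(record, labels, arch, score, threshold = 0) {
  kinds <- arch_kinds(arch)
  chars <- strsplit(record$seq, "")[[1L]]
  qchars <- strsplit(record$qual, "")[[1L]]
  stopifnot(length(labels) == length(chars))

  read_idx <- which(kinds == "READ")
  read_pos <- which(labels == read_idx)
  fp_pos <- which(labels %in% which(kinds == "FINGERPRINT"))
  read_seq <- paste(chars[read_pos], collapse = "")
  read_qual <- paste(qchars[read_pos], collapse = "")
  umi_seq <- paste(chars[fp_pos], collapse = "")

  accepted <- TRUE
  reason <- NA_character_
  if (score$q < threshold) {
    accepted <- FALSE; reason <- "threshold"
  } else if (identical(score$best_barcode, "background")) {
    accepted <- FALSE; reason <- "ambiguous barcode"
  } else if (nchar(umi_seq) != arch$total_fingerprint_length) {
    accepted <- FALSE; reason <- "fingerprint length"
  } else if (grepl("N", umi_seq, fixed = TRUE)) {
    accepted <- FALSE; reason <- "ambiguous UMI"
  } else if (length(read_pos) == 0L) {
    accepted <- FALSE; reason <- "empty read"
  }
  umi_code <- if (accepted && nchar(umi_seq) > 0L) encode_umi(umi_seq)
              else NA_real_
  structure(list(source = record$id, labels = labels,
                 read_seq = read_seq, read_qual = read_qual,
                 barcode = score$best_barcode,
                 umi_seq = umi_seq, umi_code = umi_code,
                 q = score$q, accepted = accepted, reason = reason),
            class = "labeled_read")
}

#' @export
print.labeled_read <- function(x, ...) {
  cat("labeled_read", x$source,
      if (x$accepted) "[accepted]" else paste0("[rejected: ", x$reason, "]"),
      "\n  read:", x$read_seq,
      "\n  barcode:", if (is.na(x$barcode)) "<none>" else x$barcode,
      " umi:", if (nzchar(x$umi_seq)) x$umi_seq else "<none>",
      " q:", sprintf("%.2f", x$q), "\n")
  invisible(x)
}
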