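logsumexp2 <- function(a, b) {
  if (a == -Inf) return(b)
  if (b == -Inf) return(a)
  m <- max(a, b)
  m + log1p(exp(min(a, b) - m))
}

hmm_cpp_args <- function(hmm) {
  list(n_states = hmm$n_states, silent = hmm$silent, emis = hmm$emis,
       edge_from = hmm$edges$from - 1L, edge_to = hmm$edges$to - 1L,
       edge_logp = hmm$edges$logp, start = hmm$start - 1L,
       end = hmm$end - 1L)
}

#' Forward algorithm over a compiled profile HMM
#'
#' Fills the forward log-probability matrix `f` (states x read positions,
#' position 0 = nothing emitted) by log-sum-exp dynamic programming; silent
#' states are resolved by an ordered within-position sweep. `logPxM` is the
#' total probability of the read summed over all state paths.
#'
#' @param hmm A `profile_hmm` from [assemble_global_hmm()] or
#'   [build_segment_hmm()].
#' @param x Nucleotide string over `A,C,G,T,N`.
#' @return A `scoring_matrices` object with elements `f`, `logPxM` and the
#'   encoded read `x_codes` (and, from [hmm_backward()], `b`).
#' @export
hmm_forward <- function(hmm, x) {
  codes <- seq_to_int(x)
  a <- hmm_cpp_args(hmm)
  res <- hmm_fwdbwd_cpp(a$n_states, a$silent, a$emis, a$edge_from, a$edge_to,
                        a$edge_logp, a$start, a$end, codes, FALSE)
  structure(list(f = res$f, logPxM = res$logPxM, x_codes = codes),
            class = "scoring_matrices")
}

#' Forward and backward matrices over a compiled profile HMM
#'
#' As [hmm_forward()], additionally filling the backward matrix `b`. The
#' totals of the two recursions agree to numerical precision; a discrepancy
#' beyond `1e-9` in log space raises an error.
#'
#' @inheritParams hmm_forward
#' @return A `scoring_matrices` object with `f`, `b`, `logPxM`, `x_codes`.
#' @export
hmm_backward <- function(hmm, x) {
  codes <- seq_to_int(x)
  a <- hmm_cpp_args(hmm)
  res <- hmm_fwdbwd_cpp(a$n_states, a$silent, a$emis, a$edge_from, a$edge_to,
                        a$edge_logp, a$start, a$end, codes, TRUE)
  if (is.finite(res$logPxM) || is.finite(res$logPxM_bwd)) {
    if (abs(res$logPxM - res$logPxM_bwd) > 1e-9 *
        max(1, abs(res$logPxM))) {
      stop("internal error: forward and backward totals disagree (",
           res$logPxM, " vs ", res$logPxM_bwd, ")")
    }
  }
  structure(list(f = res$f, b = res$b, logPxM = res$logPxM,
                 logPxM_bwd = res$logPxM_bwd, x_codes = codes),
            class = "scoring_matrices")
}

#' Posterior confidence of the best barcode call
#'
#' For every chain `j` of a barcode segment (the declared barcodes plus the
#' competing background chain) the summed posterior mass of entering that
#' chain is computed from the forward value at the segment's entry silent
#' state, the entry transition, the first emission and the backward value,
#' accumulated over all read positions and divided by the total probability
#' of the read. The masses sum to 1 across chains. `V` is the largest mass
#' and `best_barcode` the corresponding barcode sequence, or `"background"`
#' when the background chain wins (the read is then considered too ambiguous
#' to assign). Architectures without barcode segments get `V = 1`.
#'
#' With several barcode segments the per-segment maxima are multiplied and
#' the winning labels joined with `"+"` (any segment won by its background
#' chain makes the overall call `"background"`).
#'
#' Ties are broken to the lowest chain index; a tie involving the background
#' chain resolves to background.
#'
#' @param m A `scoring_matrices` object from [hmm_backward()].
#' @param hmm The `profile_hmm` the matrices were computed with.
#' @return List with `V`, `best_barcode`, and `per_segment` (a list of named
#'   per-chain posterior masses).
#' @export
barcode_confidence <- function(m, hmm) {
  if (is.null(m$b)) stop("barcode_confidence needs backward matrices; ",
                         "use hmm_backward()", call. = FALSE)
  if (nrow(m$f) != hmm$n_states)
    stop("scoring matrices do not match the model", call. = FALSE)
  if (length(hmm$barcode_info) == 0L) {
    return(list(V = 1, best_barcode = NA_character_, per_segment = list()))
  }
  L <- length(m$x_codes)
  per_segment <- list()
  V <- 1
  labels_won <- character()
  any_bg <- FALSE
  for (info in hmm$barcode_info) {
    s <- info$entry
    eidx <- which(hmm$edges$from == s)
    mass <- numeric(nrow(info$chains))
    for (e in eidx) {
      t <- hmm$edges$to[[e]]
      ch <- hmm$chain[[t]]
      if (ch == 0L) next
      lp <- hmm$edges$logp[[e]]
      if (hmm$silent[[t]]) {
        ii <- seq_len(L + 1L)
        terms <- m$f[s, ii] + lp + m$b[t, ii]
      } else {
        ii <- seq_len(L)
        terms <- m$f[s, ii] + lp + hmm$emis[t, m$x_codes + 1L] +
          m$b[t, ii + 1L]
      }
      terms <- terms - m$logPxM
      mass[[ch]] <- mass[[ch]] + sum(exp(terms[is.finite(terms)]))
    }
    names(mass) <- info$chains$label
    per_segment[[length(per_segment) + 1L]] <- mass
    best <- which(mass == max(mass))
    bg_chain <- which(info$chains$label == "background")
    win <- if (length(bg_chain) && bg_chain %in% best) bg_chain else min(best)
    V <- V * mass[[win]]
    if (info$chains$label[[win]] == "background") any_bg <- TRUE
    labels_won <- c(labels_won, info$chains$label[[win]])
  }
  list(V = min(V, 1),
       best_barcode = if (any_bg) "background" else
         paste(labels_won, collapse = "+"),
       per_segment = per_segment)
}

#' Phred-scaled extraction quality
#'
#' The probability that the extraction (architecture match plus barcode
#' call) is wrong is `p_error = 1 - V * P(x|M) / (P(x|M) + P(x|R))`,
#' evaluated stably in log space. The phred quality is
#' `q = -10 * log10(p_error)`, capped at 60 (in particular when `p_error`
#' underflows to zero), mirroring mapping-quality conventions.
#'
#' @param logPxM Log-probability of the read under the architecture model.
#' @param logPxR Log-probability under the zero-order background model.
#' @param V Barcode confidence from [barcode_confidence()].
#' @param q_cap Phred cap.
#' @return List with `p_error` and `q`.
#' @export
extraction_quality <- function(logPxM, logPxR, V = 1, q_cap = 60) {
  if (logPxM == -Inf && logPxR == -Inf) {
    stop("both model and background probabilities are zero", call. = FALSE)
  }
  stopifnot(V >= 0, V <= 1)
  den <- logsumexp2(logPxM, logPxR)
  frac <- if (V == 0) 0 else exp(logPxM + log(V) - den)
  p_error <- min(max(1 - frac, 0), 1)
  q <- if (p_error <= 0) q_cap else min(q_cap, -10 * log10(p_error))
  list(p_error = p_error, q = q)
}

#' Score one read against a compiled architecture model
#'
#' Runs the forward and backward algorithms, the zero-order background
#' model, the barcode-confidence computation and the extraction-quality
#' conversion for a single read.
#'
#' @inheritParams hmm_forward
#' @param keep_matrices Keep the forward/backward matrices in the result
#'   (needed for posterior decoding).
#' @return A `score_result`: `logPxM`, `logPxR`, `V`, `best_barcode`,
#'   `p_error`, `q`, and (optionally) `matrices`.
#' @export
score_read <- function(hmm, x, keep_matrices = TRUE) {
  m <- hmm_backward(hmm, x)
  logPxR <- background_score(x, hmm$bg)
  bc <- barcode_confidence(m, hmm)
  eq <- extraction_quality(m$logPxM, logPxR, bc$V)
  structure(list(logPxM = m$logPxM, logPxR = logPxR, V = bc$V,
                 best_barcode = bc$best_barcode,
                 per_segment = bc$per_segment,
                 p_error = eq$p_error, q = eq$q,
                 matrices = if (keep_matrices) m else NULL),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf(
    "score_result: log P(x|M) = %.4f, log P(x|R) = %.4f, V = %.4f, q = %.2f, barcode = %s\n",
    x$logPxM, x$logPxR, x$V, x$q,
    if (is.na(x$best_barcode)) "<none>" else x$best_barcode))
  invisible(x)
}
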