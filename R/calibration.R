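# run expr with a temporarily fixed RNG state; NULL seed = use current RNG
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
  })
  set.seed(seed)
  force(expr)
}

#' Emit (simulate) reads from the architecture model
#'
#' Samples reads by walking the compiled HMM from its start to its end
#' state, drawing transitions and emissions. When `read_length` is given,
#' the read segment emits exactly that many nucleotides instead of following
#' its geometric length prior, so emitted reads mimic an instrument's read
#' layout; the remaining blocks are sampled from the model as-is (including
#' any background barcode chain).
#'
#' @param hmm A `profile_hmm`.
#' @param n Number of reads.
#' @param seed Random seed (`NULL`: use the current RNG state).
#' @param read_length Fixed read-segment (insert) length, or `NULL`.
#' @param max_len Hard cap on emitted length.
#' @return Character vector of `n` sequences.
#' @export
emit_from_model <- function(hmm, n, seed = NULL, read_length = NULL,
                            max_len = 100000L) {
  stopifnot(n >= 1)
  a <- hmm_cpp_args(hmm)
  rm_ <- if (is.na(hmm$read_match)) -1L else hmm$read_match - 1L
  ri_ <- if (is.na(hmm$read_insert)) -1L else hmm$read_insert - 1L
  rl <- if (is.null(read_length)) 0L else as.integer(read_length)
  with_seed(seed,
    hmm_emit_cpp(a$n_states, a$silent, a$emis, a$edge_from, a$edge_to,
                 a$edge_logp, a$start, a$end, as.integer(n),
                 rm_, ri_, rl, as.integer(max_len)))
}

#' Emit i.i.d. reads from the zero-order background model
#'
#' @param bg A [background_model()].
#' @param n Number of reads.
#' @param seed Random seed (`NULL`: use the current RNG state).
#' @param length Read length(s), recycled to `n`.
#' @return Character vector of `n` sequences.
#' @export
emit_random <- function(bg, n, seed = NULL, length = 50L) {
  stopifnot(n >= 1, all(length >= 1))
  len <- rep_len(as.integer(length), n)
  with_seed(seed, {
    vapply(len, function(l) {
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE,
                   prob = bg$freqs), collapse = "")
    }, "")
  })
}

#' Choose the extraction-quality threshold maximizing sensitivity plus
#' specificity
#'
#' Candidate cutoffs are the midpoints between adjacent distinct values of
#' the pooled scores, plus one candidate below and one above all scores.
#' Sensitivity is the fraction of model scores at or above the cutoff,
#' specificity the fraction of random scores below it. The lowest cutoff
#' attaining the maximal sum is returned.
#'
#' @param scores_model Extraction qualities of reads emitted from the model.
#' @param scores_random Extraction qualities of background reads.
#' @return A `threshold_result`: `threshold`, `sensitivity`, `specificity`,
#'   `n_model`, `n_random`.
#' @export
select_threshold <- function(scores_model, scores_random) {
  if (length(scores_model) == 0L || length(scores_random) == 0L) {
    stop("both score lists must be non-empty", call. = FALSE)
  }
  u <- sort(unique(c(scores_model, scores_random)))
  cand <- c(u[[1L]] - 1,
            if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2,
            u[[length(u)]] + 1)
  sm <- sort(scores_model); sr <- sort(scores_random)
  sens <- 1 - findInterval(cand, sm) / length(sm)
  spec <- findInterval(cand, sr) / length(sr)
  tot <- sens + spec
  i <- which(tot == max(tot))[[1L]]   # candidates ascend: lowest cutoff wins
  structure(list(threshold = cand[[i]], sensitivity = sens[[i]],
                 specificity = spec[[i]],
                 n_model = length(scores_model),
                 n_random = length(scores_random)),
            class = "threshold_result")
}

#' Calibrate the acceptance threshold for an architecture
#'
#' Emits `n` reads from the architecture model and `n` length-matched reads
#' from the background model, scores both sets, and applies
#' [select_threshold()]. Thresholds are architecture-specific because the
#' overlap between the model and background score distributions depends on
#' how much fixed sequence the architecture contains.
#'
#' @param hmm A `profile_hmm`.
#' @param n Reads emitted per class.
#' @param seed Random seed for the emission.
#' @param read_length Read-segment length used for the emitted model reads
#'   (set it to the insert length of the data being processed).
#' @return A `threshold_result` with the extra fields `seed` and `q_model` /
#'   `q_random` score vectors.
#' @export
calibrate_threshold <- function(hmm, n = 10000L, seed = 42L,
                                read_length = 30L) {
  with_seed(seed, {
    model_reads <- emit_from_model(hmm, n, read_length = read_length)
    random_reads <- emit_random(hmm$bg, n, length = nchar(model_reads))
    q_model <- vapply(model_reads, function(x) score_read(
      hmm, x, keep_matrices = FALSE)$q, 0, USE.NAMES = FALSE)
    q_random <- vapply(random_reads, function(x) score_read(
      hmm, x, keep_matrices = FALSE)$q, 0, USE.NAMES = FALSE)
    res <- select_threshold(q_model, q_random)
    res$seed <- seed
    res$q_model <- q_model
    res$q_random <- q_random
    res
  })
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "threshold_result: q >= %.3f (sensitivity %.3f, specificity %.3f; %d model + %d random reads)\n",
    x$threshold, x$sensitivity, x$specificity, x$n_model, x$n_random))
  invisible(x)
}
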