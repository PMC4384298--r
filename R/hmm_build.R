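# Compilation of a read architecture into a global profile HMM.
#
# State bookkeeping contract used by the C++ kernels: every transition whose
# target is non-emitting (silent connector or delete state) must go from a
# lower to a higher state id, so a single ordered sweep per read position
# resolves within-position dependencies. The builder below creates states in
# an order that guarantees this (segment entry silent -> chain states in
# column order -> segment exit silent) and new_hmm() asserts it.

new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$type <- character()    # "M", "I", "D", "S"
  env$seg <- integer()       # architecture segment id (0 for global ends)
  env$chain <- integer()     # alternative id within a barcode segment
  env$emis <- list()
  env$from <- integer(); env$to <- integer(); env$logp <- numeric()
  env
}

add_state <- function(bld, type, seg = 0L, chain = 0L, emis = NULL) {
  bld$type <- c(bld$type, type)
  bld$seg <- c(bld$seg, as.integer(seg))
  bld$chain <- c(bld$chain, as.integer(chain))
  bld$emis[[length(bld$type)]] <- if (is.null(emis)) rep(-Inf, 5) else emis
  length(bld$type)
}

add_edge <- function(bld, from, to, p) {
  if (p <= 0) return(invisible(NULL))
  bld$from <- c(bld$from, from)
  bld$to <- c(bld$to, to)
  bld$logp <- c(bld$logp, log(p))
  invisible(NULL)
}

# log emissions (A,C,G,T,N) of a match state for `base` (0..3).
# N in the input is emitted with the background frequency of the state's
# most likely base, keeping ambiguous bases score-neutral.
emis_match <- function(base, err, bg) {
  p <- rep(err$base_error, 4)
  p[base + 1L] <- 1 - 3 * err$base_error
  log(c(p, bg$freqs[[which.max(p)]]))
}

emis_background <- function(bg) {
  log(c(bg$freqs, max(bg$freqs)))
}

# one linear match/insert/delete chain between two silent states
add_chain <- function(bld, codes, err, bg, s_in, s_out_promise, p_in, seg,
                      chain = 0L, background_emission = FALSE,
                      partial = FALSE, p_skip = 0.1, p_exit = 0.1) {
  io <- err$indel_open
  ie <- err$indel_extend
  L <- length(codes)
  em <- function(j) {
    if (background_emission) emis_background(bg) else
      emis_match(codes[[j]], err, bg)
  }
  m <- integer(L); i_st <- integer(L + 1L); d <- integer(L)
  if (io > 0 && !partial)
    i_st[1L] <- add_state(bld, "I", seg, chain, emis_background(bg))
  for (j in seq_len(L)) {
    m[j] <- add_state(bld, "M", seg, chain, em(j))
    if (io > 0) {
      i_st[j + 1L] <- add_state(bld, "I", seg, chain, emis_background(bg))
      d[j] <- add_state(bld, "D", seg, chain)
    }
  }
  # entry
  if (partial) {
    for (j in seq_len(L)) add_edge(bld, s_in, m[j], p_in * (1 - p_skip) / L)
  } else if (io > 0) {
    add_edge(bld, s_in, m[1L], p_in * (1 - 2 * io))
    add_edge(bld, s_in, i_st[1L], p_in * io)
    add_edge(bld, s_in, d[1L], p_in * io)
    add_edge(bld, i_st[1L], i_st[1L], ie)
    add_edge(bld, i_st[1L], m[1L], 1 - ie)
  } else {
    add_edge(bld, s_in, m[1L], p_in)
  }
  px <- if (partial) p_exit else 0
  # internal transitions; exits to s_out are deferred until it exists
  deferred <- list()
  defer <- function(from, p) deferred[[length(deferred) + 1L]] <<- list(from, p)
  for (j in seq_len(L)) {
    last <- j == L
    if (partial && !last) defer(m[j], px)
    if (io > 0) {
      if (last) {
        add_edge(bld, m[j], i_st[j + 1L], io)
        defer(m[j], 1 - io)
        add_edge(bld, i_st[j + 1L], i_st[j + 1L], ie)
        defer(i_st[j + 1L], 1 - ie)
        defer(d[j], 1)
      } else {
        add_edge(bld, m[j], m[j + 1L], 1 - 2 * io - px)
        add_edge(bld, m[j], i_st[j + 1L], io)
        add_edge(bld, m[j], d[j + 1L], io)
        add_edge(bld, i_st[j + 1L], i_st[j + 1L], ie)
        add_edge(bld, i_st[j + 1L], m[j + 1L], 1 - ie)
        add_edge(bld, d[j], m[j + 1L], 1 - ie)
        add_edge(bld, d[j], d[j + 1L], ie)
      }
    } else {
      if (last) defer(m[j], 1) else add_edge(bld, m[j], m[j + 1L], 1 - px)
    }
  }
  list(first_match = m[1L], deferred = deferred)
}

# append one architecture segment between fresh entry/exit silent states
add_segment <- function(bld, seg_spec, err, bg, prev_exit,
                        with_background_chain, expected_read_length) {
  k <- seg_spec$index
  s_in <- add_state(bld, "S", k)
  if (!is.null(prev_exit)) add_edge(bld, prev_exit, s_in, 1)
  deferred <- list()
  info <- list(seg = k, entry = s_in, kind = seg_spec$kind)

  if (seg_spec$kind == "READ") {
    p_loop <- 1 - 1 / expected_read_length
    m <- add_state(bld, "M", k, 0L, emis_background(bg))
    i <- add_state(bld, "I", k, 0L, emis_background(bg))
    add_edge(bld, s_in, m, 1)
    add_edge(bld, m, i, p_loop)
    add_edge(bld, i, i, p_loop)
    deferred <- list(list(m, 1 - p_loop), list(i, 1 - p_loop))
    info$read_match <- m
    info$read_insert <- i
  } else if (seg_spec$kind == "BARCODE") {
    n_chain <- length(seg_spec$sequences) + as.integer(with_background_chain)
    p_in <- 1 / n_chain
    labels <- seg_spec$sequences
    for (j in seq_along(seg_spec$sequences)) {
      ch <- add_chain(bld, seq_to_int(seg_spec$sequences[[j]]), err, bg,
                      s_in, NULL, p_in, k, chain = j)
      deferred <- c(deferred, ch$deferred)
    }
    if (with_background_chain) {
      ch <- add_chain(bld, rep(0L, seg_spec$length), err, bg, s_in, NULL,
                      p_in, k, chain = n_chain, background_emission = TRUE)
      deferred <- c(deferred, ch$deferred)
      labels <- c(labels, "background")
    }
    info$chains <- data.frame(chain = seq_len(length(labels)),
                              label = labels, stringsAsFactors = FALSE)
  } else if (seg_spec$kind == "FINGERPRINT") {
    ch <- add_chain(bld, rep(0L, seg_spec$length), err, bg, s_in, NULL, 1,
                    k, background_emission = TRUE)
    deferred <- ch$deferred
  } else if (seg_spec$kind == "SPACER") {
    ch <- add_chain(bld, seq_to_int(seg_spec$sequences[[1L]]), err, bg,
                    s_in, NULL, 1, k)
    deferred <- ch$deferred
  } else if (seg_spec$kind == "PARTIAL") {
    p_skip <- 0.1
    ch <- add_chain(bld, seq_to_int(seg_spec$sequences[[1L]]), err, bg,
                    s_in, NULL, 1, k, partial = TRUE, p_skip = p_skip)
    deferred <- c(list(list(s_in, p_skip)), ch$deferred)
  }
  s_out <- add_state(bld, "S", k)
  for (dfr in deferred) add_edge(bld, dfr[[1L]], s_out, dfr[[2L]])
  info$exit <- s_out
  list(exit = s_out, info = info)
}

finalize_hmm <- function(bld, segments, barcode_info, read_match, read_insert,
                         err, bg, expected_read_length, arch = NULL) {
  n <- length(bld$type)
  emis <- do.call(rbind, bld$emis)
  hmm <- structure(list(
    n_states = n,
    type = bld$type,
    seg = bld$seg,
    chain = bld$chain,
    silent = bld$type %in% c("S", "D"),
    emis = emis,
    edges = data.frame(from = bld$from, to = bld$to, logp = bld$logp),
    start = 1L,
    end = n,
    segments = segments,
    barcode_info = barcode_info,
    read_match = read_match,
    read_insert = read_insert,
    err = err, bg = bg,
    expected_read_length = expected_read_length,
    arch = arch), class = "profile_hmm")
  validate_hmm(hmm)
  hmm
}

validate_hmm <- function(hmm) {
  out <- tapply(exp(hmm$edges$logp), hmm$edges$from, sum)
  has_out <- setdiff(seq_len(hmm$n_states), hmm$end)
  if (!all(as.integer(names(out)) %in% has_out) ||
      !setequal(as.integer(names(out)), has_out) ||
      any(abs(out - 1) > 1e-9)) {
    stop("internal error: outgoing transition probabilities do not sum to 1")
  }
  esum <- rowSums(exp(hmm$emis[, 1:4, drop = FALSE]))
  if (any(abs(esum[!hmm$silent] - 1) > 1e-9)) {
    stop("internal error: emission probabilities do not sum to 1")
  }
  sil_to <- hmm$silent[hmm$edges$to]
  if (any(hmm$edges$from[sil_to] >= hmm$edges$to[sil_to])) {
    stop("internal error: non-topological edge into a silent state")
  }
  invisible(hmm)
}

#' Compile a single architecture segment into a profile HMM fragment
#'
#' Builds the per-segment model between one silent start and one silent end
#' state: spacer and barcode alternatives become linear match-state chains
#' (parallel chains share the entry and exit silent states), fingerprints
#' emit background frequencies, the read segment is a single match column
#' with a self-looping insert state (geometric length prior), and partial
#' adapters allow entry at and exit after every match column as well as
#' skipping the block entirely. With `err$indel_open > 0` each chain also
#' carries insert and delete states.
#'
#' Mostly useful for inspection and testing; [assemble_global_hmm()] builds
#' the model actually used for scoring.
#'
#' @param seg A [parse_segment()] result.
#' @param err An [error_model()].
#' @param bg A [background_model()].
#' @param expected_read_length Mean of the geometric length prior of the
#'   read segment's insert loop.
#' @return A `profile_hmm` object.
#' @export
build_segment_hmm <- function(seg, err = error_model(),
                              bg = background_model(),
                              expected_read_length = 1000) {
  bld <- new_builder()
  start <- add_state(bld, "S", 0L)
  res <- add_segment(bld, seg, err, bg, start,
                     with_background_chain = FALSE,
                     expected_read_length = expected_read_length)
  end <- add_state(bld, "S", 0L)
  add_edge(bld, res$exit, end, 1)
  info <- res$info
  finalize_hmm(bld, segments = list(seg),
               barcode_info = if (seg$kind == "BARCODE") list(info) else list(),
               read_match = if (seg$kind == "READ") info$read_match else NA_integer_,
               read_insert = if (seg$kind == "READ") info$read_insert else NA_integer_,
               err = err, bg = bg,
               expected_read_length = expected_read_length)
}

#' Assemble the global profile HMM for a read architecture
#'
#' Segment models are concatenated through silent states in architecture
#' order, flanked by one global start and one global end silent state. Every
#' barcode segment additionally receives a competing background chain of the
#' same length whose emissions are the background frequencies; it captures
#' reads whose barcode is too ambiguous to assign, and winning it rejects
#' the read.
#'
#' @inheritParams build_segment_hmm
#' @param arch A [parse_architecture()] result.
#' @return A `profile_hmm` object.
#' @export
assemble_global_hmm <- function(arch, err = error_model(),
                                bg = background_model(),
                                expected_read_length = 1000) {
  bld <- new_builder()
  start <- add_state(bld, "S", 0L)
  prev <- start
  barcode_info <- list()
  read_match <- NA_integer_; read_insert <- NA_integer_
  for (seg in arch$segments) {
    res <- add_segment(bld, seg, err, bg, prev,
                       with_background_chain = seg$kind == "BARCODE",
                       expected_read_length = expected_read_length)
    prev <- res$exit
    if (seg$kind == "BARCODE") barcode_info <- c(barcode_info, list(res$info))
    if (seg$kind == "READ") {
      read_match <- res$info$read_match
      read_insert <- res$info$read_insert
    }
  }
  end <- add_state(bld, "S", 0L)
  add_edge(bld, prev, end, 1)
  finalize_hmm(bld, segments = arch$segments, barcode_info = barcode_info,
               read_match = read_match, read_insert = read_insert,
               err = err, bg = bg,
               expected_read_length = expected_read_length, arch = arch)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile HMM:", x$n_states, "states (",
      sum(!x$silent), "emitting ),", nrow(x$edges), "transitions,",
      length(x$segments), "segment(s)\n")
  invisible(x)
}
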