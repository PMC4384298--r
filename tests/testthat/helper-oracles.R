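# Independent oracles used across the suite. These deliberately avoid the
# package's dynamic-programming code paths: probabilities are accumulated by
# explicit path enumeration in linear space, edit distances by the classic
# quadratic recurrence, labelings by exhaustive search.

seq2int <- function(x) {
  match(strsplit(toupper(x), "")[[1L]], c("A", "C", "G", "T", "N")) - 1L
}

# Exhaustive enumeration of all state paths of a small HMM for read x.
# Returns the total path probability, per-(state, position) posterior mass,
# and the probability mass flowing through each chain of each barcode
# segment.
enum_paths <- function(hmm, x) {
  codes <- seq2int(x)
  L <- length(codes)
  by_from <- split(seq_len(nrow(hmm$edges)), hmm$edges$from)
  total <- 0
  state_pos <- matrix(0, hmm$n_states, L)
  chain_key <- paste(hmm$seg, hmm$chain)
  chain_mass <- new.env(parent = emptyenv())

  rec <- function(s, i, p, emitted, visited) {
    if (s == hmm$end) {
      if (i == L) {
        total <<- total + p
        if (length(emitted)) {
          for (k in seq_along(emitted)) {
            state_pos[emitted[[k]], k] <<- state_pos[emitted[[k]], k] + p
          }
        }
        for (ck in unique(chain_key[visited])) {
          old <- if (exists(ck, chain_mass)) get(ck, chain_mass) else 0
          assign(ck, old + p, chain_mass)
        }
      }
      return(invisible(NULL))
    }
    eids <- by_from[[as.character(s)]]
    for (e in eids) {
      t <- hmm$edges$to[[e]]
      pe <- exp(hmm$edges$logp[[e]])
      if (hmm$silent[[t]]) {
        rec(t, i, p * pe, emitted, c(visited, t))
      } else if (i < L) {
        em <- unname(exp(hmm$emis[t, codes[[i + 1L]] + 1L]))
        if (em > 0) rec(t, i + 1L, p * pe * em, c(emitted, t),
                        c(visited, t))
      }
    }
  }
  rec(hmm$start, 0L, 1, integer(), integer())
  masses <- lapply(hmm$barcode_info, function(info) {
    vapply(info$chains$chain, function(ch) {
      ck <- paste(info$seg, ch)
      if (exists(ck, chain_mass)) get(ck, chain_mass) else 0
    }, 0)
  })
  list(total = total, state_pos = state_pos, chain_mass = masses)
}

# enumeration-based posterior label matrix (positions x labels), with the
# background chain of each barcode segment as its own label, matching the
# column layout of posterior_labels()
enum_posterior <- function(hmm, x) {
  en <- enum_paths(hmm, x)
  n_seg <- length(hmm$segments)
  lab <- ifelse(hmm$silent, 0L, hmm$seg)
  extra <- 0L
  for (info in hmm$barcode_info) {
    bg_chain <- info$chains$chain[info$chains$label == "background"]
    if (length(bg_chain)) {
      extra <- extra + 1L
      lab[!hmm$silent & hmm$seg == info$seg & hmm$chain == bg_chain] <-
        n_seg + extra
    }
  }
  L <- ncol(en$state_pos)
  post <- matrix(0, L, n_seg + extra)
  for (s in seq_len(hmm$n_states)) {
    if (lab[[s]] > 0L) post[, lab[[s]]] <- post[, lab[[s]]] + en$state_pos[s, ]
  }
  post / en$total
}

# exhaustive optimal-accuracy labeling over all monotone label sequences
enum_decode_score <- function(post_mat, kinds, skip_penalty = 1000) {
  L <- nrow(post_mat)
  K <- length(kinds)
  pen <- ifelse(kinds == "PARTIAL", 0, skip_penalty)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
  best <- -Inf
  for (r in seq_len(nrow(grid))) {
    labs <- grid[r, ]
    if (L > 1L && any(diff(labs) < 0)) next
    sc <- sum(post_mat[cbind(seq_len(L), labs)]) -
      sum(pen[setdiff(seq_len(K), unique(labs))])
    if (sc > best) best <- sc
  }
  best
}

# classic semi-global Wagner-Fischer edit distance (full pattern against any
# text substring); N matches nothing, as in the bit-vector search
wf_semiglobal <- function(pattern, text) {
  pc <- strsplit(toupper(pattern), "")[[1L]]
  tc <- strsplit(toupper(text), "")[[1L]]
  n <- length(tc)
  prev <- rep(0, n + 1L)
  for (i in seq_along(pc)) {
    mism <- (pc[[i]] != tc) | pc[[i]] == "N" | tc == "N"
    tmp <- pmin(prev[1:n] + mism, prev[2:(n + 1L)] + 1)
    v <- c(i, tmp)
    js <- 0:n
    prev <- cummin(v - js) + js
  }
  min(prev)
}

# exhaustive sensitivity+specificity scan over every effectively distinct
# cutoff
brute_best_cutoff <- function(qm, qr) {
  u <- sort(unique(c(qm, qr)))
  cand <- sort(c(u - 1e-9, u + 1e-9, u[[1L]] - 1, u[[length(u)]] + 1))
  best <- -Inf
  for (cc in cand) {
    tot <- mean(qm >= cc) + mean(qr < cc)
    if (tot > best) best <- tot
  }
  best
}

arch_kinds_of <- function(arch) vapply(arch$segments, `[[`, "", "kind")

# drop dimnames and auxiliary attributes for numeric matrix comparison
bare <- function(m) matrix(as.numeric(m), nrow(m), ncol(m))

# unconditional minimal semi-global distance via the package's search
myers_dist <- function(p, t) {
  bitvector_edit_search(p, t, max_k = nchar(p) + nchar(t))$distance
}

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]), collapse = "")
}

random_read <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# a small randomized architecture drawing from all block kinds
random_small_arch <- function() {
  blocks <- c(
    paste0("S:", random_read(sample(1:3, 1))),
    paste0("B:", random_read(2), ",", random_read(2)),
    "F:NN",
    paste0("P:", random_read(sample(2:4, 1))))
  chosen <- sample(blocks, sample(1:2, 1))
  specs <- append(chosen, "R:N", after = sample(0:length(chosen), 1))
  parse_architecture(specs, name = "random")
}
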