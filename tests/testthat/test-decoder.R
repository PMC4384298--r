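test_that("posterior label rows are normalized and match enumeration", {
  set.seed(201)
  for (rep in 1:10) {
    arch <- random_small_arch()
    err <- error_model(0.05, sample(c(0, 0.02), 1))
    hmm <- assemble_global_hmm(arch, err, expected_read_length = 4)
    x <- random_read(sample(3:6, 1))
    m <- hmm_backward(hmm, x)
    if (m$logPxM == -Inf) next
    post <- posterior_labels(m, hmm)
    expect_equal(unname(rowSums(post)), rep(1, nchar(x)), tolerance = 1e-6)
    expect_equal(bare(post), bare(enum_posterior(hmm, x)), tolerance = 1e-9)
  }
})

test_that("deterministic models give one-hot posteriors and identity decoding", {
  arch <- parse_architecture(c("S:ACG", "R:N"))
  hmm <- assemble_global_hmm(arch, error_model(0, 0))
  m <- hmm_backward(hmm, "ACGTTTT")
  post <- posterior_labels(m, hmm)
  expect_equal(unname(post[, 1]), c(1, 1, 1, 0, 0, 0, 0))
  labels <- optimal_accuracy_decode(post, arch)
  expect_equal(as.integer(labels), c(1L, 1L, 1L, 2L, 2L, 2L, 2L))
  expect_equal(attr(labels, "score"), 7, tolerance = 1e-9)
})

test_that("uniform posteriors break ties to the earliest segment switch", {
  arch <- parse_architecture(c("S:AA", "R:N"))
  post <- matrix(0.5, nrow = 4, ncol = 2,
                 dimnames = list(NULL, c("seg1", "seg2")))
  labels <- optimal_accuracy_decode(post, arch)
  expect_equal(as.integer(labels), c(1L, 2L, 2L, 2L))
  expect_equal(attr(labels, "score"), 2.0)
})

test_that("decoding matches exhaustive search over monotone labelings", {
  set.seed(202)
  archs <- list(parse_architecture(c("S:A", "R:N")),
                parse_architecture(c("S:A", "F:NN", "R:N")),
                parse_architecture(c("P:ACG", "S:T", "R:N")))
  for (rep in 1:34) {
    arch <- archs[[sample(length(archs), 1)]]
    K <- length(arch$segments)
    L <- sample(2:6, 1)
    post <- matrix(runif(L * K), L, K)
    post <- post / rowSums(post)
    colnames(post) <- paste0("seg", seq_len(K))
    labels <- optimal_accuracy_decode(post, arch)
    expect_true(all(diff(labels) >= 0))
    expect_equal(attr(labels, "score"),
                 enum_decode_score(post, arch_kinds_of(arch)),
                 tolerance = 1e-12)
  }
})

test_that("labels always traverse the architecture monotonically", {
  set.seed(203)
  for (rep in 1:10) {
    arch <- random_small_arch()
    hmm <- assemble_global_hmm(arch, expected_read_length = 6)
    x <- random_read(sample(4:10, 1))
    m <- hmm_backward(hmm, x)
    labels <- optimal_accuracy_decode(posterior_labels(m, hmm), arch)
    expect_true(all(diff(labels) >= 0))
  }
})

test_that("extraction cuts read, barcode and UMI and applies the guards", {
  arch <- parse_architecture(c("B:GTA,AAC", "R:N"))
  hmm <- assemble_global_hmm(arch, error_model(0.02, 0))
  seqx <- "GTAACGTACGTACGT"
  rec <- list(id = "r1", seq = seqx, qual = strrep("I", nchar(seqx)))
  sc <- score_read(hmm, seqx)
  labels <- optimal_accuracy_decode(posterior_labels(sc$matrices, hmm), arch)
  lr <- extract_read(rec, labels, arch, sc, threshold = 0)
  expect_true(lr$accepted)
  expect_equal(lr$barcode, "GTA")
  expect_equal(lr$read_seq, substr(seqx, 4, nchar(seqx)))
  expect_equal(nchar(lr$read_qual), nchar(lr$read_seq))

  # identity architecture: whole input is the read
  id_arch <- parse_architecture("R:N")
  id_hmm <- assemble_global_hmm(id_arch)
  sc2 <- score_read(id_hmm, seqx)
  lab2 <- optimal_accuracy_decode(posterior_labels(sc2$matrices, id_hmm),
                                  id_arch)
  lr2 <- extract_read(rec, lab2, id_arch, sc2, threshold = 0)
  expect_equal(lr2$read_seq, seqx)

  # threshold rejection
  lr3 <- extract_read(rec, labels, arch, sc, threshold = sc$q + 1)
  expect_false(lr3$accepted)
  expect_equal(lr3$reason, "threshold")

  # fingerprint-length rejection: fabricate a 9-long UMI labeling under a
  # 10-nt fingerprint declaration
  umi_arch <- parse_architecture(c("F:NNNNNNNNNN", "R:N"))
  bad_labels <- c(rep(1L, 9), rep(2L, nchar(seqx) - 9))
  sc$best_barcode <- NA_character_
  lr4 <- extract_read(rec, bad_labels, umi_arch, sc, threshold = 0)
  expect_false(lr4$accepted)
  expect_equal(lr4$reason, "fingerprint length")
})

test_that("UMI encoding is the documented base-4 code and round-trips", {
  expect_equal(encode_umi("AAAA"), 0)
  expect_equal(encode_umi("ACGT"), 27)
  expect_equal(encode_umi("T"), 3)
  expect_error(encode_umi("ACNT"), "ambiguous UMI")
  set.seed(204)
  for (len in c(1, 5, 10)) {
    u <- random_read(len)
    expect_equal(decode_umi(encode_umi(u), len), u)
  }
  # injective over all length-3 fingerprints
  all3 <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                            c("A","C","G","T")), 1, paste, collapse = "")
  expect_equal(anyDuplicated(vapply(all3, encode_umi, 0)), 0L)
})
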