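test_that("model emission is deterministic given a seed and honors the model", {
  hmm <- build_segment_hmm(parse_segment("S:ACGT", 1), error_model(0, 0))
  expect_equal(unique(emit_from_model(hmm, 20, seed = 1)), "ACGT")

  arch <- parse_architecture(c("B:GTA,AAC", "R:N"))
  g <- assemble_global_hmm(arch, error_model(0.05, indel_open = 0))
  a <- emit_from_model(g, 50, seed = 7, read_length = 10)
  b <- emit_from_model(g, 50, seed = 7, read_length = 10)
  expect_identical(a, b)
  expect_true(all(nchar(a) == 13))
})

test_that("emitted base frequencies follow the background within binomial bounds", {
  hmm <- assemble_global_hmm(parse_architecture("R:N"),
                             bg = background_model(c(A = 0.4, C = 0.3,
                                                     G = 0.2, T = 0.1)))
  reads <- emit_from_model(hmm, 2500, seed = 11, read_length = 40)
  chars <- strsplit(paste(reads, collapse = ""), "")[[1]]
  n <- length(chars)
  freqs <- c(A = 0.4, C = 0.3, G = 0.2, T = 0.1)
  for (nm in names(freqs)) {
    p <- freqs[[nm]]
    expect_lt(abs(mean(chars == nm) - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("random emission is reproducible and respects degenerate backgrounds", {
  bg <- background_model(c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(unique(emit_random(bg, 10, seed = 3, length = 5)), "AAAAA")
  bg2 <- background_model(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  expect_identical(emit_random(bg2, 20, seed = 5, length = 7),
                   emit_random(bg2, 20, seed = 5, length = 7))
  lens <- c(3, 9, 4)
  expect_equal(nchar(emit_random(bg2, 3, seed = 1, length = lens)), lens)
})

test_that("threshold selection is globally optimal and handles edge cases", {
  res <- select_threshold(c(30, 35), c(2, 3))
  expect_equal(res$sensitivity + res$specificity, 2)
  expect_gt(res$threshold, 3)
  expect_lte(res$threshold, 30)

  same <- select_threshold(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$sensitivity + same$specificity, 1)

  set.seed(301)
  for (rep in 1:100) {
    qm <- round(runif(sample(1:20, 1), 0, 10), 1)
    qr <- round(runif(sample(1:20, 1), 0, 10), 1)
    res <- select_threshold(qm, qr)
    expect_equal(res$sensitivity, mean(qm >= res$threshold))
    expect_equal(res$specificity, mean(qr < res$threshold))
    expect_equal(res$sensitivity + res$specificity,
                 brute_best_cutoff(qm, qr), tolerance = 1e-12)
  }
  expect_error(select_threshold(numeric(0), 1), "non-empty")
})

test_that("calibration is reproducible bit-for-bit given the seed", {
  arch <- parse_architecture(c("B:GTACCA,AACGTT", "R:N"))
  hmm <- assemble_global_hmm(arch)
  a <- calibrate_threshold(hmm, n = 150, seed = 42, read_length = 12)
  b <- calibrate_threshold(hmm, n = 150, seed = 42, read_length = 12)
  expect_identical(a$threshold, b$threshold)
  expect_identical(a$q_model, b$q_model)
  expect_gte(a$sensitivity, 0); expect_lte(a$sensitivity, 1)
  expect_gte(a$specificity, 0); expect_lte(a$specificity, 1)
})
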