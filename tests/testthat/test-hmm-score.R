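test_that("forward equals exhaustive path enumeration on tiny models", {
  set.seed(101)
  for (rep in 1:20) {
    arch <- random_small_arch()
    err <- error_model(base_error = runif(1, 0.01, 0.1),
                       indel_open = sample(c(0, 0.02), 1))
    hmm <- assemble_global_hmm(arch, err, expected_read_length = 4)
    x <- random_read(sample(2:6, 1))
    en <- enum_paths(hmm, x)
    m <- hmm_backward(hmm, x)
    if (en$total == 0) {
      expect_equal(m$logPxM, -Inf)
    } else {
      expect_equal(m$logPxM, log(en$total), tolerance = 1e-9)
    }
    expect_equal(m$logPxM, m$logPxM_bwd, tolerance = 1e-9)
  }
})

test_that("backward matches enumeration suffix sums via posterior masses", {
  set.seed(102)
  arch <- parse_architecture(c("S:AC", "R:N"))
  hmm <- assemble_global_hmm(arch, error_model(0.05, 0.02),
                             expected_read_length = 4)
  for (rep in 1:5) {
    x <- random_read(5)
    en <- enum_paths(hmm, x)
    m <- hmm_backward(hmm, x)
    # f*b at every (state, position) must equal the enumerated path mass
    for (i in seq_len(nchar(x))) {
      got <- exp(m$f[, i + 1] + m$b[, i + 1])
      got[hmm$silent] <- 0
      expect_equal(unname(got), unname(en$state_pos[, i]), tolerance = 1e-9)
    }
  }
})

test_that("impossible emissions give zero probability", {
  hmm <- build_segment_hmm(parse_segment("S:ACGT", 1),
                           error_model(0, 0))
  expect_equal(hmm_forward(hmm, "ACGA")$logPxM, -Inf)
  expect_error(hmm_forward(hmm, "ACXT"), "outside")
})

test_that("background score has its closed forms", {
  expect_equal(background_score(strrep("A", 10)), log(0.25^10))
  skew <- background_model(c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(background_score("AAA", skew), 0)
  half <- background_model(c(A = 0.5, C = 0.5, G = 0, T = 0))
  expect_equal(background_score("G", half), -Inf)
  # N scores as the maximum base frequency
  expect_equal(background_score("N", half), log(0.5))
})

test_that("barcode confidence is 1 without barcodes and splits symmetric ties", {
  hmm <- assemble_global_hmm(parse_architecture("R:N"))
  bc <- barcode_confidence(hmm_backward(hmm, "ACGTACGT"), hmm)
  expect_equal(bc$V, 1)

  # read GCC is equidistant from GTA and GAT; a heavily skewed background
  # makes the competing background chain negligible
  skew <- background_model(c(A = 0.9997, C = 1e-4, G = 1e-4, T = 1e-4))
  arch <- parse_architecture(c("B:GTA,GAT", "R:N"))
  hmm <- assemble_global_hmm(arch, error_model(0.05, 0), bg = skew)
  bc <- barcode_confidence(hmm_backward(hmm, "GCCAAAA"), hmm)
  expect_equal(bc$V, 0.5, tolerance = 1e-6)
})

test_that("chain entry posteriors match path enumeration and sum to one", {
  set.seed(103)
  arch <- parse_architecture(c("B:GT,AC", "R:N"))
  for (io in c(0, 0.02)) {
    hmm <- assemble_global_hmm(arch, error_model(0.05, io),
                               expected_read_length = 4)
    for (rep in 1:5) {
      x <- random_read(sample(3:6, 1))
      en <- enum_paths(hmm, x)
      m <- hmm_backward(hmm, x)
      bc <- barcode_confidence(m, hmm)
      mass <- bc$per_segment[[1]]
      expect_equal(sum(mass), 1, tolerance = 1e-6)
      expect_equal(unname(mass), unname(en$chain_mass[[1]] / en$total),
                   tolerance = 1e-9)
      expect_equal(bc$V, max(en$chain_mass[[1]] / en$total),
                   tolerance = 1e-9)
    }
  }
})

test_that("extraction quality reproduces its algebraic fixed points", {
  eq <- extraction_quality(-10, -10, V = 1)
  expect_equal(eq$p_error, 0.5, tolerance = 1e-12)
  expect_equal(eq$q, -10 * log10(0.5), tolerance = 1e-12)

  eq <- extraction_quality(-10, -Inf, V = 1)
  expect_equal(eq$p_error, 0, tolerance = 1e-12)
  expect_equal(eq$q, 60)

  eq <- extraction_quality(-10, -Inf, V = 0.5)
  expect_equal(eq$p_error, 0.5, tolerance = 1e-12)

  expect_error(extraction_quality(-Inf, -Inf, 1), "zero")
})

test_that("scores stay in range over randomized inputs", {
  set.seed(104)
  for (rep in 1:10) {
    arch <- random_small_arch()
    hmm <- assemble_global_hmm(arch, expected_read_length = 10)
    sc <- score_read(hmm, random_read(sample(4:12, 1)))
    expect_gte(sc$V, 0); expect_lte(sc$V, 1)
    expect_gte(sc$p_error, 0); expect_lte(sc$p_error, 1)
    expect_gte(sc$q, 0)
  }
})
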