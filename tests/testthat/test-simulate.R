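test_that("barcode sets respect the requested pairwise distance", {
  pair <- generate_barcode_set(2, 4, 2, seed = 601)
  expect_length(pair, 2)
  expect_gte(sum(strsplit(pair[1], "")[[1]] != strsplit(pair[2], "")[[1]]), 2)

  b6 <- generate_barcode_set(8, 6, 3, seed = 602)
  d <- utils::combn(b6, 2, function(p)
    sum(strsplit(p[1], "")[[1]] != strsplit(p[2], "")[[1]]))
  expect_true(all(d >= 3))
  expect_identical(b6, generate_barcode_set(8, 6, 3, seed = 602))

  # sphere-packing infeasible request
  expect_error(generate_barcode_set(300, 4, 3, seed = 603,
                                    max_attempts = 20000), "could not find")
})

test_that("error-free simulation renders architectures exactly", {
  arch <- parse_architecture(c("B:GTACCA,AACGTT", "S:GG", "R:N"))
  ds <- simulate_dataset(arch, error_rate = 0, n_true = 25, n_random = 5,
                         read_length = 12, seed = 604)
  expect_equal(nrow(ds$records), 30)
  expect_equal(sum(ds$truth$origin == "true"), 25)
  for (i in 1:25) {
    s <- ds$records$seq[i]
    tr <- ds$truth[i, ]
    expect_equal(substr(s, 1, 6), tr$barcode_seq)
    expect_equal(substr(s, 7, 8), "GG")
    expect_equal(nchar(s), 20)
    expect_equal(tr$read_start, 8)
    expect_equal(tr$read_end, 20)
  }
  expect_identical(
    simulate_dataset(arch, 0, 25, 5, 12, seed = 604)$records, ds$records)
})

test_that("substitution fraction tracks the requested error rate", {
  arch <- parse_architecture(c("S:ACGTACGTACGTACGTACGT", "R:N"))
  rate <- 0.05
  ds <- simulate_dataset(arch, error_rate = rate, n_true = 400, n_random = 0,
                         read_length = 5, seed = 605)
  planted <- "ACGTACGTACGTACGTACGT"
  obs <- vapply(ds$records$seq, function(s)
    sum(strsplit(substr(s, 1, 20), "")[[1]] !=
          strsplit(planted, "")[[1]]), 0, USE.NAMES = FALSE)
  n <- 400 * 20
  expect_lt(abs(sum(obs) / n - rate), 3 * sqrt(rate * (1 - rate) / n))
})

test_that("evaluation reproduces a hand-computed worked example", {
  truth <- data.frame(
    id = paste0("r", 1:10),
    origin = c(rep("true", 8), "random", "random"),
    barcode = c(1, 1, 2, 2, 1, 2, 1, 2, NA, NA),
    barcode_seq = c("AAA", "AAA", "CCC", "CCC", "AAA", "CCC", "AAA", "CCC",
                    NA, NA),
    stringsAsFactors = FALSE)
  labeled <- data.frame(
    id = truth$id,
    accepted = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE,
                 TRUE, FALSE),
    barcode = c("AAA", "AAA", "CCC", "AAA", "AAA", NA, NA, "CCC",
                "AAA", NA),
    stringsAsFactors = FALSE)
  # accepted true & correct: r1,r2,r3,r5,r8 = 5; r4 misassigned;
  # r9 accepted random = false positive; assigned total = 7
  ev <- evaluate_extraction(labeled, truth)
  expect_equal(ev$recall, 5 / 8)
  expect_equal(ev$precision, 5 / 7)
  expect_equal(ev$misassigned, 1)
  expect_equal(ev$false_positives, 1)
})

test_that("degenerate evaluations follow the documented conventions", {
  truth <- data.frame(id = c("a", "b"), origin = c("true", "true"),
                      barcode = c(1, 1), barcode_seq = c("AA", "AA"),
                      stringsAsFactors = FALSE)
  nothing <- data.frame(id = c("a", "b"), accepted = c(FALSE, FALSE),
                        barcode = c(NA_character_, NA_character_),
                        stringsAsFactors = FALSE)
  ev <- evaluate_extraction(nothing, truth)
  expect_equal(ev$recall, 0)
  expect_equal(ev$precision, 1)  # no assignments, no errors

  perfect <- data.frame(id = c("a", "b"), accepted = TRUE, barcode = "AA",
                        stringsAsFactors = FALSE)
  ev2 <- evaluate_extraction(perfect, truth)
  expect_equal(ev2$recall, 1)
  expect_equal(ev2$precision, 1)
})

test_that("long adapters keep recall and precision degrades with error rate", {
  b6 <- generate_barcode_set(8, 6, 3, seed = 607)
  plain <- parse_architecture(
    c(paste0("B:", paste(b6, collapse = ",")), "R:N"), "plain")
  adapt <- parse_architecture(
    c("P:AGGGAGGACGATGCGG", paste0("B:", paste(b6, collapse = ",")),
      "R:N", "P:GTGTCAGTCACTTCCAGCGG"), "adapters")
  hp <- assemble_global_hmm(plain)
  ha <- assemble_global_hmm(adapt)
  cp <- calibrate_threshold(hp, n = 2000, seed = 42, read_length = 30)
  ca <- calibrate_threshold(ha, n = 2000, seed = 42, read_length = 30)

  run_eval <- function(arch, hmm, thr, err, seed) {
    ds <- simulate_dataset(arch, error_rate = err, n_true = 700,
                           n_random = 70, read_length = 30, seed = seed)
    evaluate_extraction(extract_reads(ds$records, hmm, arch, thr), ds$truth)
  }
  ev_plain <- run_eval(plain, hp, cp$threshold, 0.01, 608)
  ev_adapt <- run_eval(adapt, ha, ca$threshold, 0.01, 609)
  expect_gte(ev_adapt$recall, ev_plain$recall - 0.02)

  # precision is non-increasing in the error rate on average across seeds
  prec <- function(err) mean(vapply(c(610, 611), function(s)
    run_eval(plain, hp, cp$threshold, err, s)$precision, 0))
  expect_gte(prec(0.01), prec(0.08) - 0.01)
})
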