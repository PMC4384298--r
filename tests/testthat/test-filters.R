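test_that("bit-vector search finds exact and approximate substrings", {
  hit <- bitvector_edit_search("ACGT", "ACGT", 0)
  expect_equal(hit$distance, 0)

  hit <- bitvector_edit_search("ACG", "TTACGTT", 0)
  expect_equal(hit$distance, 0)
  expect_equal(hit$end, 4L)  # 0-based end of the match

  expect_null(bitvector_edit_search("AAAA", "CCCCCCCC", 2))
  hit <- bitvector_edit_search("ACGTACGT", "TTTACGAACGTTT", 2)
  expect_equal(hit$distance, wf_semiglobal("ACGTACGT", "TTTACGAACGTTT"))
  expect_error(bitvector_edit_search("", "ACGT", 1))
})

test_that("bit-vector distances equal semi-global Wagner-Fischer, incl. >64 nt", {
  set.seed(501)
  for (rep in 1:120) {
    m <- sample(c(3:30, 60:70, 100:120), 1)
    n <- sample(10:400, 1)
    pat <- random_read(m)
    txt <- random_read(n)
    got <- myers_dist(pat, txt)
    expect_equal(got, wf_semiglobal(pat, txt))
  }
})

test_that("search distance is strand-consistent", {
  set.seed(502)
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  for (rep in 1:20) {
    pat <- random_read(sample(5:40, 1))
    txt <- random_read(sample(30:100, 1))
    expect_equal(myers_dist(pat, txt), myers_dist(rc(pat), rc(txt)))
  }
})

test_that("contaminant filtering removes hits on either strand and keeps counts", {
  set.seed(503)
  refs <- c(rrna = random_read(200), spike = random_read(150))
  reads <- c(r1 = substr(refs[["rrna"]], 21, 60),          # forward hit
             r2 = revcomp_chr(substr(refs[["spike"]], 51, 90)),  # reverse hit
             r3 = random_read(40),
             r4 = random_read(40))
  res <- filter_contaminants(reads, refs, max_k = 0)
  expect_setequal(names(res$removed), c("r1", "r2"))
  expect_setequal(names(res$kept), c("r3", "r4"))
  expect_equal(unname(res$counts["rrna"]), 1L)
  expect_equal(unname(res$counts["spike"]), 1L)
  expect_equal(sum(res$counts), length(res$removed))
  # partition: nothing lost or duplicated
  expect_setequal(c(names(res$kept), names(res$removed)), names(reads))

  none <- filter_contaminants(reads, character(0), max_k = 3)
  expect_equal(length(none$kept), length(reads))
})

test_that("DUST scoring matches its closed forms and a hash-count oracle", {
  polyA <- dust_score(strrep("A", 64))
  expect_equal(polyA$score, 3100)
  expect_true(polyA$flagged)

  # all 3-mers distinct
  distinct <- dust_score("ACGTAGCTTGCA")
  expect_equal(distinct$score, 0)
  expect_false(distinct$flagged)

  expect_equal(dust_score("AC")$score, 0)

  set.seed(504)
  for (rep in 1:200) {
    s <- random_read(64)
    got <- dust_score(s)$score
    # independent recount via an environment hash
    h <- new.env()
    for (i in 1:62) {
      k <- substr(s, i, i + 2)
      assign(k, (if (exists(k, h)) get(k, h) else 0) + 1, h)
    }
    cs <- vapply(ls(h), function(k) get(k, h), 0)
    expect_equal(got, 100 * sum(cs * (cs - 1) / 2) / 61)
  }
})

test_that("DUST ignores bases beyond the 64-nt window", {
  set.seed(505)
  s <- random_read(64)
  expect_equal(dust_score(paste0(s, strrep("A", 100)))$score,
               dust_score(s)$score)
})
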