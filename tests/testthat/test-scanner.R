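test_that("candidate windows enumerate every full-length ungapped placement", {
  expect_equal(nrow(candidate_windows(100, 21)), 80L)
  w <- candidate_windows(21, 21)
  expect_equal(nrow(w), 1L)
  expect_equal(c(w$start, w$end), c(0L, 21L))
  expect_equal(nrow(candidate_windows(20, 21)), 0L)
  expect_error(candidate_windows(-1, 21), "non-negative")
})

test_that("a planted perfect-complement site is found at its exact coordinates", {
  set.seed(201)
  m <- mirna("mirX", rand_mirna_seq(21))
  tr <- list(id = "t1", sequence = plant_site(rand_seq(400),
                                              reverse_complement(m$sequence),
                                              123L))
  hits <- scan_pair(m, tr)
  planted <- hits[hits$start == 123L, ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$end, 144L)
  expect_equal(planted$score, 0)
  expect_equal(planted$site_seq, reverse_complement(m$sequence))
})

test_that("a central-region mismatch disqualifies an otherwise perfect site", {
  set.seed(202)
  m <- mirna("mirX", rand_mirna_seq(21))
  # the transcript is exactly the damaged site: one candidate window only
  tr <- list(id = "t1", sequence = build_site(m$sequence, 10, integer(0)))
  expect_equal(nrow(scan_pair(m, tr)), 0L)
  expect_equal(nrow(oracle_scan(m, tr)), 0L)
})

test_that("the scanner and the naive oracle agree on random inputs", {
  set.seed(203)
  cfg <- rule_config()
  for (i in 1:100) {
    L <- sample(18:24, 1)
    m <- mirna("m", rand_mirna_seq(L))
    tlen <- sample(200:2000, 1)
    seq <- rand_seq(tlen)
    if (i %% 3L == 0L) {
      # plant a near-complementary site so non-trivial hits are exercised
      site <- build_site(m$sequence, sort(sample(setdiff(12:L, 1:11),
                                                 sample(0:3, 1))), integer(0))
      seq <- plant_site(seq, site, sample(0:(tlen - L), 1))
    }
    tr <- list(id = "t", sequence = seq)
    expect_identical(scan_pair(m, tr, cfg), oracle_scan(m, tr, cfg))
  }
})

test_that("scan membership matches per-window rule evaluation exhaustively", {
  set.seed(204)
  cfg <- rule_config()
  for (rep in 1:5) {
    L <- sample(18:24, 1)
    m <- mirna("m", rand_mirna_seq(L))
    tlen <- sample(50:500, 1)
    seq <- plant_site(rand_seq(tlen), reverse_complement(m$sequence),
                      sample(0:(tlen - L), 1))
    tr <- list(id = "t", sequence = seq)
    hits <- scan_pair(m, tr, cfg)
    windows <- candidate_windows(tlen, L)
    for (k in seq_len(nrow(windows))) {
      site <- substr(seq, windows$start[k] + 1L, windows$end[k])
      passed <- evaluate_rules(score_duplex(m$sequence, site, cfg), cfg)$passed
      expect_equal(windows$start[k] %in% hits$start, passed,
                   label = sprintf("window %d of rep %d", k, rep))
    }
  }
})

test_that("prepending bases shifts every hit start by exactly the prefix length", {
  set.seed(205)
  m <- mirna("m", rand_mirna_seq(21))
  seq <- plant_site(rand_seq(600), reverse_complement(m$sequence), 200L)
  hits <- scan_pair(m, list(id = "t", sequence = seq))
  k <- 37L
  shifted <- scan_pair(m, list(id = "t", sequence = paste0(rand_seq(k), seq)))
  expect_equal(nrow(shifted), nrow(hits))
  expect_equal(shifted$start, hits$start + k)
  expect_equal(shifted$score, hits$score)
})

test_that("embedding a miRNA's reverse complement always yields a covering hit", {
  set.seed(206)
  for (i in 1:20) {
    L <- sample(18:24, 1)
    m <- mirna("m", rand_mirna_seq(L))
    pos <- sample(0:(300 - L), 1)
    tr <- list(id = "t", sequence = plant_site(rand_seq(300),
                                               reverse_complement(m$sequence),
                                               pos))
    hits <- scan_pair(m, tr)
    expect_true(any(hits$start == pos))
  }
})

test_that("scanning all pairs concatenates, sorts, and summarizes", {
  set.seed(207)
  mirs <- data.frame(id = c("mirA", "mirB"),
                     sequence = c(rand_mirna_seq(21), rand_mirna_seq(21)),
                     stringsAsFactors = FALSE)
  trs <- data.frame(id = sprintf("t%d", 1:3),
                    sequence = vapply(1:3, function(i) rand_seq(300), ""),
                    stringsAsFactors = FALSE)
  for (ti in 1:3) {
    seq <- trs$sequence[ti]
    seq <- plant_site(seq, reverse_complement(mirs$sequence[1]), 10L)
    seq <- plant_site(seq, reverse_complement(mirs$sequence[2]), 100L)
    trs$sequence[ti] <- seq
  }
  hits <- scan_all(mirs, trs)
  expect_equal(nrow(hits), 6L)
  expect_false(is.unsorted(order(hits$mirna_id, hits$transcript_id, hits$start)))
  s <- hit_summary(hits)
  expect_equal(s$total_sites, 6L)
  expect_equal(s$total_target_transcripts, 3L)
  expect_equal(s$per_mirna$n_sites, c(3L, 3L))
  expect_equal(s$per_mirna$n_transcripts, c(3L, 3L))

  # empty miRNA set -> empty table with the standard columns
  empty <- scan_all(mirs[0, ], trs)
  expect_equal(nrow(empty), 0L)
  expect_identical(names(empty), names(hits))

  # determinism: two runs give byte-identical TSV output
  f1 <- tempfile(); f2 <- tempfile()
  write_tsv(scan_all(mirs, trs), f1)
  write_tsv(scan_all(mirs, trs), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  expect_error(scan_all(rbind(mirs, mirs[1, ]), trs), "duplicate")
  expect_error(scan_all(mirs, rbind(trs, trs[1, ])), "duplicate")
})

test_that("best-per-pair reporting keeps the lowest score, earliest start", {
  set.seed(208)
  m <- rand_mirna_seq(21)
  seq <- rand_seq(500)
  seq <- plant_site(seq, build_site(m, c(13, 16), integer(0)), 50L)  # score 2
  seq <- plant_site(seq, reverse_complement(m), 200L)                # score 0
  mirs <- data.frame(id = "mirA", sequence = m, stringsAsFactors = FALSE)
  trs <- data.frame(id = "t1", sequence = seq, stringsAsFactors = FALSE)
  all_hits <- scan_all(mirs, trs)
  expect_gte(nrow(all_hits), 2L)
  best <- scan_all(mirs, trs, best_per_pair = TRUE)
  expect_equal(nrow(best), 1L)
  expect_equal(best$start, 200L)
  expect_equal(best$score, 0)
})
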