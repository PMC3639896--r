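test_that("sequence normalization uppercases, maps T to U, and rejects junk", {
  expect_identical(normalize_sequence("acgt"), "ACGU")
  expect_identical(normalize_sequence("ACGU"), "ACGU")
  expect_identical(normalize_sequence("acgtnACGTN"), "ACGUNACGUN")
  expect_error(normalize_sequence("ACXG"), "position 3")
  expect_error(normalize_sequence(""), "non-empty")
  expect_error(normalize_sequence("AC GU"), "position 3")
})

test_that("pair states match the pairing chemistry over the whole alphabet", {
  bases <- c("A", "C", "G", "U", "N")
  for (m in bases) {
    for (t in bases) {
      expect_identical(pair_state(m, t), brute_states(m, t),
                       label = sprintf("pair %s:%s", m, t))
    }
  }
  # spot checks straight from the definitions
  expect_identical(pair_state("A", "U"), "match")
  expect_identical(pair_state("G", "U"), "gu")
  expect_identical(pair_state("U", "G"), "gu")
  expect_identical(pair_state("A", "C"), "mismatch")
  expect_identical(pair_state("N", "A"), "mismatch")
  expect_error(pair_state("a", "U"), "normalized")
})

test_that("duplex scoring counts states and weights wobbles by 0.5", {
  m <- "UGACAGAAGAGAGUGAGCACA"
  d <- score_duplex(m, reverse_complement(m))
  expect_equal(d$score, 0)
  expect_equal(d$n_match, nchar(m))
  expect_true(all(d$states == "match"))

  # two mismatches and one wobble: score 2 * 1.0 + 1 * 0.5
  gu_pos <- setdiff(which(strsplit(m, "")[[1]] %in% c("G", "U")), c(13, 16))[1]
  site <- build_site(m, c(13, 16), gu_pos)
  d2 <- score_duplex(m, site)
  expect_equal(d2$score, 2.5)
  expect_equal(d2$n_mismatch, 2L)
  expect_equal(d2$n_gu, 1L)

  expect_error(score_duplex(m, substr(site, 1, 20)), "length")
})

test_that("each positional rule fails exactly where it should", {
  m <- "UGACAGAAGAGAGUGAGCACA"
  cfg <- rule_config()

  v <- evaluate_rules(score_duplex(m, build_site(m, 10, integer(0))), cfg)
  expect_false(v$pass_central)
  expect_true(v$pass_total && v$pass_contiguous && v$pass_seed)
  expect_false(v$passed)

  v <- evaluate_rules(score_duplex(m, build_site(m, c(2, 5), integer(0))), cfg)
  expect_false(v$pass_seed)
  expect_true(v$pass_total && v$pass_contiguous && v$pass_central)

  v <- evaluate_rules(score_duplex(m, build_site(m, 13:15, integer(0))), cfg)
  expect_false(v$pass_contiguous)
  expect_true(v$pass_total && v$pass_seed && v$pass_central)

  # boundary: 3 mismatches + 2 wobbles = 4.0 passes everything
  gu_pos <- setdiff(which(strsplit(m, "")[[1]] %in% c("G", "U")),
                    c(10, 11, 13, 16, 19))[1:2]
  v <- evaluate_rules(score_duplex(m, build_site(m, c(13, 16, 19), gu_pos)), cfg)
  expect_true(v$passed)
})

test_that("stored duplex counts are recomputable from the states", {
  set.seed(101)
  for (i in 1:200) {
    L <- sample(15:24, 1)
    d <- score_duplex(rand_seq(L), rand_seq(L))
    expect_equal(d$n_match, sum(d$states == "match"))
    expect_equal(d$n_gu, sum(d$states == "gu"))
    expect_equal(d$n_mismatch, sum(d$states == "mismatch"))
    expect_equal(d$n_match + d$n_gu + d$n_mismatch, L)
    expect_equal(d$score, d$n_mismatch + 0.5 * d$n_gu)
    expect_lte(d$max_run_mismatch, d$n_mismatch)
  }
})

test_that("turning a match into a mismatch never lowers the score or rescues a verdict", {
  set.seed(102)
  cfg <- rule_config()
  for (i in 1:100) {
    m <- rand_mirna_seq(21)
    spec_mm <- sort(sample(21, sample(0:4, 1)))
    site <- build_site(m, spec_mm, integer(0))
    d <- score_duplex(m, site)
    match_pos <- which(d$states == "match")
    if (!length(match_pos)) next
    flip <- match_pos[sample.int(length(match_pos), 1)]
    d2 <- score_duplex(m, build_site(m, sort(c(spec_mm, flip)), integer(0)))
    expect_gte(d2$score, d$score)
    v1 <- evaluate_rules(d, cfg)
    v2 <- evaluate_rules(d2, cfg)
    expect_false(!v1$passed && v2$passed)
  }
})

test_that("wobbles alone never trip the positional rules; eight is the score limit", {
  # an all-G/U miRNA lets a wobble be planted at any position
  m <- paste(rep(c("G", "U"), length.out = 21), collapse = "")
  cfg <- rule_config()
  set.seed(103)
  for (k in 0:9) {
    gu_pos <- sort(sample(21, k))
    v <- evaluate_rules(score_duplex(m, build_site(m, integer(0), gu_pos)), cfg)
    expect_true(v$pass_contiguous && v$pass_seed && v$pass_central,
                label = sprintf("positional rules with %d wobbles", k))
    expect_equal(v$pass_total, k <= 8,
                 label = sprintf("score rule with %d wobbles", k))
  }
})

test_that("the stricter wobble convention counts G:U in the positional rules", {
  m <- paste(rep(c("G", "U"), length.out = 21), collapse = "")
  strict <- rule_config(gu_counts_in_positional_rules = TRUE)
  site <- build_site(m, integer(0), 10)   # single wobble in the central region
  expect_true(evaluate_rules(score_duplex(m, site), rule_config())$pass_central)
  expect_false(evaluate_rules(score_duplex(m, site), strict)$pass_central)
})

test_that("rule verdicts agree with an independently coded checker on random duplexes", {
  set.seed(104)
  configs <- list(rule_config(),
                  rule_config(gu_counts_in_positional_rules = TRUE),
                  rule_config(max_total_score = 3, max_seed_mismatch = 0))
  n_bad <- 0L
  for (i in 1:10000) {
    L <- sample(12:24, 1)
    mseq <- rand_seq(L)
    # skew toward near-complementary sites so passes are actually exercised
    site <- if (i %% 2L == 0L) {
      build_site(mseq, sort(sample(L, sample(0:5, 1))), integer(0))
    } else {
      rand_seq(L)
    }
    cfg <- configs[[(i %% length(configs)) + 1L]]
    d <- score_duplex(mseq, site, cfg)
    got <- evaluate_rules(d, cfg)
    want <- brute_verdict(brute_states(mseq, site), cfg)
    if (!identical(unclass(got)[names(want)], want)) n_bad <- n_bad + 1L
  }
  expect_identical(n_bad, 0L)
})

test_that("regions beyond the miRNA length are a configuration error", {
  m <- rand_mirna_seq(12)
  cfg <- rule_config(central_region = c(13, 14))
  expect_error(score_duplex(m, rand_seq(12), cfg), "beyond")
  d <- score_duplex(m, rand_seq(12))
  expect_error(evaluate_rules(d, cfg), "beyond")
})

test_that("miRNA construction validates alphabet, length and direction", {
  mi <- mirna("mir1", "ugacagaagagaguGAGCACA", direction = "down")
  expect_identical(mi$sequence, "UGACAGAAGAGAGUGAGCACA")
  expect_error(mirna("m", "ACGUACGUACG"), "shorter")
  expect_error(mirna("m", "ACGUACGUACGU", direction = "sideways"), "direction")
})
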