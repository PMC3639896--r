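test_that("relative abundance scales a library to a million", {
  expect_equal(relative_abundance(c(5, 5)), c(5e5, 5e5))
  expect_equal(relative_abundance(c(1, 0, 3)), c(2.5e5, 0, 7.5e5))
  set.seed(301)
  x <- rpois(500, 40)
  expect_equal(sum(relative_abundance(x)), 1e6, tolerance = 1e-9)
  expect_error(relative_abundance(c(0, 0)), "all-zero")
  expect_error(relative_abundance(c(-1, 2)), "non-negative")
})

test_that("fold change applies the zero-denominator conventions", {
  expect_true(is_nd(fold_change(10, 0)))
  expect_equal(fold_change(4, 2), 2)
  expect_true(is.nan(fold_change(0, 0)))
  expect_equal(fold_change(c(10, 4, 0), c(0, 2, 0)), c(Inf, 2, NaN))
  expect_error(fold_change(-1, 2), "non-negative")
  expect_false(is_nd(2))
  expect_false(is_nd(NaN))
})

test_that("DE calls are inclusive at both fold boundaries and at p = 0.05", {
  expect_equal(classify_de(2.0, 0.04), "up")
  expect_equal(classify_de(1.9, 0.001), "unchanged")
  expect_equal(classify_de(0.4, 0.01), "down")
  expect_equal(classify_de(0.5, 0.05), "down")       # both boundaries inclusive
  expect_equal(classify_de(2.0, 0.05), "up")
  expect_equal(classify_de(2.0, 0.051), "unchanged") # p just over
  expect_equal(classify_de(Inf, 0.01), "up")         # n.d. counts as up
  expect_equal(classify_de(Inf, 0.2), "unchanged")
  expect_equal(classify_de(NaN, 0.001), "unchanged") # 0/0 never called
  expect_equal(classify_de(8, NULL), "up")           # no p column: skipped
  expect_error(classify_de(2, 1.2), "\\[0, 1\\]")
})

test_that("no record with positive control abundance is ever n.d.", {
  set.seed(302)
  ab_n <- c(runif(200, 0.1, 100), rep(0, 20))
  ab_e <- runif(220, 0, 100)
  fold <- fold_change(ab_e, ab_n)
  expect_false(any(is_nd(fold) & ab_n > 0))
  expect_true(all(is_nd(fold[ab_n == 0 & ab_e > 0])))
})

test_that("fold changes and calls are invariant to a common count rescaling", {
  set.seed(303)
  x <- data.frame(id = sprintf("g%d", 1:50),
                  count_nonelicited = rpois(50, 30),
                  count_elicited = rpois(50, 30),
                  adjusted_p = runif(50))
  x$count_nonelicited[1] <- 0  # keep an n.d. case in play
  a <- expression_table(x)
  y <- x
  y$count_nonelicited <- y$count_nonelicited * 7
  y$count_elicited <- y$count_elicited * 7
  b <- expression_table(y)
  expect_equal(a$fold, b$fold)
  expect_identical(a$direction, b$direction)
  expect_identical(a$nd, b$nd)
})

test_that("expression tables accept counts or per-million input and flag p usage", {
  x <- data.frame(id = c("a", "b", "c"),
                  count_nonelicited = c(10, 0, 30),
                  count_elicited = c(40, 10, 30))
  tab <- expression_table(x)
  expect_false(attr(tab, "p_criterion_used"))
  expect_equal(tab$abundance_nonelicited, c(250000, 0, 750000))
  expect_true(tab$nd[2])
  expect_equal(tab$direction[1], "up")

  tpm <- data.frame(id = c("a", "b"),
                    abundance_nonelicited = c(100, 400),
                    abundance_elicited = c(300, 100),
                    adjusted_p = c(0.01, 0.2))
  tab2 <- expression_table(tpm, input = "tpm")
  expect_true(attr(tab2, "p_criterion_used"))
  expect_equal(tab2$direction, c("up", "unchanged"))
  expect_error(expression_table(rbind(x, x[1, ])), "duplicate")
})

test_that("pathways are classified by their strong movers and counts conserve", {
  records <- expr_records(
    sprintf("g%d", 1:10),
    folds = c(5.0, 6.2, 8.0, 0.2, 3.0, 3.5, Inf, 0.1, 1.0, 0.3),
    directions = c("up", "up", "up", "down", "up", "up", "up", "down",
                   "unchanged", "down")
  )
  map <- data.frame(
    pathway_id = c("increased", "increased", "mixed", "mixed", "below", "below",
                   "nd_up", "decreased", "none_flat", "sub_thresh_down"),
    member_id = c("g1", "g2", "g3", "g4", "g5", "g6", "g7", "g8", "g9", "g10"),
    stringsAsFactors = FALSE
  )
  s <- summarize_pathways(records, map, pathway_fold_threshold = 4)
  got <- setNames(s$classification, s$pathway_id)
  expect_equal(got[["increased"]], "increased")   # folds 5.0, 6.2
  expect_equal(got[["mixed"]], "mixed")           # folds 8.0 and 0.2
  expect_equal(got[["below"]], "none")            # 3.0, 3.5 below fourfold
  expect_equal(got[["nd_up"]], "increased")       # n.d. counts as up
  expect_equal(got[["decreased"]], "decreased")   # fold 0.1
  expect_equal(got[["none_flat"]], "none")
  # 0.3 is significant twofold-down but not fourfold-down
  expect_equal(got[["sub_thresh_down"]], "none")
  expect_true(all(s$n_up + s$n_down <= s$n_members))

  # membership in several pathways and missing members
  map2 <- rbind(map, data.frame(pathway_id = c("increased", "ghost"),
                                member_id = c("g3", "not_present")))
  expect_warning(expect_warning(s2 <- summarize_pathways(records, map2),
                                "missing"),
                 "no resolvable members")
  expect_equal(s2$n_up[s2$pathway_id == "increased"], 3L)
  expect_equal(s2$classification[s2$pathway_id == "ghost"], "none")
  expect_equal(s2$n_missing[s2$pathway_id == "ghost"], 1L)
})
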