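test_that("the Likert mapping is the printed bijection", {
  labels <- c("strongly agree", "agree", "neutral", "disagree",
              "strongly disagree")
  scores <- map_likert(labels)
  expect_identical(scores, c(2L, 1L, 0L, -1L, -2L))
  expect_identical(anyDuplicated(scores), 0L)
  expect_error(map_likert("meh"), "unknown rating label")
})

test_that("score summaries report mean and sample SD (population behind a flag)", {
  expect_identical(summarize_scores(c(2, 2, 2)), list(mean = 2, sd = 0))
  expect_identical(summarize_scores(c(1, -1))$mean, 0)
  s <- summarize_scores(c(rep(2, 8), rep(1, 7)))
  expect_equal(s$mean, 1.533, tolerance = 1e-3)
  expect_equal(s$sd, 0.516, tolerance = 1e-3)
  # the 15-rating multiset {nine 2s, five 1s, one 0} reproduces a reported
  # mean/SD pattern of 1.533 (0.639) under the sample-SD convention
  s2 <- summarize_scores(c(rep(2, 9), rep(1, 5), 0))
  expect_equal(round(s2$mean, 3), 1.533)
  expect_equal(round(s2$sd, 3), 0.64)
  pop <- summarize_scores(c(1, 2, 3), population = TRUE)
  expect_equal(pop$sd, sqrt(2 / 3), tolerance = 1e-12)
  expect_error(summarize_scores(numeric()), "no scores")
})

test_that("the exact Wilcoxon p matches sign-assignment enumeration", {
  expect_equal(wilcoxon_signed_rank_vs_zero(rep(1, 5))$p, 0.0625)
  expect_equal(wilcoxon_signed_rank_vs_zero(c(1, -1))$p, 1.0)
  # any all-positive vector of n >= 6 nonzero scores is significant
  expect_lt(wilcoxon_signed_rank_vs_zero(c(1, 2, 1, 2, 1, 2))$p, 0.05)
  # random small vectors against the brute-force oracle
  rng <- rng_stream(67, "fb.wilcox")
  for (i in 1:25) {
    n <- rng_int(rng, 3, 10)
    x <- rng_int(rng, n, 5) - 3L   # scores in -2..2
    if (all(x == 0L)) next
    got <- wilcoxon_signed_rank_vs_zero(x)$p
    expect_equal(got, wilcoxon_brute_p(x), tolerance = 1e-12)
  }
  expect_error(wilcoxon_signed_rank_vs_zero(c(0, 0)), "undefined")
})

test_that("the exact p is invariant under a global sign flip", {
  rng <- rng_stream(71, "fb.flip")
  for (i in 1:10) {
    x <- rng_int(rng, 8, 5) - 3L
    if (all(x == 0L)) next
    expect_equal(wilcoxon_signed_rank_vs_zero(x)$p,
                 wilcoxon_signed_rank_vs_zero(-x)$p, tolerance = 1e-12)
  }
})

test_that("exact and approximate branches agree closely on n = 15 vectors", {
  # tie-free data: the continuity-corrected normal approximation tracks the
  # exact enumeration tightly
  rng <- rng_stream(73, "fb.approx")
  for (i in 1:15) {
    x <- round(rng_unif(rng, 15) * 20 - 8, 3)
    x <- x[x != 0]
    exact <- wilcoxon_signed_rank_vs_zero(x, exact_limit = 25)$p
    approx <- wilcoxon_signed_rank_vs_zero(x, exact_limit = 0)$p
    expect_lt(abs(exact - approx), 0.02)
  }
  # heavily tied 5-point Likert scores make the null distribution coarse;
  # the approximation still lands within the discreteness of the exact law
  for (i in 1:15) {
    x <- rng_int(rng, 15, 5) - 3L
    x <- x[x != 0]
    if (length(x) < 5) next
    exact <- wilcoxon_signed_rank_vs_zero(x, exact_limit = 25)$p
    approx <- wilcoxon_signed_rank_vs_zero(x, exact_limit = 0)$p
    expect_lt(abs(exact - approx), 0.15)
  }
})

test_that("tie-free cases agree with the standard library test", {
  x <- c(2, 5, -3, 7, -1, 4, 6)
  got <- wilcoxon_signed_rank_vs_zero(x)
  ref <- stats::wilcox.test(x, mu = 0, exact = TRUE)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
})

test_that("percentages round ties away from zero as printed", {
  expect_identical(percent(11, 15), 73L)
  expect_identical(percent(7, 15), 47L)
  expect_identical(percent(0, 15), 0L)
  expect_identical(percent(1, 8), 13L)   # 12.5 rounds away from zero
  expect_error(percent(1, 0), "positive")
  expect_error(percent(5, 4), "\\[0, n\\]")
  # complement property
  for (n in c(8, 15, 20)) {
    for (k in 0:n) {
      s <- percent(k, n) + percent(n - k, n)
      expect_true(s %in% c(99L, 100L, 101L))
      if ((100 * k) %% n == 0) expect_identical(s, 100L)
    }
  }
})

test_that("the per-aspect feedback table aggregates correctly", {
  set.seed(1)
  users <- sprintf("u%02d", 1:15)
  tbl <- expand.grid(user_id = users, game = c("g1", "g2"),
                     aspect = c("instructions", "fun", "purpose"),
                     stringsAsFactors = FALSE)
  tbl$rating_label <- sample(c("strongly agree", "agree", "neutral"),
                             nrow(tbl), replace = TRUE)
  out <- analyze_feedback(tbl)
  expect_identical(nrow(out), 6L)
  expect_true(all(out$n == 15L))
  expect_true(all(out$p >= 0 & out$p <= 1))
  one <- out[out$game == "g1" & out$aspect == "fun", ]
  scores <- map_likert(tbl$rating_label[tbl$game == "g1" & tbl$aspect == "fun"])
  expect_equal(one$mean, mean(scores))
  # duplicate ratings rejected
  expect_error(analyze_feedback(rbind(tbl, tbl[1, ])), "one rating per")
})

test_that("multi-select summaries count and percentage each option", {
  tbl <- data.frame(user_id = sprintf("u%02d", 1:15),
                    understood = c(rep(TRUE, 11), rep(FALSE, 4)),
                    frustrated = c(rep(TRUE, 6), rep(FALSE, 9)))
  out <- summarize_multiselect(tbl)
  expect_identical(out$count[out$option == "understood"], 11L)
  expect_identical(out$percent[out$option == "understood"], 73L)
  expect_identical(out$percent[out$option == "frustrated"], 40L)
})
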