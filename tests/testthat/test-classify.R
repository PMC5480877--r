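# Derived statistics, thresholds, groups and bookkeeping.

test_that("binding calls are zero/positive and monotone", {
  expect_false(call_binding(0))
  expect_true(call_binding(1))
  expect_true(call_binding(350))
  expect_error(call_binding(-1), "negative")
  set.seed(3)
  reads <- sort(c(0, 0, rexp(20) * 100))
  calls <- call_binding(reads)
  expect_true(all(diff(calls) >= 0))  # once bound, stays bound
})

test_that("mean_plus_2sd matches a direct two-pass formula", {
  expect_equal(mean_plus_2sd(c(1, 1, 1)), 1)
  expect_equal(mean_plus_2sd(c(0, 10, 20)), 30)  # mean 10, sample SD 10
  expect_error(mean_plus_2sd(5), "2 values")
  set.seed(8)
  for (i in 1:5) {
    x <- rnorm(20, 50, 9)
    m <- sum(x) / length(x)
    s2 <- sum((x - m)^2) / (length(x) - 1)
    expect_equal(mean_plus_2sd(x), m + 2 * sqrt(s2))
  }
})

test_that("PolII and DHS group classifiers partition the line with
           boundaries in the lower group", {
  expect_equal(as.character(classify_polii(c(0, 100, 182, 183, -5), 182)),
               c("none", "low", "low", "high", "none"))
  expect_equal(as.character(classify_dhs(c(0.8, 1.0, 1.2, 1.35, 1.5), 1.35)),
               c("down", "up", "up", "up", "strong"))
  expect_error(classify_dhs(0), "positive")
  # totality: exactly one group for every value including boundaries
  set.seed(5)
  deltas <- c(-1e6, 0, 182, 1e6, rnorm(200, 0, 300))
  expect_false(anyNA(classify_polii(deltas, 182)))
  ratios <- c(1e-9, 1, 1.35, 100, rexp(200) + 0.01)
  expect_false(anyNA(classify_dhs(ratios, 1.35)))
})

test_that("dev_ratio applies the pseudocount and guards zero denominators", {
  expect_equal(dev_ratio(99, 9, 1), 10)
  expect_equal(dev_ratio(0, 0, 1), 1)  # no signal is neutral
  expect_error(dev_ratio(5, 0, 0), "denominator")
})

test_that("derive_stats computes the documented statistics", {
  raw <- matrix(0, 3, 13,
                dimnames = list(c("a", "b", "c"),
                                signature_features()$feature))
  raw["a", ] <- c(10, 20, 60, 199, 21, 100, 200, 500, 10, 300, 150, 160, 400)
  raw["b", ] <- c(50, 60, 62, 65, 66, 900, 800, 600, 20, 10, 0, 0, 0)
  raw["c", ] <- c(5, 9, 30, 99, 8, 100, 120, 139, 30, 130, 0, 0, 0)
  se <- SummarizedExperiment(assays = list(counts = raw, cpm = raw))
  st <- derive_stats(se, rod_thresholds(), preset = "fixed")
  expect_equal(st$k4_ratio, c(200 / 21, 66 / 61, 10))
  expect_equal(st$k4_rd1_depleted, c(TRUE, FALSE, TRUE))
  expect_equal(st$delta_polii, c(290, -10, 100))
  expect_equal(st$dhs_ratio, c(501 / 101, 601 / 901, 140 / 101))
  expect_equal(st$crx_bound, c(TRUE, FALSE, FALSE))
  expect_equal(st$nrl_bound, c(TRUE, FALSE, FALSE))
  expect_equal(as.character(st$polii_group), c("high", "none", "low"))
  expect_equal(as.character(st$dhs_group), c("strong", "down", "strong"))
  # data preset recomputes cutoffs as mean + 2 SD of the input set
  st2 <- derive_stats(se, rod_thresholds(), preset = "data")
  th <- attr(st2, "thresholds")
  expect_equal(th$t_polii, mean_plus_2sd(c(290, 100)))
  expect_equal(th$t_dhs_strong, mean_plus_2sd(st$dhs_ratio))
})

test_that("the rule-based rod call requires the chromatin gates but not
           the transcription factors", {
  base <- data.frame(tss_id = "x", k4_ratio = 10.1, k4_rd1_depleted = TRUE,
                     dhs_group = factor("strong",
                                        c("down", "up", "strong")),
                     crx_bound = TRUE, nrl_bound = TRUE,
                     polii_group = factor("high", c("none", "low", "high")))
  full <- classify_rod_signature(base, rod_thresholds())
  expect_equal(as.character(full$class), "rod")
  expect_equal(full$confidence, 1)
  # fails every gate
  none <- transform(base, k4_ratio = 1, dhs_group = factor("down",
                    c("down", "up", "strong")), crx_bound = FALSE,
                    nrl_bound = FALSE, polii_group = factor("none",
                    c("none", "low", "high")))
  expect_equal(as.character(classify_rod_signature(none)$class), "common")
  # no TF binding still gives rod, at lower confidence
  notf <- transform(base, crx_bound = FALSE, nrl_bound = FALSE)
  out <- classify_rod_signature(notf, rod_thresholds())
  expect_equal(as.character(out$class), "rod")
  expect_lt(out$confidence, full$confidence)
  # a missing statistic is an error
  expect_error(classify_rod_signature(base[, -2]), "k4_ratio")
})

test_that("summarize_groups reproduces printed count/percent bookkeeping", {
  expect_equal(summarize_groups(rep(c("b", "u"), c(55, 17)), "b"),
               c(count = 55, percent = 76))
  expect_equal(summarize_groups(rep(c("b", "u"), c(68, 4)), "b"),
               c(count = 68, percent = 94))
  expect_equal(summarize_groups(rep("u", 10), "b"), c(count = 0, percent = 0))
  expect_error(summarize_groups(character(), "b"), "empty")
  # percentages over all categories sum to 100 within rounding
  set.seed(9)
  for (i in 1:10) {
    labs <- sample(letters[1:4], sample(5:50, 1), replace = TRUE)
    gs <- group_summary(labs)
    expect_lte(abs(sum(gs$percent) - 100), 1)
  }
})

test_that("round_half_away rounds halves away from zero", {
  expect_equal(round_half_away(c(2.5, -2.5, 2.4, -2.4, 0.5)),
               c(3, -3, 2, -2, 1))
})

test_that("compare_groups is a two-tailed unpaired Student t-test", {
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3)), t.test(
    c(1, 2, 3), c(1, 2, 3), var.equal = TRUE)$p.value)
  expect_equal(compare_groups(c(5, 5, 5), c(5, 5)), 1)
  set.seed(12)
  a <- rnorm(50, 0, 1); b <- rnorm(50, 5, 1)
  expect_lt(compare_groups(a, b), 1e-6)
  expect_equal(compare_groups(a, b), compare_groups(b, a))
  # standard-formula oracle: pooled-variance t statistic
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(compare_groups(a, b),
               2 * pt(-abs(tstat), length(a) + length(b) - 2))
})

test_that("rule classification separates the synthetic classes on the
           derived ratios as reported", {
  s <- default_sim()
  st <- quiet(derive_stats(s$se, preset = "fixed"))
  truth <- setNames(s$sim$truth$tss$known_class, s$sim$truth$tss$tss_id)
  rodr <- st$k4_ratio[truth[st$tss_id] == "rod"]
  comr <- st$k4_ratio[truth[st$tss_id] == "common"]
  # the rod cohort sits several-fold above the common cohort and the
  # difference is highly significant on the log scale (ratios are
  # heavy-tailed, so the comparison is made on log-ratios)
  expect_gt(mean(rodr) / mean(comr), 3)
  expect_lt(compare_groups(log(rodr), log(comr)), 1e-4)
})
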