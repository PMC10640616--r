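test_that("population summary computes the reported statistics", {
  s <- summarize_population(rep(0.5, 12), target = 0.5)
  expect_equal(s$mean, 0.5)
  expect_equal(s$sd, 0)
  expect_equal(s$fraction_at_target, 1.0)
  # the 70%-at-target cohort shape: 70 cells at 1.0, 20 at 0.8, 10 at 0.5
  fr <- c(rep(1.0, 70), rep(0.8, 20), rep(0.5, 10))
  s2 <- summarize_population(fr, target = 1.0, tolerance = 0.1)
  expect_equal(s2$fraction_at_target, 0.70)
  expect_equal(s2$n, 100)
  expect_equal(s2$sem, stats::sd(fr) / 10)
  expect_equal(sum(s2$counts), 100)
  expect_error(summarize_population(numeric(0), 1))
})

test_that("summary matches a two-pass reference and is permutation invariant", {
  set.seed(5)
  fr <- stats::rlnorm(57, log(0.9), 0.2)
  s <- summarize_population(fr, 1.0)
  # two-pass reference computation
  m <- sum(fr) / length(fr)
  v <- sum((fr - m)^2) / (length(fr) - 1)
  expect_equal(s$mean, m, tolerance = 1e-12)
  expect_equal(s$sd, sqrt(v), tolerance = 1e-12)
  s2 <- summarize_population(sample(fr), 1.0)
  expect_equal(s2$mean, s$mean)
  expect_equal(s2$counts, s$counts)
})

test_that("fraction at target grows with tolerance", {
  set.seed(8)
  fr <- stats::runif(80, 0.3, 1.4)
  tols <- seq(0, 0.5, by = 0.05)
  fat <- vapply(tols, function(tl) {
    summarize_population(fr, 1.0, tolerance = tl)$fraction_at_target
  }, numeric(1))
  expect_true(all(diff(fat) >= 0))
})

test_that("histogram bins are anchored at 0 with sem-based width", {
  fr <- c(rep(1.0, 70), rep(0.8, 20), rep(0.5, 10))
  s <- summarize_population(fr, 1.0)
  expect_equal(s$bin_width, signif(stats::sd(fr) / 10, 1))
  expect_equal(s$breaks[1], 0)
  expect_equal(diff(s$breaks), rep(s$bin_width, length(s$breaks) - 1))
})

test_that("count error bars are sqrt(N) percent", {
  expect_equal(count_error_percent(100), 10)
  expect_equal(count_error_percent(87), sqrt(87))
  expect_equal(count_error_percent(0), 0)
})

test_that("activation curves aggregate per-level response fractions", {
  tr <- data.frame(level = c(1, 1, 1, 1, 2, 2), responded = c(TRUE, TRUE,
                                                              TRUE, FALSE,
                                                              TRUE, TRUE))
  ac <- activation_curve(tr, units = "V")
  expect_equal(ac$curve$fraction_percent, c(75, 100))
  expect_equal(ac$curve$n, c(4, 2))
  # all responded at one level -> exactly 100
  expect_equal(activation_curve(data.frame(level = 3, responded = TRUE))
               $curve$fraction_percent, 100)
  # monotone threshold model with noise stays in [0, 100]
  set.seed(2)
  lv <- rep(1:6, each = 8)
  resp <- stats::runif(48) < stats::plogis((lv - 3) * 2)
  ac2 <- activation_curve(data.frame(level = lv, responded = resp))
  expect_true(all(ac2$curve$fraction_percent >= 0 &
                    ac2$curve$fraction_percent <= 100))
})

test_that("equal-activation dose pairing interpolates both curves", {
  # synthetic linear curves: optical 10*level %, electrical 25*level %
  co <- activation_curve(data.frame(level = rep(1:10, each = 4),
                                    responded = rep(TRUE, 40)))
  co$curve$fraction_percent <- 10 * co$curve$level
  ce <- activation_curve(data.frame(level = rep(1:4, each = 4),
                                    responded = rep(TRUE, 16)))
  ce$curve$fraction_percent <- 25 * ce$curve$level
  tab <- pair_equivalent_doses(co, ce, targets = c(25, 50, 100))
  expect_equal(tab$level_optical, c(2.5, 5, 10))
  expect_equal(tab$level_electrical, c(1, 2, 4))
  # a target equal to a sampled point returns that sample exactly
  expect_equal(pair_equivalent_doses(co, ce, 75)$level_electrical, 3)
  expect_error(pair_equivalent_doses(co, ce, 150), "outside")
})

test_that("measured equivalence table pairs reproduce from exact curves", {
  # dose-response curves holding the measured pairing points:
  # 27% at 1 V / 3.4 mW/mm2, 90% at 2 V / 8.3, 100% at 3 V / 18.4
  co <- structure(list(curve = data.frame(
    level = c(1.2, 3.4, 8.3, 18.4, 25),
    fraction_percent = c(10, 27, 90, 100, 100), n = rep(8, 5)),
    units = "mW/mm^2"), class = "activation_curve")
  ce <- structure(list(curve = data.frame(
    level = c(0.5, 1, 2, 3), fraction_percent = c(5, 27, 90, 100),
    n = rep(8, 4)), units = "V"), class = "activation_curve")
  tab <- pair_equivalent_doses(co, ce, targets = c(27, 90, 100))
  expect_equal(tab$level_electrical, c(1, 2, 3))
  expect_equal(tab$level_optical, c(3.4, 8.3, 18.4))
})
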