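test_that("the unpaired t test matches the textbook formula", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4)
  got <- unpairedT(a, b)
  want <- textbookT(a, b)
  expect_equal(got$statistic, want$t)
  expect_equal(got$df1, want$df)
  expect_equal(got$p_value, want$p)

  # swapping groups flips the sign, p unchanged
  rev <- unpairedT(b, a)
  expect_equal(rev$statistic, -got$statistic)
  expect_equal(rev$p_value, got$p_value)

  # identical constant groups: t = 0, p = 1; unequal constants: error
  same <- unpairedT(c(2, 2, 2), c(2, 2))
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)
  expect_error(unpairedT(c(1, 1), c(2, 2)), "degenerate")

  # Welch flag reproduces the unequal-variance variant
  x <- c(1, 5, 9, 2); y <- c(2, 2.5, 3, 2.2, 2.8)
  expect_equal(unpairedT(x, y, welch = TRUE)$statistic,
               unname(t.test(x, y)$statistic))
  expect_error(unpairedT(1, c(1, 2)), "n >= 2")
})

test_that("two-way ANOVA agrees with hand-computed sums of squares", {
  # balanced 2x2 with two replicates per cell
  d <- data.frame(A = rep(c("a1", "a2"), each = 4),
                  B = rep(c("b1", "b2"), each = 2, times = 2),
                  y = c(3, 5, 6, 8, 7, 9, 12, 14))
  got <- twoWayAnova(d, "y", "A", "B")

  # manual two-way ANOVA arithmetic
  gm <- mean(d$y)
  cell <- tapply(d$y, list(d$A, d$B), mean)
  mA <- tapply(d$y, d$A, mean); mB <- tapply(d$y, d$B, mean)
  ssA <- 4 * sum((mA - gm)^2)
  ssB <- 4 * sum((mB - gm)^2)
  ssAB <- 2 * sum((cell - outer(mA - gm, mB - gm, "+") - gm)^2)
  ssE <- sum((d$y - cell[cbind(d$A, d$B)])^2)
  fs <- c(ssA / 1, ssB / 1, ssAB / 1) / (ssE / 4)
  expect_equal(got$statistic, fs)
  expect_equal(got$df1, c(1, 1, 1))
  expect_equal(got$df2, c(4, 4, 4))
  expect_equal(got$p_value, pf(fs, 1, 4, lower.tail = FALSE))

  expect_error(twoWayAnova(within(d, A <- "a1"), "y", "A", "B"), "levels")
  expect_error(twoWayAnova(d, "y", "A", "missing"), "not in data")
})

test_that("the repeated-measures route fits a subject random intercept", {
  withr::with_seed(13, {
    d <- expand.grid(subj = sprintf("s%02d", 1:12),
                     phase = c("pre", "post"), grp = c("ctl", "trt"))
    d <- d[!(d$subj %in% sprintf("s%02d", 1:6) & d$grp == "trt") &
             !(d$subj %in% sprintf("s%02d", 7:12) & d$grp == "ctl"), ]
    d$y <- rnorm(nrow(d)) + 2 * (d$subj %in% sprintf("s%02d", c(1, 3, 8)))
    # a subject removed mid-experiment leaves a missing cell
    d <- d[!(d$subj == "s01" & d$phase == "post"), ]
    got <- twoWayAnova(d, "y", "phase", "grp", subject = "subj",
                       repeatedOn = "phase")
    expect_identical(nrow(got), 3L)
    expect_identical(got$test, rep("mixed_effects_anova", 3))
    expect_true(all(is.finite(got$p_value)))
    expect_true(all(got$p_value >= 0 & got$p_value <= 1))
    expect_error(twoWayAnova(d, "y", "phase", "grp", repeatedOn = "phase"),
                 "subject")
  })
})

test_that("p-value adjustments follow their closed forms and ordering", {
  expect_identical(adjustP(0.01, "bonferroni", 4), 0.04)
  expect_equal(adjustP(0.01, "sidak", 4), 1 - 0.99^4)  # ~0.0394
  expect_identical(adjustP(0, "bonferroni", 7), 0)
  expect_identical(adjustP(0, "sidak", 7), 0)
  expect_identical(adjustP(0, "dunnett", 7), 0)
  expect_error(adjustP(0.5, "bonferroni", 0), "m must be")
  expect_error(adjustP(1.5, "sidak", 2), "p values")

  # adjusted p non-decreasing in m; never below the raw p
  p <- c(0.001, 0.01, 0.05, 0.2)
  for (method in c("bonferroni", "sidak")) {
    prev <- p
    for (m in 1:6) {
      cur <- adjustP(p, method, m)
      expect_true(all(cur >= prev - 1e-12))
      expect_true(all(cur >= p - 1e-12))  # sidak at m = 1 is p up to 1 ulp
      prev <- cur
    }
  }
  # Dunnett: between the raw p (m = 1) and the Bonferroni envelope
  for (m in c(2, 4)) {
    dn <- adjustP(p, "dunnett", m, df = 20)
    expect_true(all(dn >= p - 1e-6))
    expect_true(all(dn <= pmin(1, m * p) + 1e-6))
  }
  expect_equal(adjustP(0.03, "dunnett", 1, df = 20), 0.03,
               tolerance = 1e-6)
})
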