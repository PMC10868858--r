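test_that("hatching rates follow larvae over eggs with an unfertilized sentinel", {
  expect_equal(round(hatching_rate(55, 1), 4), 0.0182)
  expect_equal(hatching_rate(100, 0), 0)
  expect_equal(hatching_rate(80, 80), 1)
  expect_true(is.na(hatching_rate(0, 0)))
  expect_error(hatching_rate(10, 11), "larvae <= eggs")
})

test_that("the binomial LRT is null on equal groups and invariant to labels", {
  d <- data.frame(eggs = rep(50, 20), larvae = rep(25, 20),
                  grp = rep(c(TRUE, FALSE), 10))
  res <- lrt_presence_effect(d, "grp")
  expect_lt(res$value, 1e-8)
  expect_gt(res$p, 0.999)
  res_swap <- lrt_presence_effect(d, !d$grp)
  expect_equal(res$value, res_swap$value, tolerance = 1e-10)
  expect_gte(res$value, 0)
})

test_that("the LRT flags separation but still reports a statistic", {
  d <- data.frame(eggs = rep(40, 12),
                  larvae = c(rep(0, 6), rpois(6, 20)),
                  grp = rep(c(TRUE, FALSE), each = 6))
  res <- lrt_presence_effect(d, "grp")
  expect_true("separation" %in% res$flags)
  expect_gt(res$value, 10)
  expect_lt(res$p, 1e-3)
})

test_that("the LRT holds its nominal size under a binomial null", {
  rejections <- cidkit:::with_seed(91, vapply(1:200, function(i) {
    d <- data.frame(eggs = 30 + rpois(40, 25))
    d$larvae <- rbinom(40, d$eggs, 0.5)
    d$grp <- sample(rep(c(TRUE, FALSE), 20))
    lrt_presence_effect(d, "grp")$p < 0.05
  }, TRUE))
  expect_lt(abs(mean(rejections) - 0.05), 0.045)
})

test_that("Spearman association handles perfect and constant covariates", {
  hr <- c(0.1, 0.4, 0.2, 0.9, 0.6, 0.3)
  expect_equal(spearman_assoc(hr, hr)$value, 1)
  expect_equal(spearman_assoc(hr, -hr)$value, -1)
  expect_error(spearman_assoc(hr, rep(2, 6)), "constant")
  sims <- cidkit:::with_seed(92, vapply(1:300, function(i)
    spearman_assoc(runif(58), runif(58))$value, 1))
  expect_lt(abs(mean(sims)), 2 * sd(sims) / sqrt(length(sims)) + 0.01)
})

test_that("the Levene test detects spread differences and stays calibrated", {
  g1 <- c(0.5, 0.52, 0.48, 0.51, 0.49, 0.5)
  expect_lt(levene_compare(list(g1, g1))$value, 1e-8)

  power <- cidkit:::with_seed(93, vapply(1:100, function(i) {
    a <- rnorm(30, 0.5, 0.05)
    b <- median(a) + (rnorm(30, 0.5, 0.05) - 0.5) * 3
    levene_compare(list(a, b))$p < 0.01
  }, TRUE))
  expect_gte(mean(power), 0.95)

  size <- cidkit:::with_seed(94, vapply(1:200, function(i) {
    levene_compare(list(rnorm(30), rnorm(30)))$p < 0.05
  }, TRUE))
  expect_lt(abs(mean(size) - 0.05), 0.045)
  expect_error(levene_compare(list(g1, c(1, 2))), "at least 3")
})

test_that("levene_compare agrees with a direct deviation-ANOVA oracle", {
  set.seed(95)
  a <- rnorm(25); b <- rnorm(25, 0, 2)
  res <- levene_compare(list(a, b))
  dev <- c(abs(a - median(a)), abs(b - median(b)))
  g <- factor(rep(1:2, each = 25))
  oracle <- anova(lm(dev ~ g))
  expect_equal(res$value, oracle[1, "F value"], tolerance = 1e-10)
  expect_equal(res$p, oracle[1, "Pr(>F)"], tolerance = 1e-10)
})
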