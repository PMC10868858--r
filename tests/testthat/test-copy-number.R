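test_that("the worked two-variant copy split resolves to (2, 1)", {
  est <- integerize_copies(3.0, c("cidA-III-α(5)-25" = 32000,
                                  "cidA-III-γ(3)-12" = 10800))
  expect_equal(unname(est$composition), c(2L, 1L))
  expect_equal(est$total, 3L)
  expect_false(est$ambiguous)
})

test_that("compositions match the exhaustive enumeration oracle", {
  set.seed(61)
  for (i in 1:200) {
    k <- sample(2:3, 1)
    total <- sample(k:6, 1)
    counts <- setNames(rpois(k, lambda = sample(c(50, 500, 5000), 1)) + 1,
                       paste0("v", sample(letters, k)))
    est <- integerize_copies(total, counts)
    expect_equal(est$composition, oracle_integerize(total, counts))
    expect_equal(sum(est$composition), total)
  }
})

test_that("degenerate and flagged cases behave as documented", {
  expect_equal(unname(integerize_copies(4.0, c(v = 900))$composition), 4L)
  # exact (2,1,1,1) proportions at total 5
  est <- integerize_copies(5.0, c(a = 2000, b = 1000, c = 1000, d = 1000))
  expect_equal(unname(est$composition), c(2L, 1L, 1L, 1L))
  expect_true(integerize_copies(3.4, c(a = 10, b = 5))$ambiguous)
  expect_false(integerize_copies(2.9, c(a = 10, b = 5))$ambiguous)
  expect_error(integerize_copies(2.0, c(a = 5, b = 5, c = 5)),
               "total below variant count")
})

test_that("genotype classification follows marker presence", {
  expect_equal(classify_genotype(2.1, 0.9), "(β+,16+)")
  expect_equal(classify_genotype(1.05, 0.02), "(β+,16-)")
  expect_equal(classify_genotype(0.0, 0.0), "(β-,16-)")
  expect_equal(classify_genotype(0.1, 1.2), "inconsistent")
})

test_that("the mixture screen distinguishes bimodal from unimodal totals", {
  x_bi <- cidkit:::with_seed(62, c(rnorm(30, 3, 0.3), rnorm(30, 5, 0.3)))
  fit <- detect_coinfection(x_bi)
  expect_equal(fit$verdict, "multimodal")
  expect_lt(abs(min(fit$means) - 3), 0.2)
  expect_lt(abs(max(fit$means) - 5), 0.2)

  x_uni <- cidkit:::with_seed(63, rnorm(60, 4, 0.3))
  expect_equal(detect_coinfection(x_uni)$verdict, "unimodal")
  expect_error(detect_coinfection(rnorm(10)), "at least 20")
})

test_that("replicate agreement returns signed perfect correlations", {
  x <- c(4.2, 5.1, 4.8, 5.5, 4.9)
  expect_equal(replicate_agreement(x, x)$value, 1)
  expect_equal(replicate_agreement(x, -x)$value, -1)
  expect_error(replicate_agreement(x, rep(1, 5)), "zero variance")
})
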