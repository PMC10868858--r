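test_that("incompatible crosses hatch nothing without leakage", {
  cr <- simulate_crosses(BMM, IST, n_females = 40, leak_prob = 0, seed = 31)
  expect_true(all(cr$hr == 0))
  expect_true(all(cr$larvae == 0))
})

test_that("compatible crosses hatch with overdispersed rates", {
  cr <- simulate_crosses(B16PP, IST, n_females = 60, seed = 32)
  expect_true(all(cr$hr >= 0 & cr$hr <= 1))
  expect_gt(mean(cr$hr > 0), 0.9)
  expect_gt(sd(cr$hr), 0.1)  # raft-level heterogeneity, not binomial noise
  expect_true(all(cr$larvae <= cr$eggs))
  expect_true(all(cr$eggs >= 30))
})

test_that("a forced leak yields a single larva", {
  cr <- simulate_crosses(BMM, IST, n_females = 20, leak_prob = 1, seed = 33)
  expect_true(all(cr$larvae == 1))
  expect_equal(cr$hr, 1 / cr$eggs)
  # a 55-egg raft with one larva gives the 1.8% hatch rate
  expect_equal(round(1 / 55, 4), 0.0182)
})

test_that("cross simulation is deterministic and genotype-labelled", {
  c1 <- simulate_crosses(B16PM, IST, n_females = 10, seed = 34)
  c2 <- simulate_crosses(B16PM, IST, n_females = 10, seed = 34)
  expect_identical(c1, c2)
  expect_true(all(c1$female_genotype == "(β+,16-)"))
  expect_true(all(c1$male_line == "Ist"))
})

test_that("tandem loss lineages stay viable and track the loss rate", {
  lin0 <- simulate_tandem_loss(B16PM, 10, loss_rate = 0, seed = 35)
  expect_true(all(vapply(lin0$repertoires, function(r)
    identical(names(r$tandems), names(B16PM$tandems)), TRUE)))

  lin <- simulate_tandem_loss(BMM, 200, loss_rate = 0.05, seed = 36)
  # every surviving repertoire is self-compatible (no uncovered toxin)
  expect_true(all(vapply(lin$repertoires, function(r)
    predict_cross(r, r)$compatible, TRUE)))
  # realized per-copy loss frequency across many independent
  # one-generation proposals from a five-copy founder sits within 3 SE
  # of the nominal rate (long single lineages are absorbed at one copy,
  # where the viability screen forbids further loss)
  tallies <- vapply(1:1500, function(s) {
    l <- simulate_tandem_loss(B16PM, 1, loss_rate = 0.05, seed = 1000 + s)
    c(attr(l, "lost"), attr(l, "at_risk"))
  }, c(0, 0))
  p_hat <- sum(tallies[1, ]) / sum(tallies[2, ])
  se <- sqrt(0.05 * 0.95 / sum(tallies[2, ]))
  expect_lt(abs(p_hat - 0.05), 3 * se + 1e-6)
})

test_that("losing the two extra tandems of (β+,16-) leaves the minimal viable repertoire", {
  remaining <- B16PM$tandems[c("cidA-III-α(5)-25_cidB-III-ae3",
                               "cidA-III-γ(3)-12_cidB-III-ag1")]
  reduced <- repertoire(unname(remaining), label = "(β-,16-)")
  expect_setequal(names(reduced$tandems), names(BMM$tandems))
  expect_true(predict_cross(reduced, reduced)$compatible)
  expect_error(simulate_tandem_loss(IST, 5, 0.1,
                                    binding = binding_matrix(data.frame(
                                      a_up = "x", a_down = "x", b_up = "x",
                                      b_down = "x", binds = TRUE))),
               "not self-compatible")
})
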