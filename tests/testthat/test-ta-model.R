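test_that("the default binding rules encode partner and recombinant binding", {
  m <- default_binding_matrix()
  beta25 <- cid_variant("cidA", "III", reg("cidA", "upstream", "β(2)"),
                        reg("cidA", "downstream", "25"))
  alpha25 <- cid_variant("cidA", "III", reg("cidA", "upstream", "α(5)"),
                         reg("cidA", "downstream", "25"))
  tox2 <- cid_variant("cidB", "IV", reg("cidB", "upstream", "ak"),
                      reg("cidB", "downstream", "2"))
  ae3 <- cid_variant("cidB", "III", reg("cidB", "upstream", "ae"),
                     reg("cidB", "downstream", "3"))
  expect_true(binds(beta25, tox2, m))      # recombinant for recombinant
  expect_false(binds(alpha25, tox2, m))    # alpha cannot rescue the 2-toxin
  expect_true(binds(alpha25, ae3, m))      # tandem-partner pair
  expect_false(binds(beta25, ae3, m))
})

test_that("cross predictions reproduce the genotype-compatibility map", {
  expect_false(predict_cross(BMM, IST)$compatible)
  expect_equal(predict_cross(BMM, IST)$uncovered, "cidB-IV-ak2")
  expect_true(predict_cross(B16PM, IST)$compatible)
  expect_true(predict_cross(B16PP, IST)$compatible)
  # directionality: the reverse cross stays incompatible
  expect_false(predict_cross(IST, B16PP)$compatible)
  # every preset is self-compatible and Slab lines are mutually compatible
  for (r in list(BMM, B16PM, B16PP, IST))
    expect_true(predict_cross(r, r)$compatible)
  for (f in list(BMM, B16PM, B16PP)) for (m in list(BMM, B16PM, B16PP))
    expect_true(predict_cross(f, m)$compatible)
})

test_that("adding an antidote never breaks compatibility (monotonicity)", {
  extra <- B16PP$tandems[["cidA-III-β(2)-25_cidB-III-ae3"]]
  for (f in list(BMM, B16PM, B16PP)) {
    for (m in list(BMM, B16PM, B16PP, IST)) {
      before <- predict_cross(f, m)$compatible
      aug <- if (extra$name %in% names(f$tandems)) f else
        repertoire(c(unname(f$tandems), list(extra)), label = f$label)
      after <- predict_cross(aug, m)$compatible
      expect_true(!before || after)
    }
  }
})

test_that("concordance tables count predicted versus observed CI", {
  gmap <- list("(β+,16+)" = B16PP, "(β+,16-)" = B16PM, "(β-,16-)" = BMM)
  panel <- simulate_study_panel(10, 4, 8, male_rep = IST, library = LIB,
                                leak_prob = 0, seed = 81)
  conc <- concordance_table(panel, IST, genotype_map = gmap)
  expect_length(conc$mismatches, 0)
  expect_equal(conc$table["incompatible", "incompatible"], 8)
  expect_equal(sum(conc$table), 22)

  # with leak_max = 0 a single-larva leak becomes the one mismatch
  leak <- simulate_crosses(BMM, IST, n_females = 1, leak_prob = 1, seed = 82)
  leak$eggs <- 55L; leak$larvae <- 1L; leak$hr <- 1 / 55  # the 1.8% raft
  panel2 <- rbind(panel, leak)
  panel2$female_id <- sprintf("F%04d", seq_len(nrow(panel2)))
  conc2 <- concordance_table(panel2, IST, genotype_map = gmap, leak_max = 0)
  expect_length(conc2$mismatches, 1)
  # at the default leak_max = 0.02 the 1.8% leak is absorbed
  conc3 <- concordance_table(panel2, IST, genotype_map = gmap)
  expect_length(conc3$mismatches, 0)

  # unresolvable genotypes are skipped with a warning
  panel2$female_genotype[1] <- "mystery"
  expect_warning(conc4 <- concordance_table(panel2, IST, genotype_map = gmap),
                 "skipped")
  expect_equal(conc4$skipped, 1L)
})

test_that("binding matrices round-trip through CSV", {
  m <- default_binding_matrix()
  path <- tempfile(fileext = ".csv")
  write_binding_matrix(m, path)
  m2 <- read_binding_matrix(path)
  expect_equal(m$rules, m2$rules)
})
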