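test_that("exact reads map to their entry at distance zero", {
  dbA <- build_reference_db(known_slab_variants, "cidA")
  e <- dbA$entries[[3]]
  asg <- assign_reads(e$seq, dbA)
  expect_equal(asg$assignments$entry, e$name)
  expect_equal(asg$assignments$dist, 0L)
})

test_that("equidistant reads are discarded, not randomly assigned", {
  a <- reg("cidA", "upstream", "α(5)")
  g <- reg("cidA", "upstream", "γ(3)")
  d25 <- reg("cidA", "downstream", "25")
  v1 <- cid_variant("cidA", "III", a, d25)
  v2 <- cid_variant("cidA", "III", g, d25)
  db <- build_reference_db(list(v1, v2), "cidA")
  # construct a read exactly equidistant from both references: flip half
  # of the divergent positions toward v2; with an odd divergence count,
  # set one divergent position to a third base (mismatching both)
  c1 <- strsplit(v1$seq, "")[[1]]
  c2 <- strsplit(v2$seq, "")[[1]]
  diffs <- which(c1 != c2)
  ch <- c1
  if (length(diffs) %% 2 == 1) {
    odd <- diffs[length(diffs)]
    ch[odd] <- setdiff(c("A", "C", "G", "T"), c(c1[odd], c2[odd]))[1]
    diffs <- diffs[-length(diffs)]
  }
  flip <- diffs[seq_len(length(diffs) / 2)]
  ch[flip] <- c2[flip]
  read <- paste(ch, collapse = "")
  expect_equal(as.integer(adist(read, v1$seq)), as.integer(adist(read, v2$seq)))
  asg <- assign_reads(read, db)
  expect_true(is.na(asg$assignments$entry))
  expect_equal(asg$assignments$reason, "tie")
})

test_that("distant reads are discarded by the distance ceiling", {
  dbA <- build_reference_db(known_slab_variants, "cidA")
  junk <- paste(sample(c("A", "C", "G", "T"), 1400, TRUE), collapse = "")
  asg <- assign_reads(junk, dbA, max_dist_frac = 0.15)
  expect_true(is.na(asg$assignments$entry))
  expect_equal(asg$assignments$reason, "too_distant")
})

test_that("noisy reads are assigned to their source variant", {
  reads <- simulate_amplicon_reads(BMM, "cidA", 2000, error_rate = 0.05,
                                   bias_sd = 0.3, seed = 41)
  dbA <- build_reference_db(known_slab_variants, "cidA")
  asg <- assign_reads(reads, dbA)
  acc <- mean(asg$assignments$entry == asg$assignments$truth, na.rm = TRUE)
  expect_gte(acc, 0.95)
  # error-free reads recover truth for 100% of reads
  clean <- simulate_amplicon_reads(BMM, "cidA", 500, error_rate = 0,
                                   bias_sd = 0, seed = 42)
  asg0 <- assign_reads(clean, dbA)
  expect_true(all(asg0$assignments$entry == asg0$assignments$truth))
})

test_that("projected scoring reproduces the exact-distance assignment", {
  dbA <- build_reference_db(known_slab_variants, "cidA")
  reads <- simulate_amplicon_reads(B16PP, "cidA", 25, error_rate = 0.05,
                                   bias_sd = 0, seed = 43)
  eseqs <- vapply(dbA$entries, `[[`, "", "seq")
  d_oracle <- adist(reads$seq, eseqs)       # utils::adist, independent route
  best_oracle <- apply(d_oracle, 1, which.min)
  asg <- assign_reads(reads, dbA)
  # the argmin entry agrees with the exact-distance oracle
  expect_equal(asg$assignments$entry, names(dbA$entries)[best_oracle])
  # the projected score is a tight upper bound on the exact distance:
  # it is the cost of a valid alignment (the anchor path), so it can
  # exceed the optimum only where a read indel hits a divergence column
  d_exact <- d_oracle[cbind(seq_len(nrow(reads)), best_oracle)]
  expect_true(all(asg$assignments$dist >= d_exact))
  expect_true(all(asg$assignments$dist - d_exact <= 5))
  # and it is exact for error-free reads
  clean <- simulate_amplicon_reads(B16PP, "cidA", 20, error_rate = 0,
                                   bias_sd = 0, seed = 45)
  asg0 <- assign_reads(clean, dbA)
  expect_equal(asg0$assignments$dist,
               as.integer(apply(adist(clean$seq, eseqs), 1, min)))
})

test_that("coverage fractions sum to one over covered entries", {
  reads <- simulate_amplicon_reads(B16PP, "cidAB", 400, 0.05, 0.3, seed = 44)
  asg <- assign_reads(reads, slab_cidab_db)
  cov <- asg$coverage
  expect_equal(sum(cov$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(cov$count), attr(cov, "n_assigned"))
})
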