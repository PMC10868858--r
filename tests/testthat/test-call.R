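test_that("the minimum-fraction threshold filters and renormalizes calls", {
  cov <- fake_coverage(c("v1", "v2", "v3"), c(7400, 2500, 100))
  calls <- call_repertoire(cov, min_fraction = 0.05)
  expect_equal(nrow(calls), 2)
  expect_equal(sum(calls$fraction), 1, tolerance = 1e-12)
  # single-variant repertoire: one call with fraction 1
  cov1 <- fake_coverage("v1", 500)
  calls1 <- call_repertoire(cov1)
  expect_equal(calls1$fraction, 1)
  # nothing above threshold -> no call
  covx <- fake_coverage(c("a", "b", "c"), c(10, 10, 10))
  expect_error(call_repertoire(covx, min_fraction = 0.5), "no call")
})

test_that("retained in-silico entries are flagged as novel combinations", {
  cov <- fake_coverage(c("v1", "v2"), c(700, 300),
                       provenance = c("known", "in_silico"))
  calls <- call_repertoire(cov)
  expect_equal(calls$novel[calls$entry == "v2"], TRUE)
  expect_equal(calls$novel[calls$entry == "v1"], FALSE)
})

test_that("novel-SNP screening separates signal from the error floor", {
  e <- repertoire_variants(BMM, "cidA")[[1]]
  reads <- simulate_amplicon_reads(BMM, "cidA", 220, error_rate = 0.05,
                                   bias_sd = 0, seed = 51)
  reads <- reads[reads$truth == e$name, ]
  rep_ok <- detect_novel_snps(reads, e$seq, err_rate = 0.05, min_reads = 100)
  expect_equal(rep_ok$status, "ok")
  expect_equal(nrow(rep_ok$snps), 0)

  # a fixed novel SNP: consensus differs from the reference at 1 position
  mut <- e$seq
  substr(mut, 700, 700) <- setdiff(c("A", "C", "G", "T"),
                                   substr(e$seq, 700, 700))[1]
  reads2 <- data.frame(id = sprintf("r%03d", 1:120), seq = rep(mut, 120))
  rep2 <- detect_novel_snps(reads2, e$seq, err_rate = 0.05)
  expect_equal(rep2$snps$column, 700)
  expect_equal(hamming(rep2$consensus, e$seq), 1L)

  # coverage below min_reads -> no call
  expect_equal(detect_novel_snps(reads2[1:10, ], e$seq)$status, "no_call")
})

test_that("a 50:50 mixture with two linked SNPs phases into two haplotypes", {
  e <- repertoire_variants(BMM, "cidA")[[1]]
  mut <- e$seq
  for (p in c(300, 900))
    substr(mut, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substr(e$seq, p, p))[1]
  reads <- cidkit:::with_seed(52, {
    half <- lapply(1:120, function(i)
      cidkit:::cpp_mutate_read(if (i %% 2 == 0) e$seq else mut,
                               0.03, 60, 20, 20))
    data.frame(id = sprintf("r%03d", 1:120), seq = unlist(half))
  })
  rep3 <- detect_novel_snps(reads, e$seq, err_rate = 0.03)
  expect_true(all(c(300, 900) %in% rep3$snps$column))
  expect_length(rep3$haplotypes, 2)
  expect_true(any(rep3$haplotypes == e$seq))
  expect_true(any(rep3$haplotypes == mut))
})

test_that("tandem reconstruction keeps pairings and flags unpaired variants", {
  cov <- fake_coverage(c("a1_b1", "a2_b2"), c(600, 400), mode = "cidAB")
  cidA_calls <- data.frame(entry = c("a1", "a2"))
  cidB_calls <- data.frame(entry = c("b1", "b2"))
  td <- reconstruct_tandems(cidA_calls, cidB_calls, cov)
  expect_equal(nrow(td), 2)
  expect_length(attr(td, "unpaired"), 0)

  cidA_calls2 <- data.frame(entry = c("a1", "a2", "a3"))
  expect_warning(td2 <- reconstruct_tandems(cidA_calls2, cidB_calls, cov),
                 "unpaired")
  expect_equal(attr(td2, "unpaired"), "a3")

  cov1 <- fake_coverage("a1_b1", 500, mode = "cidAB")
  td1 <- reconstruct_tandems(data.frame(entry = "a1"),
                             data.frame(entry = "b1"), cov1)
  expect_equal(td1$fraction, 1)
})

test_that("single-gene and tandem coverages agree after marginalization", {
  # the worked coverage comparison: tandem counts (10800, 32000) vs
  # single-gene counts (3000, 10000)
  cov_t <- fake_coverage(c("cidA-III-γ(3)-12_cidB-III-ag1",
                           "cidA-III-α(5)-25_cidB-III-ae3"),
                         c(10800, 32000), mode = "cidAB")
  cov_s <- fake_coverage(c("cidA-III-γ(3)-12", "cidA-III-α(5)-25"),
                         c(3000, 10000))
  cons <- check_amplicon_consistency(cov_s, cov_t, "cidA")
  expect_lt(abs(cons$max_delta - 0.021), 0.001)
  expect_true(cons$pass)

  cons0 <- check_amplicon_consistency(cov_s,
                                      fake_coverage(c("cidA-III-γ(3)-12_x",
                                                      "cidA-III-α(5)-25_y"),
                                                    c(3000, 10000),
                                                    mode = "cidAB"), "cidA")
  expect_equal(cons0$max_delta, 0)

  cov_bad <- fake_coverage(c("cidA-III-γ(3)-12_x", "cidA-III-α(5)-25_y"),
                           c(9000, 1000), mode = "cidAB")
  cons_bad <- check_amplicon_consistency(cov_s, cov_bad, "cidA")
  expect_false(cons_bad$pass)
  expect_error(check_amplicon_consistency(cov_s,
                                          fake_coverage("z1_z2", 10,
                                                        mode = "cidAB"),
                                          "cidA"),
               "share no variant")
})
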