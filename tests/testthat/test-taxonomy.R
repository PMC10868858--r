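test_that("snp_distance counts mismatch columns and separates indel events", {
  a <- reg("cidA", "upstream", "α(5)")
  expect_equal(as.integer(snp_distance(a, a)), 0L)
  # three scattered substitutions
  ch <- strsplit(a$seq, "")[[1]]
  for (p in c(10, 400, 790))
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  a3 <- region_seq("a3", "cidA", "upstream", paste(ch, collapse = ""))
  expect_equal(as.integer(snp_distance(a, a3)), 3L)
  expect_equal(as.integer(snp_distance(a3, a)), 3L)  # symmetric
  # a 3-nt insertion is one indel event, zero SNPs
  ins <- region_seq("ins", "cidA", "upstream",
                    paste0(substr(a$seq, 1, 500), "TTT",
                           substr(a$seq, 501, 800)))
  d <- snp_distance(a, ins)
  expect_equal(as.integer(d), 0L)
  expect_equal(attr(d, "indels"), 1L)
  expect_error(snp_distance(a, reg("cidB", "upstream", "ae")), "same gene")
})

test_that("snp_distance equals the column-count oracle on random pairs", {
  set.seed(71)
  base <- reg("cidA", "downstream", "25")
  for (i in 1:25) {
    r1 <- perturb_region(base, sample(0:10, 1), "r1")
    r2 <- perturb_region(base, sample(0:10, 1), "r2")
    oracle <- sum(strsplit(r1$seq, "")[[1]] != strsplit(r2$seq, "")[[1]])
    expect_equal(as.integer(snp_distance(r1, r2)), oracle)
  }
})

test_that("single-linkage clustering groups regions within the SNP threshold", {
  a <- reg("cidA", "upstream", "α(5)")
  g <- reg("cidA", "upstream", "γ(3)")
  b <- reg("cidA", "upstream", "β(2)")
  set.seed(72)
  # an alpha-like chain of 5 members, each within 3 SNPs of the previous
  chain <- list(a)
  for (i in 2:5) chain[[i]] <- perturb_region(chain[[i - 1]], 2,
                                              paste0("a", i))
  regions <- c(chain, list(g), list(b))
  cl <- cluster_regions(regions, threshold = 3)
  expect_length(cl$clusters, 3)
  sizes <- sort(vapply(cl$clusters, length, 1L), decreasing = TRUE)
  expect_equal(unname(sizes), c(5L, 1L, 1L))
  # biggest cluster gets the first Greek label and indexed member names
  big <- names(which.max(vapply(cl$clusters, length, 1L)))
  expect_equal(big, "α")
  expect_equal(sum(grepl("^α\\(", cl$assignments$new_name)), 5)

  # identical sequences collapse into one cluster
  dup <- region_seq("dup", "cidA", "upstream", a$seq)
  expect_length(cluster_regions(list(a, dup))$clusters, 1)
  # threshold 0: clusters are identical-sequence groups
  expect_length(cluster_regions(list(a, dup, g), threshold = 0)$clusters, 2)
  expect_error(cluster_regions(list(a, reg("cidB", "upstream", "ae"))),
               "single gene")
})

test_that("clustering is permutation invariant", {
  set.seed(73)
  a <- reg("cidA", "upstream", "α(5)")
  members <- c(list(a, reg("cidA", "upstream", "γ(3)"),
                    reg("cidA", "upstream", "β(2)")),
               lapply(1:4, function(i) perturb_region(a, 3, paste0("p", i))))
  cl1 <- cluster_regions(members)
  cl2 <- cluster_regions(rev(members))
  expect_identical(cl1$assignments[order(cl1$assignments$region), ],
                   cl2$assignments[order(cl2$assignments$region), ])
})

test_that("canonical names render with group substitution and cidB fusion", {
  up <- reg("cidA", "upstream", "α(5)")
  down <- reg("cidA", "downstream", "25")
  v3 <- cid_variant("cidA", "III", up, down)
  v4 <- cid_variant("cidA", "IV", up, down)
  expect_equal(name_variant(v3), "cidA-III-α(5)-25")
  expect_equal(name_variant(v4), "cidA-IV-α(5)-25")
  vb <- cid_variant("cidB", "III", reg("cidB", "upstream", "ae"),
                    reg("cidB", "downstream", "3"))
  expect_equal(name_variant(vb), "cidB-III-ae3")
  un <- region_seq("x", "cidA", "upstream", up$seq)  # no cluster label
  expect_error(name_variant(cid_variant("cidA", "III", un, down)),
               "unclustered")
})

test_that("mosaic regions are called with ordered parents and clean controls", {
  a <- reg("cidA", "upstream", "α(5)")
  g <- reg("cidA", "upstream", "γ(3)")
  b <- reg("cidA", "upstream", "β(2)")
  call <- detect_recombinant(b, list(a, g))
  expect_false(is.null(call))
  expect_equal(call$parent1, "α(5)")
  expect_equal(call$parent2, "γ(3)")
  expect_equal(call$unexplained, 0)
  # the breakpoint lies between the last parental difference before 400
  # and the first at/after 400 (exhaustive construction check)
  diffs <- which(strsplit(a$seq, "")[[1]] != strsplit(g$seq, "")[[1]])
  expect_gt(call$breakpoint, max(diffs[diffs < 400]))
  expect_lte(call$breakpoint, min(diffs[diffs >= 400]))

  # cidB downstream-2 is a mosaic of regions 1 and 3
  call_b <- detect_recombinant(reg("cidB", "downstream", "2"),
                               list(reg("cidB", "downstream", "1"),
                                    reg("cidB", "downstream", "3")))
  expect_equal(call_b$parent1, "1")
  expect_equal(call_b$parent2, "3")

  # a plain cluster member is never called
  set.seed(74)
  member <- perturb_region(a, 2, "a2")
  expect_null(detect_recombinant(member, list(a, g)))
  expect_error(detect_recombinant(b, list(a)), "at least 2")
})

test_that("interface peptides translate and slice correctly", {
  expect_equal(as.character(interface_peptide("ATGGCTTGA", c(1, 2))), "MA")
  expect_error(interface_peptide("ATGGCTTGA", c(1, 10)), "outside")
  expect_true(attr(interface_peptide("ATGGCTTGA", c(1, 3)), "stop_codon"))
  # the mosaic's interface peptide is a mosaic of the parents' peptides
  a <- cid_variant("cidA", "III", reg("cidA", "upstream", "α(5)"),
                   reg("cidA", "downstream", "25"))
  g <- cid_variant("cidA", "III", reg("cidA", "upstream", "γ(3)"),
                   reg("cidA", "downstream", "25"))
  b <- cid_variant("cidA", "III", reg("cidA", "upstream", "β(2)"),
                   reg("cidA", "downstream", "25"))
  w <- c(100, 160)  # aa window spanning the nt-400 breakpoint (aa 134)
  pa <- interface_peptide(a, w); pg <- interface_peptide(g, w)
  pb <- interface_peptide(b, w)
  split_aa <- ceiling((400 - 1) / 3) - w[1] + 1
  expect_equal(substr(pb, 1, split_aa - 1), substr(pa, 1, split_aa - 1))
  expect_equal(substr(pb, split_aa + 1, nchar(pb)),
               substr(pg, split_aa + 1, nchar(pg)))
})
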