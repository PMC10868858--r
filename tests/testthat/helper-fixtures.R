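# Shared fixtures: the study-system region library and preset
# repertoires are deterministic, so build them once per test run.

LIB <- default_region_library()
B16PP <- build_preset_repertoire("SLAB_B16PP", LIB)
B16PM <- build_preset_repertoire("SLAB_B16PM", LIB)
BMM <- build_preset_repertoire("SLAB_BMM", LIB)
IST <- build_preset_repertoire("IST", LIB)

reg <- function(gene, role, name) LIB[[paste(gene, role, name, sep = "/")]]

# All distinct known variants across the Slab presets (the reference
# universe for calling).
known_slab_variants <- local({
  vs <- unlist(lapply(list(B16PP, B16PM, BMM), function(r)
    c(repertoire_variants(r, "cidA"), repertoire_variants(r, "cidB"))),
    recursive = FALSE)
  vs[!duplicated(vapply(vs, `[[`, "", "name"))]
})

# cidAB reference database spanning all in-silico combinations.
slab_cidab_db <- local({
  dbA <- build_reference_db(known_slab_variants, "cidA")
  dbB <- build_reference_db(known_slab_variants, "cidB")
  build_reference_db(c(lapply(dbA$entries, `[[`, "variant"),
                       lapply(dbB$entries, `[[`, "variant")), "cidAB")
})

# Independent exhaustive oracle for the integer-composition argmax:
# enumerate every composition with expand.grid and score the multinomial
# log-likelihood directly.
oracle_integerize <- function(total, counts) {
  k <- length(counts)
  ord <- order(names(counts))
  n <- counts[ord]
  grid <- do.call(expand.grid, rep(list(seq_len(total)), k))
  grid <- grid[rowSums(grid) == total, , drop = FALSE]
  ll <- as.matrix(log(grid)) %*% n
  best <- which(ll == max(ll))
  if (length(best) > 1) {
    key <- apply(grid[best, , drop = FALSE], 1, paste, collapse = ",")
    best <- best[order(key)][1]
  }
  comp <- as.integer(grid[best[1], ])
  names(comp) <- names(n)
  comp[names(counts)]
}

# Build a small coverage table by hand.
fake_coverage <- function(entries, counts, provenance = "known",
                          mode = "cidA") {
  out <- data.frame(entry = entries, count = counts,
                    fraction = counts / sum(counts),
                    provenance = rep(provenance, length.out = length(entries)),
                    stringsAsFactors = FALSE)
  attr(out, "n_assigned") <- sum(counts)
  attr(out, "n_discarded") <- 0L
  attr(out, "mode") <- mode
  class(out) <- c("cid_coverage", "data.frame")
  out
}
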