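# End-to-end composition: reads + qPCR -> repertoire -> genotypes ->
# coinfection screen -> TA predictions vs observed crosses -> statistics.

#' Infer a cid repertoire from tandem-amplicon reads and a qPCR total
#'
#' Builds the in-silico reference space from the known variants (all
#' upstream x downstream combinations per gene, then all cidA x cidB
#' pairings for the tandem amplicon), assigns the reads by minimal edit
#' distance, calls the tandem pairings present, and fuses the coverage
#' fractions with the continuous qPCR copy total into integer per-tandem
#' copy numbers.
#'
#' @param reads `cid_reads` from the cidAB amplicon.
#' @param known list of known `cid_variant`s (both genes).
#' @param total_cont continuous cidA copies/genome from qPCR.
#' @param min_fraction coverage call threshold.
#' @param max_dist_frac assignment distance ceiling.
#' @return An object of class `cid_inference`: `tandem_calls` (with a
#'   `copies` column), `total`, `cidA_copies`, `cidB_copies` (named
#'   integer vectors), `coverage`, `ambiguous`.
#' @export
infer_repertoire <- function(reads, known, total_cont, min_fraction = 0.05,
                             max_dist_frac = 0.15) {
  dbA <- build_reference_db(known, "cidA")
  dbB <- build_reference_db(known, "cidB")
  universe <- c(lapply(dbA$entries, `[[`, "variant"),
                lapply(dbB$entries, `[[`, "variant"))
  dbAB <- build_reference_db(universe, "cidAB")
  asg <- assign_reads(reads, dbAB, max_dist_frac = max_dist_frac)
  calls <- call_repertoire(asg$coverage, min_fraction)
  counts <- setNames(calls$count, calls$entry)
  est <- integerize_copies(total_cont, counts)
  parts <- strsplit(calls$entry, "_", fixed = TRUE)
  tandem_calls <- data.frame(
    tandem = calls$entry,
    cidA = vapply(parts, `[[`, "", 1),
    cidB = vapply(parts, `[[`, "", 2),
    fraction = calls$fraction,
    copies = as.integer(est$composition[calls$entry]),
    stringsAsFactors = FALSE)
  agg <- function(by) {
    v <- tapply(tandem_calls$copies, tandem_calls[[by]], sum)
    setNames(as.integer(v), names(v))
  }
  structure(list(tandem_calls = tandem_calls, total = est$total,
                 cidA_copies = agg("cidA"), cidB_copies = agg("cidB"),
                 coverage = asg$coverage, ambiguous = est$ambiguous),
            class = "cid_inference")
}

#' @export
print.cid_inference <- function(x, ...) {
  cat(sprintf("<cid_inference> %d tandem copies over %d pairing(s)%s\n",
              x$total, nrow(x$tandem_calls),
              if (x$ambiguous) " (total ambiguous)" else ""))
  print(x$tandem_calls, row.names = FALSE)
  invisible(x)
}

#' Line-level qPCR copy total pooled over individuals
#'
#' Simulates triplicate relative qPCR on `n_females` individuals of a
#' line and returns the mean per-individual copies/genome estimate --
#' the line-level total used for integerisation, mirroring the practice
#' of quantifying several females per line to beat replicate-level qPCR
#' noise.
#'
#' @param rep the line's `cid_repertoire`.
#' @param marker marker for [marker_copies()].
#' @param n_females individuals pooled (default 8).
#' @param noise_sd Cq-scale replicate noise.
#' @param efficiency amplification efficiency.
#' @param seed RNG seed.
#' @return Numeric mean estimate with attribute `per_female`.
#' @export
simulate_line_total <- function(rep, marker = "cidA", n_females = 8,
                                noise_sd = 0.2, efficiency = 1, seed = NULL) {
  with_seed(seed, {
    ests <- vapply(seq_len(n_females), function(i) {
      pair <- simulate_qpcr_run(rep, marker, efficiency = efficiency,
                                noise_sd = noise_sd,
                                sample_id = sprintf("f%02d", i))
      as.numeric(qpcr_copy_estimate(pair$target, pair$reference))
    }, 1)
    structure(mean(ests), per_female = ests)
  })
}

#' Run the full synthetic analysis pipeline
#'
#' Simulate -> call -> copy numbers -> genotype classification ->
#' coinfection screen -> TA predictions vs observed crosses -> hatch-rate
#' statistics, under one master seed.  The report records the resolved
#' configuration, so a fixed seed reproduces it byte for byte.
#'
#' @param config a [run_config()].
#' @return A list of class `cid_report` with sections `config`,
#'   `lines` (per-line inference summaries), `genotype_counts`,
#'   `coinfection`, `concordance`, `stats`, `taxonomy`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "cid_config"))
  with_seed(config$seed, {
    lib <- default_region_library()
    presets <- c("SLAB_B16PP", "SLAB_B16PM", "SLAB_BMM")
    reps <- lapply(presets, build_preset_repertoire, library = lib)
    names(reps) <- vapply(reps, `[[`, "", "label")
    ist <- build_preset_repertoire("IST", lib)
    known <- unlist(lapply(reps, function(r)
      c(repertoire_variants(r, "cidA"), repertoire_variants(r, "cidB"))),
      recursive = FALSE)
    known <- known[!duplicated(vapply(known, `[[`, "", "name"))]

    # per-line repertoire inference from cidAB reads + pooled qPCR
    lines <- lapply(reps, function(r) {
      reads <- simulate_amplicon_reads(r, "cidAB", config$n_reads,
                                       config$error_rate, config$bias_sd)
      total <- simulate_line_total(r, "cidA", config$n_qpcr_females,
                                   config$qpcr_noise_sd)
      inf <- infer_repertoire(reads, known, as.numeric(total),
                              min_fraction = config$min_fraction)
      list(label = r$label, truth_total = total_copies(r),
           inferred_total = inf$total,
           tandem_calls = inf$tandem_calls,
           recovered = setequal(inf$tandem_calls$tandem, names(r$tandems)) &&
             inf$total == total_copies(r))
    })

    # female panel: marker quantifications, genotypes, crosses
    panel <- simulate_study_panel(config$n_b16pp, config$n_b16pm,
                                  config$n_bmm, male_rep = ist, library = lib,
                                  leak_prob = config$leak_prob,
                                  qpcr_noise_sd = config$qpcr_noise_sd)
    panel$genotype_call <- mapply(classify_genotype, panel$cidA_beta,
                                  panel$cidA_16,
                                  MoreArgs = list(presence_threshold =
                                                    config$presence_threshold))
    genotype_counts <- table(panel$genotype_call)

    coinf <- detect_coinfection(panel$cidA_total)
    conc <- concordance_table(panel, ist,
                              genotype_map = setNames(reps, names(reps)),
                              leak_max = config$leak_max)

    compat <- panel[which(!is.na(panel$hr) & panel$hr > config$leak_max), ]
    stats <- list(
      beta_presence = lrt_presence_effect(panel, panel$cidA_beta >
                                            config$presence_threshold),
      hr_vs_infection = spearman_assoc(compat$hr, compat$infection),
      hr_vs_cidA_total = spearman_assoc(compat$hr, compat$cidA_total))

    # taxonomy: cluster the library's cidA upstream regions and scan the
    # non-trivial ones for mosaic origin
    ups <- Filter(function(r) r$gene == "cidA" && r$role == "upstream", lib)
    clus <- cluster_regions(unname(ups), threshold = config$snp_threshold)
    recomb <- Filter(Negate(is.null), lapply(ups, function(child)
      detect_recombinant(child, unname(ups[vapply(ups, `[[`, "", "name") !=
                                             child$name]),
                         tol = config$recomb_tol,
                         cluster_threshold = config$snp_threshold)))

    report <- structure(list(config = unclass(config), lines = lines,
                             genotype_counts = genotype_counts,
                             coinfection = coinf, concordance = conc,
                             stats = stats,
                             taxonomy = list(clustering = clus,
                                             recombinants = recomb),
                             panel = panel),
                        class = "cid_report")
    if (!is.null(config$out_dir)) write_report(report, config$out_dir)
    report
  })
}

#' @export
print.cid_report <- function(x, ...) {
  cat("<cid_report>\n")
  cat("  lines recovered:",
      paste(sprintf("%s=%s", vapply(x$lines, `[[`, "", "label"),
                    vapply(x$lines, `[[`, TRUE, "recovered")),
            collapse = ", "), "\n")
  cat("  genotypes:", paste(sprintf("%s:%d", names(x$genotype_counts),
                                    as.integer(x$genotype_counts)),
                            collapse = ", "), "\n")
  cat("  coinfection screen:", x$coinfection$verdict, "\n")
  cat("  concordance mismatches:", length(x$concordance$mismatches), "\n")
  invisible(x)
}

#' Write a pipeline report to disk (JSON summary + CSV tables)
#'
#' @param report a `cid_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(
    config = report$config,
    lines = lapply(report$lines, function(l)
      list(label = l$label, truth_total = l$truth_total,
           inferred_total = l$inferred_total, recovered = l$recovered)),
    genotype_counts = as.list(report$genotype_counts),
    coinfection = list(verdict = report$coinfection$verdict,
                       k = report$coinfection$k,
                       means = report$coinfection$means),
    concordance = list(table = as.vector(report$concordance$table),
                       mismatches = report$concordance$mismatches),
    stats = lapply(report$stats, function(s)
      list(name = s$name, value = s$value, p = s$p, n = s$n)))
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_cross_table(report$panel, file.path(dir, "panel.csv"))
  for (l in report$lines)
    write.csv(l$tandem_calls,
              file.path(dir, paste0("tandems_", gsub("[^A-Za-z0-9+-]", "",
                                                     l$label), ".csv")),
              row.names = FALSE)
  invisible(dir)
}
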