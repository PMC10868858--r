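# File formats: FASTA/FASTQ via Biostrings, CSV tables for qPCR runs and
# cross outcomes, YAML run configuration.

#' Read a FASTA file
#'
#' @param path file path.
#' @return Named character vector of upper-cased sequences (names are the
#'   full headers).  Mixed-case input is upper-cased with a warning;
#'   duplicate ids are an error; an empty file yields an empty vector.
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0) return(setNames(character(0), character(0)))
  x <- Biostrings::readBStringSet(path, format = "fasta")
  seqs <- as.character(x)
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (any(grepl("[a-z]", seqs))) {
    warning("mixed-case sequences upper-cased")
    seqs <- toupper(seqs)
  }
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector (names become headers).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Export / import a reference database as FASTA
#'
#' Headers carry the structured fields `name|mode|provenance` plus the
#' component region or variant names, pipe-separated, so the database
#' round-trips losslessly.
#'
#' @param db a `cid_refdb`.
#' @param path file path.
#' @return For the reader, a `cid_refdb`.
#' @export
write_reference_db <- function(db, path) {
  headers <- vapply(db$entries, function(e) {
    extra <- if (db$mode == "cidAB") c(e$a_name, e$b_name)
    else c(e$up_name, e$down_name)
    paste(c(e$name, db$mode, e$provenance, extra), collapse = "|")
  }, "")
  write_fasta(setNames(vapply(db$entries, `[[`, "", "seq"), headers), path)
}

#' @rdname write_reference_db
#' @export
read_reference_db <- function(path) {
  seqs <- read_fasta(path)
  fields <- strsplit(names(seqs), "|", fixed = TRUE)
  mode <- unique(vapply(fields, `[[`, "", 2))
  if (length(mode) != 1) stop("mixed reference modes in ", path)
  entries <- Map(function(f, s) {
    e <- list(name = f[1], seq = unname(s), provenance = f[3])
    if (mode == "cidAB") { e$a_name <- f[4]; e$b_name <- f[5] }
    else { e$up_name <- f[4]; e$down_name <- f[5] }
    e
  }, fields, seqs)
  names(entries) <- vapply(entries, `[[`, "", "name")
  structure(list(mode = mode, entries = entries), class = "cid_refdb")
}

#' Write simulated reads as FASTQ
#'
#' Quality is a constant Phred score encoding the simulation error rate,
#' `Q = round(-10 log10(error_rate))` (capped at 40 for error-free
#' reads).
#'
#' @param reads a `cid_reads` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  err <- attr(reads, "error_rate") %||% 0.05
  q <- if (err <= 0) 40L else min(40L, as.integer(round(-10 * log10(err))))
  qchar <- rawToChar(as.raw(q + 33L))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(reads))) {
    writeLines(c(paste0("@", reads$id[i]), reads$seq[i], "+",
                 strrep(qchar, nchar(reads$seq[i]))), con)
  }
  invisible(path)
}

#' Read amplicon reads (FASTQ or FASTA)
#'
#' @param path file path.
#' @param format `"fastq"` or `"fasta"`.
#' @return A `cid_reads` data.frame (`id`, `seq`).
#' @export
read_reads <- function(path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  x <- Biostrings::readBStringSet(path, format = format)
  out <- data.frame(id = names(x), seq = toupper(as.character(x)),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("cid_reads", "data.frame")
  out
}

#' Write / read qPCR runs as CSV
#'
#' Layout: `sample,target,cq1,cq2,cq3,efficiency`, one row per run.
#'
#' @param runs list of `cid_qpcr` (or `cid_qpcr_pair`, which are
#'   flattened).
#' @param path file path.
#' @return For the reader, a list of `cid_qpcr`.
#' @export
write_qpcr_csv <- function(runs, path) {
  flat <- list()
  for (r in runs) {
    if (inherits(r, "cid_qpcr_pair")) flat <- c(flat, list(r$target, r$reference))
    else flat <- c(flat, list(r))
  }
  df <- do.call(rbind, lapply(flat, function(r)
    data.frame(sample = r$sample_id, target = r$target,
               cq1 = r$cq[1], cq2 = r$cq[2], cq3 = r$cq[3],
               efficiency = r$efficiency, stringsAsFactors = FALSE)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_qpcr_csv
#' @export
read_qpcr_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    qpcr_run(df$sample[i], df$target[i],
             c(df$cq1[i], df$cq2[i], df$cq3[i]), df$efficiency[i]))
}

#' Read a cross-outcome table
#'
#' Accepts the individual-female cross layout: one row per female with at
#' least `eggs` and `larvae`; optional `female_id`, `female_genotype`,
#' `male_line`, `hr`, `fertilized` (or an `NF` marker in the `hr`
#' column), marker quantification and infection columns.  The hatching
#' rate is recomputed and checked against the file's `hr` column within
#' 0.005 (per-row warning beyond that); rows with `larvae > eggs` are
#' rejected with their row number; unfertilized rows are flagged and
#' excluded from hatch-rate analyses downstream.
#'
#' @param path CSV path.
#' @return A `cid_crosses` data.frame.
#' @export
read_cross_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("eggs", "larvae")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  nf <- rep(FALSE, nrow(df))
  if ("hr" %in% names(df) && is.character(df$hr)) {
    nf <- toupper(trimws(df$hr)) == "NF"
    df$hr <- suppressWarnings(as.numeric(df$hr))
  }
  if ("fertilized" %in% names(df)) {
    df$fertilized <- as.logical(df$fertilized)
  } else {
    df$fertilized <- !nf
  }
  df$larvae[!df$fertilized & is.na(df$larvae)] <- 0L
  bad <- which(!is.na(df$larvae) & !is.na(df$eggs) & df$larvae > df$eggs)
  if (length(bad)) stop("larvae > eggs in row(s): ", paste(bad, collapse = ", "))
  hr_calc <- hatching_rate(df$eggs, ifelse(is.na(df$larvae), 0L, df$larvae))
  if ("hr" %in% names(df)) {
    chk <- which(df$fertilized & !is.na(df$hr) &
                   abs(df$hr - hr_calc) > 0.005)
    for (i in chk)
      warning("row ", i, ": stated HR ", df$hr[i],
              " disagrees with larvae/eggs = ", round(hr_calc[i], 4))
  }
  df$hr <- ifelse(df$fertilized, hr_calc, NA_real_)
  if (!"female_id" %in% names(df))
    df$female_id <- sprintf("F%04d", seq_len(nrow(df)))
  class(df) <- c("cid_crosses", "data.frame")
  df
}

#' Write a cross-outcome table as CSV
#' @param records a `cid_crosses` data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_cross_table <- function(records, path) {
  write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects the seeds and thresholds of a full synthetic run; serializes
#' losslessly to YAML.  The amplicon boundaries are the 1-based
#' downstream starts (801 for cidA, 1201 for cidB); internally all
#' interval arithmetic is 0-based half-open with the conversion at the
#' I/O edge.
#'
#' @param seed master RNG seed.
#' @param n_reads cidAB reads per line.
#' @param error_rate read error rate.
#' @param bias_sd per-tandem amplification bias log-SD.
#' @param qpcr_noise_sd Cq-scale replicate noise.
#' @param n_qpcr_females individuals pooled per line-level copy estimate.
#' @param min_fraction coverage call threshold.
#' @param presence_threshold genotype marker presence cutoff (copies).
#' @param snp_threshold nomenclature clustering threshold (SNPs).
#' @param recomb_tol unexplained-SNP tolerance for recombination calls.
#' @param leak_max hatch-rate ceiling for observed incompatibility.
#' @param n_b16pp,n_b16pm,n_bmm panel genotype mix.
#' @param leak_prob single-larva leak probability.
#' @param boundaries named 1-based downstream starts per gene.
#' @param interface_coords illustrative interface-I window (aa).
#' @param out_dir optional output directory for report files.
#' @return A list of class `cid_config`.
#' @export
run_config <- function(seed = 1, n_reads = 20000, error_rate = 0.05,
                       bias_sd = 0.3, qpcr_noise_sd = 0.2,
                       n_qpcr_females = 8, min_fraction = 0.05,
                       presence_threshold = 0.5, snp_threshold = 3,
                       recomb_tol = 1, leak_max = 0.02,
                       n_b16pp = 58, n_b16pm = 8, n_bmm = 23,
                       leak_prob = 0.04,
                       boundaries = c(cidA = 801, cidB = 1201),
                       interface_coords = c(10, 60), out_dir = NULL) {
  cfg <- list(seed = seed, n_reads = n_reads, error_rate = error_rate,
              bias_sd = bias_sd, qpcr_noise_sd = qpcr_noise_sd,
              n_qpcr_females = n_qpcr_females, min_fraction = min_fraction,
              presence_threshold = presence_threshold,
              snp_threshold = snp_threshold, recomb_tol = recomb_tol,
              leak_max = leak_max, n_b16pp = n_b16pp, n_b16pm = n_b16pm,
              n_bmm = n_bmm, leak_prob = leak_prob,
              boundaries = as.list(boundaries),
              interface_coords = as.numeric(interface_coords),
              out_dir = out_dir)
  stopifnot(cfg$min_fraction > 0, cfg$min_fraction < 1,
            cfg$error_rate >= 0, cfg$error_rate < 0.2,
            cfg$leak_max >= 0, cfg$leak_max < 1)
  class(cfg) <- "cid_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}
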