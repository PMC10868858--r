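# Repertoire calling from coverage tables: thresholding, novel-SNP
# screening with haplotype phasing, tandem reconstruction from the cidAB
# amplicon, and the single-vs-tandem consistency check.

#' Call the variants present in a repertoire from a coverage table
#'
#' Entries whose fraction of assigned reads reaches `min_fraction` are
#' retained and their fractions renormalized.  Retained in-silico entries
#' are flagged as novel combinations.
#'
#' @param cov a `cid_coverage` with at least one assigned read.
#' @param min_fraction minimal raw fraction for a call (default 0.05; the
#'   smallest true per-copy fraction in a five-copy repertoire is 0.2, so
#'   this leaves ample margin for amplification bias while suppressing
#'   chimeric noise).
#' @return A data.frame of class `cid_calls`: `entry`, `count`,
#'   `fraction` (renormalized), `novel`.
#' @export
call_repertoire <- function(cov, min_fraction = 0.05) {
  if (attr(cov, "n_assigned") %||% sum(cov$count) < 1)
    stop("coverage table has no assigned reads")
  keep <- cov$count > 0 & cov$fraction >= min_fraction
  if (!any(keep)) stop("no entry reaches min_fraction: no call")
  out <- cov[keep, c("entry", "count", "fraction"), drop = FALSE]
  out$fraction <- out$fraction / sum(out$fraction)
  out$novel <- cov$provenance[keep] == "in_silico"
  out <- out[order(-out$fraction), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mode") <- attr(cov, "mode")
  class(out) <- c("cid_calls", "data.frame")
  out
}

#' Screen reads assigned to one reference entry for novel SNPs
#'
#' Reads are aligned to the entry and stacked into reference columns; a
#' column is reported as a novel SNP when its most frequent
#' non-reference base exceeds `3 * err_rate` (a conservative noise
#' ceiling for a per-position error process).  When at least two novel
#' biallelic columns have minor-allele frequency above `minor_freq`,
#' alleles are linked by per-read co-occurrence (agreement > `agree`
#' places them on the same haplotype) and split haplotype calls are
#' emitted.
#'
#' @param reads character vector or `cid_reads` of reads assigned to the
#'   entry.
#' @param entry reference sequence (character scalar).
#' @param err_rate assumed per-position error rate of the reads.
#' @param min_reads minimal coverage to attempt a call (default 100).
#' @param minor_freq minimal minor-allele frequency for phasing.
#' @param agree per-read co-occurrence agreement above which two columns
#'   are phased together.
#' @param band alignment band half-width.
#' @return A list of class `cid_snp_report`: `status` (`"ok"` or
#'   `"no_call"`), `consensus`, `snps` (data.frame `column`, `ref`,
#'   `alt`, `freq`), `haplotypes` (character vector of phased sequences).
#' @export
detect_novel_snps <- function(reads, entry, err_rate = 0.05, min_reads = 100,
                              minor_freq = 0.2, agree = 0.8, band = 64L) {
  if (inherits(reads, "data.frame")) reads <- reads$seq
  if (length(reads) < min_reads)
    return(structure(list(status = "no_call", consensus = NULL,
                          snps = NULL, haplotypes = NULL),
                     class = "cid_snp_report"))
  m <- nchar(entry)
  ref_codes <- cpp_encode(entry)
  proj <- matrix(0L, nrow = length(reads), ncol = m)
  for (i in seq_along(reads))
    proj[i, ] <- banded_align_auto(reads[i], entry, band)$proj
  bases <- c("A", "C", "G", "T")
  # per-column base frequencies among reads contributing a base
  freq <- sapply(1:4, function(b) colSums(proj == b))
  depth <- rowSums(freq)                       # per column
  freq <- freq / pmax(depth, 1L)
  major_code <- max.col(freq, ties.method = "first")
  # top non-reference allele per column
  nonref <- freq
  nonref[cbind(seq_len(m), ref_codes)] <- 0
  alt_code <- max.col(nonref, ties.method = "first")
  alt_freq <- nonref[cbind(seq_len(m), alt_code)]
  novel <- which(alt_freq > 3 * err_rate & depth > 0)
  consensus <- paste(bases[major_code], collapse = "")
  snps <- data.frame(column = novel, ref = bases[ref_codes[novel]],
                     alt = bases[alt_code[novel]],
                     freq = alt_freq[novel], stringsAsFactors = FALSE)
  haplotypes <- character(0)
  phase <- snps[snps$freq > minor_freq & snps$freq < 1 - minor_freq, ,
                drop = FALSE]
  if (nrow(phase) >= 2) {
    linked <- TRUE
    for (i in seq_len(nrow(phase) - 1)) {
      c1 <- phase$column[i]; c2 <- phase$column[i + 1]
      a1 <- proj[, c1] == cpp_encode(phase$alt[i])[1]
      a2 <- proj[, c2] == cpp_encode(phase$alt[i + 1])[1]
      use <- proj[, c1] != 0L & proj[, c2] != 0L
      agreement <- mean(a1[use] == a2[use])
      if (is.na(agreement) || agreement <= agree) linked <- FALSE
    }
    if (linked) {
      ch <- strsplit(entry, "", fixed = TRUE)[[1]]
      hap_ref <- paste(ch, collapse = "")
      ch[phase$column] <- phase$alt
      haplotypes <- c(hap_ref, paste(ch, collapse = ""))
    }
  }
  structure(list(status = "ok", consensus = consensus, snps = snps,
                 haplotypes = haplotypes),
            class = "cid_snp_report")
}

#' @export
print.cid_snp_report <- function(x, ...) {
  if (x$status == "no_call") {
    cat("<cid_snp_report> no call (coverage below threshold)\n")
  } else {
    cat(sprintf("<cid_snp_report> %d novel SNP column(s), %d phased haplotype(s)\n",
                nrow(x$snps), length(x$haplotypes)))
    if (nrow(x$snps)) print(x$snps, row.names = FALSE)
  }
  invisible(x)
}

#' Reconstruct cidA-cidB tandems from tandem-amplicon coverage
#'
#' Pairings whose coverage fraction reaches `min_fraction` are retained;
#' every called cidA and cidB variant must appear in at least one
#' retained pairing, otherwise it is flagged as unpaired.
#'
#' @param cidA_calls,cidB_calls `cid_calls` from the single-gene
#'   amplicons (entry names are variant names).
#' @param tandem_cov `cid_coverage` over a cidAB reference database.
#' @param min_fraction retention threshold.
#' @return A data.frame of class `cid_tandem_calls` (`tandem`, `cidA`,
#'   `cidB`, `count`, `fraction`), with attribute `unpaired` listing
#'   called variants missing from all retained pairings.
#' @export
reconstruct_tandems <- function(cidA_calls, cidB_calls, tandem_cov,
                                min_fraction = 0.05) {
  calls <- call_repertoire(tandem_cov, min_fraction)
  parts <- strsplit(calls$entry, "_", fixed = TRUE)
  out <- data.frame(tandem = calls$entry,
                    cidA = vapply(parts, `[[`, "", 1),
                    cidB = vapply(parts, `[[`, "", 2),
                    count = calls$count, fraction = calls$fraction,
                    stringsAsFactors = FALSE)
  unpaired <- c(setdiff(cidA_calls$entry, out$cidA),
                setdiff(cidB_calls$entry, out$cidB))
  if (length(unpaired))
    warning("called variant(s) unpaired in tandem coverage: ",
            paste(unpaired, collapse = ", "))
  attr(out, "unpaired") <- unpaired
  class(out) <- c("cid_tandem_calls", "data.frame")
  out
}

#' Consistency of single-gene and tandem amplicon coverages
#'
#' Marginalizes the tandem coverage to one gene (a variant's fraction is
#' the sum of the fractions of the tandems containing it) and compares
#' with the single-gene coverage fractions.
#'
#' @param cov_single `cid_coverage` (or `cid_calls`) from the single-gene
#'   amplicon.
#' @param cov_tandem `cid_coverage` from the cidAB amplicon.
#' @param gene which component to marginalize to (`"cidA"` or `"cidB"`).
#' @param tol pass tolerance on the maximal per-variant fraction
#'   difference (default 0.15).
#' @return A list of class `cid_consistency`: `delta` (named per-variant
#'   |difference|), `max_delta`, `pass`.
#' @export
check_amplicon_consistency <- function(cov_single, cov_tandem,
                                       gene = c("cidA", "cidB"), tol = 0.15) {
  gene <- match.arg(gene)
  if (!nrow(cov_single) || !nrow(cov_tandem)) stop("empty coverage table")
  single <- cov_single[cov_single$count > 0, , drop = FALSE]
  sfrac <- single$count / sum(single$count)
  names(sfrac) <- single$entry
  tand <- cov_tandem[cov_tandem$count > 0, , drop = FALSE]
  comp <- vapply(strsplit(tand$entry, "_", fixed = TRUE), `[[`, "",
                 if (gene == "cidA") 1L else 2L)
  tfrac <- tapply(tand$count / sum(tand$count), comp, sum)
  shared <- intersect(names(sfrac), names(tfrac))
  if (!length(shared))
    stop("single and tandem coverages share no variant")
  all_v <- union(names(sfrac), names(tfrac))
  delta <- abs(ifelse(is.na(sfrac[all_v]), 0, sfrac[all_v]) -
                 ifelse(is.na(tfrac[all_v]), 0, tfrac[all_v]))
  names(delta) <- all_v
  structure(list(delta = delta, max_delta = max(delta),
                 pass = max(delta) <= tol),
            class = "cid_consistency")
}

#' @export
print.cid_consistency <- function(x, ...) {
  cat(sprintf("<cid_consistency> max |delta fraction| = %.3f -> %s\n",
              x$max_delta, if (x$pass) "pass" else "FAIL"))
  invisible(x)
}
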