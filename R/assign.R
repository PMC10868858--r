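# Reference-based read assignment by minimal edit distance.
#
# References inside one database are same-length amplicons sharing a
# constant backbone, so a read is aligned once (banded global alignment
# with traceback) against an anchor entry and every other entry is scored
# from the projected alignment at the columns where it diverges from the
# anchor.  This reproduces the per-entry Levenshtein distance except in
# rare corner cases where a read indel falls on a divergence column, and
# turns an O(entries x length^2) problem into one banded alignment per
# read.  Databases with unequal entry lengths fall back to per-entry
# alignment.

# Exact banded alignment with automatic band widening: the band is
# doubled until the optimal path no longer touches the band boundary.
banded_align_auto <- function(read, ref, band = 64L) {
  repeat {
    res <- cpp_banded_align(read, ref, band)
    if (!res$edge || band >= max(nchar(read), nchar(ref))) return(res)
    band <- band * 2L
  }
}

#' Exact edit (Levenshtein) distance between two sequences
#'
#' @param a,b character scalars.
#' @return Integer distance.
#' @export
edit_distance <- function(a, b) {
  banded_align_auto(a, b)$dist
}

#' Assign amplicon reads to reference entries
#'
#' Each read is assigned to the database entry at minimal edit distance.
#' Reads whose best distance exceeds `max_dist_frac` times the read
#' length, or whose two best distances tie, are discarded (ties are never
#' broken at random, so coverage is seed-independent).
#'
#' @param reads a `cid_reads` data.frame (columns `id`, `seq`) or a
#'   character vector of sequences.
#' @param db a `cid_refdb`.
#' @param max_dist_frac maximal best distance as a fraction of read
#'   length (default 0.15).
#' @param band initial alignment band half-width (widened automatically
#'   whenever the optimal path touches the band boundary, so results are
#'   exact regardless of the start value).
#' @return A list of class `cid_assignment`: `assignments` (data.frame
#'   `id`, `entry`, `dist`, `reason`) and `coverage` (a `cid_coverage`
#'   data.frame: `entry`, `count`, `fraction`, `provenance`, with
#'   attributes `n_assigned` and `n_discarded`).
#' @export
assign_reads <- function(reads, db, max_dist_frac = 0.15, band = 16L) {
  stopifnot(inherits(db, "cid_refdb"), length(db$entries) >= 1)
  if (is.character(reads))
    reads <- data.frame(id = sprintf("read%06d", seq_along(reads)),
                        seq = reads, stringsAsFactors = FALSE)
  n <- nrow(reads)
  enames <- names(db$entries)
  eseqs <- vapply(db$entries, `[[`, "", "seq")
  same_len <- length(unique(nchar(eseqs))) == 1L
  entry <- rep(NA_character_, n)
  bestd <- rep(NA_integer_, n)
  reason <- rep("assigned", n)

  if (same_len && length(eseqs) > 1) {
    res <- cpp_assign_batch(reads$seq, unname(eseqs), max_dist_frac, band)
    entry <- enames[res$entry]
    bestd <- ifelse(is.na(res$entry), NA_integer_, res$dist)
    reason <- c("assigned", "tie", "too_distant")[res$reason + 1L]
  } else {
    for (i in seq_len(n)) {
      d <- vapply(eseqs, function(s) banded_align_auto(reads$seq[i], s, band)$dist,
                  1L)
      o <- order(d)
      if (length(d) > 1 && d[o[1]] == d[o[2]]) {
        reason[i] <- "tie"
      } else if (d[o[1]] > max_dist_frac * nchar(reads$seq[i])) {
        reason[i] <- "too_distant"
      } else {
        entry[i] <- enames[o[1]]
        bestd[i] <- d[o[1]]
      }
    }
  }
  assignments <- data.frame(id = reads$id, entry = entry, dist = bestd,
                            reason = reason, stringsAsFactors = FALSE)
  if ("truth" %in% names(reads)) assignments$truth <- reads$truth
  cov <- coverage_table(assignments, db)
  structure(list(assignments = assignments, coverage = cov),
            class = "cid_assignment")
}

#' Build a coverage table from read assignments
#'
#' @param assignments data.frame with an `entry` column (`NA` =
#'   discarded).
#' @param db the `cid_refdb` the reads were assigned against.
#' @return A `cid_coverage` data.frame (`entry`, `count`, `fraction`,
#'   `provenance`); fractions sum to 1 over entries with nonzero count.
#' @export
coverage_table <- function(assignments, db) {
  enames <- names(db$entries)
  counts <- table(factor(assignments$entry, levels = enames))
  n_assigned <- sum(counts)
  out <- data.frame(entry = enames, count = as.integer(counts),
                    fraction = if (n_assigned > 0)
                      as.integer(counts) / n_assigned else 0,
                    provenance = vapply(db$entries, `[[`, "", "provenance"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_assigned") <- n_assigned
  attr(out, "n_discarded") <- sum(is.na(assignments$entry))
  attr(out, "mode") <- db$mode
  class(out) <- c("cid_coverage", "data.frame")
  out
}

#' @export
print.cid_assignment <- function(x, ...) {
  cat(sprintf("<cid_assignment> %d assigned, %d discarded\n",
              attr(x$coverage, "n_assigned"), attr(x$coverage, "n_discarded")))
  print(x$coverage[x$coverage$count > 0, ], row.names = FALSE)
  invisible(x)
}
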