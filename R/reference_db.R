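# Reference databases for read assignment: all upstream x downstream
# region combinations observed in the known variants (combinations never
# seen before are carried as in-silico entries), or -- for the cidAB
# tandem amplicon -- all cidA x cidB pairings.

#' Build a reference database for an amplicon
#'
#' For `mode = "cidA"` / `"cidB"` the database holds every upstream x
#' downstream combination of the regions observed in `known`, flagged
#' `in_silico` when that combination is not itself a known variant.  For
#' `mode = "cidAB"` it holds every pairing of the supplied cidA and cidB
#' variants (the tandem amplicon spans both genes).
#'
#' @param known non-empty list of `cid_variant` objects (for `cidAB`,
#'   variants of both genes).
#' @param mode `"cidA"`, `"cidB"` or `"cidAB"`.
#' @return An object of class `cid_refdb`: fields `mode` and `entries`, a
#'   list of entries with `name`, `seq`, `provenance` and the component
#'   names (`a_name`/`b_name` in tandem mode).
#' @export
build_reference_db <- function(known, mode = c("cidA", "cidB", "cidAB")) {
  mode <- match.arg(mode)
  stopifnot(length(known) >= 1,
            all(vapply(known, inherits, TRUE, "cid_variant")))
  entries <- list()
  if (mode %in% c("cidA", "cidB")) {
    known <- Filter(function(v) v$gene == mode, known)
    if (!length(known)) stop("no ", mode, " variants supplied")
    ups <- unique_regions(lapply(known, `[[`, "upstream"))
    downs <- unique_regions(lapply(known, `[[`, "downstream"))
    known_keys <- vapply(known, function(v)
      paste(v$upstream$name, v$downstream$name, sep = "|"), "")
    group <- known[[1]]$group
    for (u in ups) for (d in downs) {
      v <- cid_variant(mode, group, u, d)
      entries[[length(entries) + 1L]] <- list(
        name = v$name, seq = v$seq,
        provenance = if (paste(u$name, d$name, sep = "|") %in% known_keys)
          "known" else "in_silico",
        up_name = u$name, down_name = d$name, variant = v)
    }
  } else {
    as <- Filter(function(v) v$gene == "cidA", known)
    bs <- Filter(function(v) v$gene == "cidB", known)
    if (!length(as) || !length(bs))
      stop("cidAB mode needs both cidA and cidB variants")
    as <- as[!duplicated(vapply(as, `[[`, "", "name"))]
    bs <- bs[!duplicated(vapply(bs, `[[`, "", "name"))]
    for (a in as) for (b in bs) {
      entries[[length(entries) + 1L]] <- list(
        name = paste(a$name, b$name, sep = "_"),
        seq = paste0(a$seq, b$seq),
        provenance = "in_silico",  # pairing support comes from the reads
        a_name = a$name, b_name = b$name)
    }
  }
  seqs <- vapply(entries, `[[`, "", "seq")
  if (anyDuplicated(seqs)) {
    dup <- vapply(entries[duplicated(seqs) | duplicated(seqs, fromLast = TRUE)],
                  `[[`, "", "name")
    stop("duplicate reference sequences: ", paste(dup, collapse = ", "))
  }
  names(entries) <- vapply(entries, `[[`, "", "name")
  structure(list(mode = mode, entries = entries), class = "cid_refdb")
}

unique_regions <- function(regions) {
  regions[!duplicated(vapply(regions, `[[`, "", "name"))]
}

#' @export
print.cid_refdb <- function(x, ...) {
  prov <- vapply(x$entries, `[[`, "", "provenance")
  cat(sprintf("<cid_refdb> mode %s: %d entries (%d in silico)\n",
              x$mode, length(x$entries), sum(prov == "in_silico")))
  invisible(x)
}

#' @export
length.cid_refdb <- function(x) length(x$entries)
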