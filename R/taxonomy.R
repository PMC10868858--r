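# Region taxonomy: SNP distances, single-linkage clustering with
# nomenclature assignment, recombinant (mosaic) detection, and
# interface-peptide extraction.

#' SNP distance between two regions
#'
#' Number of mismatch columns in a global pairwise alignment.  For
#' equal-length regions this is the Hamming distance; otherwise a global
#' alignment is computed and each contiguous gap run is counted as one
#' indel event, reported separately (gaps are not SNPs).
#'
#' @param a,b `cid_region` objects of the same gene and role.
#' @return Integer SNP count with attribute `indels` (gap-run events).
#' @export
snp_distance <- function(a, b) {
  stopifnot(inherits(a, "cid_region"), inherits(b, "cid_region"))
  if (a$gene != b$gene || a$role != b$role)
    stop("snp_distance() compares regions of the same gene and role")
  if (!nzchar(a$seq) || !nzchar(b$seq)) stop("empty sequence")
  if (nchar(a$seq) == nchar(b$seq)) {
    return(structure(hamming(a$seq, b$seq), indels = 0L))
  }
  aln <- Biostrings::pairwiseAlignment(a$seq, b$seq, type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap <- p == "-" | s == "-"
  snps <- sum(p != s & !gap)
  runs <- rle(gap)
  structure(as.integer(snps), indels = sum(runs$values))
}

#' Cluster regions by SNP distance (single linkage)
#'
#' Regions within `threshold` SNPs of some other member belong to the
#' same cluster (single linkage at distance <= threshold).  Cluster
#' labels are assigned in decreasing cluster-size order (ties broken by
#' the lexicographically first member name): Greek letters for cidA
#' upstream regions, Latin letters for cidB upstream regions, digits for
#' downstream regions.  Members are numbered `"(1)"`, `"(2)"`, ... by
#' name order within the cluster (upstream regions; a downstream region
#' keeps the bare cluster digit when it is the sole member).
#'
#' @param regions list of `cid_region` objects of one gene and role.
#' @param threshold maximal within-cluster SNP distance (default 3).
#' @return An object of class `cid_clustering`: `assignments`
#'   (data.frame `region`, `cluster`, `index`, `new_name`), `clusters`
#'   (named list of member region names), `threshold`.
#' @export
cluster_regions <- function(regions, threshold = 3) {
  stopifnot(length(regions) >= 1,
            all(vapply(regions, inherits, TRUE, "cid_region")))
  gene <- unique(vapply(regions, `[[`, "", "gene"))
  role <- unique(vapply(regions, `[[`, "", "role"))
  if (length(gene) != 1 || length(role) != 1)
    stop("cluster_regions() needs regions of a single gene and role")
  nms <- vapply(regions, `[[`, "", "name")
  n <- length(regions)
  member <- if (n == 1) rep(1L, 1) else {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- as.integer(snp_distance(regions[[i]], regions[[j]]))
    cutree(hclust(as.dist(d), method = "single"), h = threshold + 0.5)
  }
  # order clusters: size desc, then lexicographic first member name
  info <- lapply(unique(member), function(k) {
    mem <- sort(nms[member == k])
    list(k = k, size = length(mem), first = mem[1], members = mem)
  })
  info <- info[order(-vapply(info, `[[`, 1L, "size"),
                     vapply(info, `[[`, "", "first"))]
  labels <- cluster_labels(gene, role, length(info))
  assignments <- do.call(rbind, lapply(seq_along(info), function(r) {
    mem <- info[[r]]$members
    idx <- seq_along(mem)
    new_name <- if (role == "upstream" && gene == "cidA") {
      paste0(labels[r], "(", idx, ")")
    } else if (role == "upstream") {
      if (length(mem) == 1) labels[r] else paste0(labels[r], "(", idx, ")")
    } else {
      if (length(mem) == 1) labels[r] else paste0(labels[r], "(", idx, ")")
    }
    data.frame(region = mem, cluster = labels[r], index = idx,
               new_name = new_name, stringsAsFactors = FALSE)
  }))
  clusters <- lapply(info, `[[`, "members")
  names(clusters) <- labels
  structure(list(assignments = assignments, clusters = clusters,
                 threshold = threshold, gene = gene, role = role),
            class = "cid_clustering")
}

cluster_labels <- function(gene, role, k) {
  if (role == "downstream") return(as.character(seq_len(k)))
  if (gene == "cidA") {
    if (k > length(greek_alphabet)) stop("too many clusters to label")
    greek_alphabet[seq_len(k)]
  } else {
    # Latin letter pairs: aa, ab, ac, ...
    paste0(rep(letters, each = 26), letters)[seq_len(k)]
  }
}

#' @export
print.cid_clustering <- function(x, ...) {
  cat(sprintf("<cid_clustering> %s %s: %d cluster(s) at <= %d SNPs\n",
              x$gene, x$role, length(x$clusters), x$threshold))
  print(x$assignments, row.names = FALSE)
  invisible(x)
}

#' Canonical name of a variant under a clustering-based nomenclature
#'
#' Identical region sequences receive identical names regardless of the
#' wPip group, so the name is portable across groups.
#'
#' @param v a `cid_variant`.
#' @param upstream_clustering,downstream_clustering optional
#'   `cid_clustering` objects; when given, the regions' nomenclature
#'   names are taken from them, otherwise from the regions themselves
#'   (which must then carry a cluster label).
#' @return Character canonical name, e.g. `"cidA-III-\u03b1(5)-25"`.
#' @export
name_variant <- function(v, upstream_clustering = NULL,
                         downstream_clustering = NULL) {
  lookup <- function(region, clustering) {
    if (is.null(clustering)) {
      if (is.na(region$cluster))
        stop("region '", region$name, "' is unclustered")
      return(region$name)
    }
    a <- clustering$assignments
    hit <- a$new_name[a$region == region$name]
    if (!length(hit)) stop("region '", region$name, "' not in clustering")
    hit[1]
  }
  variant_name(v$gene, v$group,
               lookup(v$upstream, upstream_clustering),
               lookup(v$downstream, downstream_clustering))
}

#' Detect a recombinant (mosaic) region
#'
#' Scans all ordered parent pairs `(p, q)` and breakpoints `b` at least
#' `min_segment` from both ends, scoring the mosaic `p[..b] + q[b..]`
#' against the child; a recombination call is emitted iff the minimal
#' number of unexplained SNPs is at most `tol` and the child is farther
#' than `cluster_threshold` SNPs from every single parent of the best
#' pair (otherwise the child is just a cluster member, not a mosaic).
#' Ties on the unexplained count break to the smallest breakpoint, then
#' to lexicographic parent names.
#'
#' @param child `cid_region` to test.
#' @param candidates list of candidate parent `cid_region`s (>= 2),
#'   equal length with the child.
#' @param tol maximal unexplained SNPs (default 1).
#' @param min_segment minimal segment length on each side (default 50).
#' @param cluster_threshold the nomenclature clustering threshold
#'   (default 3).
#' @return An object of class `cid_recomb` (`child`, `parent1`,
#'   `parent2`, `breakpoint`, `unexplained`), or `NULL` when no mosaic
#'   signal is found.
#' @export
detect_recombinant <- function(child, candidates, tol = 1, min_segment = 50,
                               cluster_threshold = 3) {
  if (length(candidates) < 2) stop("need at least 2 candidate parents")
  len <- nchar(child$seq)
  if (any(vapply(candidates, function(r) nchar(r$seq), 1L) != len))
    stop("candidates must be aligned to the child (equal length)")
  cn <- vapply(candidates, `[[`, "", "name")
  ord <- order(cn)
  candidates <- candidates[ord]; cn <- cn[ord]
  cc <- strsplit(child$seq, "", fixed = TRUE)[[1]]
  mism <- lapply(candidates, function(r)
    as.integer(strsplit(r$seq, "", fixed = TRUE)[[1]] != cc))
  csum <- lapply(mism, function(mm) c(0L, cumsum(mm)))  # csum[[i]][b] = mism in 1..b-1
  bs <- seq.int(min_segment + 1L, len - min_segment + 1L)
  if (!length(bs)) stop("min_segment too large for the region length")
  best <- NULL
  for (i in seq_along(candidates)) for (j in seq_along(candidates)) {
    if (i == j) next
    tot_j <- csum[[j]][len + 1L]
    unexpl <- csum[[i]][bs] + (tot_j - csum[[j]][bs])
    k <- which.min(unexpl)           # smallest b among ties (bs ascending)
    cand <- list(p = i, q = j, b = bs[k], unexplained = unexpl[k])
    if (is.null(best) || cand$unexplained < best$unexplained ||
        (cand$unexplained == best$unexplained && cand$b < best$b))
      best <- cand   # equal (unexplained, b): keep lexicographically first pair
  }
  if (best$unexplained > tol) return(NULL)
  d1 <- sum(mism[[best$p]])
  d2 <- sum(mism[[best$q]])
  if (d1 <= cluster_threshold || d2 <= cluster_threshold) return(NULL)
  structure(list(child = child$name, parent1 = cn[best$p], parent2 = cn[best$q],
                 breakpoint = best$b, unexplained = best$unexplained),
            class = "cid_recomb")
}

#' @export
print.cid_recomb <- function(x, ...) {
  cat(sprintf("<cid_recomb> %s = %s[..%d] + %s[%d..] (%d unexplained SNP(s))\n",
              x$child, x$parent1, x$breakpoint, x$parent2, x$breakpoint,
              x$unexplained))
  invisible(x)
}

#' Extract the interface-I peptide of a variant
#'
#' Translates the variant in the given frame (standard genetic code) and
#' slices the interface window in amino-acid coordinates.  The window
#' coordinates are a user configuration for real data; the packaged
#' default is illustrative only.
#'
#' @param v a `cid_variant`, or a nucleotide sequence over ACGT.
#' @param interface_coords length-2 integer vector, 1-based first and
#'   last amino acid of the window.
#' @param frame reading frame offset 1-3.
#' @return Character amino-acid sequence; attribute `stop_codon` is TRUE
#'   when a stop lies inside the window.
#' @export
interface_peptide <- function(v, interface_coords, frame = 1) {
  stopifnot(length(interface_coords) == 2, frame %in% 1:3)
  nt <- if (is.character(v)) toupper(v) else v$seq
  seq <- substr(nt, frame, nchar(nt))
  if (grepl("[^ACGT]", seq)) stop("sequence contains ambiguity codes")
  seq <- substr(seq, 1, nchar(seq) - nchar(seq) %% 3)
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(seq))))
  from <- interface_coords[1]; to <- interface_coords[2]
  if (from < 1 || to > nchar(aa) || from > to)
    stop("interface coordinates outside the translated protein (length ",
         nchar(aa), ")")
  pep <- substr(aa, from, to)
  structure(pep, stop_codon = grepl("*", pep, fixed = TRUE))
}
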