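# Full-gene cid haplotypes (variants), cidA-cidB tandems and repertoires.

#' Create a full cid gene haplotype from its two regions
#'
#' A variant is the concatenation of one upstream and one downstream
#' region; the downstream region starts at nucleotide 801 (cidA) or 1201
#' (cidB) of the gene.
#'
#' @param gene `"cidA"` or `"cidB"`.
#' @param group wPip phylogenetic group as a Roman numeral (`"I"`..`"V"`).
#' @param upstream,downstream `cid_region` objects of matching gene/role.
#' @return An object of class `cid_variant` with the canonical name, e.g.
#'   `cidA-III-\u03b1(5)-25` or `cidB-III-ae3`.
#' @export
cid_variant <- function(gene, group, upstream, downstream) {
  gene <- match.arg(gene, c("cidA", "cidB"))
  group <- match.arg(group, c("I", "II", "III", "IV", "V"))
  stopifnot(upstream$gene == gene, upstream$role == "upstream",
            downstream$gene == gene, downstream$role == "downstream")
  if (nchar(upstream$seq) != CID_BOUNDARY[[gene]] - 1L)
    stop(gene, " upstream region must end at nucleotide ",
         CID_BOUNDARY[[gene]] - 1L)
  structure(list(gene = gene, group = group,
                 upstream = upstream, downstream = downstream,
                 seq = paste0(upstream$seq, downstream$seq),
                 name = variant_name(gene, group, upstream$name, downstream$name)),
            class = "cid_variant")
}

#' Render a canonical variant name
#'
#' cidA variants join the fields with hyphens (`cidA-III-\u03b1(5)-25`); cidB
#' variants concatenate the letter-coded upstream and digit-coded
#' downstream region (`cidB-III-ae3`).
#'
#' @param gene,group,upstream,downstream name components.
#' @return A character scalar.
#' @export
variant_name <- function(gene, group, upstream, downstream) {
  if (gene == "cidB" && grepl("^[a-z]+$", upstream) &&
      grepl("^[0-9]+$", downstream)) {
    paste(gene, group, paste0(upstream, downstream), sep = "-")
  } else {
    paste(gene, group, upstream, downstream, sep = "-")
  }
}

#' @export
print.cid_variant <- function(x, ...) {
  cat(sprintf("<cid_variant> %s (%d nt)\n", x$name, nchar(x$seq)))
  invisible(x)
}

#' Create a cidA-cidB tandem
#'
#' @param cidA,cidB `cid_variant` objects of the respective genes.
#' @param copies positive integer genomic copy number.
#' @return An object of class `cid_tandem`.
#' @export
tandem <- function(cidA, cidB, copies = 1L) {
  stopifnot(inherits(cidA, "cid_variant"), cidA$gene == "cidA",
            inherits(cidB, "cid_variant"), cidB$gene == "cidB",
            copies >= 1)
  structure(list(cidA = cidA, cidB = cidB, copies = as.integer(copies),
                 name = paste(cidA$name, cidB$name, sep = "_")),
            class = "cid_tandem")
}

#' Assemble a cid repertoire
#'
#' The repertoire is the full multiset of cidA-cidB tandem copies carried
#' by one Wolbachia genome.  Total cidA and cidB copies are equal by
#' construction, and no two tandems may share the same variant pairing.
#'
#' @param tandems list of `cid_tandem` objects.
#' @param label repertoire label, e.g. `"(\u03b2+,16+)"`.
#' @return An object of class `cid_repertoire`.
#' @export
repertoire <- function(tandems, label = NULL) {
  stopifnot(length(tandems) >= 1,
            all(vapply(tandems, inherits, TRUE, "cid_tandem")))
  nm <- vapply(tandems, `[[`, "", "name")
  if (anyDuplicated(nm))
    stop("duplicate tandem pairing(s): ", paste(nm[duplicated(nm)], collapse = ", "))
  names(tandems) <- nm
  structure(list(tandems = tandems, label = label), class = "cid_repertoire")
}

#' @export
print.cid_repertoire <- function(x, ...) {
  cat(sprintf("<cid_repertoire>%s %d tandem pairing(s), %d copies\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              length(x$tandems), total_copies(x)))
  for (t in x$tandems)
    cat(sprintf("  %s x%d\n", t$name, t$copies))
  invisible(x)
}

#' Total tandem copy number of a repertoire
#' @param rep a `cid_repertoire`.
#' @return Integer total (equal for cidA and cidB).
#' @export
total_copies <- function(rep) {
  sum(vapply(rep$tandems, `[[`, 1L, "copies"))
}

#' Distinct variants of one gene in a repertoire
#' @param rep a `cid_repertoire`.
#' @param gene `"cidA"` or `"cidB"`.
#' @return Named list of `cid_variant` objects (by canonical name).
#' @export
repertoire_variants <- function(rep, gene = c("cidA", "cidB")) {
  gene <- match.arg(gene)
  vs <- lapply(rep$tandems, `[[`, gene)
  vs <- vs[!duplicated(vapply(vs, `[[`, "", "name"))]
  names(vs) <- vapply(vs, `[[`, "", "name")
  vs
}

#' Per-variant copy numbers of one gene
#' @param rep a `cid_repertoire`.
#' @param gene `"cidA"` or `"cidB"`.
#' @return Named integer vector of copies per distinct variant.
#' @export
repertoire_copies <- function(rep, gene = c("cidA", "cidB")) {
  gene <- match.arg(gene)
  nm <- vapply(rep$tandems, function(t) t[[gene]]$name, "")
  cp <- vapply(rep$tandems, `[[`, 1L, "copies")
  tapply_int <- tapply(cp, nm, sum)
  out <- as.integer(tapply_int)
  names(out) <- names(tapply_int)
  out[order(names(out))]
}

#' qPCR marker definition for a region
#'
#' @param gene `"cidA"` or `"cidB"`.
#' @param role `"upstream"` or `"downstream"`.
#' @param name region name the assay targets (e.g. `"\u03b2(2)"`, `"16"`).
#' @return An object of class `cid_marker`.
#' @export
region_marker <- function(gene, role, name) {
  structure(list(gene = match.arg(gene, c("cidA", "cidB")),
                 role = match.arg(role, c("upstream", "downstream")),
                 name = name),
            class = "cid_marker")
}

#' True copies per Wolbachia genome of a qPCR marker
#'
#' @param rep a `cid_repertoire`.
#' @param marker `"cidA"` or `"cidB"` (total gene copies), `"wsp"`
#'   (single-copy reference, always 1), or a [region_marker()] counting
#'   copies whose region matches by name.
#' @return Numeric copies per genome.
#' @export
marker_copies <- function(rep, marker) {
  if (inherits(marker, "cid_marker")) {
    cp <- vapply(rep$tandems, `[[`, 1L, "copies")
    hit <- vapply(rep$tandems, function(t)
      t[[marker$gene]][[marker$role]]$name == marker$name, TRUE)
    return(sum(cp[hit]))
  }
  switch(marker,
         cidA = ,
         cidB = total_copies(rep),
         wsp = 1,
         stop("unknown marker: ", marker))
}

#' Preset repertoires of the Slab sublines and the Istanbul line
#'
#' * `SLAB_BMM` -- the minimal (\u03b2-,16-) repertoire:
#'   `cidA-III-\u03b1(5)-25_cidB-III-ae3` x2 and `cidA-III-\u03b3(3)-12_cidB-III-ag1`
#'   x1 (3 copies, 2 distinct cidA variants).
#' * `SLAB_B16PM` -- (\u03b2+,16-): adds `cidA-III-\u03b2(2)-25_cidB-III-ae3` and
#'   `cidA-III-\u03b3(3)-12_cidB-III-ae3` (5 copies).
#' * `SLAB_B16PP` -- (\u03b2+,16+): as `SLAB_B16PM` but with
#'   `cidA-III-\u03b2(2)-16_cidB-III-ae3` in place of the extra
#'   \u03b3(3)-12 tandem (5 copies, 4 distinct cidA variants).
#' * `IST` -- a configurable wPip group-IV repertoire whose toxin set
#'   carries the recombinant downstream-2 region (default
#'   `cidA-IV-\u03b4(1)-41_cidB-IV-ak2` x2).
#'
#' @param preset one of `"SLAB_B16PP"`, `"SLAB_B16PM"`, `"SLAB_BMM"`,
#'   `"IST"`.
#' @param library region library (default [default_region_library()]).
#' @param ist_tandems for `IST`, an optional list of
#'   `list(a_up, a_down, b_up, b_down, copies)` region-name specs
#'   overriding the default variant list.
#' @return A `cid_repertoire`.
#' @export
build_preset_repertoire <- function(preset, library = default_region_library(),
                                    ist_tandems = NULL) {
  reg <- function(gene, role, name) {
    r <- library[[region_key(gene, role, name)]]
    if (is.null(r)) stop("region not in library: ", region_key(gene, role, name))
    r
  }
  td <- function(group, a_up, a_down, b_up, b_down, copies) {
    tandem(cid_variant("cidA", group, reg("cidA", "upstream", a_up),
                       reg("cidA", "downstream", a_down)),
           cid_variant("cidB", group, reg("cidB", "upstream", b_up),
                       reg("cidB", "downstream", b_down)),
           copies)
  }
  core <- list(td("III", "\u03b1(5)", "25", "ae", "3", 2L),
               td("III", "\u03b3(3)", "12", "ag", "1", 1L))
  switch(preset,
    SLAB_BMM = repertoire(core, label = "(\u03b2-,16-)"),
    SLAB_B16PM = repertoire(c(core, list(
      td("III", "\u03b2(2)", "25", "ae", "3", 1L),
      td("III", "\u03b3(3)", "12", "ae", "3", 1L))), label = "(\u03b2+,16-)"),
    SLAB_B16PP = repertoire(c(core, list(
      td("III", "\u03b2(2)", "25", "ae", "3", 1L),
      td("III", "\u03b2(2)", "16", "ae", "3", 1L))), label = "(\u03b2+,16+)"),
    IST = {
      specs <- ist_tandems %||%
        list(list(a_up = "\u03b4(1)", a_down = "41", b_up = "ak", b_down = "2",
                  copies = 2L))
      repertoire(lapply(specs, function(s)
        td("IV", s$a_up, s$a_down, s$b_up, s$b_down, s$copies)),
        label = "Ist")
    },
    stop("unknown preset: ", preset)
  )
}
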