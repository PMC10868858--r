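# Polymorphic upstream/downstream regions of the cid genes.
#
# Each cid gene carries its polymorphism in two segments: an upstream
# region (positions < 801 for cidA, < 1201 for cidB) and a downstream
# region (positions >= the boundary).  A full-gene haplotype is the
# concatenation of one upstream and one downstream region on an otherwise
# constant backbone, so a region library plus the combination rule spans
# the variant space.

# 1-based position at which the downstream region starts.
CID_BOUNDARY <- c(cidA = 801L, cidB = 1201L)
# Default full-gene lengths (amplicon-scale stand-ins, configurable).
CID_GENE_LENGTH <- c(cidA = 1400L, cidB = 2000L)

#' Region lengths implied by the gene boundaries
#' @param gene_length named lengths for cidA and cidB.
#' @return A list with upstream/downstream lengths per gene.
#' @keywords internal
region_lengths <- function(gene_length = CID_GENE_LENGTH) {
  list(
    cidA = c(upstream = CID_BOUNDARY[["cidA"]] - 1L,
             downstream = gene_length[["cidA"]] - CID_BOUNDARY[["cidA"]] + 1L),
    cidB = c(upstream = CID_BOUNDARY[["cidB"]] - 1L,
             downstream = gene_length[["cidB"]] - CID_BOUNDARY[["cidB"]] + 1L)
  )
}

#' Create a polymorphic cid region
#'
#' @param name region identifier (Greek letter + index for cidA upstream,
#'   Latin letters for cidB upstream, digits for downstream regions).
#' @param gene `"cidA"` or `"cidB"`.
#' @param role `"upstream"` or `"downstream"`.
#' @param seq nucleotide sequence over ACGT.
#' @param cluster cluster label, or `NA` if not yet clustered.
#' @return An object of class `cid_region`.
#' @export
region_seq <- function(name, gene, role, seq, cluster = NA_character_) {
  gene <- match.arg(gene, c("cidA", "cidB"))
  role <- match.arg(role, c("upstream", "downstream"))
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("region sequence must be non-empty")
  if (grepl("[^ACGT]", seq)) stop("region sequence must be over {A,C,G,T}")
  structure(list(name = name, gene = gene, role = role, seq = seq,
                 cluster = cluster),
            class = "cid_region")
}

#' @export
print.cid_region <- function(x, ...) {
  cat(sprintf("<cid_region> %s %s '%s' (%d nt%s)\n", x$gene, x$role, x$name,
              nchar(x$seq),
              if (is.na(x$cluster)) "" else paste0(", cluster ", x$cluster)))
  invisible(x)
}

#' Build a mosaic (recombinant) region from two parents
#'
#' The child takes positions `< breakpoint` from `parent1` and positions
#' `>= breakpoint` (1-based) from `parent2`.
#'
#' @param parent1,parent2 `cid_region` objects of the same gene/role.
#' @param breakpoint 1-based position at which `parent2` takes over.
#' @param name name for the child region.
#' @param cluster optional cluster label.
#' @return A `cid_region`.
#' @export
mosaic_region <- function(parent1, parent2, breakpoint, name,
                          cluster = NA_character_) {
  if (parent1$gene != parent2$gene || parent1$role != parent2$role)
    stop("mosaic parents must share gene and role")
  len <- nchar(parent1$seq)
  if (nchar(parent2$seq) != len) stop("mosaic parents must have equal length")
  if (breakpoint < 2 || breakpoint > len)
    stop("breakpoint must lie strictly inside the region")
  seq <- paste0(substr(parent1$seq, 1, breakpoint - 1),
                substr(parent2$seq, breakpoint, len))
  region_seq(name, parent1$gene, parent1$role, seq, cluster = cluster)
}

#' Generate a library of polymorphic regions
#'
#' Draws `n_per_role` independent random regions for each gene/role
#' combination (a fixed backbone per gene/role, mutated at `snp_rate`
#' per position), then appends mosaic regions built as
#' `parent1[..b] + parent2[b..]` according to `mosaic_specs`.
#'
#' @param seed RNG seed; the library is deterministic given the seed.
#' @param n_per_role number of independent regions per (gene, role); >= 2.
#' @param snp_rate per-position substitution probability relative to the
#'   backbone (default 0.02, so two regions differ at about
#'   `2 * snp_rate * length` sites).
#' @param mosaic_specs list of lists with elements `name`, `gene`, `role`,
#'   `parent1`, `parent2`, `breakpoint`.
#' @param gene_length named full-gene lengths.
#' @return A list of `cid_region` objects.
#' @export
make_region_library <- function(seed, n_per_role = 3, snp_rate = 0.02,
                                mosaic_specs = NULL,
                                gene_length = CID_GENE_LENGTH) {
  stopifnot(n_per_role >= 2)
  lens <- region_lengths(gene_length)
  with_seed(seed, {
    lib <- list()
    for (gene in c("cidA", "cidB")) {
      for (role in c("upstream", "downstream")) {
        len <- lens[[gene]][[role]]
        backbone <- random_seq(len)
        for (i in seq_len(n_per_role)) {
          nmut <- rbinom(1, len, snp_rate)
          pos <- sample.int(len, nmut)
          nm <- paste0(substr(gene, 4, 4), substr(role, 1, 1), i)
          lib[[length(lib) + 1L]] <-
            region_seq(nm, gene, role, substitute_at(backbone, pos))
        }
      }
    }
    names(lib) <- vapply(lib, function(r) region_key(r$gene, r$role, r$name), "")
    for (ms in mosaic_specs) {
      k1 <- region_key(ms$gene, ms$role, ms$parent1)
      k2 <- region_key(ms$gene, ms$role, ms$parent2)
      for (k in c(k1, k2)) {
        if (!k %in% names(lib))
          stop("unknown mosaic parent region: ", k)
      }
      lib[[region_key(ms$gene, ms$role, ms$name)]] <-
        mosaic_region(lib[[k1]], lib[[k2]], ms$breakpoint, ms$name)
    }
    lib
  })
}

#' @keywords internal
region_key <- function(gene, role, name) paste(gene, role, name, sep = "/")

#' Derive a new region differing from a template by a fixed number of SNPs
#'
#' Useful for building within-cluster members (the nomenclature groups
#' regions differing by at most 3 SNPs into one cluster).
#'
#' @param region template `cid_region`.
#' @param n_snps number of substituted positions.
#' @param name name of the derived region.
#' @return A `cid_region`.
#' @export
perturb_region <- function(region, n_snps, name) {
  pos <- sample.int(nchar(region$seq), n_snps)
  region_seq(name, region$gene, region$role,
             substitute_at(region$seq, pos), cluster = region$cluster)
}

#' Region library for the Slab / Istanbul study system
#'
#' Builds the named regions behind the preset repertoires: cidA upstream
#' regions alpha(5), gamma(3) plus the recombinants beta(2) (alpha/gamma
#' mosaic) and delta(1); cidA downstream regions 25, 16, 12, 41; cidB
#' upstream regions ae, ag, ak; and cidB downstream regions 3, 1 plus the
#' recombinant region 2 (mosaic of 1 and 3).  Sequences are synthetic;
#' names and the mosaic structure mirror the study system.
#'
#' @param seed RNG seed fixing the sequences (default 101).
#' @param snp_rate per-position divergence of independent regions from the
#'   shared backbone.
#' @return A named list of `cid_region` objects keyed `gene/role/name`.
#' @export
default_region_library <- function(seed = 101, snp_rate = 0.02) {
  lens <- region_lengths()
  with_seed(seed, {
    lib <- list()
    add <- function(gene, role, name, seq, cluster) {
      lib[[region_key(gene, role, name)]] <<-
        region_seq(name, gene, role, seq, cluster = cluster)
    }
    indep <- function(backbone, snp_rate) {
      len <- nchar(backbone)
      substitute_at(backbone, sample.int(len, rbinom(1, len, snp_rate)))
    }

    # cidA upstream: alpha(5) and gamma(3) independent; beta(2) and
    # delta(1) are alpha/gamma mosaics with distinct breakpoints.
    bbAu <- random_seq(lens$cidA[["upstream"]])
    add("cidA", "upstream", "\u03b1(5)", indep(bbAu, snp_rate), "\u03b1")
    add("cidA", "upstream", "\u03b3(3)", indep(bbAu, snp_rate), "\u03b3")
    lib[[region_key("cidA", "upstream", "\u03b2(2)")]] <-
      mosaic_region(lib[[region_key("cidA", "upstream", "\u03b1(5)")]],
                    lib[[region_key("cidA", "upstream", "\u03b3(3)")]],
                    400L, "\u03b2(2)", cluster = "\u03b2")
    lib[[region_key("cidA", "upstream", "\u03b4(1)")]] <-
      mosaic_region(lib[[region_key("cidA", "upstream", "\u03b1(5)")]],
                    lib[[region_key("cidA", "upstream", "\u03b3(3)")]],
                    560L, "\u03b4(1)", cluster = "\u03b4")

    # cidA downstream regions (digits).
    bbAd <- random_seq(lens$cidA[["downstream"]])
    for (nm in c("25", "16", "12", "41"))
      add("cidA", "downstream", nm, indep(bbAd, snp_rate), nm)

    # cidB upstream regions (Latin letters).
    bbBu <- random_seq(lens$cidB[["upstream"]])
    for (nm in c("ae", "ag", "ak"))
      add("cidB", "upstream", nm, indep(bbBu, snp_rate), nm)

    # cidB downstream: 3 and 1 independent, 2 recombinant between them.
    bbBd <- random_seq(lens$cidB[["downstream"]])
    add("cidB", "downstream", "3", indep(bbBd, snp_rate), "3")
    add("cidB", "downstream", "1", indep(bbBd, snp_rate), "1")
    lib[[region_key("cidB", "downstream", "2")]] <-
      mosaic_region(lib[[region_key("cidB", "downstream", "1")]],
                    lib[[region_key("cidB", "downstream", "3")]],
                    400L, "2", cluster = "2")
    lib
  })
}
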