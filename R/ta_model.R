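# Toxin-antidote (TA) model of cytoplasmic incompatibility: a cross is
# compatible iff every CidB toxin brought by the male's sperm is bound by
# at least one CidA antidote present in the female's egg.

#' Construct a CidA-CidB binding matrix
#'
#' Rules are matched on the four region coordinates of an (antidote,
#' toxin) pair.  The two interface-I partners -- the cidA upstream region
#' and the cidB downstream region -- are matched at the cluster level
#' (`"\u03b2"` matches `\u03b2(2)`, `\u03b2(7)`, ...), the other two fields by exact
#' region name; `"*"` matches anything.  Any pair matched by no rule does
#' not bind.
#'
#' @param rules data.frame with columns `a_up`, `a_down`, `b_up`,
#'   `b_down`, `binds` (logical).
#' @return An object of class `cid_binding`.
#' @export
binding_matrix <- function(rules) {
  need <- c("a_up", "a_down", "b_up", "b_down", "binds")
  if (!all(need %in% names(rules))) {
    stop("binding rules need columns: ", paste(need, collapse = ", "))
  }
  rules[need[1:4]] <- lapply(rules[need[1:4]], as.character)
  rules$binds <- as.logical(rules$binds)
  structure(list(rules = rules), class = "cid_binding")
}

#' @export
print.cid_binding <- function(x, ...) {
  cat("<cid_binding> rule set:\n")
  print(x$rules, row.names = FALSE)
  invisible(x)
}

#' Default binding rule set for the Slab / Istanbul system
#'
#' Encodes (i) the tandem-partner rule for the within-Slab pairs
#' (\u03b1(5)-25 binds ae3; \u03b3(3)-12 binds ag1), and (ii) the
#' recombinant-for-recombinant rule: any cidA with a \u03b2- or \u03b4-cluster
#' upstream region binds any cidB carrying the recombinant downstream-2
#' region.  The Slab toxins ae3 and ag1 are bound by no Istanbul
#' antidote, so the Ist-female x Slab-male direction stays incompatible.
#' All unlisted pairs do not bind.  The matrix is data, not code: edit or
#' replace it to explore other binding hypotheses.
#'
#' @return A `cid_binding` object.
#' @export
default_binding_matrix <- function() {
  binding_matrix(data.frame(
    a_up  = c("\u03b1", "\u03b3", "\u03b2", "\u03b4"),
    a_down = c("25", "12", "*", "*"),
    b_up  = c("ae", "ag", "*", "*"),
    b_down = c("3", "1", "2", "2"),
    binds = TRUE,
    stringsAsFactors = FALSE))
}

# Strip the parenthesised within-cluster index: "\u03b2(2)" -> "\u03b2".
region_cluster_label <- function(name) sub("\\(.*\\)$", "", name)

#' Does an antidote bind a toxin under a binding matrix?
#'
#' @param cidA_variant,cidB_variant `cid_variant` objects.
#' @param m a `cid_binding`.
#' @return Logical scalar.
#' @export
binds <- function(cidA_variant, cidB_variant, m = default_binding_matrix()) {
  a_up <- region_cluster_label(cidA_variant$upstream$name)
  a_down <- cidA_variant$downstream$name
  b_up <- cidB_variant$upstream$name
  b_down <- region_cluster_label(cidB_variant$downstream$name)
  r <- m$rules
  hit <- (r$a_up == "*" | r$a_up == a_up) &
    (r$a_down == "*" | r$a_down == a_down) &
    (r$b_up == "*" | r$b_up == b_up) &
    (r$b_down == "*" | r$b_down == b_down)
  any(r$binds[hit])
}

#' Predict the outcome of a cross under the TA model
#'
#' The cross is compatible iff every distinct cidB variant in the male
#' repertoire is bound by at least one cidA variant in the female
#' repertoire.  Copy numbers do not enter the binary verdict.
#'
#' @param female,male `cid_repertoire` objects (non-empty).
#' @param m a `cid_binding`.
#' @return An object of class `cid_compat`: `compatible` flag and
#'   `uncovered` (names of male toxins with no binding female antidote).
#' @export
predict_cross <- function(female, male, m = default_binding_matrix()) {
  stopifnot(length(female$tandems) >= 1, length(male$tandems) >= 1)
  antidotes <- repertoire_variants(female, "cidA")
  toxins <- repertoire_variants(male, "cidB")
  uncovered <- character(0)
  for (tox in toxins) {
    covered <- any(vapply(antidotes, binds, TRUE, cidB_variant = tox, m = m))
    if (!covered) uncovered <- c(uncovered, tox$name)
  }
  structure(list(compatible = length(uncovered) == 0, uncovered = uncovered),
            class = "cid_compat")
}

#' @export
print.cid_compat <- function(x, ...) {
  if (x$compatible) cat("<cid_compat> compatible\n")
  else cat("<cid_compat> INCOMPATIBLE; uncovered toxin(s):",
           paste(x$uncovered, collapse = ", "), "\n")
  invisible(x)
}

#' Concordance between TA predictions and observed cross outcomes
#'
#' A female's observed status is "incompatible" when her hatch rate is at
#' most `leak_max` (default 0.02, accommodating single-larva leakage).
#' Unfertilized records are excluded.  Genotype labels are resolved to
#' repertoires through `genotype_map`.
#'
#' @param records a `cid_crosses` data.frame (or compatible layout).
#' @param male_rep male `cid_repertoire`.
#' @param genotype_map named list mapping `female_genotype` labels to
#'   `cid_repertoire` objects; defaults to the three Slab presets keyed by
#'   their labels.
#' @param m binding matrix.
#' @param leak_max hatch-rate ceiling for observed incompatibility.
#' @return A list of class `cid_concordance`: `table` (2x2 predicted x
#'   observed counts), `mismatches` (female ids), `skipped` (count of
#'   unresolvable genotypes).
#' @export
concordance_table <- function(records, male_rep, genotype_map = NULL,
                              m = default_binding_matrix(), leak_max = 0.02) {
  if (is.null(genotype_map)) {
    lib <- default_region_library()
    reps <- lapply(c("SLAB_B16PP", "SLAB_B16PM", "SLAB_BMM"),
                   build_preset_repertoire, library = lib)
    genotype_map <- setNames(reps, vapply(reps, `[[`, "", "label"))
  }
  keep <- if ("fertilized" %in% names(records)) records$fertilized else
    rep(TRUE, nrow(records))
  records <- records[keep & !is.na(records$hr), , drop = FALSE]
  skipped <- 0L
  pred <- obs <- logical(0)
  ids <- character(0)
  pred_cache <- list()
  for (i in seq_len(nrow(records))) {
    g <- records$female_genotype[i]
    if (is.null(genotype_map[[g]])) {
      skipped <- skipped + 1L
      next
    }
    if (is.null(pred_cache[[g]]))
      pred_cache[[g]] <- predict_cross(genotype_map[[g]], male_rep, m)$compatible
    pred <- c(pred, pred_cache[[g]])
    obs <- c(obs, records$hr[i] > leak_max)
    ids <- c(ids, records$female_id[i])
  }
  if (skipped > 0)
    warning(skipped, " record(s) with unresolvable genotype skipped")
  tab <- table(predicted = factor(ifelse(pred, "compatible", "incompatible"),
                                  c("compatible", "incompatible")),
               observed = factor(ifelse(obs, "compatible", "incompatible"),
                                 c("compatible", "incompatible")))
  structure(list(table = tab, mismatches = ids[pred != obs], skipped = skipped),
            class = "cid_concordance")
}

#' @export
print.cid_concordance <- function(x, ...) {
  cat("<cid_concordance>\n")
  print(x$table)
  if (length(x$mismatches))
    cat("mismatching females:", paste(x$mismatches, collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a binding matrix as CSV
#'
#' @param path file path.
#' @return For the reader, a `cid_binding`.
#' @export
read_binding_matrix <- function(path) {
  binding_matrix(read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(binds = "logical")))
}

#' @rdname read_binding_matrix
#' @param m a `cid_binding` to serialize.
#' @export
write_binding_matrix <- function(m, path) {
  write.csv(m$rules, path, row.names = FALSE)
  invisible(path)
}
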