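# qPCR simulator: triplicate Cq values on the cycle scale, with the
# single-copy Wolbachia gene wsp as the reference channel.

#' Construct a qPCR run (one sample x one target, triplicate Cq)
#'
#' @param sample_id sample identifier.
#' @param target marker name.
#' @param cq numeric vector of exactly 3 replicate Cq values (finite, > 0).
#' @param efficiency amplification efficiency in (0, 1].
#' @return An object of class `cid_qpcr`.
#' @export
qpcr_run <- function(sample_id, target, cq, efficiency = 1) {
  if (length(cq) != 3) stop("qPCR runs are analyzed in triplicate: need 3 Cq values")
  if (!all(is.finite(cq)) || any(cq <= 0)) stop("Cq values must be finite and > 0")
  if (efficiency <= 0 || efficiency > 1) stop("efficiency must be in (0, 1]")
  structure(list(sample_id = sample_id, target = target,
                 cq = as.numeric(cq), efficiency = efficiency),
            class = "cid_qpcr")
}

#' @export
print.cid_qpcr <- function(x, ...) {
  cat(sprintf("<cid_qpcr> %s / %s  Cq = %s  (E = %.2f)\n", x$sample_id,
              x$target, paste(sprintf("%.2f", x$cq), collapse = ", "),
              x$efficiency))
  invisible(x)
}

#' Simulate a relative qPCR run (target + wsp reference)
#'
#' Cq values are generated so that the efficiency-corrected ratio
#' `(1+E)^(Cq_wsp - Cq_target)` has expectation equal to the marker's true
#' copies per Wolbachia genome; Gaussian noise of SD `noise_sd` is added
#' independently to every Cq replicate (noise lives on the cycle scale,
#' matching replicate-level qPCR variability).  A marker absent from the
#' repertoire yields a high-Cq sentinel (no amplification).
#'
#' @param rep a `cid_repertoire`.
#' @param marker marker accepted by [marker_copies()].
#' @param efficiency amplification efficiency in (0, 1] (both channels).
#' @param noise_sd Gaussian SD added to each Cq replicate, in cycles.
#' @param seed RNG seed.
#' @param sample_id sample identifier.
#' @param base_cq Cq of a single-copy target in this sample (arbitrary
#'   scale anchor; cancels in the ratio).
#' @param sentinel_cq Cq reported for absent markers (default 40).
#' @return A list of class `cid_qpcr_pair` with elements `target` and
#'   `reference` (both `cid_qpcr`).
#' @export
simulate_qpcr_run <- function(rep, marker, efficiency = 1, noise_sd = 0.2,
                              seed = NULL, sample_id = "sample1",
                              base_cq = 20, sentinel_cq = 40) {
  t_true <- marker_copies(rep, marker)
  target_name <- if (inherits(marker, "cid_marker"))
    paste0(marker$gene, ":", marker$name) else marker
  with_seed(seed, {
    cq_ref <- base_cq + rnorm(3, 0, noise_sd)
    cq_tgt <- if (t_true <= 0) {
      rep_len <- rnorm(3, 0, noise_sd)
      sentinel_cq + rep_len
    } else {
      base_cq - log(t_true) / log(1 + efficiency) + rnorm(3, 0, noise_sd)
    }
    structure(list(
      target = qpcr_run(sample_id, target_name, cq_tgt, efficiency),
      reference = qpcr_run(sample_id, "wsp", cq_ref, efficiency)
    ), class = "cid_qpcr_pair")
  })
}
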