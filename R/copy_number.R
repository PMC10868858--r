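# qPCR copies-per-genome estimation, fusion with coverage fractions into
# integer per-variant copy numbers, genotype classification, and the
# mixture-based coinfection screen.

#' Relative qPCR copy estimate (target / wsp)
#'
#' The per-replicate ratio is `(1+E_ref)^Cq_ref / (1+E_tgt)^Cq_tgt`
#' (which reduces to `2^(Cq_ref - Cq_tgt)` at full efficiency); the
#' estimate is the mean over the three replicate pairs.  When calibrator
#' pairs are supplied (samples known to carry exactly one target copy)
#' the estimate is divided by the mean calibrator ratio.
#'
#' @param target,reference `cid_qpcr` runs for the same sample.
#' @param calibrators optional list of `cid_qpcr_pair` objects measured
#'   on single-copy calibrator individuals.
#' @param floor estimates below this value are reported as 0 (absent
#'   marker; sentinel Cq values land here).
#' @return Numeric copies per genome, with attributes `cv` (replicate
#'   coefficient of variation) and `flag` (`"high_cv"` when the CV
#'   exceeds 0.5).
#' @export
qpcr_copy_estimate <- function(target, reference, calibrators = NULL,
                               floor = 1e-3) {
  stopifnot(inherits(target, "cid_qpcr"), inherits(reference, "cid_qpcr"))
  if (!identical(target$sample_id, reference$sample_id))
    stop("target and reference runs come from different samples")
  ratios <- (1 + reference$efficiency)^reference$cq /
    (1 + target$efficiency)^target$cq
  est <- mean(ratios)
  cv <- stats::sd(ratios) / est
  if (!is.null(calibrators)) {
    cal <- vapply(calibrators, function(p)
      mean((1 + p$reference$efficiency)^p$reference$cq /
             (1 + p$target$efficiency)^p$target$cq), 1)
    est <- est / mean(cal)
  }
  if (est < floor) est <- 0
  flag <- if (is.finite(cv) && cv > 0.5) "high_cv" else "ok"
  structure(est, cv = cv, flag = flag)
}

#' Fuse a continuous copy total with coverage fractions into integers
#'
#' The continuous qPCR total is rounded to `T` (flagged ambiguous when it
#' sits more than 0.3 from an integer, reflecting intrinsic qPCR
#' variability); the per-variant composition is the exhaustive-argmax of
#' the multinomial log-likelihood `sum n_i log(c_i / T)` over integer
#' compositions with `c_i >= 1` (a variant seen in the reads has at least
#' one genomic copy) and `sum c_i = T`.  Ties break to the
#' lexicographically smallest composition by variant name order.
#'
#' @param total_cont continuous copies/genome (> 0).
#' @param counts named integer read counts per called variant (the
#'   relative coverage).
#' @param max_total largest total for which exhaustive enumeration is
#'   attempted (default 12).
#' @return An object of class `cid_copy_estimate`: `total_cont`, `total`
#'   (rounded), `composition` (named integer vector), `ambiguous`,
#'   `loglik`.
#' @export
integerize_copies <- function(total_cont, counts, max_total = 12L) {
  stopifnot(total_cont > 0, length(counts) >= 1, all(counts >= 0))
  if (is.null(names(counts)))
    names(counts) <- paste0("variant", seq_along(counts))
  total <- as.integer(round(total_cont))
  if (total < length(counts))
    stop("total below variant count: ", total, " copies for ",
         length(counts), " called variants")
  if (total > max_total)
    stop("total ", total, " exceeds enumeration limit ", max_total)
  ambiguous <- abs(total_cont - total) > 0.3
  ord <- order(names(counts))
  n <- counts[ord]
  comps <- integer_compositions(total, length(n))    # each row sums to total
  ll <- as.vector(log(comps) %*% n)                  # sum n_i log c_i (up to const)
  best <- which(ll == max(ll))
  # lexicographically smallest composition among ties (variants in name order)
  if (length(best) > 1) {
    key <- apply(comps[best, , drop = FALSE], 1, paste, collapse = ",")
    best <- best[order(key)][1]
  }
  comp <- comps[best[1], ]
  names(comp) <- names(n)
  comp <- comp[names(counts)]                        # original order
  structure(list(total_cont = total_cont, total = total,
                 composition = comp, ambiguous = ambiguous,
                 loglik = max(ll) - sum(n) * log(total)),
            class = "cid_copy_estimate")
}

# All compositions of `total` into `k` positive integer parts (rows).
integer_compositions <- function(total, k) {
  if (k == 1) return(matrix(total, ncol = 1))
  out <- list()
  for (first in seq_len(total - k + 1)) {
    rest <- integer_compositions(total - first, k - 1)
    out[[first]] <- cbind(first, rest)
  }
  do.call(rbind, out)
}

#' @export
print.cid_copy_estimate <- function(x, ...) {
  cat(sprintf("<cid_copy_estimate> %.2f copies/genome -> total %d%s\n",
              x$total_cont, x$total, if (x$ambiguous) " (ambiguous)" else ""))
  for (nm in names(x$composition))
    cat(sprintf("  %s: %d\n", nm, x$composition[[nm]]))
  invisible(x)
}

#' Classify the (\u03b2,16) genotype from marker copy estimates
#'
#' Presence of a marker is an estimate above `presence_threshold`
#' (default 0.5 copies).  The combination \u03b2 absent / 16 present is
#' reported as `"inconsistent"` (no such repertoire exists: the
#' downstream-16 region is only carried by a \u03b2-upstream variant).
#'
#' @param beta_copies,s16_copies marker copy estimates (>= 0).
#' @param presence_threshold presence cutoff in copies/genome.
#' @return One of `"(\u03b2+,16+)"`, `"(\u03b2+,16-)"`, `"(\u03b2-,16-)"`,
#'   `"inconsistent"`.
#' @export
classify_genotype <- function(beta_copies, s16_copies,
                              presence_threshold = 0.5) {
  stopifnot(beta_copies >= 0, s16_copies >= 0)
  b <- beta_copies > presence_threshold
  s <- s16_copies > presence_threshold
  if (b && s) "(\u03b2+,16+)" else if (b) "(\u03b2+,16-)"
  else if (!s) "(\u03b2-,16-)" else "inconsistent"
}

#' Screen per-individual copy totals for coinfection (bimodality)
#'
#' A lasting coinfection of strains with different repertoire sizes would
#' blur per-individual quantifications into a unimodal intermediate
#' distribution, whereas genotype segregation produces distinct modes.
#' Fits equal-variance Gaussian mixtures with 1-3 components and selects
#' by BIC; the verdict is multimodal when the best model has at least two
#' components whose means are separated by more than twice the pooled SD.
#'
#' @param totals numeric vector of per-individual copies/genome (>= 20
#'   values).
#' @param k_max maximal number of components (default 3).
#' @return An object of class `cid_mixture`: `k`, `means`, `weights`,
#'   `sd`, `bic` (per k), `verdict` (`"unimodal"` / `"multimodal"`).
#' @export
detect_coinfection <- function(totals, k_max = 3) {
  if (length(totals) < 20)
    stop("need at least 20 individuals for the coinfection screen")
  mclustBIC <- mclust::mclustBIC   # Mclust() resolves this in the caller
  fit <- mclust::Mclust(totals, G = 1:k_max, modelNames = "E",
                        verbose = FALSE)
  means <- sort(as.numeric(fit$parameters$mean))
  sdv <- sqrt(fit$parameters$variance$sigmasq[1])
  sep <- if (fit$G >= 2) min(diff(means)) else 0
  verdict <- if (fit$G >= 2 && sep > 2 * sdv) "multimodal" else "unimodal"
  structure(list(k = fit$G, means = means,
                 weights = as.numeric(fit$parameters$pro),
                 sd = sdv, bic = fit$BIC, verdict = verdict,
                 data = totals),
            class = "cid_mixture")
}

#' @export
print.cid_mixture <- function(x, ...) {
  cat(sprintf("<cid_mixture> %s: k = %d, means = %s, sd = %.2f\n",
              x$verdict, x$k,
              paste(sprintf("%.2f", x$means), collapse = ", "), x$sd))
  invisible(x)
}

#' @export
plot.cid_mixture <- function(x, breaks = 20, ...) {
  hist(x$data, breaks = breaks, freq = FALSE,
       main = sprintf("copy-number distribution (%s)", x$verdict),
       xlab = "copies per genome", ...)
  xs <- seq(min(x$data), max(x$data), length.out = 200)
  dens <- rowSums(sapply(seq_len(x$k), function(j)
    x$weights[j] * stats::dnorm(xs, x$means[j], x$sd)))
  lines(xs, dens, lwd = 2)
  abline(v = x$means, lty = 2)
  invisible(x)
}

#' Agreement between two repeated quantifications (Pearson)
#'
#' @param measure1,measure2 paired numeric vectors (n >= 3).
#' @return A `cid_stat` with the correlation, df and two-sided p-value.
#' @export
replicate_agreement <- function(measure1, measure2) {
  stopifnot(length(measure1) == length(measure2), length(measure1) >= 3)
  if (stats::sd(measure1) == 0 || stats::sd(measure2) == 0)
    stop("zero variance in one of the measurement vectors")
  ct <- cor.test(measure1, measure2, method = "pearson")
  cid_stat("Pearson r", unname(ct$estimate), df = unname(ct$parameter),
           p = ct$p.value, n = length(measure1))
}
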