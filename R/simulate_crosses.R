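# Cross simulator: binary compatibility from the toxin-antidote model,
# overdispersed hatch rates in compatible crosses, rare single-larva
# leakage in incompatible ones, and per-female qPCR-style marker noise.

#' Simulate individual-female cross outcomes
#'
#' Compatibility of the cross is decided by [predict_cross()].  For an
#' incompatible pairing every raft has zero larvae, except that with
#' probability `leak_prob` exactly one larva hatches (leakage).  For a
#' compatible pairing each female draws a hatch propensity from
#' `Beta(hr_alpha, hr_beta)` and her larvae from a binomial on the eggs
#' laid, giving raft-level overdispersion.  Eggs per raft follow
#' `30 + Poisson(eggs_mean - 30)` so that rafts are never tiny.
#'
#' @param female_rep,male_rep `cid_repertoire` objects.
#' @param binding a binding matrix (default [default_binding_matrix()]).
#' @param n_females number of females (> 0).
#' @param eggs_mean mean eggs per raft (>= 31).
#' @param hr_alpha,hr_beta Beta parameters of the compatible-cross hatch
#'   propensity.
#' @param leak_prob probability of a single-larva leak in an incompatible
#'   cross.
#' @param unfert_prob probability that a female lays an unfertilized raft
#'   (excluded from hatch-rate analyses downstream).
#' @param qpcr_noise_sd Cq-scale SD for the per-female marker
#'   quantifications carried in the record.
#' @param infection_sdlog log-SD of the per-female wsp/ace-2 infection
#'   level (centred on 1 genome per genome).
#' @param seed RNG seed.
#' @return A data.frame of class `cid_crosses` with one row per female:
#'   `female_id`, `female_genotype`, `male_line`, `eggs`, `larvae`, `hr`,
#'   `fertilized`, `cidA_total`, `cidA_beta`, `cidA_16`, `infection`.
#' @export
simulate_crosses <- function(female_rep, male_rep,
                             binding = default_binding_matrix(),
                             n_females, eggs_mean = 55,
                             hr_alpha = 2, hr_beta = 1.5,
                             leak_prob = 0.04, unfert_prob = 0,
                             qpcr_noise_sd = 0.2, infection_sdlog = 0.8,
                             seed = NULL) {
  stopifnot(n_females > 0, eggs_mean >= 31)
  pred <- predict_cross(female_rep, male_rep, binding)
  beta_marker <- region_marker("cidA", "upstream", "\u03b2(2)")
  s16_marker <- region_marker("cidA", "downstream", "16")
  true_marks <- c(cidA_total = marker_copies(female_rep, "cidA"),
                  cidA_beta = marker_copies(female_rep, beta_marker),
                  cidA_16 = marker_copies(female_rep, s16_marker))
  with_seed(seed, {
    eggs <- 30L + rpois(n_females, eggs_mean - 30)
    fertilized <- runif(n_females) >= unfert_prob
    larvae <- integer(n_females)
    if (pred$compatible) {
      p <- rbeta(n_females, hr_alpha, hr_beta)
      larvae <- rbinom(n_females, eggs, p)
    } else {
      leak <- runif(n_females) < leak_prob
      larvae[leak] <- 1L
    }
    larvae[!fertilized] <- 0L
    hr <- ifelse(fertilized, larvae / eggs, NA_real_)
    # qPCR-style multiplicative noise on the marker quantifications:
    # triplicate-mean of 2^N(0, sd*sqrt(2)) per female and marker.
    noisy <- function(true) {
      if (true <= 0) return(rep(0, n_females))
      m <- matrix(2^rnorm(3 * n_females, 0, qpcr_noise_sd * sqrt(2)),
                  nrow = n_females)
      true * rowMeans(m)
    }
    out <- data.frame(
      female_id = sprintf("F%04d", seq_len(n_females)),
      female_genotype = female_rep$label %||% "unknown",
      male_line = male_rep$label %||% "unknown",
      eggs = eggs, larvae = larvae, hr = hr, fertilized = fertilized,
      cidA_total = noisy(true_marks[["cidA_total"]]),
      cidA_beta = noisy(true_marks[["cidA_beta"]]),
      cidA_16 = noisy(true_marks[["cidA_16"]]),
      infection = rlnorm(n_females, 0, infection_sdlog),
      stringsAsFactors = FALSE)
    class(out) <- c("cid_crosses", "data.frame")
    out
  })
}

#' Simulate the mixed-genotype female panel of a Slab x Ist cross
#'
#' Convenience wrapper building a panel with the three Slab genotypes
#' crossed to Ist males (defaults reproduce the study's 58/8/23 genotype
#' mix).
#'
#' @param n_b16pp,n_b16pm,n_bmm females per genotype.
#' @param male_rep male repertoire (default the `IST` preset).
#' @param library region library for the presets.
#' @param seed RNG seed.
#' @param ... passed to [simulate_crosses()].
#' @return A `cid_crosses` data.frame (rows concatenated over genotypes).
#' @export
simulate_study_panel <- function(n_b16pp = 58, n_b16pm = 8, n_bmm = 23,
                                 male_rep = NULL,
                                 library = default_region_library(),
                                 seed = NULL, ...) {
  male_rep <- male_rep %||% build_preset_repertoire("IST", library)
  with_seed(seed, {
    parts <- list(
      simulate_crosses(build_preset_repertoire("SLAB_B16PP", library),
                       male_rep, n_females = n_b16pp, ...),
      simulate_crosses(build_preset_repertoire("SLAB_B16PM", library),
                       male_rep, n_females = n_b16pm, ...),
      simulate_crosses(build_preset_repertoire("SLAB_BMM", library),
                       male_rep, n_females = n_bmm, ...))
    out <- do.call(rbind, parts)
    out$female_id <- sprintf("F%04d", seq_len(nrow(out)))
    class(out) <- c("cid_crosses", "data.frame")
    out
  })
}

#' Simulate tandem loss along a maternal lineage
#'
#' Per generation every tandem copy is independently lost with
#' probability `loss_rate`; a proposed repertoire is rejected (and the
#' generation resampled) unless it remains viable, i.e. non-empty and
#' self-compatible under `binding` -- a repertoire whose remaining toxins
#' include one with no matching antidote is an immediate evolutionary
#' dead-end.
#'
#' @param founder starting `cid_repertoire` (must be self-compatible).
#' @param generations number of generations to simulate.
#' @param loss_rate per-copy per-generation loss probability in `[0, 1)`.
#' @param binding binding matrix used for the viability screen.
#' @param seed RNG seed.
#' @return A list of class `cid_lineage`: elements `generation` (integer
#'   vector 0..generations) and `repertoires` (list).  Attributes
#'   `lost` / `at_risk` tally realized per-copy losses among accepted
#'   proposals.
#' @export
simulate_tandem_loss <- function(founder, generations, loss_rate,
                                 binding = default_binding_matrix(),
                                 seed = NULL) {
  stopifnot(loss_rate >= 0, loss_rate < 1)
  if (!predict_cross(founder, founder, binding)$compatible)
    stop("founder repertoire is not self-compatible")
  with_seed(seed, {
    cur <- founder
    reps <- vector("list", generations + 1L)
    reps[[1]] <- cur
    lost_tally <- 0L; risk_tally <- 0L
    for (g in seq_len(generations)) {
      repeat {
        copies <- vapply(cur$tandems, `[[`, 1L, "copies")
        kept <- vapply(copies, function(k) sum(runif(k) >= loss_rate), 1L)
        if (sum(kept) == 0) next
        cand_t <- Map(function(t, k) { t$copies <- as.integer(k); t },
                      cur$tandems[kept > 0], kept[kept > 0])
        cand <- repertoire(unname(cand_t), label = cur$label)
        if (predict_cross(cand, cand, binding)$compatible) {
          lost_tally <- lost_tally + (sum(copies) - sum(kept))
          risk_tally <- risk_tally + sum(copies)
          cur <- cand
          break
        }
      }
      reps[[g + 1L]] <- cur
    }
    structure(list(generation = 0:generations, repertoires = reps),
              class = "cid_lineage", lost = lost_tally, at_risk = risk_tally)
  })
}
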