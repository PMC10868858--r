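---
title: "Inferring cid repertoires and predicting cytoplasmic incompatibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cid repertoires and predicting cytoplasmic incompatibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cidkit)
```

## The biological model

*Wolbachia* of *Culex pipiens* (*w*Pip) induce cytoplasmic incompatibility
(CI) through a toxin–antidote (TA) system: sperm of infected males carries
CidB toxins; eggs hatch only if the female's *Wolbachia* provide CidA
antidotes that bind every toxin present. *w*Pip genomes carry several
*cidA–cidB* tandem copies — the *cid repertoire* — and both genes are
polymorphic in exactly two segments, an upstream region (gene positions
< 801 for *cidA*, < 1201 for *cidB*) and a downstream region. A variant is
an upstream × downstream combination on an otherwise constant backbone, and
the combination space is what the reference bases for read assignment are
built from.

`cidkit` models this chain end to end. The binary verdict of
`predict_cross()` is intentionally simple: compatibility iff every distinct
male toxin has at least one binding female antidote, copy numbers ignored.
Quantitative (partial-CI) prediction is out of scope by design — observed
hatch-rate variability in compatible crosses is not explained by the *cid*
markers, so a repertoire-based quantitative model would have no support.

The binding matrix is data, not code. The default encodes two rules: the
tandem-partner conjecture for the within-line pairs (each toxin is rescued
by the antidote it is amplified with: α(5)-25 ↔ ae3, γ(3)-12 ↔ ag1), and
recombinant-for-recombinant binding at interaction interface I (any β- or
δ-cluster cidA upstream region binds any cidB carrying the recombinant
downstream-2 region). Interface I is formed by the cidA upstream and cidB
downstream regions, which is why those two fields match at the cluster
level while the other two match exactly. The other two interfaces are not
modelled; which Slab antidote rescues which Slab toxin is a conjecture, so
`binding_matrix()` accepts any replacement rule set (CSV-serializable).

## What the synthetic generator emulates

The generator exists so that every pipeline stage is testable without any
sequence download; its defaults are the study conditions.

* **Region library** (`default_region_library()`): backbones of 1,400 nt
  (cidA) and 2,000 nt (cidB) — amplicon-scale stand-ins, configurable;
  independent regions diverge from the backbone at 2% of positions, so two
  regions differ at ≈ 30 sites, comfortably above the ≤ 3-SNP
  within-cluster radius of the nomenclature. The β(2) and δ(1) upstream
  regions and the cidB downstream-2 region are true mosaics built as
  `parent1[..b] + parent2[b..]`.
* **Preset repertoires**: (β−,16−) = {α(5)-25_ae3 ×2, γ(3)-12_ag1} (3
  copies); (β+,16−) adds β(2)-25_ae3 and a second γ(3)-12 tandem on ae3;
  (β+,16+) instead carries β(2)-16_ae3 (5 copies, 4 distinct cidA
  variants). The Istanbul-like preset is configurable; its default toxin
  carries the downstream-2 region, which is the only property the TA
  analyses rely on.
* **Reads**: each read is drawn from a tandem with probability ∝ copies ×
  lognormal(0, `bias_sd`) — one bias draw per tandem per run, emulating
  amplification bias — then passed through a per-position error process at
  rate 0.05 with substitution:insertion:deletion = 60:20:20,
  homopolymer-independent. Chimeric reads, quality trajectories and
  basecalling are deliberately not simulated, so passing tests say nothing
  about those artifacts in real data.
* **qPCR**: noise is Gaussian on the Cq scale (SD 0.2 cycles per
  replicate), not on the ratio scale, matching replicate-level variability;
  an absent marker returns a Cq-40 sentinel. With efficiency 1 the
  estimator reduces to `2^(Cq_wsp − Cq_target)` averaged over the three
  replicate pairs.
* **Crosses**: eggs per raft are `30 + Poisson(25)` (no tiny rafts, which
  would destabilize hatch rates); compatible females draw a hatch
  propensity from Beta(2, 1.5) before the binomial, giving the strong
  raft-level overdispersion seen in real panels; incompatible crosses are
  all-zero except a single-larva leak with probability 0.04 (≈ one leak
  among two dozen incompatible rafts).

## Inference and numerical choices

**Read assignment** is by minimal Levenshtein distance to the reference
entries. Because all entries of a database are same-length amplicons
differing by substitutions only, each read is aligned once — an exact
banded global alignment (Rcpp) whose band doubles automatically whenever
the optimal path touches the band edge — and every entry is then scored
from the projected alignment at its divergence columns. The projected
score is the cost of a valid alignment, hence an upper bound on the exact
distance that is tight except when a read indel lands on a divergence
column; with ≈ 30-SNP margins between references the induced ranking is
the exact-distance ranking (the suite cross-checks this against
`utils::adist`). Reads whose two best distances tie are discarded rather
than randomly assigned, so coverage tables are seed-independent; reads
farther than 15% of their length from every entry are discarded as
unassignable.

**Calling** keeps entries at ≥ 5% of assigned reads: the smallest true
per-copy fraction in a five-copy repertoire is 0.2, so 0.05 leaves a wide
margin for amplification bias while suppressing error-driven noise
assignments. Retained in-silico entries are flagged as novel combinations.
Novel-SNP screening reports columns whose top non-reference allele exceeds
3× the assumed error rate (needs ≥ 100 reads); biallelic columns with
minor frequency > 0.2 are phased by per-read co-occurrence at agreement
> 0.8. These thresholds are implementation choices, stated here because no
published values exist for them.

**Copy numbers**: the continuous qPCR total is rounded to the nearest
integer with an ambiguity flag beyond ± 0.3 — observed totals range from
about 2.2 to 6.2 around true values of 3 and 5, and intermediates are
attributed to qPCR variability, so a hard failure would be wrong but an
unflagged round would hide real uncertainty. The composition is the
exhaustive argmax of the multinomial log-likelihood with every called
variant constrained to ≥ 1 copy (it was seen in the reads); enumeration is
exact for totals ≤ 12, far beyond observed repertoire sizes. Ties break to
the lexicographically smallest composition in variant-name order, making
results order-independent. Line-level totals pool the per-female estimates
of 8 simulated individuals, mirroring the practice of quantifying 8–10
females per line; a single triplicate at Cq-noise 0.2 has a ≈ 12% standard
error, too noisy to pin an integer total reliably, while the 8-female mean
is accurate to ≈ 4%.

**Coinfection screening** fits equal-variance Gaussian mixtures with 1–3
components (mclust) and selects by BIC, declaring multimodality only when
the best model has ≥ 2 components separated by > 2 pooled SD. A mixture
was chosen over a dip test because it also yields the mode locations
(≈ 3 and ≈ 5 copies), which are themselves informative.

**Region taxonomy** replaces phylogenetic-network construction with
single-linkage clustering at ≤ 3 SNPs — the downstream use of the network
is cluster membership, which single linkage reproduces exactly; splits
graphs are cosmetic for this purpose. Cluster labels are assigned by
decreasing size with lexicographic tie-break (the historical letter
assignment is not reconstructible), Greek for cidA upstream, Latin for
cidB upstream, digits for downstream regions. Recombination detection
scans all ordered parent pairs and breakpoints ≥ 50 nt from both ends,
tolerating ≤ 1 unexplained SNP, and refuses to call a child that is within
the clustering threshold of a single parent. Interface-I peptide
coordinates are not published; the packaged default window is marked
illustrative and real analyses must supply their own.

**Statistics**: hatch rates are analyzed as per-raft binomial counts
(larvae of eggs) in a plain binomial GLM with likelihood-ratio tests —
overdispersion is deliberately not modelled in the test because the
published analysis used a plain binomial GLM; the type-I calibration in
the acceptance suite therefore uses binomial nulls. Levene tests use
median centring (Brown–Forsythe) by default with a `center` switch, since
the centring convention is not stated. A replicate covariate can be added
to both the null and full models via `covariates=`; it is off by default
because the published model specification leaves it open.

## Problem sizes and determinism

All randomness flows through one seeded RNG per call (`seed` arguments;
internally `with_seed()` restores the caller's RNG state). The test suite
runs the full-scale end-to-end check — 20 seeds × two preset architectures
× 20,000 tandem-amplicon reads at 5% error plus pooled qPCR — and expects
≥ 90% exact recovery of variant sets, totals and tandem counts; module
tests use smaller read counts (hundreds to thousands) chosen to keep the
whole suite in the tens of minutes on one core while leaving every
statistical assertion well-powered. `run_pipeline()` writes a JSON + CSV
report that is byte-identical under a fixed seed.

## Known limitations

* Variants whose regions are absent from the known region library are only
  reachable via novel-SNP flagging, not called de novo (no assembly).
* The error model is homopolymer-independent; real Nanopore error is not.
* Binding is binary and interface-I-centric; partial rescue, dosage
  effects and the other two interaction interfaces are not modelled.
* The coinfection screen tests the marginal copy-number distribution; a
  coinfection perfectly balanced across all individuals would evade it.
* Exact reproduction of published test statistics on the study's own
  per-female table requires that table as input (`read_cross_table()`
  accepts its CSV layout); the suite instead verifies the printed summary
  counts on a synthetic stand-in panel constructed from them.
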