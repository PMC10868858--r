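# cidkit

Inference of *Wolbachia* (*w*Pip) **cid-gene repertoires** and prediction of
**cytoplasmic incompatibility (CI)** in *Culex pipiens* crosses.

CI is a *Wolbachia*-induced embryonic lethality: eggs of a female die unless
her CidA antidotes neutralize the CidB toxins deposited by the male's sperm.
In *w*Pip the *cidA* (antidote) and *cidB* (toxin) genes sit in amplified
*cidA–cidB* tandems; the full multiset of tandem copies in one *Wolbachia*
genome is the **cid repertoire**. Each gene is polymorphic in two segments —
an upstream region (before nucleotide 801 for *cidA*, 1201 for *cidB*) and a
downstream region — and a variant is named by its gene, *w*Pip group and
region pair, e.g. `cidA-III-β(2)-16` or `cidB-III-ae3`.

`cidkit` implements the full inference chain from raw observations to CI
predictions:

* **Amplicon calling** — assign long noisy reads (cidA, cidB, or the tandem
  cidAB amplicon) to a reference base of all known *and in-silico* region
  combinations by minimal edit distance (banded alignment in C++), call the
  variants above a coverage threshold, screen for novel SNPs with haplotype
  phasing, and reconstruct cidA–cidB tandem pairings.
* **Copy numbers** — estimate copies per genome from relative qPCR
  (`(1+E)^ΔCq` against the single-copy gene *wsp*), then fuse the continuous
  total with relative read coverage into integer per-variant copies by
  exhaustive multinomial maximum likelihood: the composition `c` with
  `c_i ≥ 1`, `Σ c_i = T` maximizing `Σ n_i log(c_i / T)`.
* **Genotypes & coinfection** — classify females as (β+,16+), (β+,16−) or
  (β−,16−) from marker qPCRs, and test copy-number distributions for
  bimodality (equal-variance Gaussian mixtures, BIC) to exclude lasting
  coinfection.
* **Region taxonomy** — single-linkage SNP-distance clustering (≤ 3 SNPs per
  cluster) with canonical nomenclature, and exhaustive breakpoint scans that
  detect recombinant (mosaic) regions such as the β upstream region
  (an α/γ mosaic) and the cidB downstream-2 region (a 1/3 mosaic).
* **Toxin–antidote model** — a replaceable CidA×CidB binding matrix (tandem
  partners bind; recombinant β/δ antidotes bind recombinant downstream-2
  toxins) drives `predict_cross()`: a cross is compatible iff every male
  toxin is bound by some female antidote.
* **Hatch-rate statistics** — binomial GLM likelihood-ratio tests for marker
  effects, Spearman associations, Levene (Brown–Forsythe) variance
  comparisons.
* **Synthetic data** — generators for region libraries, preset repertoires
  (the three Slab sublines and an Istanbul-like line), amplicon reads with
  amplification bias and substitution/indel errors, triplicate qPCR with
  Cq-scale noise, and individual-female cross panels with overdispersed
  hatch rates and rare single-larva leakage.

## Worked example

```r
library(cidkit)
lib <- default_region_library()
truth <- build_preset_repertoire("SLAB_B16PP", lib)   # (β+,16+), 5 copies

# simulate a sequencing run and a pooled qPCR total
reads <- simulate_amplicon_reads(truth, "cidAB", 20000,
                                 error_rate = 0.05, bias_sd = 0.3, seed = 7)
total <- simulate_line_total(truth, "cidA", n_females = 8,
                             noise_sd = 0.2, seed = 8)

# infer the repertoire from the data alone
known <- unlist(lapply(c("SLAB_B16PP", "SLAB_B16PM", "SLAB_BMM"), function(p) {
  r <- build_preset_repertoire(p, lib)
  c(repertoire_variants(r, "cidA"), repertoire_variants(r, "cidB"))
}), recursive = FALSE)
infer_repertoire(reads, known, as.numeric(total))
```

```
<cid_inference> 5 tandem copies over 4 pairing(s)
                        tandem             cidA         cidB fraction copies
 cidA-III-α(5)-25_cidB-III-ae3 cidA-III-α(5)-25 cidB-III-ae3  0.62220      2
 cidA-III-β(2)-16_cidB-III-ae3 cidA-III-β(2)-16 cidB-III-ae3  0.14130      1
 cidA-III-β(2)-25_cidB-III-ae3 cidA-III-β(2)-25 cidB-III-ae3  0.12715      1
 cidA-III-γ(3)-12_cidB-III-ag1 cidA-III-γ(3)-12 cidB-III-ag1  0.10935      1
```

The five tandem copies (two of `α(5)-25_ae3`, one each of the others) match
the simulated genome exactly: the qPCR total fixed `T = 5` and the coverage
fractions resolved the per-tandem multiplicities. Downstream,

```r
predict_cross(build_preset_repertoire("SLAB_BMM", lib),
              build_preset_repertoire("IST", lib))
#> <cid_compat> INCOMPATIBLE; uncovered toxin(s): cidB-IV-ak2
```

shows why (β−,16−) females — which lack the recombinant β antidote — cannot
rescue males whose toxin carries the recombinant downstream-2 region.

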