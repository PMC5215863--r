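# countseg

De novo chromatin-state annotation from multivariate sequencing count
tracks, for epigenomics researchers who want to map promoters, enhancers
and repressed domains from histone-modification ChIP-seq and accessibility
data — plus the benchmarking and enrichment statistics needed to evaluate
the resulting maps.

## The model

The genome is tiled into fixed-width bins (200 bp default) and each assay
("track") is summarized by fragment-midpoint counts per bin. A hidden
Markov model with K states is fitted to the resulting count matrix
O = (o_0, ..., o_T), o_t ∈ ℕ^D. Conditional on the hidden state, tracks
are independent: ψ_k(o_t) = ∏_d ψ_{k,d}(o_{t,d}). Two overdispersed
emission families are supported, each with state- and track-specific
variance:

* negative binomial (Poisson–Gamma), mean μ, size r,
  variance μ + μ²/r;
* Poisson-lognormal (Poisson with lognormal rate), parameters
  (μ_log, σ), evaluated by deterministic quadrature.

Fitting is Baum–Welch with a log-space forward–backward E-step and a
grouped-count M-step: emission objectives are collapsed onto unique
counts, argmax_ψ Σ_{c∈C_d} f_c log ψ(c) with
f_c = Σ_{t: o_t = c} Pr(s_t = i | O). Library-size differences between
cell types are handled by total-count size factors
s_{d,l} = (1/r_{d,l}) · mean_k r_{d,k}; emission means are scaled by the
depth-relative factor 1/s_{d,l} inside the likelihood. Initialization
follows the Poisson-threshold / background-cluster / k-means scheme;
decoding is per-bin posterior argmax (Viterbi available).

Evaluation tools: per-state precision ranking against reference region
sets, cumulative recall/FDR curves, bin-level AUC from state ranks,
TF enrichment (TF_s^nt/TF^nt)/(s^nt/l) with per-TF normalization,
TF–TF co-binding Jaccard within states, GWAS trait enrichment
(one-sided Fisher vs rest-of-catalog, Benjamini–Yekutieli adjustment,
≥20-variant filter) and coverage-controlled SNP recall by segment
subsampling. A seeded synthetic-data module generates HMM count tracks,
reference regions, TF peaks and GWAS catalogs with known truth.

## Worked example

```r
library(countseg)

genome <- binned_genome(data.frame(chrom = "chrS", length = 2e6), bin_width = 200)
truth  <- example_model(K = 3, D = 2, family = "negbinom")
sim    <- simulate_hmm_counts(truth, genome, seed = 1)

init <- initialize_hmm(sim$counts[[1]], K = 3, family = "negbinom", seed = 1)
fit  <- baum_welch(init, sim$counts[[1]])
glance(fit)
#> # A tibble: 1 × 6
#>   n_states n_tracks family   log_likelihood iterations converged
#>      <int>    <int> <chr>             <dbl>      <int> <lgl>
#> 1        3        2 negbinom        -36859.          8 TRUE

tidy(fit)[, c("state", "track", "mean")]
#> # A tibble: 6 × 3
#>   state track    mean
#>   <int> <chr>   <dbl>
#> 1     1 track1  0.498
#> 2     1 track2  0.510
#> 3     2 track1 20.0
#> 4     2 track2  0.502
#> 5     3 track1  0.511
#> 6     3 track2 20.0

path <- posterior_decode(forward_backward(fit, sim$counts[[1]]))
mean(path == sim$truth$paths[[1]])   # state accuracy (labels matched truth here)
#> [1] 0.9984

annotation <- path_to_segments(path, genome)
truth_ann <- path_to_segments(sim$truth$paths[[1]], genome)
refs <- truth_ann[truth_ann$state == "S3", ]   # the planted state-3 regions
auc_score(annotation, refs, genome)
#> [1] 0.9994552
```

The fitted means recover the generating model (background 0.5 reads/bin,
signal 20 reads/bin on each state's own track), the decoded path matches
the simulated truth on 99.8% of bins, and the true state-3 regions are
ranked almost perfectly by the annotation (AUC ≈ 0.999). Fitted state
labels are only identified up to permutation in general; in this run they
come back in the planted order.

## Command line

A `countseg` executable ships in `inst/cli/`
(`system.file("cli", "countseg", package = "countseg")`):

```sh
countseg simulate  --spec sim.json --seed 1 --out-dir fixtures/
countseg bin       --reads H3K4me3=reads.tagAlign --genome chrom.sizes --shift auto --out counts.tsv
countseg fit       --counts K562=counts.tsv --states 18 --family poilog --seed 1 --out model.json
countseg decode    --model model.json --counts counts.tsv --genome chrom.sizes --out states.bed
countseg benchmark --states states.bed --reference tss.bed --genome chrom.sizes --out curve.tsv
countseg enrich    gwas --states states.bed --genome chrom.sizes --catalog gwas.tsv \
                   --state-group Enh,EnhW --coverage 0.02 --seed 1 --out gwas.tsv
```

All outputs are plain text with `#`-prefixed provenance headers and are
byte-identical across reruns with the same seed.

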