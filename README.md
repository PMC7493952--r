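# sepol

Super-enhancer polarization and epigenetic entropy analysis for
compressive-force mechanoresponse ChIP-seq.

## The problem

When cells are put under mechanical compression, the H3K27ac signal over
super-enhancers (SEs) does not simply shrink — it *delocalizes*. Sharp
constituent-enhancer peaks flatten, low wide "hillocks" of acetylation
fill the space between them, and the SE's one-sided H3K27me3 boundary
domain is what normally keeps the signal polarized. Restoring EZH2 levels
during force (oeEZH2) flattens SE signal even further. Total signal is a
poor readout of this; its *shape* is the phenotype.

## The core statistic

`sepol` quantifies shape with a per-region Shannon entropy ("epigenetic
entropy"). Per-base normalized density `d_i` over a region of length `L`
is turned into a probability mass function
`p_i = (d_i + eps) / sum(d_j + eps)` and scored as
`H = -sum(p_i * log2(p_i))` bits, so `0 <= H <= log2(L)`: low entropy =
polarized SE, high entropy = flattened SE. The adaptive pseudocount makes
`H` exactly invariant under library-size renormalization. Condition
effects are reported as per-SE entropy differences, calibrated against
two nulls (input-vs-input deltas on the same regions, and matched-length
random genomic regions) and tested with an exact-where-feasible Wilcoxon
signed-rank test.

Around it sits the full pipeline: an ecdf-difference-peak partition of
differentially expressed genes by absolute expression difference (AED),
ROSE-style SE calling (12.5 kb stitching, input-corrected scores,
rank-curve inflection cutoff), SE orientation against flanking H3K27me3,
TSS metaprofiles, and a synthetic-data generator with a ground-truth
manifest whose defaults emulate the force / force+oeEZH2 study design.

## Worked example

Everything below is deterministic in `(config, seed)`.

```r
library(sepol)

cfg <- synthetic_config(genome_length = 3e6, n_genes = 300, n_ses = 18,
                        n_typical = 90,
                        group_counts = c(strong_up = 71, weak_up = 75,
                                         strong_down = 26, weak_down = 116))
res <- run_pipeline(cfg, seed = 2)

res$partition$t_star
#> [1] 1.494386
res$partition$counts
#>   strong_up     weak_up strong_down   weak_down
#>          68          79          21         120

sapply(res$se_sets, function(g) sum(g$is_super))
#>      control        force force_oeEZH2
#>           25           26           32

## median per-SE entropy change (bits): background ~ 0 < force < force+oeEZH2,
## H3K27me3 indistinguishable from background
sapply(res$entropy$deltas, function(d) d$summary[["median"]])
#>       background            force     force_oeEZH2        me3_force
#>      0.002482290      0.899717785      1.014884344      0.006641455
#> force_bg_regions
#>      0.003101425

res$entropy$report$vs_zero
#>                set  n      median   W      p_value     p_adj_bh
#> 1       background 25 0.002482290 189 4.841898e-01 5.011555e-01
#> 2            force 25 0.899717785 302 1.839758e-04 4.599395e-04
#> 3     force_oeEZH2 25 1.014884344 325 1.307061e-05 6.535303e-05
#> 4        me3_force 25 0.006641455 188 5.011555e-01 5.011555e-01
#> 5 force_bg_regions 25 0.003101425 196 3.745794e-01 5.011555e-01
```

The force condition raises median SE entropy by ~0.9 bits and preserving
EZH2 during force raises it further (~1.0 bits), while both nulls and the
repressive mark sit at zero — the study's qualitative signature,
recovered from synthetic data with known truth.

See `vignettes/epigenetic-entropy.Rmd` for the model, every generator
parameter and its rationale, and the numerical choices.

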