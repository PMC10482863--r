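# efnet — evolving elementary-functionome networks

`efnet` reconstructs and analyses the coevolution of protein **loop
prototypes** (supersecondary motifs, e.g. `DS.HE.3.1.1`) and **fold-family
domains** (SCOP concise classification strings, e.g. `c.37.1.12`) along a
phylogenomic chronology. Domains carry a relative time of origin *nd* ∈
[0, 1] (0 = origin of proteins, 1 = the present), convertible to geological
time through a linear molecular clock anchored at 3.8 Gy. The package is
aimed at molecular-evolution researchers studying how modular building
blocks are recruited into growing structures.

The core objects and statistics:

- **Age transfer and classification.** A loop inherits its age from its
  domains: scheme 1 takes the age of the most ancient associated domain,
  scheme 2 the more recent of the two most ancient (with a founder
  exception at the global minimum age). Prototypes are labelled
  **M** (mapped to domains of ≥ 2 distinct ages), **M′** (≥ 2 contemporaneous
  domains) or **NM** (a single domain), and domains fall into Venn groups by
  the loop kinds they recruit.
- **Networks.** The *elementary functionome* (EF) is the bipartite graph of
  M loops and their domains. One-mode projections connect loops sharing a
  domain (and domains sharing a loop) with arc weight = number of shared
  partners and direction old → young (seeded coin flip for contemporaneous
  pairs). Each distinct node age is a *time event*; cumulative snapshots
  form a growing network series.
- **Per-event statistics.** Degree distributions are tested for scale-free
  behavior with P(k) ~ k^(−γ) regression (γ, R²), discrete maximum-likelihood
  exponents α (zeta normalization) and a Kolmogorov–Smirnov fit statistic
  with bootstrap p-values; Barabási and Barabási-age growth models serve as
  controls. Modularity is tracked with six indices — Newman–Girvan
  Q = (1/2m) Σ_ij (A_ij − k_i k_j / 2m) δ(c_i, c_j) partitioned by age
  (NG_age) or by detected communities (NG_vos), VOS quality, fast-greedy
  community modularity, the average clustering coefficient C and the
  clustering ratio — plus scaled pairwise modularity matrices
  (A_ij − k_i k_j / 2m)·M_nd with Ward dendrograms.
- **Waterfall layouts** place age on the vertical axis and a
  community-constrained Kamada–Kawai spread on the horizontal axis, with
  Pajek (.net/.clu), GraphML and TSV exports.
- **Loop stitching** builds time-ordered growing molecular intermediates
  (`34 → 34|213 → 34|80|213 → 34|80|186|213`) and replacement variants for
  fold-emergence modeling, written as multi-FASTA.
- **Synthetic data** with planted ground truth (NM fraction,
  contemporaneous pairs, preferential reuse, planted communities) makes the
  whole pipeline testable offline.

## Worked example

```r
library(efnet)

ds <- generate_dataset(synth_config(n_domains = 400, n_events = 50,
                                    seed = 42L))
cls <- classify_prototypes(ds$mapping, ds$chronology)
cls
#> <ef_classification> 400 loops: 94 M, 4 M', 302 NM

ef <- build_bipartite(ds$mapping, ds$chronology, subset = "M")
lp <- project(ef, "loop", seed = 43L)
c(density = projection_density(lp), avg_degree = node_average_degree(lp))
#>    density avg_degree
#> 0.01876001 3.48936170

modularity_report(lp, seed = 46L)
#> <ef_modreport> NG_age 0.046 | NG_vos 0.512 | VQ 0.512 | FGC 0.507 |
#>   C 0.2532004 | C-ratio 0.2209302 (19 communities)
```

The classification splits the 400 simulated prototypes into modular,
contemporaneous-modular and non-modular sets (the planted NM share was
0.72). The loop projection's density and average degree summarize how often
loops co-occur in domains; the modularity report gives the six per-event
indices of the full network — here the network is strongly community-
structured (NG_vos ≈ 0.51) but only weakly age-assortative (NG_age ≈ 0.05).

The numbered drivers under `analysis/` run the same workflow end to end
(`01_simulate.R` → `05_stitch.R`), printing what each stage found and
writing its tables under `results/`.

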