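# phylocomm

Community phylogenetics for plot-based vegetation surveys: per-plot
phylogenetic diversity and structure with randomization nulls, and distance
decay of phylogenetic similarity.

## The problem

Small presence/absence plots (here: 1 × 1 m grassland plots at the lower
timberline of the Tianshan Mountains, 17 sites / 35 plots over a ~92-species
pool) plus a dated phylogeny of the pool raise three questions: do refugial
sites hold more species than recolonized ones; is within-plot composition
phylogenetically clustered or overdispersed relative to chance; and does
phylogenetic similarity between plots decay with geographic or environmental
distance? `phylocomm` answers all three from two CSV files and a Newick tree.

Statistics implemented (SR = species richness of a plot, T = total tree
length):

* **PD** (Faith): total branch length spanned by a plot's species, rooted
  convention (MRCA-to-root path included); also reported as PD/T.
* **RPD** = PD(actual tree) / PD(equal-branch-length comparison tree with
  the same topology and total).
* **MPD, MNTD**: mean pairwise and mean nearest-taxon patristic distance.
* **NRI** = −(MPD − mean MPD₉₉₉)/sd(MPD₉₉₉), **NTI** likewise from MNTD;
  nulls from an independent-swap randomization (fixed row/column sums) or
  richness-preserving pool draws; two-tailed flags at the top/bottom 2.5%.
* **PhyloSor**(A, B) = BL_shared / (½(BL_A + BL_B)).
* Mann–Whitney U (exact for small tie-free samples), SR–environment
  correlation screen (Pearson, 25 variables + refugium indicator),
  haversine distances, standardized environmental distance, and Mantel
  permutation tests for distance decay.

A seedable generator (`generate_study()`) produces trees, Brownian traits,
site tables and assembled communities at the study's scale under neutral,
filtering and competition scenarios, so the whole pipeline is testable
offline. A bundled table (`tianshan_plots()`) transcribes the published
per-plot indices of the motivating 35-plot survey.

## Worked example

```r
library(phylocomm)

## refugial vs colonizing richness on the bundled survey table
tp <- tianshan_plots()
mann_whitney_u(tp$SR[tp$group == "refugial"], tp$SR[tp$group == "colonizing"])
#> Mann-Whitney U = 205 (n1 = 11, n2 = 24), two-sided p = 0.009608 (normal_approx), A>B
```

The 11 refugial plots (sites around the Ili Valley) are significantly richer
than the 24 colonizing plots (U = 205, p ≈ 0.0096 < 0.05).

```r
## a synthetic study under environmental filtering, analysed end to end
st <- generate_study(sim_config(seed = 7, scenario = "filtering"))
st
#> Synthetic study: 35 plots, 17 sites, 92-species pool, scenario 'filtering'
#>  richness range: 12-26

sa <- structure_analysis(st$tree, st$community,
                         structure_config(n_rand = 199, seed = 7))
sa
#> Phylogenetic structure analysis: 35 plots, 199 randomizations
#>  significant flags: PD 8 | RPD 5 | NRI 3 | NTI 10

head(sa$metric_table[, c("plot", "SR", "PD", "RPD", "NRI", "NTI")], 3)
#>    plot SR    PD   RPD     NRI   NTI
#> 1 S01-1 12 0.266 0.808  0.5537 1.309
#> 2 S02-1 13 0.290 0.910 -0.5698 1.871
#> 3 S02-2 19 0.381 0.949 -0.0664 0.837
```

`PD` is proportional (PD/T); positive NRI/NTI indicate phylogenetic
clustering, which the filtering scenario plants (NTI flags fire at 10/35
plots here). `run_full(pipeline_config(...))` executes the same stages from
files and writes TSV/JSON reports plus a provenance record; the command line
equivalent is

```sh
Rscript -e 'quit(status = phylocomm::phylocomm_cli())' full-run \
  --tree tree.nwk --community community.csv --sites sites.csv \
  --out results --seed 7
```

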