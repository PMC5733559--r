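---
title: "Methods: phylogenetic diversity, structure nulls, and distance decay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic diversity, structure nulls, and distance decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`phylocomm` re-implements, as a tested pipeline, the community-phylogenetics
workflow used for plot-based vegetation surveys in which a species pool is
scored as present/absent in small plots and a dated phylogeny of the pool is
available: per-plot diversity (SR, PD, RPD), standardized structure indices
(NRI, NTI) against randomization nulls, and phylogenetic beta diversity
(PhyloSor) related to geographic and environmental distance. The motivating
design is a survey of grassland plots at the lower timberline of the Tianshan
Mountains, where western sites near the Ili Valley acted as glacial refugia
and the east was recolonized after glaciation.

## The statistics and their conventions

**Faith's PD** is the total branch length spanned by a plot's species. We use
the *rooted* convention: the spanning set includes the path from the species'
MRCA up to the root. Two consequences make this convention attractive: PD is
monotone under adding species, and PD of the full pool equals the total tree
length exactly (both are tested as invariants). The MRCA-only variant is a
possible later addition; nothing downstream depends on the choice of
convention beyond the reported values. The root's own incoming edge length,
when a Newick file carries one, is a serialization artifact and is ignored
everywhere.

**Proportional PD** divides PD by the total tree length. The bundled
reference table reports PD on this scale (values around 0.11–0.17 on a tree
dated in Ma are not raw branch-length sums), so the pipeline's metric table
defaults to `pd_convention = "proportional"` and always carries both columns
(`PD_raw`, `PD_prop`).

**RPD** divides a plot's PD on the real tree by its PD on a comparison tree
with the same topology and equal branch lengths that preserve the total
(`equalize_branch_lengths()`). RPD > 1 signals over-representation of long
branches (overdispersion), RPD < 1 of short branches (clustering). On the
comparison tree a spanning set of $m$ edges has PD $= m \cdot L$ with
$L = \text{total}/n_{\text{edges}}$, which the implementation exploits.

**MPD / MNTD** are the mean pairwise patristic distance and the mean
nearest-neighbour patristic distance within a plot. Both are undefined for
single-species plots and are reported as `NA` there — not 0, which would
silently bias null comparisons.

**NRI / NTI** are $-1 \times$ the standardized effect size of MPD / MNTD
against a null distribution:
$\mathrm{NRI} = -(\mathrm{MPD} - \overline{\mathrm{MPD}}_{\mathrm{rand}}) /
\mathrm{sd}(\mathrm{MPD}_{\mathrm{rand}})$, with the sample standard
deviation over 999 randomized assemblages by default. Positive values mean
co-occurring species are more related than chance (clustering).

**PhyloSor** between plots $A$ and $B$ is
$BL_{\mathrm{shared}} / \tfrac12 (BL_A + BL_B)$ over the rooted spanning
sets; it is 1 for identical composition and 0 for plots sharing no
positive-length branches. Zero-length branches contribute nothing; a plot
pair spanning zero total length is rejected rather than returning 0/0.

## Null models and significance

Two nulls are available for every statistic:

* **independent swap** — repeated random 2×2 checkerboard flips of the
  binary matrix, preserving all row (plot richness) and column (species
  occurrence frequency) sums. Each of the 999 null matrices is produced from
  the *original* matrix by a fresh chain of `10 × plots × species` attempted
  swaps, folding burn-in into every chain and leaving the null draws
  uncorrelated. The chain is implemented in C++ because a default analysis
  attempts ~32 million swaps.
* **richness-preserving pool draw** — a uniform random subset of the pool at
  the plot's observed richness.

By default NRI/NTI use the independent swap and PD/RPD significance uses the
richness-preserving draw (the original analysis computed PD/RPD significance
in a program whose null "retained structural features" of the data; per-plot
richness is the minimal such feature, and the choice is configurable).

Two-tailed significance ranks the observed value within the set
{999 nulls + observed}; a plot is flagged `high`/`low` when its quantile
position passes $1 - \alpha/2$ / $\alpha/2$ (top or bottom 2.5% at
$\alpha = 0.05$). Ties are resolved by midranks, so an observed value equal
to a block of null values sits at the centre of that block. A null
distribution with zero spread (a plot equal to the pool) yields SES 0 with
an explicit degeneracy flag rather than an error.

All randomness flows from one master seed. Per-plot pool-draw streams are
derived deterministically from `(seed, plot id)` and the swap stream from
`(seed, "swap")`, so results do not depend on plot evaluation order and
replays are byte-identical. One economy is worth noting: `structure_analysis()`
shares a single set of 999 swap matrices across plots, which is marginally
equivalent to per-plot chains (each plot only reads its own row) and ~35×
cheaper; standalone `nri()`/`nti()` calls build their own chains.

## The statistical stage

The refugial/colonizing SR comparison uses a Mann–Whitney U test with
midranks: exact enumeration of all rank assignments when $n_1 + n_2 \le 12$
with no ties (doubling rule for the two-sided p), otherwise the normal
approximation with tie and continuity corrections — the same construction
`wilcox.test` uses, which serves as the test oracle.

The correlation screen relates SR to 25 environmental variables (altitude,
19 bioclimatic, 5 soil) plus a refugium indicator. Pearson correlation is the
default because the original analysis names only "correlation coefficients"
computed in a general statistics package whose default is Pearson; the binary
indicator then yields the point-biserial coefficient. Spearman is available
behind `method = "spearman"`. Per-variable stars (0.05, 0.01) are reported
without multiple-testing correction, matching the per-variable presentation
of the source, and a Benjamini–Hochberg `q` column is added for transparency.

Geographic distance is the haversine great-circle distance (Earth radius
6371 km) at plot coordinates; no projection is assumed. Environmental
distance z-scores each variable across plots before Euclidean distance —
the variables mix metres, degrees and soil indices, and unstandardized
distance would be dominated by the large-magnitude ones; zero-variance
variables are dropped with a warning and count toward neither the numerator
nor the dimension. Distance decay of PhyloSor is summarized by the Pearson
correlation and least-squares slope per distance axis, with inference from a
two-sided Mantel permutation test (≥ 999 joint row/column permutations);
plot pairs are not independent, so ordinary regression p-values are not
reported as primary.

## The synthetic world

The generator states one world and the tests live in it: a 92-species pool
on an ultrametric pure-birth tree of depth 110 time units (the deepest
calibration of the motivating study's tree), one Brownian trait
(`sigma2 = 1`, trait SD ≈ 10.5 at the tips), 17 sites / 35 plots on a
west–east transect with the 6 western sites (11 plots) refugial, base
per-plot richness uniform on 10–21 plus a +5 refugial shift (overall span
10–26, matching the reference table's group medians), and 25 environmental
variables that are linear in the west–east gradient and/or the group
indicator plus Gaussian noise, with the strong links on altitude and four
temperature variables — the variables the motivating survey found
significant. A `pool_split` switch assigns disjoint pool halves to the
western and eastern blocks, the positive control for distance decay.

Assembly scenarios: *neutral* draws uniform subsets; *filtering* samples
without replacement with weights
$\exp(-(x_i - \mu_p)^2 / 2w^2)$ around a plot optimum that tracks the
gradient; *competition* admits species in random order rejecting any within
trait distance $d$ of an admitted one, halving $d$ (with a logged note) when
the target richness is unreachable.

Two scenario knobs were calibrated once, on seeds disjoint from every test
seed, and then frozen. `filter_width = 1` (~0.1 trait SD) emulates strong
abiotic filtering and yields mean NRI around +1 to +2. `limiting_radius = 12`
(~1.1 trait SD) gives the most consistently negative NRI among the values
examined, but a structural limit applies: with a *single* Brownian trait on
a deep pure-birth tree, trait distance and patristic distance correlate only
weakly (~0.13 here), and random subsets of such a pool already sit near the
MPD maximum, so clustering is easy to generate and overdispersion hard. Even
selecting species to directly maximize patristic spread (bypassing traits)
only reaches mean NRI ≈ −0.5 under the swap null; trait-mediated limiting
similarity tops out around −0.1 to −0.35. The acceptance expectation of mean
NRI < −0.5 for this scenario is therefore left failing by design, with the
analysis recorded; the unit suite asserts what the world can deliver — sign
separation of the three scenarios.

What a green test does **not** establish: the generator has no spatial
dispersal, no abundance structure, one trait axis, and environmental
variables independent of community assembly given the gradient; real
surveys violate all of these.

## Numerical and degenerate-input choices

* Ultrametricity is checked with relative tolerance `1e-6`; no metric
  requires it.
* `equalize_branch_lengths` preserves totals to within `1e-9` relative
  tolerance (tested over random trees).
* Newick dialect: unquoted and single-quoted labels (quotes stripped,
  content verbatim), internal labels ignored, scientific-notation lengths;
  output emits plain labels with `_` for spaces at 15 significant digits,
  and round trips are exact under `ape::all.equal.phylo`.
* Malformed Newick reports the character offset of the first unbalanced
  parenthesis; missing branch lengths name the offending edges.
* Community matrices must be strictly binary; abundances are rejected unless
  explicitly binarized (`binarize = TRUE`), because every index here is
  incidence-based.
* The bundled reference table transcribes its printed source verbatim,
  including one internal inconsistency of that source (a plot with SR = 28
  against a stated 10–26 range); the refugial site assignment (the six
  Ili-Valley sites) is a documented reading of the source's map and is
  overridable.
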