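---
title: "Prioritizing candidate genes from gene-family expansion and drought differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing candidate genes from gene-family expansion and drought differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(expanDE)
```

## The question and the model

Drought response and drought *adaptation* are different things: thousands of
genes change expression when a plant dries out, but only a subset of those
changes reflects evolved tolerance. expanDE implements a comparative
prioritization strategy for a panel of related species with contrasting
tolerance phenotypes (the motivating case is four Brassicaceae: two
drought-tolerant and two drought-sensitive species, one of them an
allotetraploid). The reasoning is:

1. Genes are grouped into hierarchical orthologous groups (HOGs, "gene
   families") across all species, e.g. by OrthoFinder. Only families with at
   least one member in *every* study species (the **Conserved Set**) are
   analyzed; everything downstream uses this set as its universe, so that
   presence/absence variation and annotation artifacts do not masquerade as
   expansion signal.
2. A family is **expanded** in a focal species when its ploidy-corrected
   copy number is at least a configurable factor (default 2) times the
   ploidy-corrected copy number of *every* species with the opposite
   phenotype. Retained duplications shared by the tolerant species but
   absent from the sensitive ones are candidates for trait-linked selection
   rather than lineage history.
3. Families are intersected with per-species differential expression
   (drought vs control, adjusted `p <= 0.1` from a count-based DE tool).
   Families expanded in all tolerant species *and* DE in at least one of
   them form the **candidate** tier; requiring DE in every tolerant species
   gives the **conserved-DE** tier; additionally requiring no DEG in any
   sensitive species and only up-regulated tolerant DEGs gives the
   **unique-up** tier. The tiers are nested by construction.
4. Every claim about these sets is an exact one-sided hypergeometric
   (equivalently, one-sided Fisher) tail probability on an explicitly stated
   universe, and the evaluation brings in two independent marks of adaptive
   relevance: cross-species conservation of DE, and precomputed
   branch-site (aBSREL-style) diversifying-selection tests, consumed as a
   table of corrected p-values.

## Ploidy correction

Copy numbers are compared on a diploid scale: a species of ploidy $p$
contributes $2c/p$ for a raw count of $c$, so a tetraploid's counts are
halved. The correction is applied *symmetrically* — a polyploid is scaled
whether it appears as the focal or a background species. The per-species
ploidy is a property of the species, not of its role in a contrast, and an
asymmetric rule would make "A expanded vs B" and "B expanded vs A"
structurally different tests. This is a genuine design choice (the
alternative, scaling only background species, is conceivable) and is the
package default throughout.

A second guard, `min_focal_copies` (default 2), requires the focal species
to carry at least two raw copies. The bare fold inequality would call a
family with one focal gene "expanded" against a tetraploid single-copy
family (1 >= 2 x 0.5), which contradicts what expansion means — a retained
duplication. Setting `min_focal_copies = 1` restores the literal
inequality for users who want it. Ties count as expanded ("at least
twice"), and the flag for a multi-focal hypothesis is the AND over its
focal species.

## The DE-conservation null

To ask whether drought DE is conserved across species or species-specific,
the package compares the observed number of families containing a DEG from
*every* species (and from *none*) with an independence null. With $s_i$
families containing a DEG of species $i$ among $N$ conserved families,
$p_{s,i} = s_i / N$ and

$$p_{s4} = \prod_i p_{s,i}, \qquad p_{f4} = \prod_i (1 - p_{s,i}),$$

giving expected counts $N p_{s4}$ and $N p_{f4}$. Observed counts are
tested with a two-cell chi-square goodness-of-fit against $(p, 1-p)$
(df = 1, no continuity correction — mirroring a plain `chisq.test(x, p)`
call, so parity with an independent R session is checkable). An excess of
both all-species and no-species families indicates conserved regulation.

```{r conservation}
conservation_null(c(esa = 7434, aly = 8866, ath = 2865, bna = 6956), 17488,
                  observed_all = 846, observed_none = 3957)
```

## The enrichment engine

All over/under-representation claims go through one code path:
`hypergeom_over()` / `hypergeom_under()` compute $P(X \ge k)$ and
$P(X \le k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$ by summing
`dhyper(log = TRUE)` terms in log space. No normal approximation is used;
the tails agree with brute-force enumeration to $10^{-12}$ over the whole
parameter range with $N \le 25$ and with `phyper`/`fisher.test` elsewhere
(both serve as independent cross-checks in the test suite, never as the
implementation). P-values are kept at full precision and conventionally
displayed at two significant figures.

Numerical and reporting conventions, chosen once:

* Thresholds on adjusted p-values are **inclusive** (`padj <= 0.1` is DE,
  `p_corrected <= 0.05` is selected); the GO reporting filter is **strict**
  (`p < 0.05`), following the different conventions of the source analyses.
* The 0.05 level is presentation metadata: the engine never filters results
  by it.
* P-values across the enrichment battery are reported raw; a
  Benjamini–Hochberg column is available as an opt-in
  (`enrichment_battery(..., bh = TRUE)`).
* Every enrichment result records its universe definition, because the
  universes legitimately differ between tests (whole Conserved Set,
  families DE in any tolerant species, families DE in both) and silent
  universe drift is the easiest way to get these statistics wrong.
* A degenerate all-zero 2x2 table returns p = 1 by convention; a DEG
  flagged with `log2fc = 0` is treated as a corrupt record and errors.
* DE records with missing `padj` (independent filtering) are retained but
  can never be flagged DE; DE genes that map to no conserved family are
  tallied as unassigned and excluded from all statistics.

## Selection integration

Only genes that passed the upstream selection workflow's quality filters
("tested", roughly 70% in the motivating study) enter either side of a
selection contingency: the published per-species percentages only
reconcile when untested genes are outside both foreground and background,
so denominators count tested genes exclusively. Three gene-level designs
are provided (`selection_report_tables()`): DEGs vs all genes
(under-representation), genes in expanded families vs all genes
(over-representation), and DEGs in expanded families vs all DEGs
(over-representation). For candidate *families*, a family is a success if
at least one group DEG is selected and drops out of the sample if all its
group DEGs are untested. The published table mixes a family-level
foreground with a gene-level background; both conventions
(`convention = "family"` and `"gene"`) are computed and labelled in the
result metadata rather than silently resolved.

## Regulation categories

Families with at least two DEGs (in the chosen scope) are classified `up`
(all DEGs up), `down` (all down) or `down_and_up` (mixed); fewer than two
DEGs is `not_applicable`. Whether the category pools DEGs across all
species or within one species is an explicit `scope` argument, because
figure-level analyses legitimately use both; across-species pooling is the
default for the tier tables. For the `unique_up` tier, a family DE in both
tolerant species necessarily has two or more DEGs across species, so the
across-species category is always defined; a stricter side-by-side variant
(`unique_up_min2`) additionally requires two DEGs within each tolerant
species, covering the other reading of the definition.

## GO over-representation

Family annotations are the union of the member genes' GO terms over all
species (gene ids are namespaced per species). Testing is classic
term-by-term one-sided Fisher on the flat annotations against the
Conserved Set, with a term "reported" when `p < 0.05` and it annotates at
least two subset families. No DAG propagation or TopGO-style term
decorrelation is performed: the original webapp's TopGO variant is
internal to that tool, and a flat Fisher test is the reproducible,
documented stand-in. Term ids are opaque strings throughout.

## The synthetic-data generator

`generate_study()` produces a complete, seeded study — orthogroups, DE
tables, selection table, GO map — plus a truth record of every planted
flag, so the whole pipeline is testable without any download, and
null-calibration and power properties of the statistics can be measured.
Its defaults are the study conditions: four species (two tolerant
diploids, one sensitive diploid, one sensitive tetraploid), per-species
copy numbers `1 + Geometric(q = 0.7)` per subgenome (the tetraploid sums
two subgenome draws; 5% species-absence knocks families out of the
Conserved Set), per-species gene-level DE rates (0.39, 0.45, 0.16, 0.26)
near the observed leaf drought-response rates, planting rates of 3% per
single-species expansion hypothesis and 1% per joint hypothesis, a
conservation coupling of 4 on the odds scale carried by 30%
"drought-responsive" families, a twofold DE-odds multiplier for genes in
planted expansions, 80% up-regulation among tolerant-expansion DEGs (50%
elsewhere), a 72% selection-test pass rate with 9.5% base selection rate
doubled for DEGs in planted tolerant expansions, and 50 GO terms at 2 per
gene with one term planted into tolerant-joint expansions.

Two design points deserve emphasis:

* **DE is assigned per gene**, which reproduces the real distinction
  between DEG counts and families-with-DEG counts. Naively this would make
  family-level DE probability grow with family size, so every family-level
  enrichment involving expansions (which have more copies by definition)
  would reject even with no planted association. The generator therefore
  compensates: a gene in a family with $c$ copies of its species gets
  $p(c) = 1 - (1-F)^{1/c}$, so the family-level probability of containing
  a DEG is $F$ for every family under null settings, and the expected DEG
  count per family is approximately $-\log(1-F)$ regardless of size. $F$
  is calibrated numerically (per species, against the realized copy-number
  distribution and the responsive-family coupling) so that the *gene-level*
  marginal matches the configured `de_base_rate`.
* Gene ids encode species and family of origin for debuggability; the
  pipeline must not exploit this, and a test re-runs the analysis after
  consistently scrambling all ids (`scramble_gene_ids()`) and checks the
  results are unchanged.

What the generator does *not* emulate: real sequence evolution, DESeq2's
sampling distribution (padj values are uniform below/above the cutoff;
fold-change magnitudes are lognormal and carry no meaning beyond sign),
correlated GO term semantics, or the family-splitting artifacts of real
orthology inference (the motivating study documents spurious
tetraploid-specific families; this caveat transfers to any real input).
Passing tests on synthetic data therefore validate the statistical
machinery and the pipeline plumbing, not the biology of any particular
input.

## Problem sizes used in the checks

The packaged checks use sizes chosen to make the sampling properties
measurable while keeping a full run comfortable on a laptop: null
calibration runs 100 seeds at 2,000 families (the generator's default
size) and requires at least 90% of all battery p-values to stay above
0.05 under null settings; the power check runs 100 seeds at 5,000
families with a threefold planted DE-odds multiplier and requires
rejection in at least 95% of seeds; the enumeration oracle covers every
contingency with $N \le 25$. The published desk-scale statistics are
recomputed exactly from their printed counts and need no simulation.

## Known limitations

* Expansion calls are threshold tests on copy-number ratios, not
  birth–death (CAFE-style) model fits; no duplication dating or tree
  reconciliation is attempted.
* The Conserved-Set restriction discards genuinely species-specific
  families, which is intentional for the trait contrast but means absence
  polymorphism is out of scope.
* The chi-square conservation test treats families as independent; shared
  regulatory architecture across families is not modelled.
* GO testing is flat Fisher; hierarchically correlated terms will co-occur
  in the reported list.
* The selection table is consumed as given: p-values are assumed already
  corrected (if a raw `p` column is supplied instead, apply `p.adjust`
  before loading; the package does not guess).
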