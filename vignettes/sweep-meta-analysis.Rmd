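---
title: "Calling confirmed selective sweeps from multi-study catalogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling confirmed selective sweeps from multi-study catalogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Dozens of population-genetic scans report selective sweeps for the same
livestock species, each with its own breeds, statistics (F~ST~, iHS,
XP-EHH, ROH, ...) and false-positive profile. A region reported once may
be noise; a region where sweeps from several *independent* studies pile
up is much more credible. `sweepcss` formalises that intuition: it merges
per-study sweep intervals on a shared reference coordinate system into
**confirmed selective sweeps (CSS)**, labels each CSS by the balance of
production-focused versus adaptation-focused studies behind it, and then
profiles what the confirmed regions contain — positional candidate genes,
QTL, enriched traits and GO terms, and network hub genes.

The package computes nothing from genotypes: the sweep statistics are
inputs, never recomputed, and coordinate liftover between assemblies is
assumed done upstream.

## The procedure and its assumptions

**Coordinates.** Everything internal is 1-based and closed on both ends,
the GTF/GFF convention of the two annotation formats the pipeline reads;
BED output converts to 0-based half-open on write. Two intervals overlap
when they share at least one base — adjacency does not count, and the
minimum shared length is configurable (`min_overlap_bp`, default 1 bp,
the weakest consistent reading of "overlapping" reports). Strand is
ignored throughout: sweeps and CSS are unstranded regions.

**Marker expansion.** Studies reporting a sweep as a single marker
position are expanded to marker ± 250 kb (configurable `flank`), clamped
to the chromosome. Expansion happens on input coordinates, which is
order-equivalent for same-assembly data.

**Clustering.** Clusters are connected components of the pairwise overlap
graph per chromosome (single linkage): a chain A–B, B–C joins all three
even when A and C are disjoint. This is deliberately the inclusive
reading — it matches the flanking-interval definition (min start to max
end over all members) — and a strict common-intersection mode
(`linkage = "common"`) is available for sensitivity analysis. For
intervals, single-linkage components equal maximal overlapping runs under
a start-sorted sweep line, which is what the implementation uses; the
test suite checks it against an explicit union–find over all pairs.

**CSS support and classification.** A cluster becomes a CSS when at least
`min_studies = 3` *distinct studies* contribute a member — a study with
five sweeps in one cluster counts once. Class fractions are likewise
computed over distinct studies by default. The source material for this
rule is ambiguous (support is phrased per study, the classification
sentence per sweep, and an alternative 60/60 threshold pair appears
alongside 60/70), so both bases are implemented (`basis = "studies"` or
`"sweeps"`), both threshold pairs are configurable, and
`css_count_grid()` always reports the counts under all four
combinations so the configuration matching any external reference is
identifiable. Thresholds are strict: a CSS at exactly 60% production is
unclassified.

**Annotation.** Genes and QTL are matched against the CSS *flanking
interval* (not member sweeps individually), any ≥ 1 bp overlap qualifies,
and QTL trait names and types are taken verbatim from the GFF attributes
— no internal trait ontology. Both per-CSS overlap rows and distinct
feature counts are reported, since a gene spanning two CSS is one
candidate but two positional events.

**Enrichment.** Both trait and GO-term over-representation use one
declared statistic: the exact upper-tail hypergeometric
`P(X >= k)` for `X ~ Hypergeom(N, K, n)`, with Benjamini–Hochberg
correction across the traits/terms of one run (QTL and GO corrected
separately; GO namespaces jointly). The background is genome-wide: all
records of the supplied QTL database, or the whole gene universe. This is
a deliberate, self-contained substitution for the unpublished internals
of the annotation tools used in the original analyses; equivalence with
them is not claimed, which is also why the statistic is exposed directly
(`hypergeom_upper_tail()`) and oracle-tested by enumeration. Filters are
applied exactly as stated: a QTL trait passes at FDR < 0.05 *and* more
than one database record (`min_db_count = 2`, counted genome-wide by
default); GO terms with 1000 or more assigned universe genes are excluded
*before* testing and hence before FDR. The QTL counting unit is the
database record, and a record overlapping several CSS counts once, which
keeps `k <= K` structurally true.

**Wang similarity and term reduction.** S-values propagate from a term to
its ancestors with the canonical relation weights 0.8 (`is_a`) and 0.6
(`part_of`), taking the maximum over paths; similarity is the shared
S-value mass relative to both terms' total semantic values. Reduction
groups enriched terms that are pairwise similar at ≥ 0.7 *and* share a
direct parent (components of the thresholded similarity graph restricted
to co-parented pairs, within one namespace), assigning the group to the
shared parent — when several parents qualify, the one with the largest
mean similarity to the members, tie-broken lexicographically — and
carrying the smallest member p-value. Terms that join no group stay as
singletons under themselves; a component with no parent common to all
members keeps its lowest-p member as representative, since the grouping
rule only defines the common-parent case.

**Hub genes.** Betweenness is the raw (unnormalised) Brandes count over
unordered pairs with endpoints excluded, on the undirected bipartite
gene–term graph. The hub threshold is the type-7 (linear interpolation)
sample quantile at 0.90 of the *gene-side* scores — terms are never hubs
— and membership is strictly above the threshold, so ties at the
threshold are excluded and a degenerate all-equal network has no hubs.
Gene–QTL networks link a hub gene to an enriched trait when gene and
trait record are annotated in the same CSS (co-occurrence, not direct
coordinate overlap); collapsing traits to types weights each edge by the
number of distinct traits behind it.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `flank` | 250000 bp | marker expansion, each side |
| `min_overlap_bp` | 1 bp | minimum shared bases to link sweeps |
| `min_studies` | 3 | distinct studies per CSS |
| `prod_threshold` | 0.60 | production fraction, strict `>` |
| `adap_threshold` | 0.70 | adaptation fraction, strict `>` |
| `basis` | studies | counting unit for class fractions |
| `alpha` | 0.05 | FDR threshold, both enrichment stages |
| `min_db_count` | 2 | minimum database records per QTL trait |
| `max_term_size` | 999 | largest tested GO term |
| `wang_threshold` | 0.7 | pairwise similarity for term grouping |
| `hub_quantile` | 0.90 | betweenness quantile for hubs |

All of them are recorded in the run manifest so any published run is
auditable.

## What the synthetic generator emulates

The generators produce a complete input corpus as a pure function of one
integer seed: a 3-chromosome, ~30-Mb genome; 15 planted CSS loci of
200 kb, at least 1.5 Mb apart (so marker expansion cannot merge
neighbours); a study pool of 15 production and 23 adaptation studies,
matching the catalog composition the pipeline is sized for; background
sweeps at 0.1 per Mb genome-wide (Poisson count, uniform placement,
random study); a 500-gene annotation; a 400-record QTL database with one
trait planted at 10× density inside the loci; and a 60-term GO DAG with
six planted enriched terms, each covering a random ~65% slice of the
genes inside planted loci. Planted study mixes — (4,0), (5,1), (0,4),
(1,5), (2,2) production/adaptation — keep every implied class fraction at
least 0.1 from both thresholds and robust to one contaminating background
study, so classification recovery is a sharp check rather than a coin
flip. Several planted GO terms over different gene slices are used
because a single planted term yields a star network whose gene
betweenness is identically zero, leaving the hub stage inert.

What the generator does **not** emulate: real chromosome counts and
lengths, linkage disequilibrium and the spatial autocorrelation of real
sweep calls, the heavy-tailed trait spectrum of a real QTL database, and
the depth and fan-out of the full GO. Passing recovery tests therefore
demonstrates the correctness of the interval logic, the counting rules
and the statistics under controlled conditions — not that any particular
biological catalog will reproduce a published CSS count.

## Numerical choices and degenerate inputs

Cluster and CSS identifiers are deterministic (chromosome- then
start-ordered, zero-padded), so reruns on identical input are
byte-identical. Duplicate identical intervals within one study are
deduplicated on read — support is counted over distinct studies, so this
cannot change any result. Empty inputs propagate as empty tables, not
errors (an empty CSS set gives header-only output and zero counts);
malformed rows fail fast with their line number. The all-pairs overlap
join is indexed but required by the test suite to equal a brute-force
scan on random fixtures. S-value propagation is max-product relaxation on
a DAG with weights < 1, which converges in at most graph-depth passes;
acyclicity is checked at parse time and a cycle is reported with a member
term. Hypergeometric tails are exact (`phyper`), never approximated.

## Problem sizes used in the checks

The shipped tests and the acceptance script run entirely on generated
data: 500 random catalogs of up to 50 sweeps against the union–find
oracle; 200 random graphs of up to 25 nodes against BFS path enumeration;
every hypergeometric count combination with N ≤ 20 against enumeration;
random DAGs of up to 12 terms against path-enumeration S-values; 25–50
replicate corpora for planted-CSS recovery and trait detection; and 200
all-null draws for FDR calibration. These sizes were chosen to make the
oracles exhaustive yet quick; all scale linearly if enlarged.

## Known limitations

CSS flanks are not re-merged after span expansion (two CSS whose flanks
overlap stay separate if their member sweeps never linked); the original
procedure's behaviour on this point is unspecified, and no re-merging is
the conservative default. The enrichment statistic is a declared
substitute for tool-internal methods, so published enrichment lists from
those tools are not expected to match record for record. Cross-namespace
GO similarity is undefined under the Wang measure and errors by default.
X-chromosome and mitochondrial special-casing, balancing-selection
signals, and sweep detection itself are out of scope.
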