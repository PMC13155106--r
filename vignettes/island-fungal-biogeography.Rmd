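---
title: "Methods: biogeographic analysis of island fungal metabarcoding data"
author: "mycogeo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biogeographic analysis of island fungal metabarcoding data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycogeo)
```

# The problem

Remote islands are natural experiments for microbial biogeography: if
fungal spores disperse globally, an isolated island's soil and
root-associated mycobiota should be a filtered subset of the global
species pool; if dispersal is limiting, endemic lineages should
accumulate. Testing this with ITS2 metabarcoding requires a chain of
analyses downstream of the denoised amplicon table: clustering sequence
variants (ASVs) into species-proxy OTUs, deciding which OTUs are already
"known" in global reference pools, classifying the latitudinal ranges of
the known ones, looking for intraspecific endemism in per-OTU haplotype
networks, searching occurrence data for geographic areas of endemism,
and partitioning global abundance variation into environmental and
spatial components.

`mycogeo` implements that chain as testable, seeded, reusable functions,
together with a synthetic-data generator that emulates all three inputs
(island ASV table, reference pools, global occurrence table) so that
every stage can be validated against planted ground truth without any
external database.

# Sequence operations

**Identity.** "Identity over the entire length" is computed from an
optimal global (Needleman–Wunsch) alignment that maximizes the number of
matching columns (match +1, mismatch 0, gap 0; end gaps penalized like
internal gaps). Among match-optimal alignments the shortest one is used,
obtained by lexicographically maximizing (matches, aligned pairs) in a
single dynamic program; identity is matches / alignment length. This
definition is parameter-free and exactly reproducible by an independent
dynamic program, which the test suite exploits. The C implementation is
quadratic per pair; an optional length-ratio prefilter skips pairs whose
shorter/longer length ratio is below the identity threshold of interest
(such pairs cannot reach it, so the filter is exact, not heuristic).

**Clustering.** ASVs are clustered greedily by decreasing total reads
(ties by id): an ASV joins the first centroid at ≥ 97% identity, else
founds a new OTU. Greedy centroid clustering is used instead of
tree-based clustering because it is deterministic, order-stable under the
documented tie-breaks, and verifiable against an exhaustive pairwise
oracle; no equivalence with any particular published clustering tool is
claimed beyond the threshold semantics. The threshold is inclusive
(≥ 0.97) by default with a `strict` switch for the exclusive reading.

**Rare-OTU filter.** OTUs below 0.005% of the grand total are removed;
the grand total is fixed before filtering, so survivor counts are
unchanged and the operation is idempotent.

# Community summaries and taxon selection

Rank-abundance quartiles are equal-OTU-count splits of the ranked curve
(Q1 = most abundant; remainders go to the earlier quartiles). An
equal-read-share split was considered and rejected as the default
because published quartile OTU counts are closer to equal-count splits;
the summary carries read shares so either view can be reported. Pielou's
evenness J = H/ln S is computed on order-level relative read abundance.

Plant-associated OTUs must (a) exceed 0.01% relative abundance in at
least one root sample — strictly, so a sample at exactly the floor does
not qualify — and (b) be detected (≥ 1 read, no abundance floor) in at
least 50% (inclusive) of root individuals of some (plant species, site)
stratum. The two clauses are deliberately decoupled: the prevalence
clause models host fidelity and removes sporadic carry-over, the
abundance clause removes trace noise. Non-plant-associated OTUs are the
remaining OTUs exceeding 0.01% in at least one bulk-soil sample; the two
sets are disjoint by construction.

# Reference matching and biogeographic classification

OTU representatives are matched exhaustively against the reference pool
(occurrence pool: references with georeferenced records; annotation
pool: all references). An OTU is *known* when its best identity reaches
the threshold in at least one pool; occurrence metadata are only
available for matches in the occurrence pool, mirroring the situation
where a sequence is known to taxonomy but has no environmental records.

Known OTUs are classified from the minimum and maximum latitude of their
records, evaluating rules in a fixed precedence order: cosmopolitan
(range > 60° spanning both hemispheres), arctic (min ≥ 60), antarctic
(max ≤ −50), northern hemisphere (40 ≤ min, max ≤ 60), southern
hemisphere (−50 ≤ min, max ≤ −40), low latitudes (−40 ≤ min, max ≤ 40),
else other. Band boundaries are read as closed intervals; the rule list
is a total function on {(m, M) : m ≤ M}, verified against an
independently coded oracle on a 0.5° sweep. The ubiquity index counts
distinct plant biomes among 11 labels (ten vegetated biomes plus an
unvegetated Antarctic category); tundra specificity is the percentage of
records in tundra biomes or Antarctica. Biome labels come from the input
table; polygon lookup from coordinates is out of scope.

# Haplotype networks and private haplotypes

For each OTU known in the occurrence pool, its island ASVs are merged
with the global haplotypes of the matched reference (identical sequences
collapse into one node carrying both island reads and global record
counts). The network is a minimum spanning network: distances are plain
Hamming distances (sequences of unequal length are implicitly padded by
the same global alignment used for identity, and the distance is the
count of non-identical alignment columns), processed by increasing
weight, keeping **all** edges of a tied weight that join components
still separate before that weight level. This is a deliberate
approximation of statistical-parsimony networks: the quantities the
analysis consumes — the private haplotype set and its read share — do
not depend on network topology at all, so the simpler, oracle-checkable
construction is preferred. A haplotype is island-private when it carries
island reads but no global record; the OTU is dominant-private when
private haplotypes carry strictly more than 90% of its island reads.
Global haplotype weight uses record counts, not reads, because occurrence
records carry abundance per record only.

# Areas of endemism

The world is divided into half-open cells anchored at (−90, −180);
latitude 90 is clamped into the top row and longitude wraps at the
antimeridian. Spatial congruence of a species with a candidate area is
the Jaccard index of occupied cells — a parameter-free simplification of
grid-based endemicity scores that keeps the published properties (0–1
range, 1 only for perfect coincidence, summed area score). An area's
score sums the congruences of species scoring at least 0.5, and an area
needs at least two such endemic members.

The search is deterministic. On small instances (occupied bounding box
of at most 14 cells) every connected subset of the box — including
unoccupied bridge cells — is enumerated by bitmask and the locally
maximal qualifying areas are returned, so the global optimum is
guaranteed; this exact branch exists because strict-increase
hill-climbing provably misses rare optima reachable only through
non-improving bridge states. Beyond that size, candidate areas are
seeded from each species' occupied cells (components bridged across gaps
of at most two cells; distant fragments seed separately; pairwise
species unions are added when at most 15 species are present) and
hill-climbed by adding frontier cells or removing cells under a
strictly-increasing total score. Consensus areas merge candidates that
share cells and at least 50% of their endemic species (shared fraction
over the smaller set, the most inclusive standard reading; the
union-denominator variant is a one-line change), re-scoring the species
union against the cell union.

# Spatial predictors and variance partitioning

Moran eigenvector maps are built classically: great-circle (haversine)
distances, truncation at the longest minimum-spanning-tree edge with
distances beyond it replaced by four times the threshold, double
centering of −½D², eigen-decomposition, and retention of
positive-eigenvalue eigenvectors ordered by eigenvalue. Exact duplicate
coordinates are rejected (they make the truncation threshold zero);
callers deduplicate records first.

Variance partitioning uses Ezekiel-adjusted R² from least-squares
projections: with ab = adjR²(Y~E), bc = adjR²(Y~S), abc = adjR²(Y~E∪S),
the fractions are a = abc−bc (pure environment), c = abc−ab (pure
space), b = ab+bc−abc (shared), d = 1−abc. Significance of the pure
fractions is by permutation of the response rows with the add-one rule.
The number of retained eigenvectors matters: with too few, broad
latitudinal structure is missing from S and its variance is
misattributed to the pure-environment fraction. The pipeline default
keeps the leading 120 eigenvectors, at which point the partition is
stable on the synthetic study (problem sizes below). The design matrix
for mixed-model fitting log10-transforms abundance, standardizes
latitude, MAT, precipitation, pH and SOC to mean 0 / sd 1, and adds a
standardized quadratic latitude term; model fitting itself is delegated
to standard mixed-model software and is not re-implemented here.

# The synthetic study

The generator plants, under one master seed with per-unit substreams
(identical seed ⇒ byte-identical outputs):

* **Field design** — three plant species (two native, one introduced
  lowland species) across four sites and two altitudes with 5 replicates
  per stratum: 70 individuals, each with a paired root and bulk-soil
  sample (140 samples). Depth is 50,000 reads per sample — a typical
  ITS2 soil library size; the emulated design does not fix one.
* **Reference pool** — one reference per planted known OTU, with a small
  set of global haplotypes (substitution-mutated copies), taxonomy with
  unknown ranks, and occurrence records whose latitudes follow the OTU's
  biogeographic class, or its planted endemicity zone (95% of points
  inside the box by default; the per-species congruence this implies,
  ~0.7–1.0 at 10°, matches the span of published per-species endemicity
  scores, while the spec floor is 80%).
* **Island community** — known OTUs reuse global haplotypes (identity to
  the source ≥ 97% by construction), unknown OTUs are rejection-sampled
  below 97% against every pool sequence; read totals follow a geometric
  rank-abundance law (decay 0.98) permuted independently of known
  status; a configurable fraction of known OTUs carries an island-only
  ASV, with the private read share drawn near 0.95 for dominant cases
  and 0.15–0.55 otherwise, far from the 0.9 decision boundary so that
  multinomial read noise cannot flip the planted flag.
* **Plant association** — plant OTUs are drawn from the top abundance
  ranks and concentrated in the root samples of their host species; soil
  OTUs reach roots only through sparse accidental carry-over (an 8%
  per-OTU-per-root-sample gate), the contamination mode the prevalence
  rule is designed to remove. Setting `root_leak = 0` gives a noiseless
  configuration in which the selection rules recover the planted labels
  exactly.
* **Abundance field** — log10 abundance combines weak environmental
  effects (negative MAT, positive SOC, pH and latitude), a strong smooth
  spatial field and wide noise, so that partitioned variation is
  space-dominant with a small shared and a smaller pure-environment
  fraction — the qualitative structure the analysis is meant to detect.
  MAT decreases strictly with |latitude|; precipitation peaks near the
  equator; pH and SOC rise poleward; independent noise s.d. are 1 °C,
  100 mm, 0.2 pH and 0.5% SOC.

What the generator does **not** emulate: read-level errors and chimeras,
indels (off by default so haplotype distances are Hamming), phylogenetic
sequence structure, spatially clustered sampling effort, biome polygons
(biomes follow latitude bands), and the taxonomic composition of any real
database. Passing tests therefore demonstrate correctness of the
analysis chain and recoverability of planted structure — not that real
data would yield any particular value.

# Problem sizes and numerical choices

The test suite and the acceptance script run the study at
computationally honest but desk-scale sizes, chosen as the package's own
defaults: 500 OTUs for the known-fraction round trip (the planted 0.65
is recovered within ±0.05 after clustering, filtering and matching), 337
known OTUs for haplotype-network rates (planted 18% private / 55%
dominant recovered exactly at these noise levels), 60 species with
two planted zones (12 and 6 species) for endemicity recovery at 10° and
5°, and ~1,200–1,500 deduplicated occurrence records for variance
partitioning. Degenerate inputs fail loudly and early: empty sequences,
ambiguous bases, duplicate ids, all-zero tables, zero-variance
predictors (dropped with a warning), duplicate coordinates, empty
occurrence lists. Jaccard and score comparisons use a 1e-12 strictness
margin so floating-point ties cannot flip deterministic orderings.

# Known limitations

* Greedy centroid clustering and tree-based clustering can differ near
  the threshold; only the threshold semantics are guaranteed.
* The global-alignment identity is not BLAST identity; no numeric
  equivalence with BLAST-derived known/unknown fractions is claimed.
* The endemicity heuristic is locally optimal beyond the exact-search
  size; candidate seeding determines which local optima are reachable.
* The minimum spanning network is not a statistical-parsimony network;
  only private-haplotype quantities are topology-independent.
* Areas are unions of grid cells; no polygon geometry is produced beyond
  the cell outlines.
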