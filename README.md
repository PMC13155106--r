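# mycogeo

Biogeographic analysis of fungal ITS2 metabarcoding data from isolated
island systems, built for soil and plant-root ecologists who want to ask:
*how much of an island's mycobiota is already known elsewhere on the
globe, and does anything about it look endemic?*

Starting from a denoised ASV table, the package provides the full chain:

1. **OTU clustering** — greedy centroid clustering at ≥ 97% global
   identity, where identity is `matches / alignment length` of a
   Needleman–Wunsch alignment maximizing matches (match +1, mismatch 0,
   gap 0, end gaps penalized); representatives are the most abundant
   member; OTUs below 0.005% of total reads are filtered.
2. **Community structure** — equal-count rank-abundance quartiles
   Q1–Q4, order-level Pielou evenness J = −Σ pᵢ ln pᵢ / ln S, and the
   plant-associated selection rule (relative abundance > 0.01% in a root
   sample **and** detection in ≥ 50% of root individuals of some
   species × site stratum).
3. **Known/unknown calls** — exhaustive matching of representatives
   against reference pools at ≥ 97% identity, split into an occurrence
   pool (georeferenced records) and an annotation pool (taxonomy only).
4. **Latitudinal classification** — cosmopolitan / arctic / antarctic /
   northern & southern hemisphere / low latitudes / other, from the
   min–max occurrence latitude, plus a biome ubiquity index (1–11) and a
   tundra-specificity percentage.
5. **Haplotype networks** — per-OTU minimum spanning networks over
   island ASVs and global haplotypes; island-private haplotypes
   (island reads > 0, global records = 0) and strict > 90% read-share
   dominance flags.
6. **Areas of endemism** — world grid (1°–15° cells), per-species
   Jaccard congruence with candidate connected cell sets, summed area
   scores, and 50%-shared-species consensus merging; exact enumeration
   on small instances, deterministic hill-climbing beyond.
7. **Variance partitioning** — Moran eigenvector maps from great-circle
   distances (MST-truncated PCNM construction) and adjusted-R²
   partitioning of log abundance into pure-environment / shared /
   pure-space / residual fractions with permutation tests, plus the
   standardized design matrix (including quadratic latitude) for
   mixed-effects abundance models.

A seeded synthetic-data generator (`simulation_config()`,
`simulate_reference_pool()`, `simulate_island_dataset()`) emulates the
island study design (70 paired root/soil samples), the reference pools
and the global occurrence table, planting known fractions, private
haplotypes, endemicity zones and a space-dominant abundance field so the
whole chain is testable offline.

## Worked example

```r
library(mycogeo)

cfg <- simulation_config(n_otus = 40, known_fraction = 0.65, seed = 3)
pool <- simulate_reference_pool(cfg)
island <- simulate_island_dataset(pool, cfg)

otus <- cluster_asvs(island$asvs, threshold = 0.97, len_ratio_min = 0.9)
matches <- match_otus(otus, pool, len_ratio_min = 0.9)
print(otus)
mean(matches$status == "known")
```

```
<otu_set> 40 OTUs from 75 ASVs (identity threshold 0.97)
[1] 0.65
```

All 40 planted OTUs are recovered as clusters and 26/40 = 65% of them
match the reference pool at ≥ 97% identity — the planted known fraction.
The full pipeline, with every stage and threshold exposed:

```r
run <- run_pipeline(simulation_config(n_otus = 60, known_fraction = 1, seed = 7),
                    n_perm = 99)
print(run)
print(run$results$varpart)
```

```
<mycogeo_run>
  stages: simulate -> cluster -> filter -> quartiles -> categorize -> match -> biogeo -> haplonet -> endemism -> varpart
  n_asvs                   108
  n_samples                140
  n_otus_raw               60
  n_otus                   60
  n_known                  60
  known_fraction           1
  n_plant_associated       5
  n_non_plant_associated   55
  n_networks               55
  n_private                9
  n_private_dominant       4
  n_consensus_areas        1
  elapsed: 13.8 s
<varpart_result> adjusted R2 fractions
  pure environment (a):  0.007  (p = 0.02)
  shared           (b):  0.345
  pure space       (c):  0.340  (p = 0.01)
  residual         (d):  0.308
```

Here 55 of the 60 known OTUs have occurrence records (the rest are
known in the annotation pool only), 9 networks contain island-private
ASVs and 4 of those are read-dominant; the single consensus area is a
congruent band of southern-hemisphere background species — planting
explicit endemicity zones (see `simulation_config(endemicity_zones =)`)
yields the two-zone recovery exercised by the test suite. The variance
partition is space-dominant: pure space explains ~34% of log-abundance
variation against ~1% pure environment.

`run$results` holds each stage's objects (OTU table, match table,
per-OTU biogeographic classes, haplotype networks, consensus endemicity
areas, the varpart result), and `out_dir =` writes them as TSV/JSON with
md5 checksums in the manifest.

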