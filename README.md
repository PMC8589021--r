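# ssrkit

Fingerprinting analytics for clonal genebank collections genotyped with
dominant-scored SSR (microsatellite) markers.

Large clonal collections — sweetpotato, potato, yam, cassava — are
maintained for decades as greenhouse mother plants and in-vitro cultures,
and accumulate three kinds of problems that molecular fingerprints can
expose: **redundancy** (the same clone conserved under several accession
numbers), **identity errors** (a sample mislabeled or mixed during
propagation), and **undocumented overlap** between collections held by
different institutes. In polyploids such as hexaploid sweetpotato
(2n = 6x = 90), SSR allele dosage cannot be read from a gel, so each
allele is scored only as present (1) or absent (0), with failed loci
coded 9. `ssrkit` implements the full analysis stack for such data:

* **Data model & I/O** — `allele_matrix` (samples × marker-allele columns,
  block-structured missingness), `read_matrix()` / `write_matrix()` for
  the canonical 0/1/9 delimited format, panel metadata, passport tables,
  validation, subsetting, panel-aligned merging of two collections.
* **Diversity statistics** — per-marker allele counts and mean alleles
  per individual; equal-dosage allele frequencies (a sample presenting
  *k* alleles contributes weight 1/*k* to each); Botstein's polymorphism
  information content
  `PIC = 1 − Σᵢ pᵢ² − Σᵢ<ⱼ 2 pᵢ² pⱼ²`;
  expected heterozygosity `Hₑ = 1 − Σᵢ pᵢ²`; and
  `Fst = (Hₜ − H̄ₛ)/Hₜ` by any sample grouping.
* **Relationships** — Jaccard dissimilarity
  `d = 1 − a/(a + b + c)` (shared absences ignored, missing blocks
  pairwise-complete), Saitou–Nei neighbor-joining with deterministic tie
  breaking and Newick export, and classical PCoA (Gower double
  centering).
* **Redundancy pruning** — duplicate groups at a similarity threshold
  (default ≥ 95%) under single- or complete-linkage, pruning to one
  representative per group.
* **Identity** — paired mother-plant/in-vitro true-to-type verification,
  cross-collection reconciliation with declared-transfer and name-match
  links, nearest-neighbor search.
* **Simulator** — a structured-population hexaploid fingerprint
  generator with complete ground truth (ancestries, clone groups,
  planted label swaps and link errors), so every stage is testable
  without any external data.

## Worked example

```r
library(ssrkit)

cfg <- sim_config(n_individuals = 60, clone_rate = 0.4, seed = 42)
sim <- simulate_collection(cfg)
sim
#> <sim_result> 85 samples (60 individuals), 20 markers, K = 4

head(diversity_report(sim$matrix), 4)
#>   marker n_scored total_alleles mean_alleles_per_individual   pic    He
#> 1    M01       81            12                        3.51 0.794 0.817
#> 2    M02       82            10                        2.98 0.748 0.777
#> 3    M03       84             7                        3.55 0.777 0.805
#> 4    M04       83            11                        3.34 0.795 0.815

dm <- jaccard_matrix(sim$matrix)
g  <- find_duplicates(dm, threshold = 0.95)
g
#> <duplicate_groups> 85 samples -> 60 groups at similarity >= 0.95 (single linkage); largest group 2
pr <- prune_duplicates(sim$matrix, g)
#> removed 25 samples (29.4%)
```

The report columns mirror the standard published panel summary: number
of distinct alleles seen per marker, the mean number carried per
individual (bounded by the ploidy), and the marker's informativeness
(PIC) and gene diversity (He) under the equal-dosage frequency
estimator. Here the 25 planted clonal copies are recovered exactly —
85 samples collapse back to the 60 simulated founders.

Paired true-to-type verification with a planted 15% mislabeling rate:

```r
fx <- make_paired_fixture(sim_config(n_individuals = 200,
                                     label_swap_rate = 0.15, seed = 7), 200)
verify_pairs(fx$matrix, fx$pairs[, c("sample_a", "sample_b")])
#> <pair_verdicts> 200 pairs: 179 match, 21 mismatch (10.5%), 0 indeterminate
```

Each mismatching pair is reported with its per-marker allele conflicts;
the 21/200 estimate is a draw around the planted 15% rate (binomial
sampling), and the generator's truth table says exactly which pairs were
swapped.

A command-line front end covers the same pipeline on files:

```sh
ssrkit simulate --config sim.json --out data/
ssrkit stats    --input data/matrix.csv --output report.csv
ssrkit tree     --input data/matrix.csv --output tree.nwk
ssrkit prune    --input data/matrix.csv --output pruned.csv --threshold 0.95
```

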