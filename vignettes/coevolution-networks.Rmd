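---
title: "Mutual information coevolution networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutual information coevolution networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(coevomap)
```

## The model

An MSA of homologous proteins carries conservation signal (which residues a
position tolerates) and covariation signal (which positions change together).
`coevomap` scores covariation between columns $i, j$ with mutual information
over weighted amino-acid pair frequencies,

$$ MI(i,j) \;=\; \sum_{a,b} p_{ij}(a,b)\,
   \ln\!\frac{p_{ij}(a,b)}{p_i(a)\,p_j(b)} , $$

in nats, and reports each pair as a z-score against a column-permutation
null. The pipeline is: redundancy weighting, pair frequencies with a
low-count correction, MI, average product correction (APC), permutation
z-scores, and network construction at the significance threshold $z > 6.5$.

Raw MI is biased: shared phylogeny inflates every pair involving a
fast-evolving position, and high-entropy columns score high by chance. Two
corrections address this:

* **APC** subtracts $\overline{MI}_i \, \overline{MI}_j / \overline{MI}$ from
  entry $(i,j)$, where $\overline{MI}_i$ is the mean over the defined
  off-diagonal entries of row $i$ and $\overline{MI}$ the mean over all
  defined off-diagonal entries. An all-equal matrix is corrected exactly to
  zero.
* The **permutation null** shuffles the residues within every kept column
  independently (gaps travel along), which preserves every column's
  composition — hence its entropy and gap structure — while destroying
  inter-column correlation. The full APC-corrected matrix is recomputed per
  replicate, and $z(i,j) = (MI_{APC} - \mu_{null}) / \sigma_{null}$.

APC is applied before z-scoring. The z-score is invariant to the logarithm
base, which is why MI is reported in nats without loss of comparability.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `identity_threshold` | 0.62 | single-linkage clustering cutoff; each sequence weighs 1/cluster-size |
| `pseudocount` | 0.05 | additive mass per joint cell (low-count correction) |
| `n_permutations` | 100 | null replicates; 25 already separates a strong pair cleanly |
| `max_gap_fraction` | 0.5 | columns with more gaps are masked |
| `z_threshold` | 6.5 | edge retention, strict `>` |
| `distance_cutoff` | 5 Å | distance-network edges, strict `<` |
| `radius` | 5 Å | pMI neighborhood, inclusive `<=`, self excluded |
| `null` | per-pair | per-pair null moments; `pooled` shares moments across pairs |
| `background` | blosum62 | KL conservation background; `uniform` available |

Notes on the choices that were genuinely open:

* **Weights are normalized to mean 1** before use. Pair frequencies then
  become exactly invariant to rescaling all weights, and the balance between
  observed counts and the additive pseudocount does not depend on the
  arbitrary scale of the weighting scheme.
* **Single-linkage clustering** (transitive closure of identity $\ge$
  threshold) was preferred over greedy cluster assignment because the result
  is invariant to sequence order, which makes the weighting reproducible and
  testable. The 0.62 default follows common practice for this family of MI
  methods; it is a package default, not a fact about any particular dataset.
* **Per-pair null moments** are the default because conserved and variable
  columns have very different null scales; a pooled null would understate
  significance for low-entropy pairs. The pooled variant remains available
  behind the `null` flag for comparison.
* **Degenerate pairs** (fewer than two sequences with standard residues at
  both columns) propagate as missing values through APC and z-scoring rather
  than as zeros. Pairs whose null spread is exactly zero — e.g. in a fully
  conserved, permutation-invariant alignment — get $z = 0$ and a degeneracy
  flag rather than 0/0.
* **Conservation** is Kullback–Leibler divergence from a BLOSUM62-derived
  amino-acid background (uniform optional). A fully conserved column under a
  uniform background scores $\ln 20 \approx 3.0$ nats. Logo data decompose a
  column's KL into signed per-residue enrichment/depletion terms.
* **Coordinates.** Internally everything is 1-based (idiomatic R). Reported
  positions are 1-based indices into the ungapped reference sequence, or PDB
  author numbering once a structure is mapped. Columns where the reference
  has a gap are always masked, because every report is indexed by reference
  position. Sequence separation of an edge is measured on ungapped reference
  numbering.
* **Structure handling.** First PDB model only; highest-occupancy altloc
  conformer; hydrogens detected by element field (atom-name heuristic as
  fallback) and excluded from minimum-distance computation; secondary
  structure from HELIX/SHEET header records only (no DSSP), absent records
  meaning coil. Smith–Waterman mapping uses BLOSUM62 with gap open 10 /
  extend 0.5; coverage below 30% of the reference produces a warning.
* **Percentile bands** over retained-edge z-values use linear-interpolation
  quantiles; ties promote upward, so a single edge (or an all-tied edge set)
  is "top5". With 100 distinct values the split is exactly 5/25/70.

## The synthetic-data generator

`generate_msa()` draws independent columns from a background distribution
(uniform by default) and plants covarying pairs under a two-state coupled
model: with probability `coupling` the pair takes state (A,D) or (C,E),
equiprobably and fully correlated; otherwise both columns draw independently
from their 50/50 marginals. (The classic textbook labels for such states
would be (A,B)/(C,D), but `B` is not a standard amino-acid code, so the
generator uses four standard residues.) The construction fixes the marginals
regardless of coupling and gives the planted pair an exact asymptotic MI of
$\ln 2$ at coupling 1, so tests can assert against a closed form.
`generate_toy_pdb()` writes CA-only chains with exact line or ideal α-helix
geometry (radius 2.3 Å, rise 1.5 Å, 100°/residue).

What the generator deliberately does **not** model: phylogenetic structure
(sequences are i.i.d., so there is no tree-induced correlation), indel
structure (gaps are injected uniformly), and composition heterogeneity along
the sequence. A green planted-pair test therefore establishes that the
statistic and its null behave correctly on exchangeable data; it does not
certify performance against phylogenetic confounding on real families, which
is precisely what APC and sequence weighting are meant to mitigate but which
only real alignments can probe.

## Numerical notes

* MI terms with $p_{ij}(a,b) = 0$ contribute zero (only possible at
  pseudocount 0).
* With a positive pseudocount, a fully conserved pair has strictly positive
  raw MI at finite depth (the pseudocount spreads mass the marginals cannot
  explain); it vanishes only as the pseudocount or the ratio of pseudocount
  to alignment depth goes to zero. The permutation z-score is the quantity
  that is calibrated, not raw MI.
* The permutation pipeline is bitwise reproducible for a fixed seed; the
  caller's RNG state is saved and restored.
* An APC call on a matrix whose off-diagonal mean is zero returns the input
  unchanged with a warning (no division by zero).
* Thresholds: edge retention is strict (`z > 6.5`), distance-network edges
  are strict (`< cutoff`), while the pMI neighborhood is inclusive
  (`<= radius`) with the residue itself excluded (optionally included via
  `include_self`). The inclusive/exclusive split follows the distinct
  phrasings "closer than" vs "within" of the two definitions.

## A small demonstration

```{r demo}
g <- generate_msa(n_sequences = 150, n_columns = 20,
                  planted_pairs = list(c(4, 15, 1)), seed = 7)
pdb <- generate_toy_pdb(20, "helix",
                        sequence = gsub("-", "", g$alignment$seq[1]))
res <- run_pipeline(g$alignment, pdb = pdb, n_permutations = 25, seed = 7,
                    verbose = FALSE)
summary(res)
```

```{r circos, fig.width = 6, fig.height = 6}
plot(res)
```

## Known limitations

* No alternative covariation statistics (DCA, PSICOV, OMES, SCA) — MI with
  APC and a permutation null is the method implemented.
* No mmCIF input, no multi-chain analysis, no DSSP/Stride; secondary
  structure is only as good as the PDB header.
* No phylogenetic tree-based weighting; identity clustering is the only
  redundancy correction.
* The bundle's zip container is store-only (uncompressed); any unzip
  implementation reads it, but it is larger than a deflated archive.
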