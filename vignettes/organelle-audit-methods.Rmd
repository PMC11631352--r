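---
title: "Auditing cryptic organelle reads in 16S rRNA surveys: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing cryptic organelle reads in 16S rRNA surveys: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organaudit)
```

## The problem

Mitochondria and chloroplasts descend from free-living bacteria and still carry
small-subunit rRNA genes (the mitochondrial 12S is homologous to the bacterial
16S). The V4 primers used by large standardized surveys co-amplify these
organelle rRNAs. When the reference taxonomy contains an organelle sequence
similar to the read, annotation pipelines label it `Mitochondria` or
`Chloroplast` and it can be filtered out; the only cost is sequencing depth.
The dangerous case is the *cryptic* organelle read: an organelle amplicon too
divergent from any reference organelle to be recognized, which surfaces as
`Unassigned` at the domain level. Because organelle load varies across samples
and host species — diet, epibionts, heteroplasmy (intra-individual 12S
divergence can exceed 20%), and NUMTs all contribute distinct organelle
variants — cryptic reads are retained at group-varying rates, distorting
relative abundances and alpha/beta-diversity comparisons.

organaudit implements the corresponding audit-and-repair workflow at desk
scale: extend a base reference with diverse organelle amplicons, re-annotate,
quantify what moved, filter, and measure the downstream statistical effect.
Everything is exercised on seeded synthetic data, so each claim in the test
suite is a property of an explicitly stated world.

## Reference model and lineage dialects

A reference database couples DNA sequences with seven-rank lineages
(domain … species) in one of two string dialects, `silva` (`d__` prefix) or
`greengenes` (`k__`). Organelle status is always *derived* from the labels —
case-insensitive token match on `mitochondria`/`chloroplast` — never stored,
which makes audits dialect-proof. Added organelle records are filed where each
base release already places organelles:

* silva: `d__Bacteria; p__Proteobacteria; c__Alphaproteobacteria;
  o__Rickettsiales; f__Mitochondria` and `…; c__Cyanobacteriia; o__Chloroplast`
* greengenes: the same placements with `k__` and lowercase `mitochondria`

with host genus/species appended at the next ranks when known. The literal
`Unassigned` is the domain-level failure sentinel; a lineage resolved only to
`d__Bacteria` is *not* unknown.

## In-silico PCR

`extract_amplicon()` performs deterministic in-silico PCR: exact
IUPAC-degenerate matching of the forward primer (both strands searched,
leftmost site chosen), then the nearest downstream reverse-complement of the
reverse primer giving an inter-primer length within bounds (defaults
100–500 nt; `max_mismatch = 0`). Defaults are the V4 pair
`GTGTGCCAGCMGCCGCGGTAA` / `GGACTACHVGGGTWTCTAAT` as printed in EMP-style
protocols. The printed forward primer is 21 nt (two leading `GT` repeats)
rather than the canonical 19-nt 515f; we deliberately keep the printed string
as the default rather than silently "correcting" it — primer choice is the
user's statement, not ours. An optional post-extraction truncation (off by
default; 100 nt mirrors pipelines that trim reads to 100 nt) truncates from
the amplicon's 5' end and discards shorter amplicons.

## Alignment: one engine, two end-gap policies

All similarity computations use one semi-global aligner (match +1, mismatch
−1, linear gap −2; IUPAC set intersection counts as a match), implemented in
C++ and cross-checked in the test suite against an independent
dynamic-programming implementation from Biostrings. Identity is matches /
alignment columns (internal gaps count, terminal overhangs do not); coverage
is the fraction of the query inside the aligned region.

The two places the toolkit aligns need different end-gap policies, and this is
a deliberate design decision:

* **Taxonomy search** uses *query-global* alignment (query fully aligned,
  reference overhangs free). With ends-free-on-both-ends alignment, the
  optimal alignment between two *unrelated* sequences is a tiny near-perfect
  fragment — empirically, random 250-nt pairs yield short overlaps with
  identity approaching 1.0 — so an identity-only acceptance cutoff would pass
  junk hits and both negative controls (mock communities, shuffled reads)
  would fail. Query-global identity is also what the wrapped
  consensus-search tools actually compute.
* **The positive filter** uses the ends-free *overlap* mode, where coverage is
  meaningful and the screen is "identity ≥ 0.65 AND coverage ≥ 0.50 to at
  least one trusted sequence" (boundaries inclusive). A fragment hit with
  identity 1.0 but coverage 0.05 is correctly discarded by the coverage arm.

A shared-k-mer prefilter (distinct 8-mers, top 50 candidates, ties broken by
reference id) bounds the number of alignments per query; on databases of ≤ 50
sequences it is a no-op, and the tests assert exact equality with exhaustive
search there.

## Classifiers

**Top-hit consensus.** Hits with identity ≥ `perc_identity` (default 0.80)
are accepted up to `maxaccepts` (10). Walking ranks from the domain down, a
rank is kept while the plurality label is unique, non-empty, and shared by at
least `min_consensus` (0.51) of *all* accepted hits; the lineage truncates at
the first failing rank and the score is the consensus fraction at the deepest
kept rank. Plurality ties fail the rank (conservative).

**k-mer naive Bayes.** Classes are the distinct full lineages; per class the
overlapping 7-mer counts of its sequences are pooled, smoothed with
alpha = 0.001 over the 4^7 vocabulary, and normalised; priors are uniform.
Posteriors are computed in the log domain. Rank confidence aggregates class
posteriors greedily up the taxonomy (the maximal-label path), truncating at
the deepest rank with confidence ≥ 0.70. This closed-form aggregation replaces
bootstrap resampling: it is deterministic and monotone (raising the threshold
never deepens a lineage), which the tests assert. The classifier happily
detects even composition-preserving shuffled artifacts (mononucleotide and
short-word composition survive shuffling), so the shuffled-sequence negative
control is asserted for the consensus classifier only — the same asymmetry
reported for the tools this package mirrors.

## Audit quantities

Per sample, reads partition into `unassigned` / `mitochondria` /
`chloroplast` / `other`; zero-read samples are flagged and excluded from
proportions. Reclassification flows assign each feature's total read mass to a
(label under base, label under extended) cell with organelle labels overriding
the rank label. The unknown fold-change per sample is
`p_unassigned(base) / p_unassigned(extended)`, with `Inf` (counted as above
threshold) when the extended value is zero and exclusion when the base value
is zero. Read proportions are the default accounting; the audit CLI reports
per-sample tables so unique-feature accounting can be derived if wanted.
Organelle filtering drops flagged rows and touches nothing else — retained
counts are bit-identical, so all pairwise log-ratios of retained features, and
hence CLR-based (Aitchison) distances on filtered tables, are exactly
invariant to spiked organelle features. That exactness is asserted in the
acceptance tests.

## Diversity layer

Rarefaction subsamples each sample to exactly `depth` reads without
replacement (default 1000, the benchmark depth; seeded). Alpha metrics:
observed features; Shannon in log base 2; Simpson's evenness as
inverse-Simpson over observed richness, `(1/Σp²)/S` (the variant is not
uniquely pinned down by the sources we mirror, so the choice is recorded
here and in the result metadata); Faith's PD as the branch length of the
minimal subtree spanning the observed tips *including the path to the root*.
Beta metrics: binary Jaccard and Bray–Curtis via vegan; Aitchison as the
Euclidean distance of CLR(counts + 1) on *unrarefied* counts; unweighted and
(unnormalised) weighted UniFrac via phyloseq.

Group tests follow the benchmark design: Kruskal–Wallis (tie-corrected H,
chi-square p) for alpha metrics; one-way PERMANOVA for beta metrics with
pseudo-F from the standard among/within decomposition of squared distances and
`p = (1 + #{F_perm ≥ F_obs}) / (1 + n_permutations)` under seeded label
permutations. The statistic is checked against vegan's `adonis2` and the
permutation p against an exhaustive enumeration oracle at n = 6 — where, note,
two equal groups admit partition-preserving relabelings that tie the observed
F, so the exact p is 0.1, not the 1/(n+1) floor; the floor is attained at
n = 20 where partition-preserving permutations are vanishingly rare. The
default 999 permutations is a desk-scale choice (the mirrored analyses used
999 999 for p resolution; the parameter is exposed). Effect size is the test
statistic itself (H, pseudo-F), and `compare_conditions()` reports
effect-size fold-changes, p-value shifts, and alpha = 0.05 crossings between
base- and extended-reference runs, with a clearly-labelled Benjamini–Hochberg
column alongside the raw p-values (no correction is applied to the primary
comparison).

## The synthetic world

The generators are pure functions of `(sim_spec, seed)` and their defaults are
the stated benchmark world, chosen once:

* Bacterial reference: 3 phyla × 4 genera × 3 species, 250-nt amplicons.
  Phylum roots are independent random sequences; genus founders diverge 0.25
  from their root, species 0.02 from their founder — sibling species sit near
  0.96 identity, cross-genus pairs near 0.6, so consensus assignments resolve
  to genus level and the hierarchy is unambiguous. A matching tree with
  substitution-proportional branch lengths supports the phylogenetic metrics.
* Organelle pool: 12 variants, each independently diverged d = 0.20 from a
  hidden common ancestor (within the reported real-world range of 12S
  divergence). The ancestor is rejection-sampled below 0.75 identity to every
  bacterial reference and is *not itself a pool member*: with independent
  branches, cross-variant identity is ≈ 1 − 2d(1−d) − (2/3)d² ≈ 0.65, safely
  below the classifier's 0.80 acceptance threshold. Had the ancestor been in
  the base subset, every cryptic variant would sit exactly *at* the 0.80
  boundary (identity 1 − d) and "cryptic" would be a coin flip — the pool
  design makes the base reference genuinely lack the cryptic clade.
  Variants share intact primer sites and flanks (primer regions are conserved
  in real rRNA genes), so reference extension exercises the in-silico PCR.
* Study: 2 groups × 10 samples × 500 reads. Bacterial reads follow a
  Dirichlet-multinomial (concentration 50) around one shared base composition,
  so the groups' true microbiomes are exchangeable; organelle reads are added
  at group loads 5% and 30% (the between-group contrast the conceptual model
  illustrates), drawn 4:1 preferentially from cryptic variants. Sequencing
  error is 0.001/base substitutions (typical post-QC short-read scale);
  identical reads collapse to features.
* Negative controls: the mock fixture is the same study with organelle load
  forced to zero; shuffled artifacts permute each sequence's characters,
  preserving length and composition.

What a green test does and does not establish: the world has clean clade
structure, substitution-only errors, no chimeras, no indels, no primer-site
variation, and organelle divergence concentrated on a single hidden ancestor.
Green tests establish that the workflow's logic behaves as designed under the
stated conditions — not that any particular real survey has a specific
fraction of cryptic reads.

## Numerical and degenerate-input choices

Ties in search are broken by reference id ascending; plurality ties truncate;
rarefaction drops (with a message) samples below depth and errors only when
nothing survives; zero-read samples yield `NA` fractions and are excluded from
fold-change denominators; division edge cases in fold-changes are `Inf`
(counted) and excluded (base 0) respectively; duplicate organelle records
(same extracted sequence and lineage) are skipped, id collisions get
`.dupN` suffixes rather than silently dropping divergent taxonomy evidence.
All randomness flows through explicit seeds; repeated runs are bytewise
identical, and the single CLI `--seed` flag (default 0, never wall-clock)
threads through every stochastic operation.

## Scaling notes

The pipeline-level calibration test (spurious PERMANOVA rejections under
base-reference annotation versus restored calibration under extended
annotation + filtering) runs 200 replicates with sequencing error disabled, so
the unique sequence universe is the fixed set of reference and variant
amplicons; those are classified once per reference and the replicates redraw
only the count tables. This is exact reuse — classification of a given
sequence is deterministic — and keeps the property inside a desk-scale test
budget. The mock-community control is likewise run at a reduced sample count;
the stated study world itself (the cryptic-recovery experiment) runs at full
default scale.

## Known limitations

* The naive-Bayes confidence is posterior aggregation, not bootstrap; absolute
  confidence values are not comparable to bootstrap-based implementations.
* Gap costs are linear, not affine; SortMeRNA's seed algorithm is not
  reproduced, only its identity/coverage acceptance semantics.
* BIOM binary I/O, ordination plots, pairwise post-hoc PERMANOVA, and
  differential-abundance methods are out of scope.
* The weighted UniFrac is the unnormalised variant; Simpson's evenness is the
  inverse-Simpson-over-richness form (both recorded in output metadata).
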