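---
title: "Gene-cluster-centric k-mers for bacterial GWAS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-cluster-centric k-mers for bacterial GWAS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bacterial genome-wide association studies cannot lean on a single reference
genome: horizontal gene transfer makes the accessory genome large, and any
one reference misses much of it. The common workaround — encoding variation
as k-mers or as unitigs of a global de Bruijn graph built from all input
genomes — is reference-free but loses local context. Two consequences
follow. First, a k-mer whose sequence occurs in several gene clusters
(paralogs, mobile elements, repeats) collapses onto a *single* global
presence/absence pattern to which all its occurrences contribute, so an
association can implicate gene clusters that have nothing to do with the
phenotype. Second, mapping a significant k-mer back to a position in each
genome is an error-prone post hoc step.

`pankmer` encodes variants the other way around: k-mers are extracted
*within each gene cluster* of a pangenome (as clustered upstream by Roary,
panaroo or ggCaller), so the same sequence occurring in two clusters yields
two independent presence/absence patterns, and every k-mer occurrence is
recorded with base-resolution coordinates — absolute on its contig and
relative to the gene's start codon — at generation time, not after the
association.

## The procedure

For every cluster of the `gene_presence_absence.csv` matrix:

1. each member gene's sequence is pulled from its strain's GFF3 annotation
   (embedded `##FASTA` or companion FASTA), reverse-complemented for `-`
   strand genes so the sequence always reads 5'→3' in gene orientation,
   optionally extended by `upstream`/`downstream` flanking bases (truncated
   silently at contig edges, with the obtained lengths recorded so relative
   coordinates stay exact);
2. every window of length *k* is canonicalised (lexicographic minimum of
   the window and its reverse complement); windows containing non-ACGT
   characters are skipped entirely — no expansion of ambiguity codes;
3. per distinct canonical k-mer, a binary presence/absence vector over the
   strain panel is assembled (a k-mer occurring several times in one
   strain, or in several paralogous copies, is present once; every
   occurrence is still logged positionally for the target strains);
4. k-mers whose vector equals the cluster's own presence vector are dropped
   by default (they duplicate the gene presence/absence signal); `filter =
   FALSE` keeps them, which is essential when gene presence itself may be
   the causal variant;
5. each distinct vector is hashed — MD5 over the `0`/`1` string in panel
   order, 128 bits, unsalted — so identical patterns map to one identifier
   across clusters, runs and machines, and the association tool tests each
   unique pattern once.

Three tab-separated files are streamed: `kmers.tsv` (one row per logged
occurrence: cluster, strain, contig, absolute half-open interval, strand,
start-codon-relative interval, canonical sequence, pattern hash),
`kmers_to_hashes.tsv` (cluster × canonical sequence → hash) and
`hashes_to_patterns.tsv`, an Rtab matrix directly usable as pyseer
`--rtab` input.

## Coordinate conventions

Internally all intervals are 0-based half-open on the forward strand;
GFF3's 1-based inclusive coordinates are converted at the boundary, so
conversion round-trips exactly. Relative position 0 is the first base of
the start codon; upstream flank bases have negative positions (a promoter
SNP 7 bases upstream sits at −7), and `rel_end = rel_start + k`. The
`strand` column of `kmers.tsv` records the relation between the canonical
form and the window *as read in gene orientation* (`+`: equal, `-`:
reverse complement); this makes the per-base nucleotide reconstruction
used by the sequence panels possible from the positional log alone. The
identities `abs_start − rel_start = gene_start` (`+` genes) and
`abs_end + rel_start = gene_end` (`-` genes) hold for every row and are
enforced by the test suite.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 31 | k-mer length (bases); the usual bacterial GWAS choice, long enough to be specific within a cluster |
| `upstream`, `downstream` | 0 | flank lengths (bases) added in gene orientation; enables promoter-aware association |
| `filter` | `TRUE` | drop k-mers whose pattern equals their cluster's pattern |
| `targets` | all strains | strains whose occurrences are written to `kmers.tsv`; `character(0)` logs none (two-pass mode) |
| `cores` | 1 | with ≥ 3 cores, `cores − 2` forked workers process clusters |
| `alpha` | 0.05 | family-wise error rate for the Bonferroni threshold `alpha / n_patterns`, with `n_patterns` the rows of the Rtab file (uniquely tested patterns, not k-mers) |

Significance uses strict inequality (`p < threshold`).

## Two-pass workflow

Positional logging dominates disk usage at scale. The two-pass mode first
runs with no target strains — complete patterns, header-only positional
log — feeds the Rtab to the association tool, maps significant patterns
back to clusters with `annotate_associations()`, and re-runs the generator
restricted to those clusters (`run_second_pass()`). Because the pattern
hash is a pure function of the bit vector, second-pass hashes coincide
with first-pass hashes for the same (cluster, k-mer) pairs; the test suite
checks byte-identity of the pattern file and that the second-pass
positional log equals the single-pass log filtered to the selected
clusters.

## Parallel execution

With `cores >= 3`, clusters are dispatched to `cores - 2` forked workers
(`parallel::mclapply`) in fixed-size chunks (`chunk_size`, default 64
clusters), and the writer appends each chunk in cluster input order. This
keeps the number of in-flight cluster results bounded by one chunk and
makes serial and parallel outputs byte-identical — ordered emission is
part of the output contract, so golden-file comparisons are meaningful.
No timestamps or unordered-map iteration enter the files.

## Duplication statistics

`duplication_summary()` quantifies how often the same canonical sequence
occurs in two or more clusters ("multicluster" k-mers) — the quantity
that motivates cluster-centric encoding, since exactly these k-mers would
be collapsed by a global graph. Counts are over distinct canonical
sequences pangenome-wide; a sequence repeated within one cluster counts
that cluster once. The statistics are computed from
`kmers_to_hashes.tsv` as a cheap post-pass; generation must run with
`filter = FALSE` so that cluster-pattern-identical k-mers are included in
the denominator.

## Visualization

`cluster_heatmap()` projects pattern-level p-values onto base resolution:
rows are isolates (phenotype-positive group on top, then panel order — the
within-group order is fixed for determinism), the x-axis is the
start-codon-relative position, and each covered cell takes the minimum
p-value over the k-mers covering it. Cells are coloured by −log10(p)
clipped to [−log10(threshold), 10] (every p below 1e-10 maps to the top of
the scale), light grey when covered only by non-significant k-mers, dark
grey where an isolate has no logged k-mer (shorter gene, filtered k-mers,
or gene absent). A vertical line marks the start codon, a horizontal line
the phenotype-group boundary. `sequence_panel()` reconstructs the actual
nucleotides per isolate and relative position from the positional log and
draws a colour-coded letter panel, optionally boxing a position of
interest. The colormap endpoints are a documented default (pale yellow to
dark red); scale bounds, not aesthetics, are the contract.

## The synthetic pangenome generator

`simulate_pangenome()` emulates the full input set — per-strain GFF3 with
embedded FASTA, Roary-dialect presence/absence matrix, binary phenotype
table — plus a ground-truth manifest, fully determined by one seed.
Defaults: 10 strains, 5 core and 5 accessory clusters at 50 % carriage,
120–300 bp gene bodies starting with `ATG` and ending with a stop codon,
1 % per-base substitution rate between strains, genes on random strands
separated by random spacers, and 60 bp conserved flanks.

Design choices worth stating explicitly:

* **Phenotype assignment is case-control style** — exactly
  `round(n × prob)` positives, membership random. With i.i.d. assignment a
  small panel can draw a lopsided split, and a 2-strain minority group
  makes it likely that some wild-type k-mer pattern in an unrelated
  cluster coincides with the phenotype pattern, polluting the planted
  ground truth. Fixed group sizes are also how real case-control panels
  are assembled.
* **Flanks are conserved** (not mutated), so promoter k-mers differ only
  at planted variants and the planted-SNP signal is exactly localised.
* **The planted duplicated segment is a maximal shared run**: the bases
  immediately flanking the 40 bp segment are forced to differ between the
  two clusters and are excluded from mutation, so the segment contributes
  exactly `40 − k + 1` multicluster k-mers and boundary coincidences
  cannot extend the run.
* **Planted elements**: a phenotype-linked accessory gene (carried exactly
  by the positives — its k-mer patterns equal the cluster pattern, so it
  is recoverable only with `filter = FALSE`, which is precisely the filter
  semantics being tested) and a phenotype-linked promoter SNP at −7 in a
  dedicated core cluster (T in positives, C otherwise; its k-mer patterns
  differ from the all-ones cluster pattern, so it survives the default
  filter).
* `simulate_association_table()` bypasses real association testing: it
  assigns a tiny p-value (1e-12) to every pattern equal to the phenotype
  vector or its complement (a binary association is symmetric in allele
  labelling) and uniform p-values elsewhere. At a Bonferroni threshold the
  chance of a false hit among the uniform patterns is at most alpha by the
  union bound. An end-to-end fixture that is meant to be *null* must
  therefore contain no pattern coinciding with the phenotype; the test
  suite builds such fixtures with zero substitution rate so pattern
  diversity comes from accessory carriage alone.

What the simulator deliberately does **not** model: phylogenetic
population structure, recombination, linkage between clusters, indels,
annotation errors, or fragmented assemblies. Passing tests on these
fixtures demonstrate the correctness of the extraction, hashing, filter,
mapping and plotting machinery — not robustness to misannotation or to
population confounding, which in real analyses are the job of the
upstream clustering tool and of the association model (covariates,
lineage effects) respectively.

## Numerical and degenerate-input choices

* Canonical form: lexicographic minimum over the plain C-locale byte
  order of A < C < G < T; palindromic k-mers report the forward
  orientation.
* Hash collisions are not detected; at 128 bits the collision probability
  is negligible at any realistic pattern count.
* Sequences shorter than *k* (after flank truncation) yield no windows and
  no error; clusters can legitimately produce zero k-mers (e.g. a fully
  conserved core gene under the default filter) and all writers accept
  empty input, emitting header-only files.
* A gene identifier present in the matrix but absent from the strain's
  annotation demotes that strain to "cluster absent" with a warning
  (panaroo's refound identifiers routinely do this); a strain column with
  no annotation file at all is a hard error, because it would silently
  zero one position of every pattern.
* Paralogous copies (`;`-separated identifiers) are all scanned in
  genomic-coordinate order; presence is the OR over copies.
* Multiple occurrences of one k-mer in one strain are all logged
  positionally.

## Problem sizes used by the test suite

The oracle-equivalence property compares the engine against an
independently written brute-force enumerator (Biostrings-based
canonicalisation, per-window loops) on 100 random pangenomes of up to 10
strains, 5 clusters and 200 bp genes at k ∈ {3, 5, 31}; parallel/serial
byte-equivalence runs on 20 random pangenomes; the duplication summary is
checked against set-algebra brute force on 100 random cluster/k-mer sets;
end-to-end recovery runs on 10-strain simulated panels. These sizes keep
the full suite around a minute while exercising every code path,
including flank truncation, `-` strand genes, skipped ambiguous windows
and empty clusters.

## Known limitations

* Pattern counting for the Bonferroni threshold uses the generated Rtab
  rows; if the association tool drops patterns (allele-frequency
  filtering), the threshold is conservative.
* The heatmap reconstructs coverage from logged k-mers only: a base
  covered exclusively by filtered-out k-mers shows as dark grey even
  though sequence exists there — matching the semantics of the positional
  log, not of the genome.
* Column layouts of the three output files are fixed and documented here;
  other tools in this space may name columns differently.
* The CLI (`inst/scripts/pankmer`) is a thin wrapper over the exported
  functions; programmatic use gets strictly more control (e.g.
  `chunk_size`).
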