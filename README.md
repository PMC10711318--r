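# pankmer

Gene-cluster-centric k-mer variants for bacterial genome-wide association
studies (GWAS).

## The problem

Bacterial GWAS encodes genetic variation as k-mers or unitigs because no
single reference genome covers a species' accessory genome. But variants
derived from a *global* de Bruijn graph have two weaknesses: a k-mer whose
sequence occurs in several gene clusters gets one pooled presence/absence
pattern — so an association can implicate unrelated clusters — and mapping
a significant k-mer back to a position in each genome is a lossy
afterthought.

`pankmer` generates k-mers *within each gene cluster* of a pangenome
instead. Starting from a Roary/panaroo/ggCaller `gene_presence_absence.csv`
and one GFF3 (+FASTA) annotation per strain, it emits, per cluster, the
canonical k-mers (`min(s, revcomp(s))`, default k = 31, optionally
including upstream/downstream flanks so promoters are analysed in the
context of their gene), a presence/absence vector per k-mer over the
strain panel, and the position of every occurrence — absolute on the
contig and relative to the gene's start codon (negative = promoter).
Each distinct pattern `v ∈ {0,1}^n` gets a stable 128-bit identifier
`h = MD5(v)`, and the association tool tests each *unique pattern* once:
the Bonferroni threshold is `α / #patterns`. Because patterns are
per-cluster, the same sequence in two clusters keeps two independent
patterns and two independent association results.

Outputs are three TSV files: `kmers.tsv` (positional log),
`kmers_to_hashes.tsv` (cluster × k-mer → pattern id) and
`hashes_to_patterns.tsv` — an Rtab matrix fed directly to
[pyseer](https://pyseer.readthedocs.io) via `--rtab`. After the
association, significant pattern identifiers are mapped back to clusters,
k-mers and base positions, and plotted as isolate × position heatmaps.

For whom: microbial genomics groups running k-mer-based GWAS who want
variants that are interpretable at gene and base resolution without a
reference genome, and a low-footprint ("two-pass") mode for large panels.

## Worked example

A seeded synthetic pangenome (10 strains, core + accessory clusters, a
phenotype-linked promoter SNP planted at relative position −7) stands in
for the usual panaroo output:

```r
library(pankmer)

sim <- simulate_pangenome(sim_spec(planted_snp = TRUE, seed = 42), "pangenome")
run <- generate_kmers(sim$csv, sim$gff_dir, "out", k = 31, upstream = 60)
run
#> pankmer run: 11 clusters, 6450 k-mer records, 168 unique patterns, 632 filtered
```

11 clusters produced 6450 (cluster, k-mer) records collapsing onto 168
unique presence/absence patterns; 632 k-mers matched their cluster's own
pattern and were filtered (use `filter = FALSE` to keep them, e.g. when
gene presence itself may be causal). `out/hashes_to_patterns.tsv` now goes
to pyseer; here a simulated association table stands in for it:

```r
simulate_association_table(run$paths[["hashes_to_patterns"]],
                           sim$phenotype, "out/associations.tsv", seed = 43)
thr <- bonferroni_threshold(run$stats$patterns)
thr
#> Bonferroni threshold: 0.000297619 (alpha = 0.05 / 168 patterns)

ann <- annotate_associations(read_associations("out/associations.tsv"),
                             run$paths[["kmers_to_hashes"]], thr)
ann
#> association_annotation: 168 patterns, 2 significant at 0.000297619
head(ann$cluster_summary, 3)
#>   cluster        min_p n_kmers n_significant_kmers
#> 1 snpgene 1.000000e-12     869                  45
#> 2   acc03 1.004683e-02     470                   0
#> 3   acc04 1.004683e-02     317                   0
select_second_pass_genes(ann)
#> [1] "snpgene"
```

Exactly the cluster carrying the planted SNP is flagged: 2 significant
patterns (the T-allele k-mers, present in the phenotype-positive strains,
and the C-allele k-mers, present in the others), 45 significant k-mers,
all in `snpgene`. The positional log places them over the SNP — e.g. the
k-mers covering relative position −7 in strain S01:

```r
km <- read_kmers(run$paths[["kmers"]])
head(km[km$cluster == "snpgene" & km$rel_start <= -7 & km$rel_end > -7, ], 3)
#>       cluster strain   contig abs_start abs_end strand rel_start rel_end
#> 13257 snpgene    S01 S01_ctg1      3228    3259      -        -7      24
#> 13258 snpgene    S01 S01_ctg1      3229    3260      -        -8      23
#> 13259 snpgene    S01 S01_ctg1      3230    3261      -        -9      22
#>                    canonical_sequence                          hash_id
#> 13257 CACGGTGGTTCACCAAATGACCATGCACATA 9d19bd1c5808e1529ec603a0c4303c20
#> 13258 ACGGTGGTTCACCAAATGACCATGCACATAG 9d19bd1c5808e1529ec603a0c4303c20
#> 13259 CGGTGGTTCACCAAATGACCATGCACATAGC 9d19bd1c5808e1529ec603a0c4303c20
```

and the per-cluster heatmap (isolates × relative position, coloured by
−log10 p of the best covering k-mer, phenotype-positive group on top) plus
a nucleotide panel around the SNP:

```r
pheno <- read.delim(sim$phenotype)
cluster_heatmap(km, ann, pheno, cluster = "snpgene", path = "snpgene.png")
sequence_panel(km, window = c(-15, 5), cluster = "snpgene",
               highlight = -7, path = "snpgene_seq.png")
```

Other entry points: `duplication_summary()` / `plot_duplication()` for the
proportion of k-mers occurring in multiple clusters, `validate_inputs()`
for a dry run, and `run_second_pass()` for the two-pass workflow (first
pass with `targets = character(0)` writes patterns only; the second pass
logs positions for the significant clusters alone). A command-line wrapper
with subcommands `generate`, `dup-stats`, `annotate`, `plot`,
`second-pass` and `simulate` is installed under
`system.file("scripts", "pankmer", package = "pankmer")`.

See the vignette (`vignettes/cluster-centric-kmers.Rmd`) for the method,
coordinate conventions, parameter meanings and the simulator's design.

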