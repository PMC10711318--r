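#' Specification for a synthetic pangenome
#'
#' Collects the parameters of the seeded pangenome simulator. Defaults
#' describe a small but structurally realistic panel: 10 strains, 5 core
#' and 5 accessory gene clusters with 50 % carriage, 120-300 bp genes with
#' a 1 % per-base substitution rate between strains, genes on random
#' strands separated by random intergenic spacers, and 60 bp conserved
#' flanking regions (flanks are not mutated so promoter k-mers differ only
#' at planted variants). Three elements can be planted to create ground
#' truth: a duplicated segment shared between the first two core clusters
#' (producing multicluster k-mers), a phenotype-linked accessory gene
#' (whose k-mer patterns equal its cluster pattern, so it is only
#' recoverable with the cluster-identity filter disabled), and a
#' phenotype-linked promoter SNP at a chosen position relative to the
#' start codon (default -7).
#'
#' @param n_strains number of strains.
#' @param n_core,n_accessory numbers of core / accessory clusters.
#' @param carriage per-strain carriage probability of accessory clusters.
#' @param gene_length integer length-2 range of gene body lengths (bp).
#' @param snp_rate per-base substitution probability per strain in gene
#'   bodies (flanks and planted segments are conserved).
#' @param random_strand place each gene copy on a random strand.
#' @param flank conserved flank length on each side of a gene (bp).
#' @param spacer integer length-2 range of intergenic spacer lengths (bp).
#' @param planted_dup plant a shared duplicated segment into the first two
#'   core clusters.
#' @param dup_length length of the duplicated segment (bp).
#' @param planted_gene plant an accessory cluster carried exactly by
#'   phenotype-positive strains.
#' @param planted_snp plant a promoter SNP (T in phenotype-positive
#'   strains, C otherwise) in a dedicated core cluster.
#' @param snp_rel_pos relative position of the planted SNP (< 0: upstream
#'   of the start codon).
#' @param phenotype_prob probability of the positive phenotype per strain.
#' @param seed integer seed; fully determines the simulated files.
#' @return list of class `sim_spec`.
#' @export
sim_spec <- function(n_strains = 10L, n_core = 5L, n_accessory = 5L,
                     carriage = 0.5, gene_length = c(120L, 300L),
                     snp_rate = 0.01, random_strand = TRUE, flank = 60L,
                     spacer = c(20L, 80L), planted_dup = FALSE,
                     dup_length = 40L, planted_gene = FALSE,
                     planted_snp = FALSE, snp_rel_pos = -7L,
                     phenotype_prob = 0.5, seed = 1L) {
  stopifnot(n_strains >= 1L, carriage >= 0, carriage <= 1,
            phenotype_prob >= 0, phenotype_prob <= 1,
            gene_length[1] >= 10L, snp_rate >= 0, snp_rate <= 1,
            flank >= 0L, snp_rel_pos < 0L, -snp_rel_pos <= flank || !planted_snp)
  if (planted_dup && n_core < 2L) {
    stop("a planted duplicated segment needs at least two core clusters")
  }
  if (planted_dup && dup_length > gene_length[1] - 20L) {
    stop("duplicated segment does not fit the shortest gene body")
  }
  structure(as.list(environment()), class = "sim_spec")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

mutate_body <- function(body, rate, mask = integer(0)) {
  if (rate <= 0) return(body)
  ch <- strsplit(body, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  hit <- setdiff(hit, mask)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Simulate a pangenome file set
#'
#' Writes, under `dir`, one GFF3 file with embedded FASTA per strain
#' (`<strain>.gff`), a Roary-dialect `gene_presence_absence.csv`, a
#' `phenotype.tsv` (columns `strain`, `phenotype`) and a ground-truth
#' `manifest.json` recording the phenotype, carriage, and the exact
#' content and location of every planted element. Running the simulation
#' twice with the same spec yields byte-identical files.
#'
#' @param spec a [sim_spec()].
#' @param dir output directory (created).
#' @return list of class `sim_pangenome`: `dir`, `csv`, `gff_dir`,
#'   `phenotype` (path), `manifest` (the parsed ground truth), `strains`.
#' @export
simulate_pangenome <- function(spec, dir) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  strains <- sprintf("S%02d", seq_len(spec$n_strains))

  # case-control style assignment: fixed group sizes, random membership
  n_pos <- round(spec$n_strains * spec$phenotype_prob)
  if (spec$planted_gene || spec$planted_snp) {
    n_pos <- min(max(n_pos, 1L), spec$n_strains - 1L)  # both groups populated
  }
  phenotype <- integer(spec$n_strains)
  phenotype[sample.int(spec$n_strains, n_pos)] <- 1L
  names(phenotype) <- strains

  cluster_ids <- c(sprintf("core%02d", seq_len(spec$n_core)),
                   if (spec$n_accessory)
                     sprintf("acc%02d", seq_len(spec$n_accessory)),
                   if (spec$planted_gene) "phenogene",
                   if (spec$planted_snp) "snpgene")

  n_len <- diff(spec$gene_length) + 1L
  anc <- list()
  dup_segment <- NULL
  for (cid in cluster_ids) {
    L <- spec$gene_length[1] + sample.int(n_len, 1L) - 1L
    body <- paste0("ATG", rand_dna(L - 6L), "TAA")
    anc[[cid]] <- list(
      body = body,
      up = if (spec$flank) rand_dna(spec$flank) else "",
      down = if (spec$flank) rand_dna(spec$flank) else "",
      mask = integer(0)
    )
  }
  if (spec$planted_dup) {
    dup_segment <- rand_dna(spec$dup_length)
    # boundary bases are forced to differ between the two clusters (and are
    # conserved), so the shared run is maximal: exactly dup_length bases
    edge <- c(core01 = "A", core02 = "C")
    for (cid in c("core01", "core02")) {
      b <- anc[[cid]]$body
      at <- 11L  # 1-based; inside the body, clear of start/stop codons
      substr(b, at, at + spec$dup_length - 1L) <- dup_segment
      substr(b, at - 1L, at - 1L) <- edge[[cid]]
      substr(b, at + spec$dup_length, at + spec$dup_length) <- edge[[cid]]
      anc[[cid]]$body <- b
      anc[[cid]]$mask <- (at - 1L):(at + spec$dup_length)
    }
  }
  snp_idx <- NULL
  if (spec$planted_snp) {
    # flank position holding relative coordinate snp_rel_pos (1-based index)
    snp_idx <- spec$flank + spec$snp_rel_pos + 1L
    substr(anc$snpgene$up, snp_idx, snp_idx) <- "C"
  }

  carried <- matrix(FALSE, spec$n_strains, length(cluster_ids),
                    dimnames = list(strains, cluster_ids))
  for (cid in cluster_ids) {
    carried[, cid] <- if (grepl("^core|^snpgene", cid)) TRUE
      else if (cid == "phenogene") phenotype == 1L
      else stats::runif(spec$n_strains) < spec$carriage
  }

  gene_table <- matrix("", spec$n_strains, length(cluster_ids),
                       dimnames = list(strains, cluster_ids))
  for (s in strains) {
    contig <- character(0)
    offset <- 0L
    rows <- character(0)
    counter <- 0L
    for (cid in cluster_ids) {
      if (!carried[s, cid]) next
      counter <- counter + 1L
      gid <- sprintf("%s_%04d", s, counter)
      gene_table[s, cid] <- gid
      body <- mutate_body(anc[[cid]]$body, spec$snp_rate, anc[[cid]]$mask)
      up <- anc[[cid]]$up
      if (identical(cid, "snpgene") && phenotype[[s]] == 1L) {
        substr(up, snp_idx, snp_idx) <- "T"
      }
      down <- anc[[cid]]$down
      spc <- rand_dna(spec$spacer[1] + sample.int(diff(spec$spacer) + 1L, 1L) - 1L)
      strand <- if (spec$random_strand) sample(c("+", "-"), 1L) else "+"
      unit <- paste0(up, body, down)
      if (strand == "-") unit <- revcomp(unit)
      contig <- c(contig, spc, unit)
      offset <- offset + nchar(spc)
      # forward-strand gene body coordinates inside the inserted unit
      lead <- if (strand == "-") nchar(down) else nchar(up)
      g_start <- offset + lead          # 0-based inclusive
      g_end <- g_start + nchar(body)    # 0-based exclusive
      rows <- c(rows, paste(paste0(s, "_ctg1"), "pankmer_sim", "CDS",
                            g_start + 1L, g_end, ".", strand, "0",
                            paste0("ID=", gid, ";locus_tag=", gid),
                            sep = "\t"))
      offset <- offset + nchar(unit)
    }
    contig <- paste0(paste(contig, collapse = ""), rand_dna(30L))
    gff <- file.path(dir, paste0(s, ".gff"))
    con <- file(gff, "wb")
    writeLines(c("##gff-version 3",
                 paste("##sequence-region", paste0(s, "_ctg1"), 1,
                       nchar(contig)),
                 rows, "##FASTA", paste0(">", s, "_ctg1"),
                 substring(contig, seq(1, nchar(contig), 60),
                           pmin(seq(1, nchar(contig), 60) + 59, nchar(contig)))),
               con)
    close(con)
  }

  csv <- file.path(dir, "gene_presence_absence.csv")
  meta <- data.frame(
    Gene = cluster_ids, `Non-unique Gene name` = "", Annotation = "",
    `No. isolates` = colSums(carried), `No. sequences` = colSums(carried),
    `Avg sequences per isolate` = 1, `Genome Fragment` = "",
    `Order within Fragment` = "", `Accessory Fragment` = "",
    `Accessory Order with Fragment` = "", QC = "",
    `Min group size nuc` = "", `Max group size nuc` = "",
    `Avg group size nuc` = "", check.names = FALSE)
  out <- cbind(meta, as.data.frame(t(gene_table), stringsAsFactors = FALSE))
  utils::write.csv(out, csv, row.names = FALSE)

  pheno_path <- file.path(dir, "phenotype.tsv")
  utils::write.table(
    data.frame(strain = strains, phenotype = phenotype),
    pheno_path, sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    seed = spec$seed, strains = strains,
    phenotype = as.list(stats::setNames(phenotype, strains)),
    clusters = as.list(as.data.frame(carried)),
    planted = list(
      dup = if (spec$planted_dup)
        list(clusters = c("core01", "core02"), segment = dup_segment,
             length = spec$dup_length),
      gene = if (spec$planted_gene)
        list(cluster = "phenogene", carriers = strains[phenotype == 1L]),
      snp = if (spec$planted_snp)
        list(cluster = "snpgene", rel_pos = spec$snp_rel_pos,
             allele_positive = "T", allele_negative = "C",
             carriers = strains[phenotype == 1L])
    )
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")

  structure(list(dir = dir, csv = csv, gff_dir = dir,
                 phenotype = pheno_path, manifest = manifest,
                 strains = strains),
            class = "sim_pangenome")
}

#' Simulate a pyseer-style association table with planted effects
#'
#' Produces a tab-separated association table in the dialect of pyseer
#' (columns `variant`, `af`, `filter-pvalue`, `lrt-pvalue`, `beta`) for
#' every pattern of a generated Rtab matrix. Patterns exactly matching the
#' phenotype vector — or its complement, since a binary association is
#' symmetric in the allele labelling — receive a very small p-value;
#' every other pattern draws a uniform p-value, so at a Bonferroni
#' threshold only the planted effects are expected to be significant.
#'
#' @param patterns path to a `hashes_to_patterns.tsv` (Rtab) file, or the
#'   matrix from [read_rtab()].
#' @param phenotype data.frame with `strain` and `phenotype` columns, a
#'   path to such a TSV, or a named 0/1 vector.
#' @param path output TSV path.
#' @param seed seed for the uniform p-values.
#' @param causal_p p-value assigned to phenotype-matching patterns
#'   (default 1e-12).
#' @return the path, invisibly; the table is also returned as the
#'   attribute `"table"`.
#' @export
simulate_association_table <- function(patterns, phenotype, path,
                                       seed = 1L, causal_p = 1e-12) {
  m <- if (is.character(patterns)) read_rtab(patterns) else patterns
  if (is.character(phenotype) && length(phenotype) == 1L) {
    phenotype <- utils::read.delim(phenotype, stringsAsFactors = FALSE)
  }
  pheno <- as_phenotype(phenotype)
  missing <- setdiff(colnames(m), pheno$strain)
  if (length(missing)) {
    stop("phenotype missing for strain(s): ", paste(missing, collapse = ", "))
  }
  y <- pheno$phenotype[match(colnames(m), pheno$strain)]
  match_pos <- colSums(t(m) != y) == 0L
  match_neg <- colSums(t(m) != (1L - y)) == 0L
  causal <- match_pos | match_neg

  set.seed(seed)
  p <- stats::runif(nrow(m))
  p[causal] <- causal_p
  tab <- data.frame(
    variant = rownames(m), af = rowMeans(m),
    `filter-pvalue` = p, `lrt-pvalue` = p,
    beta = ifelse(causal, 1.5, 0), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- path
  attr(out, "table") <- tab
  invisible(out)
}
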