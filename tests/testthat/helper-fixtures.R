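# In-code fixture builders: tiny pangenomes written as GFF3+FASTA and CSV
# at test time, plus a random in-memory pangenome generator used by the
# oracle-equivalence and parallel-equivalence properties.

write_fixture_csv <- function(path, clusters, strains) {
  # clusters: named list cluster -> named list strain -> character ids
  rows <- vapply(names(clusters), function(cid) {
    cells <- vapply(strains, function(s) {
      paste(clusters[[cid]][[s]] %||% character(0), collapse = ";")
    }, "")
    paste(c(cid, cells), collapse = ",")
  }, "")
  writeLines(c(paste(c("Gene", strains), collapse = ","), rows), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_fixture_gff <- function(path, contigs, features, embed_fasta = TRUE) {
  # contigs: named character vector; features: data.frame(gene_id, contig,
  # start (0-based incl), end (0-based excl), strand)
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    lines <- c(lines, paste(f$contig, "fixture", "CDS", f$start + 1, f$end,
                            ".", f$strand, "0", paste0("ID=", f$gene_id),
                            sep = "\t"))
  }
  if (embed_fasta) {
    lines <- c(lines, "##FASTA",
               unlist(lapply(names(contigs), function(n) {
                 c(paste0(">", n), contigs[[n]])
               })))
    writeLines(lines, path)
  } else {
    writeLines(lines, path)
    fa <- sub("\\.gff$", ".fasta", path)
    writeLines(unlist(lapply(names(contigs), function(n) {
      c(paste0(">", n), contigs[[n]])
    })), fa)
  }
  path
}

# random in-memory pangenome: <= max_strains strains, <= max_clusters
# clusters, gene bodies <= 200 bp, one contig per strain, random strands,
# occasional N bases; returns everything both raw (for the oracle) and as
# files (for the pipeline)
random_pangenome <- function(max_strains = 10, max_clusters = 5,
                             with_files = FALSE, dir = NULL,
                             n_prob = 0.002) {
  n_strains <- sample(2:max_strains, 1)
  n_clusters <- sample(1:max_clusters, 1)
  strains <- sprintf("S%02d", seq_len(n_strains))
  cluster_ids <- sprintf("g%02d", seq_len(n_clusters))
  alphabet <- c("A", "C", "G", "T")
  anc <- lapply(cluster_ids, function(cid) {
    paste(sample(alphabet, sample(30:200, 1), replace = TRUE), collapse = "")
  })
  names(anc) <- cluster_ids
  contigs <- list()
  features <- list()
  clusters <- lapply(cluster_ids, function(cid) list())
  names(clusters) <- cluster_ids
  for (s in strains) {
    ctg <- ""
    counter <- 0
    feats <- list()
    for (cid in cluster_ids) {
      if (stats::runif(1) < 0.3) next  # accessory absence
      counter <- counter + 1
      gid <- sprintf("%s_%03d", s, counter)
      body <- anc[[cid]]
      # sprinkle substitutions and rare Ns
      ch <- strsplit(body, "")[[1]]
      mut <- stats::runif(length(ch)) < 0.02
      ch[mut] <- sample(alphabet, sum(mut), replace = TRUE)
      nn <- stats::runif(length(ch)) < n_prob
      ch[nn] <- "N"
      body <- paste(ch, collapse = "")
      spacer <- paste(sample(alphabet, sample(5:30, 1), replace = TRUE),
                      collapse = "")
      strand <- sample(c("+", "-"), 1)
      ins <- if (strand == "-") pankmer::revcomp(body) else body
      start <- nchar(ctg) + nchar(spacer)
      ctg <- paste0(ctg, spacer, ins)
      feats[[length(feats) + 1]] <- data.frame(
        gene_id = gid, contig = paste0(s, "_c1"), start = start,
        end = start + nchar(body), strand = strand, stringsAsFactors = FALSE)
      clusters[[cid]][[s]] <- gid
    }
    ctg <- paste0(ctg, paste(sample(alphabet, 10, replace = TRUE),
                             collapse = ""))
    contigs[[s]] <- stats::setNames(ctg, paste0(s, "_c1"))
    features[[s]] <- if (length(feats)) do.call(rbind, feats) else
      data.frame(gene_id = character(), contig = character(),
                 start = integer(), end = integer(), strand = character(),
                 stringsAsFactors = FALSE)
  }
  out <- list(strains = strains, cluster_ids = cluster_ids,
              clusters = clusters, contigs = contigs, features = features)
  if (with_files) {
    stopifnot(!is.null(dir))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$csv <- write_fixture_csv(file.path(dir, "gpa.csv"), clusters, strains)
    for (s in strains) {
      write_fixture_gff(file.path(dir, paste0(s, ".gff")),
                        contigs[[s]], features[[s]])
    }
    out$gff_dir <- dir
  }
  out
}

# run the package engine on a raw in-memory pangenome for one cluster
engine_cluster <- function(pg, cid, k, up, down) {
  seqs <- list()
  for (s in pg$strains) {
    gid <- pg$clusters[[cid]][[s]]
    if (is.null(gid)) next
    f <- pg$features[[s]]
    f <- f[f$gene_id == gid, ]
    os <- extract_oriented_sequence(
      list(contig = f$contig, start = f$start, end = f$end, strand = f$strand),
      pg$contigs[[s]], up, down)
    os$strain <- s
    seqs[[length(seqs) + 1]] <- os
  }
  extract_cluster_kmers(cid, seqs, pg$strains, k = k)
}

# genes table for the oracle, one cluster
oracle_genes <- function(pg, cid) {
  rows <- list()
  for (s in pg$strains) {
    gid <- pg$clusters[[cid]][[s]]
    if (is.null(gid)) next
    f <- pg$features[[s]]
    f <- f[f$gene_id == gid, ]
    rows[[length(rows) + 1]] <- data.frame(
      strain = s, contig_id = f$contig, start = f$start, end = f$end,
      strand = f$strand, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

sort_occ <- function(df) {
  df <- df[order(df$strain, df$contig, df$abs_start, df$kmer, df$strand), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}
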