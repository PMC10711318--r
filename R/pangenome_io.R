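#' Read a Roary/panaroo gene presence/absence matrix
#'
#' Parses the `gene_presence_absence.csv` dialect written by Roary, panaroo
#' and ggCaller: a comma-separated table with 14 fixed metadata columns
#' (starting with `Gene`) followed by one column per strain, each cell
#' holding zero or more `;`-separated gene identifiers. A lenient fallback
#' accepts any table whose strain columns directly follow a `Gene` column.
#'
#' @param path path to the CSV file.
#' @return an object of class `gene_cluster_table`: a list with
#'   \describe{
#'     \item{clusters}{character vector of cluster identifiers, in file order}
#'     \item{strains}{character vector of strain identifiers (column order)}
#'     \item{genes}{named list: `clusters -> (strains -> character vector of
#'       gene identifiers)`; strains with an empty cell are omitted}
#'     \item{presence}{integer matrix `clusters x strains`; 1 iff the strain
#'       has at least one gene identifier for the cluster}
#'   }
#' @details Duplicate cluster identifiers and duplicate strain columns are
#'   errors; an empty body yields an empty table.
#' @examples
#' csv <- tempfile(fileext = ".csv")
#' writeLines(c("Gene,A,B", "g1,A_0001,B_0007", "g2,A_0002,"), csv)
#' tab <- read_presence_absence(csv)
#' tab$presence
#' @export
read_presence_absence <- function(path) {
  if (!file.exists(path)) stop("presence/absence file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = NULL)
  hdr <- colnames(df)
  if (length(hdr) == 0L || hdr[1] != "Gene") {
    stop("malformed presence/absence header: first column must be 'Gene', got '",
         if (length(hdr)) hdr[1] else "<empty>", "'")
  }
  # Roary dialect: 14 metadata columns before the strain columns
  roary_meta <- c("Gene", "Non-unique Gene name", "Annotation", "No. isolates",
                  "No. sequences", "Avg sequences per isolate", "Genome Fragment",
                  "Order within Fragment", "Accessory Fragment",
                  "Accessory Order with Fragment", "QC", "Min group size nuc",
                  "Max group size nuc", "Avg group size nuc")
  n_meta <- if (length(hdr) >= 14L && identical(hdr[seq_len(14)], roary_meta)) 14L else 1L
  strains <- hdr[-seq_len(n_meta)]
  if (anyDuplicated(strains)) {
    stop("malformed presence/absence header: duplicated strain column '",
         strains[duplicated(strains)][1], "'")
  }
  clusters <- df[["Gene"]]
  if (anyDuplicated(clusters)) {
    stop("duplicate cluster identifier: '", clusters[duplicated(clusters)][1], "'")
  }
  cells <- as.matrix(df[, -seq_len(n_meta), drop = FALSE])
  genes <- lapply(seq_along(clusters), function(i) {
    row <- cells[i, ]
    nonempty <- which(!is.na(row) & nzchar(row))
    ids <- lapply(nonempty, function(j) strsplit(row[[j]], ";", fixed = TRUE)[[1]])
    names(ids) <- strains[nonempty]
    ids
  })
  names(genes) <- clusters
  presence <- matrix(0L, nrow = length(clusters), ncol = length(strains),
                     dimnames = list(clusters, strains))
  if (length(clusters)) presence[!is.na(cells) & nzchar(cells)] <- 1L
  structure(
    list(clusters = clusters, strains = strains, genes = genes, presence = presence),
    class = "gene_cluster_table"
  )
}

#' @export
print.gene_cluster_table <- function(x, ...) {
  cat("gene_cluster_table:", length(x$clusters), "clusters x",
      length(x$strains), "strains\n")
  invisible(x)
}

#' Index a strain annotation (GFF3 with embedded or companion FASTA)
#'
#' Reads a prokka/bakta style GFF3 file and its nucleotide sequence, either
#' embedded after a `##FASTA` line or supplied as a separate FASTA file.
#' Gene and CDS features carrying an `ID` attribute are indexed; GFF3
#' 1-based inclusive coordinates are converted to 0-based half-open
#' intervals on the forward strand.
#'
#' @param gff_path path to the GFF3 file.
#' @param fasta_path optional companion FASTA; required when the GFF3 has no
#'   embedded `##FASTA` section.
#' @param feature_types GFF3 feature types to index (default CDS and gene).
#' @return a list of class `strain_annotation` with
#'   \describe{
#'     \item{features}{data.frame with columns `gene_id`, `contig`, `start`
#'       (0-based inclusive), `end` (0-based exclusive), `strand`}
#'     \item{contigs}{named character vector of uppercased contig sequences}
#'   }
#' @export
read_annotation <- function(gff_path, fasta_path = NULL,
                            feature_types = c("CDS", "gene")) {
  if (!file.exists(gff_path)) stop("annotation file not found: ", gff_path)
  lines <- readLines(gff_path, warn = FALSE)
  fasta_at <- which(lines == "##FASTA")[1]
  gff_lines <- if (is.na(fasta_at)) lines else lines[seq_len(fasta_at - 1L)]
  tmp_gff <- tempfile(fileext = ".gff")
  on.exit(unlink(tmp_gff), add = TRUE)
  writeLines(gff_lines, tmp_gff)
  feats <- as.data.frame(rtracklayer::readGFF(
    tmp_gff, columns = c("seqid", "type", "start", "end", "strand"), tags = "ID"))

  if (!is.na(fasta_at)) {
    tmp_fa <- tempfile(fileext = ".fasta")
    on.exit(unlink(tmp_fa), add = TRUE)
    writeLines(lines[(fasta_at + 1L):length(lines)], tmp_fa)
    seqs <- Biostrings::readDNAStringSet(tmp_fa)
  } else if (!is.null(fasta_path) && file.exists(fasta_path)) {
    seqs <- Biostrings::readDNAStringSet(fasta_path)
  } else {
    stop("no sequence for ", gff_path,
         ": neither an embedded ##FASTA section nor a companion FASTA file")
  }
  contigs <- toupper(as.character(seqs))
  # FASTA headers may carry descriptions after the first word
  names(contigs) <- sub("\\s.*$", "", names(seqs))

  keep <- feats$type %in% feature_types & !is.na(feats$ID)
  feats <- feats[keep, , drop = FALSE]
  features <- data.frame(
    gene_id = as.character(feats$ID),
    contig = as.character(feats$seqid),
    start = as.integer(feats$start) - 1L,  # GFF3 1-based incl -> 0-based incl
    end = as.integer(feats$end),           # 1-based incl == 0-based excl
    strand = as.character(feats$strand),
    stringsAsFactors = FALSE
  )
  missing_ctg <- setdiff(unique(features$contig), names(contigs))
  if (length(missing_ctg)) {
    stop("features reference contigs absent from the sequence of ",
         basename(gff_path), ": ", paste(missing_ctg, collapse = ", "))
  }
  bad <- features$start < 0L | features$end <= features$start |
    features$end > nchar(contigs)[features$contig]
  if (any(bad)) {
    stop("feature with invalid coordinates in ", basename(gff_path), ": ",
         features$gene_id[bad][1])
  }
  structure(list(features = features, contigs = contigs),
            class = "strain_annotation")
}

#' @export
print.strain_annotation <- function(x, ...) {
  cat("strain_annotation:", nrow(x$features), "features on",
      length(x$contigs), "contig(s)\n")
  invisible(x)
}

#' Extract a gene sequence in gene orientation, with flanks
#'
#' Returns the nucleotide sequence of one gene instance read 5' to 3' in
#' gene orientation (reverse-complemented for `-` strand genes), optionally
#' extended by upstream and downstream flanking sequence. Flanks are
#' truncated silently at contig edges; the lengths actually obtained are
#' recorded so that relative coordinates stay exact.
#'
#' @param instance a list or one-row data.frame with `contig`, `start`
#'   (0-based inclusive), `end` (0-based exclusive) and `strand`.
#' @param contigs named character vector of contig sequences.
#' @param upstream,downstream requested flank lengths in bases (>= 0).
#' @return a list of class `oriented_sequence`: `bases` (the sequence in
#'   gene orientation: upstream flank, gene, downstream flank),
#'   `up_obtained` / `down_obtained` (flank bases actually available; the
#'   first base of the start codon sits at 0-based index `up_obtained`),
#'   plus the instance coordinates (`contig`, `start`, `end`, `strand`).
#' @examples
#' ctg <- c(ctg1 = "AAATGCCC")
#' inst <- list(contig = "ctg1", start = 2L, end = 5L, strand = "+")
#' extract_oriented_sequence(inst, ctg, upstream = 2, downstream = 1)$bases
#' @export
extract_oriented_sequence <- function(instance, contigs, upstream = 0L,
                                      downstream = 0L) {
  stopifnot(upstream >= 0L, downstream >= 0L)
  ctg <- contigs[[instance$contig]]
  len <- nchar(ctg)
  s <- instance$start
  e <- instance$end
  if (identical(instance$strand, "-")) {
    # upstream of a - strand gene lies beyond `end` on the forward strand
    u <- min(upstream, len - e)
    d <- min(downstream, s)
    bases <- revcomp(substr(ctg, s - d + 1L, e + u))
  } else {
    u <- min(upstream, s)
    d <- min(downstream, len - e)
    bases <- substr(ctg, s - u + 1L, e + d)
  }
  structure(
    list(bases = bases, up_obtained = as.integer(u), down_obtained = as.integer(d),
         contig = instance$contig, start = as.integer(s), end = as.integer(e),
         strand = instance$strand),
    class = "oriented_sequence"
  )
}
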