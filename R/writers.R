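#' Output bundle: the three TSV files consumed downstream
#'
#' `open_output_bundle()` creates the output directory, opens the three
#' tab-separated files and writes their headers; the pipeline then appends
#' one gene cluster at a time (in input order) with
#' `write_cluster_output()` and finishes with `close_output_bundle()`.
#' Writing is fully deterministic: no timestamps, fixed row ordering, so
#' repeated runs on identical input are byte-identical.
#'
#' The files are:
#' \describe{
#'   \item{kmers.tsv}{one row per k-mer occurrence in a target strain:
#'     `cluster`, `strain`, `contig`, `abs_start`, `abs_end` (0-based
#'     half-open forward-strand), `strand` ('+': the window read in gene
#'     orientation equals the canonical sequence; '-': it equals its
#'     reverse complement), `rel_start`, `rel_end` (relative to the first
#'     base of the start codon), `canonical_sequence`, `hash_id`. Rows are
#'     ordered by cluster input order, strain panel order, contig,
#'     `abs_start`, then sequence.}
#'   \item{kmers_to_hashes.tsv}{`cluster`, `canonical_sequence`, `hash_id`;
#'     one row per (cluster, canonical k-mer) pair. The same sequence may
#'     appear under several clusters with different hashes — the point of
#'     cluster-centric encoding.}
#'   \item{hashes_to_patterns.tsv}{Rtab dialect directly usable as pyseer
#'     `--rtab` input: header `pattern_id` followed by the strain names in
#'     panel order; one row per unique presence/absence pattern (first-seen
#'     order), cells 0/1.}
#' }
#'
#' @param dir output directory (created if needed).
#' @param panel ordered strain panel (Rtab column order).
#' @param compress write `.gz`-compressed files (suffix added).
#' @return an environment of class `output_bundle` carrying open
#'   connections, paths and the unique-pattern registry.
#' @export
open_output_bundle <- function(dir, panel, compress = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sfx <- if (isTRUE(compress)) ".gz" else ""
  b <- new.env(parent = emptyenv())
  b$panel <- panel
  b$paths <- c(
    kmers = file.path(dir, paste0("kmers.tsv", sfx)),
    kmers_to_hashes = file.path(dir, paste0("kmers_to_hashes.tsv", sfx)),
    hashes_to_patterns = file.path(dir, paste0("hashes_to_patterns.tsv", sfx))
  )
  b$con <- lapply(b$paths, open_out)
  b$seen <- new.env(parent = emptyenv())  # hash_id -> TRUE
  b$stats <- c(clusters = 0L, kmers = 0L, occurrences = 0L,
               patterns = 0L, filtered = 0L)
  writeLines(paste(c("cluster", "strain", "contig", "abs_start", "abs_end",
                     "strand", "rel_start", "rel_end", "canonical_sequence",
                     "hash_id"), collapse = "\t"), b$con$kmers)
  writeLines("cluster\tcanonical_sequence\thash_id", b$con$kmers_to_hashes)
  writeLines(paste(c("pattern_id", panel), collapse = "\t"),
             b$con$hashes_to_patterns)
  class(b) <- "output_bundle"
  b
}

#' Append one cluster's k-mers to an output bundle
#'
#' @param bundle an open `output_bundle`.
#' @param ck a (possibly filtered) `cluster_kmers` object.
#' @param n_filtered number of k-mers removed by the cluster-identity
#'   filter, for run statistics.
#' @return the bundle, invisibly.
#' @export
write_cluster_output <- function(bundle, ck, n_filtered = 0L) {
  hashes <- hash_pattern(ck$presence)
  names(hashes) <- ck$kmers

  occ <- ck$occurrences
  if (nrow(occ)) {
    occ <- occ[order(match(occ$strain, bundle$panel), occ$contig,
                     occ$abs_start, occ$kmer), , drop = FALSE]
    write_tsv_lines(data.frame(
      cluster = ck$cluster_id, strain = occ$strain, contig = occ$contig,
      abs_start = occ$abs_start, abs_end = occ$abs_end, strand = occ$strand,
      rel_start = occ$rel_start, rel_end = occ$rel_end,
      canonical_sequence = occ$kmer, hash_id = unname(hashes[occ$kmer]),
      stringsAsFactors = FALSE), bundle$con$kmers)
  }
  if (length(ck$kmers)) {
    write_tsv_lines(data.frame(
      cluster = ck$cluster_id, canonical_sequence = ck$kmers,
      hash_id = unname(hashes), stringsAsFactors = FALSE),
      bundle$con$kmers_to_hashes)
    new <- !duplicated(hashes) &
      !vapply(hashes, exists, NA, envir = bundle$seen)
    if (any(new)) {
      for (h in hashes[new]) assign(h, TRUE, envir = bundle$seen)
      write_tsv_lines(data.frame(
        pattern_id = unname(hashes[new]),
        as.data.frame(ck$presence[new, , drop = FALSE]),
        check.names = FALSE, stringsAsFactors = FALSE),
        bundle$con$hashes_to_patterns)
      bundle$stats["patterns"] <- bundle$stats["patterns"] + sum(new)
    }
  }
  bundle$stats["clusters"] <- bundle$stats["clusters"] + 1L
  bundle$stats["kmers"] <- bundle$stats["kmers"] + length(ck$kmers)
  bundle$stats["occurrences"] <- bundle$stats["occurrences"] + nrow(occ)
  bundle$stats["filtered"] <- bundle$stats["filtered"] + n_filtered
  invisible(bundle)
}

#' Close an output bundle
#' @param bundle an open `output_bundle`.
#' @return named list: `paths` and run `stats` (clusters, kmers,
#'   occurrences, unique patterns, filtered k-mers).
#' @export
close_output_bundle <- function(bundle) {
  for (con in bundle$con) close(con)
  list(paths = bundle$paths, stats = as.list(bundle$stats))
}

#' Read back an Rtab pattern matrix
#'
#' @param path a `hashes_to_patterns.tsv` (pyseer Rtab dialect) file.
#' @return integer matrix patterns x strains with pattern identifiers as
#'   row names.
#' @export
read_rtab <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Read back a kmers.tsv positional log
#' @param path a `kmers.tsv` file written by [generate_kmers()].
#' @return data.frame with the documented columns.
#' @export
read_kmers <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = c(cluster = "character", strain = "character",
                                   contig = "character", abs_start = "integer",
                                   abs_end = "integer", strand = "character",
                                   rel_start = "integer", rel_end = "integer",
                                   canonical_sequence = "character",
                                   hash_id = "character"))
}

#' Read back a kmers_to_hashes.tsv mapping
#' @param path a `kmers_to_hashes.tsv` file written by [generate_kmers()].
#' @return data.frame with columns `cluster`, `canonical_sequence`, `hash_id`.
#' @export
read_kmers_to_hashes <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
}
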