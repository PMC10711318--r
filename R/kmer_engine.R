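#' Canonical form of k-mers
#'
#' The canonical form of a k-mer is the lexicographically smaller of the
#' sequence and its reverse complement, which makes k-mer extraction
#' independent of the strand a gene happens to be annotated on.
#'
#' @param x character vector of same-length nucleotide strings (uppercase).
#' @return data.frame with columns `canonical` (NA for windows containing
#'   characters outside A/C/G/T, which callers must skip) and `rc` (logical:
#'   TRUE when the reverse complement was the smaller form; palindromic
#'   k-mers report FALSE).
#' @examples
#' canonical_kmers(c("ACGT", "TTT", "AAC", "ANG"))
#' @export
canonical_kmers <- function(x) {
  rc <- revcomp(x)
  is_rc <- rc < x
  canonical <- ifelse(is_rc, rc, x)
  canonical[grepl("[^ACGT]", x)] <- NA_character_
  data.frame(canonical = canonical, rc = is_rc & !is.na(canonical),
             stringsAsFactors = FALSE)
}

#' Extract cluster-centric canonical k-mers
#'
#' Scans every oriented gene sequence of one gene cluster with a sliding
#' window of length `k`, canonicalises each window, and aggregates a
#' presence/absence vector over the strain panel per distinct canonical
#' k-mer together with the positional record of every occurrence.
#' Windows containing non-ACGT characters are skipped. Presence is binary:
#' a k-mer occurring several times in one strain (or in several gene
#' copies) is present once, but every occurrence is logged.
#'
#' @param cluster_id cluster identifier.
#' @param sequences list of `oriented_sequence` objects (possibly several
#'   per strain for paralogs), each additionally tagged with `$strain`.
#' @param panel character vector: the full ordered strain panel.
#' @param k k-mer length (default 31).
#' @param targets strains for which occurrence positions are logged
#'   (default: all of `panel`; use `character(0)` to log none).
#' @return list of class `cluster_kmers`:
#'   \describe{
#'     \item{cluster_id}{the cluster identifier}
#'     \item{kmers}{character vector of distinct canonical sequences, in
#'       first-occurrence order (strains in panel order, copies in input
#'       order, windows left to right)}
#'     \item{presence}{integer matrix `kmers x panel`}
#'     \item{occurrences}{data.frame (target strains only) with columns
#'       `strain`, `contig`, `abs_start`, `abs_end` (0-based half-open,
#'       forward strand), `strand` ('+' when the window read in gene
#'       orientation equals the canonical form, '-' when it equals its
#'       reverse complement), `rel_start`, `rel_end` (offsets from the
#'       first base of the start codon; negative in the upstream flank)
#'       and `kmer`}
#'   }
#' @export
extract_cluster_kmers <- function(cluster_id, sequences, panel, k = 31L,
                                  targets = panel) {
  stopifnot(k >= 1L)
  per_copy <- vector("list", length(sequences))
  # scan strains in panel order so first-occurrence order is deterministic
  ord <- order(match(vapply(sequences, `[[`, "", "strain"), panel))
  for (idx in seq_along(ord)) {
    os <- sequences[[ord[idx]]]
    n <- nchar(os$bases)
    if (n < k) next
    i <- 0:(n - k)                         # 0-based window starts
    win <- substring(os$bases, i + 1L, i + k)
    can <- canonical_kmers(win)
    ok <- !is.na(can$canonical)
    if (!any(ok)) next
    i <- i[ok]
    rel_start <- i - os$up_obtained
    if (identical(os$strand, "-")) {
      abs_start <- os$end + os$up_obtained - i - k
    } else {
      abs_start <- os$start - os$up_obtained + i
    }
    per_copy[[ord[idx]]] <- data.frame(
      strain = os$strain, contig = os$contig,
      abs_start = abs_start, abs_end = abs_start + k,
      strand = ifelse(can$rc[ok], "-", "+"),
      rel_start = rel_start, rel_end = rel_start + k,
      kmer = can$canonical[ok],
      stringsAsFactors = FALSE
    )
  }
  occ <- do.call(rbind, per_copy[ord])
  if (is.null(occ)) {
    occ <- data.frame(strain = character(), contig = character(),
                      abs_start = integer(), abs_end = integer(),
                      strand = character(), rel_start = integer(),
                      rel_end = integer(), kmer = character(),
                      stringsAsFactors = FALSE)
  }
  kmers <- unique(occ$kmer)
  presence <- matrix(0L, nrow = length(kmers), ncol = length(panel),
                     dimnames = list(kmers, panel))
  if (nrow(occ)) {
    seen <- unique(occ[, c("kmer", "strain")])
    presence[cbind(match(seen$kmer, kmers), match(seen$strain, panel))] <- 1L
  }
  structure(
    list(cluster_id = cluster_id, kmers = kmers, presence = presence,
         occurrences = occ[occ$strain %in% targets, , drop = FALSE]),
    class = "cluster_kmers"
  )
}

#' Drop k-mers whose pattern equals the cluster's own presence pattern
#'
#' k-mers present in exactly the strains that carry the cluster add no
#' information beyond gene presence/absence itself and are filtered out by
#' default; disabling the filter (the `--no-filter` behaviour) keeps them,
#' which is required when gene presence itself may be the causal variant.
#'
#' @param ck a `cluster_kmers` object.
#' @param cluster_presence integer vector: the cluster's own
#'   presence/absence over the panel.
#' @param filter logical; when FALSE the input is returned unchanged.
#' @return a `cluster_kmers` object with matching k-mers (and their
#'   occurrences) removed.
#' @export
filter_cluster_identical <- function(ck, cluster_presence, filter = TRUE) {
  if (!isTRUE(filter) || length(ck$kmers) == 0L) return(ck)
  same <- colSums(t(ck$presence) != as.integer(cluster_presence)) == 0L
  ck$kmers <- ck$kmers[!same]
  ck$presence <- ck$presence[!same, , drop = FALSE]
  ck$occurrences <- ck$occurrences[ck$occurrences$kmer %in% ck$kmers, ,
                                   drop = FALSE]
  ck
}

#' Hash presence/absence patterns
#'
#' Computes a stable 128-bit identifier for each binary presence/absence
#' vector: the MD5 digest of the vector written as a string of `0`/`1`
#' characters in panel order. The hash is a pure function of the ordered
#' bit vector — independent of cluster, k-mer sequence, run or machine —
#' so identical patterns always collide onto one identifier and pattern
#' identifiers can be matched across runs.
#'
#' @param patterns integer matrix (rows = patterns, columns = panel) or a
#'   single vector.
#' @return character vector of 32-hexdigit identifiers, one per row.
#' @examples
#' hash_pattern(rbind(c(1, 0), c(0, 1), c(1, 0)))
#' @export
hash_pattern <- function(patterns) {
  if (is.null(dim(patterns))) patterns <- matrix(patterns, nrow = 1L)
  if (nrow(patterns) == 0L) return(character(0))
  cli::hash_md5(apply(patterns, 1L, paste0, collapse = ""))
}
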