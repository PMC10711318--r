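# Independent brute-force oracle for cluster-centric k-mer extraction.
# Deliberately written against a different code path than the package:
# Biostrings for reverse complement / canonicalisation, explicit per-window
# loops, set algebra via R lists.

oracle_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

oracle_canonical <- function(s) {
  if (grepl("[^ACGT]", s)) return(NA_character_)
  rc <- oracle_revcomp(s)
  if (rc < s) rc else s
}

# vectorised variant (still Biostrings-based, not the package's code path)
oracle_canonical_vec <- function(ws) {
  if (length(ws) == 0L) return(character(0))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(ws)))
  out <- ifelse(rc < ws, rc, ws)
  out[grepl("[^ACGT]", ws)] <- NA_character_
  out
}

# one oriented sequence by naive slicing of the raw contig
oracle_oriented <- function(contig, start, end, strand, up, down) {
  n <- nchar(contig)
  if (strand == "-") {
    u <- min(up, n - end)
    d <- min(down, start)
    bases <- oracle_revcomp(substr(contig, start - d + 1, end + u))
  } else {
    u <- min(up, start)
    d <- min(down, n - end)
    bases <- substr(contig, start - u + 1, end + d)
  }
  list(bases = bases, u = u, d = d)
}

# full per-cluster enumeration: every window of every gene copy; returns
# occurrences and the per-kmer strain sets
# genes: data.frame(strain, contig_id, start, end, strand); contigs: named
# list (per strain) of named character vectors
oracle_cluster <- function(genes, contigs, panel, k, up, down) {
  occ <- list()
  strain_sets <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ctg <- contigs[[g$strain]][[g$contig_id]]
    os <- oracle_oriented(ctg, g$start, g$end, g$strand, up, down)
    n <- nchar(os$bases)
    if (n < k) next
    win <- vapply(0:(n - k), function(j) substr(os$bases, j + 1, j + k), "")
    can <- oracle_canonical_vec(win)
    js <- (0:(n - k))[!is.na(can)]
    win <- win[!is.na(can)]
    can <- can[!is.na(can)]
    if (!length(js)) next
    abs_start <- integer(length(js))
    for (idx in seq_along(js)) {
      abs_start[idx] <- if (g$strand == "-") g$end + os$u - js[idx] - k
                        else g$start - os$u + js[idx]
      strain_sets[[can[idx]]] <- union(strain_sets[[can[idx]]], g$strain)
    }
    occ[[length(occ) + 1]] <- data.frame(
      strain = g$strain, contig = g$contig_id,
      abs_start = abs_start, abs_end = abs_start + k,
      strand = ifelse(win == can, "+", "-"),
      rel_start = js - os$u, rel_end = js - os$u + k,
      kmer = can, stringsAsFactors = FALSE)
  }
  occ <- if (length(occ)) do.call(rbind, occ) else
    data.frame(strain = character(), contig = character(),
               abs_start = integer(), abs_end = integer(),
               strand = character(), rel_start = integer(),
               rel_end = integer(), kmer = character(),
               stringsAsFactors = FALSE)
  presence <- t(vapply(strain_sets, function(s) as.integer(panel %in% s),
                       integer(length(panel))))
  if (length(strain_sets) == 0L) {
    presence <- matrix(integer(0), 0, length(panel))
  }
  colnames(presence) <- panel
  list(occurrences = occ, presence = presence)
}

# duplication summary by plain set algebra over cluster -> kmer-set lists
oracle_dup <- function(cluster_kmer_sets) {
  sets <- lapply(cluster_kmer_sets, unique)
  all_kmers <- unique(unlist(sets, use.names = FALSE))
  in_n <- vapply(all_kmers, function(km) {
    sum(vapply(sets, function(s) km %in% s, NA))
  }, 0L)
  multi <- all_kmers[in_n >= 2L]
  with_multi <- sum(vapply(sets, function(s) any(multi %in% s), NA))
  list(
    n_unique = length(all_kmers),
    n_multi = length(multi),
    prop_multi = if (length(all_kmers)) length(multi) / length(all_kmers) else 0,
    n_clusters_with_multi = with_multi
  )
}
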