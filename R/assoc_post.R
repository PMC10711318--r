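#' Bonferroni threshold on uniquely tested patterns
#'
#' Family-wise error control for pattern-level association testing: the
#' per-pattern significance threshold is `alpha / n_patterns`, where
#' `n_patterns` is the number of unique presence/absence patterns actually
#' tested (the rows of `hashes_to_patterns.tsv`), not the number of k-mers.
#'
#' @param n_patterns number of uniquely tested patterns (>= 1).
#' @param alpha family-wise error rate (default 0.05).
#' @return list of class `bonferroni_threshold`: `alpha`, `n_patterns`,
#'   `value` (= alpha / n_patterns).
#' @examples
#' bonferroni_threshold(2e6)$value  # 2.5e-08
#' @export
bonferroni_threshold <- function(n_patterns, alpha = 0.05) {
  n_patterns <- as.numeric(n_patterns)
  if (length(n_patterns) != 1L || is.na(n_patterns) || n_patterns < 1) {
    stop("n_patterns must be a single number >= 1")
  }
  structure(list(alpha = alpha, n_patterns = n_patterns,
                 value = alpha / n_patterns),
            class = "bonferroni_threshold")
}

#' @export
print.bonferroni_threshold <- function(x, ...) {
  cat("Bonferroni threshold:", format(x$value), "(alpha =", x$alpha, "/",
      format(x$n_patterns, big.mark = ","), "patterns)\n")
  invisible(x)
}

#' Read a pyseer association results table
#'
#' @param path tab-separated association output; must contain a variant
#'   identifier column and a p-value column.
#' @param variant_col name of the identifier column (default `variant`).
#' @param p_col name of the p-value column (default `lrt-pvalue`, pyseer's
#'   likelihood-ratio test p-value).
#' @return data.frame with columns `hash_id` and `p_value` (other columns
#'   retained).
#' @export
read_associations <- function(path, variant_col = "variant",
                              p_col = "lrt-pvalue") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c(variant_col, p_col)) {
    if (!col %in% colnames(df)) {
      stop("association table lacks column '", col, "' (have: ",
           paste(colnames(df), collapse = ", "), ")")
    }
  }
  df$hash_id <- as.character(df[[variant_col]])
  df$p_value <- as.numeric(df[[p_col]])
  df
}

#' Map association results back to clusters and k-mers
#'
#' Joins pattern-level association p-values to the (cluster, k-mer) pairs
#' carrying each pattern, flags significance against a Bonferroni
#' threshold, and summarises per cluster. This is the step that turns an
#' anonymous significant pattern into "this k-mer of this gene cluster".
#'
#' @param assoc data.frame from [read_associations()] (or any data.frame
#'   with `hash_id` and `p_value` columns).
#' @param kmers_to_hashes path to `kmers_to_hashes.tsv` or its data.frame.
#' @param threshold a `bonferroni_threshold`, or a bare numeric cutoff.
#' @return list of class `association_annotation`:
#'   \describe{
#'     \item{records}{per tested pattern: `hash_id`, `p_value`,
#'       `significant` (strict `p < threshold`), `n_clusters`, `clusters`
#'       (comma-joined)}
#'     \item{kmer_table}{per (cluster, k-mer): columns of the mapping plus
#'       `p_value` and `significant`}
#'     \item{cluster_summary}{per cluster: `min_p`, `n_kmers`,
#'       `n_significant_kmers`}
#'     \item{unmatched}{hash identifiers in the association table with no
#'       known k-mer (reported, not fatal — unless none match at all, which
#'       is a hard error suggesting mispaired inputs)}
#'     \item{threshold}{the numeric cutoff used}
#'   }
#' @export
annotate_associations <- function(assoc, kmers_to_hashes, threshold) {
  thr <- if (inherits(threshold, "bonferroni_threshold")) threshold$value
         else as.numeric(threshold)
  k2h <- if (is.character(kmers_to_hashes)) {
    read_kmers_to_hashes(kmers_to_hashes)
  } else {
    kmers_to_hashes
  }
  if (nrow(assoc) == 0L) {
    warning("empty association table")
    empty_sum <- data.frame(cluster = character(), min_p = numeric(),
                            n_kmers = integer(), n_significant_kmers = integer(),
                            stringsAsFactors = FALSE)
    return(structure(list(records = data.frame(), kmer_table = data.frame(),
                          cluster_summary = empty_sum,
                          unmatched = character(), threshold = thr),
                     class = "association_annotation"))
  }
  known <- assoc$hash_id %in% k2h$hash_id
  if (!any(known)) {
    stop("none of the ", nrow(assoc), " association identifiers match a ",
         "known pattern hash; are the association table and the ",
         "kmers_to_hashes file from the same run?")
  }
  unmatched <- unique(assoc$hash_id[!known])

  m <- match(k2h$hash_id, assoc$hash_id)
  kmer_table <- k2h[!is.na(m), , drop = FALSE]
  kmer_table$p_value <- assoc$p_value[m[!is.na(m)]]
  kmer_table$significant <- kmer_table$p_value < thr
  kmer_table <- kmer_table[order(kmer_table$p_value, kmer_table$cluster,
                                 kmer_table$canonical_sequence), , drop = FALSE]
  rownames(kmer_table) <- NULL

  rec <- assoc[known, c("hash_id", "p_value"), drop = FALSE]
  rec <- rec[!duplicated(rec$hash_id), , drop = FALSE]
  rec$significant <- rec$p_value < thr
  cl_per_hash <- split(k2h$cluster, k2h$hash_id)
  cls <- lapply(rec$hash_id, function(h) sort(unique(cl_per_hash[[h]])))
  rec$n_clusters <- lengths(cls)
  rec$clusters <- vapply(cls, paste, "", collapse = ",")
  rec <- rec[order(rec$p_value, rec$hash_id), , drop = FALSE]
  rownames(rec) <- NULL

  agg <- split(kmer_table, kmer_table$cluster)
  cluster_summary <- do.call(rbind, lapply(names(agg), function(cl) {
    d <- agg[[cl]]
    data.frame(cluster = cl, min_p = min(d$p_value), n_kmers = nrow(d),
               n_significant_kmers = sum(d$significant),
               stringsAsFactors = FALSE)
  })) %||% data.frame(cluster = character(), min_p = numeric(),
                      n_kmers = integer(), n_significant_kmers = integer())
  cluster_summary <- cluster_summary[order(cluster_summary$min_p,
                                           cluster_summary$cluster), ,
                                     drop = FALSE]
  rownames(cluster_summary) <- NULL

  structure(list(records = rec, kmer_table = kmer_table,
                 cluster_summary = cluster_summary, unmatched = unmatched,
                 threshold = thr),
            class = "association_annotation")
}

#' @export
print.association_annotation <- function(x, ...) {
  cat("association_annotation:", nrow(x$records), "patterns,",
      sum(x$records$significant %||% FALSE), "significant at",
      format(x$threshold), "\n")
  invisible(x)
}

#' Clusters to log positions for in a second pass
#'
#' Deduplicated, sorted list of gene clusters containing at least one
#' significantly associated k-mer — the input for the `genes` option of a
#' second, position-logging pass.
#'
#' @param annotation an `association_annotation`.
#' @return character vector of cluster identifiers (possibly empty),
#'   sorted for run-to-run stability.
#' @export
select_second_pass_genes <- function(annotation) {
  s <- annotation$cluster_summary
  sort(unique(s$cluster[s$n_significant_kmers >= 1L]))
}

#' Run the position-logging second pass of the two-pass workflow
#'
#' First pass: [generate_kmers()] with `targets = character(0)` emits the
#' full pattern matrix but an empty positional log (small and fast, enough
#' for the association test). After association and
#' [select_second_pass_genes()], this second pass re-runs the generator
#' restricted to the significant clusters, logging positions only for
#' them. Pattern hashes are computed the same way, so they coincide with
#' the first-pass hashes for the same (cluster, k-mer) pairs.
#'
#' @inheritParams generate_kmers
#' @param genes nonempty cluster subset (from [select_second_pass_genes()]).
#' @return a `pankmer_run` (see [generate_kmers()]).
#' @export
run_second_pass <- function(presence_absence, gff, output_dir, genes,
                            k = 31L, upstream = 0L, downstream = 0L,
                            filter = TRUE, targets = NULL, cores = 1L,
                            compress = FALSE, verbose = FALSE) {
  if (length(genes) == 0L) stop("second pass needs a nonempty cluster subset")
  generate_kmers(presence_absence, gff, output_dir, k = k,
                 upstream = upstream, downstream = downstream,
                 filter = filter, targets = targets, genes = genes,
                 cores = cores, compress = compress, verbose = verbose)
}
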