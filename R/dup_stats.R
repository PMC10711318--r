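#' Summarise k-mer duplication across gene clusters
#'
#' A "multicluster" k-mer is a canonical sequence occurring in two or more
#' distinct gene clusters of the same pangenome. Such k-mers are the ones a
#' global de Bruijn graph would collapse onto a single presence/absence
#' pattern, potentially implicating unrelated clusters in an association;
#' this summary quantifies how common they are. Counts are over distinct
#' canonical sequences pangenome-wide; a sequence occurring several times
#' within one cluster counts that cluster once.
#'
#' Run the generator with `filter = FALSE` first, so that k-mers matching
#' their cluster's own pattern are present in the mapping file.
#'
#' @param kmers_to_hashes path to a `kmers_to_hashes.tsv` file or the
#'   corresponding data.frame (columns `cluster`, `canonical_sequence`).
#' @param n_clusters total clusters in the pangenome; defaults to the
#'   number of distinct clusters in the mapping (clusters that yielded no
#'   k-mers at all are invisible there, so pass the true count if known).
#' @return one-row data.frame of class `duplication_summary` with columns
#'   `n_unique_kmers`, `n_multicluster_kmers`, `prop_multicluster`,
#'   `n_clusters`, `n_clusters_with_multi`, `prop_clusters_with_multi`
#'   (proportions are 0 for empty input).
#' @examples
#' df <- data.frame(cluster = c("g1", "g1", "g2", "g2"),
#'                  canonical_sequence = c("AAA", "AAC", "AAA", "ACA"))
#' duplication_summary(df)
#' @export
duplication_summary <- function(kmers_to_hashes, n_clusters = NULL) {
  df <- if (is.character(kmers_to_hashes)) {
    read_kmers_to_hashes(kmers_to_hashes)
  } else {
    kmers_to_hashes
  }
  pairs <- unique(df[, c("cluster", "canonical_sequence")])
  n_clusters <- as.integer(n_clusters %||% length(unique(pairs$cluster)))
  n_unique <- length(unique(pairs$canonical_sequence))
  per_kmer <- table(pairs$canonical_sequence)
  multi <- names(per_kmer)[per_kmer >= 2L]
  with_multi <- unique(pairs$cluster[pairs$canonical_sequence %in% multi])
  res <- data.frame(
    n_unique_kmers = n_unique,
    n_multicluster_kmers = length(multi),
    prop_multicluster = if (n_unique) length(multi) / n_unique else 0,
    n_clusters = n_clusters,
    n_clusters_with_multi = length(with_multi),
    prop_clusters_with_multi = if (n_clusters) length(with_multi) / n_clusters else 0
  )
  class(res) <- c("duplication_summary", class(res))
  res
}

#' Plot duplication summaries across pangenomes
#'
#' Two-panel figure: per pangenome, the proportion of multicluster k-mers
#' among unique k-mers, and the proportion of gene clusters containing at
#' least one multicluster k-mer. Axes are bounded to `[0, 1]`.
#'
#' @param summaries a list of `duplication_summary` objects (or a single
#'   one).
#' @param labels pangenome labels, one per summary.
#' @param path optional output file (`.png`, `.svg` or `.pdf`); when NULL
#'   the ggplot object is returned without saving.
#' @return the ggplot object, invisibly when saved.
#' @export
plot_duplication <- function(summaries, labels = NULL, path = NULL) {
  if (inherits(summaries, "duplication_summary")) summaries <- list(summaries)
  labels <- labels %||% paste0("pangenome_", seq_along(summaries))
  stopifnot(length(labels) == length(summaries))
  df <- do.call(rbind, lapply(seq_along(summaries), function(i) {
    s <- summaries[[i]]
    data.frame(
      pangenome = labels[i],
      panel = c("multicluster k-mers / unique k-mers",
                "clusters with a multicluster k-mer / clusters"),
      proportion = c(s$prop_multicluster, s$prop_clusters_with_multi),
      stringsAsFactors = FALSE
    )
  }))
  df$pangenome <- factor(df$pangenome, levels = labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pangenome,
                                        y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~panel, ncol = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "proportion") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(path)) {
    save_figure(p, path, width = max(4, 0.5 * length(labels) + 2), height = 5)
    return(invisible(p))
  }
  p
}

# suffix-driven figure writer (png via cairo, svg, pdf)
save_figure <- function(p, path, width = 7, height = 5) {
  ext <- tolower(tools::file_ext(path))
  dev <- switch(ext, png = grDevices::png, svg = grDevices::svg,
                pdf = grDevices::pdf,
                stop("unsupported figure format: .", ext))
  if (ext == "png") {
    dev(path, width = width, height = height, units = "in", res = 150)
  } else {
    dev(path, width = width, height = height)
  }
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}
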