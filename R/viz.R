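#' Per-base association values for one cluster's heatmap
#'
#' Projects pattern-level association p-values onto the base-resolution
#' positional log of one gene cluster: for every isolate and every
#' relative position covered by at least one logged k-mer, the cell takes
#' the minimum p-value over the covering k-mers. Cells covered only by
#' non-significant k-mers are "covered"; positions inside the plotted
#' range but not covered for an isolate (shorter gene, filtered k-mers)
#' are "uncovered"; isolates without any logged k-mer for the cluster
#' (e.g. not encoding the gene) are "absent" across the whole range.
#'
#' @param kmers data.frame in `kmers.tsv` layout (see [read_kmers()]),
#'   already restricted to one cluster, or a path plus `cluster`.
#' @param annotation an `association_annotation` (or data.frame with
#'   `hash_id`, `p_value`).
#' @param phenotype data.frame with columns `strain` and `phenotype`
#'   (binary), or a named 0/1 vector; defines the isolates plotted and the
#'   panel order within phenotype groups.
#' @param cluster cluster identifier (required when `kmers` is a path or
#'   contains several clusters).
#' @param threshold significance cutoff; defaults to the annotation's.
#' @param cap upper bound for `-log10(p)`; p-values below `10^-cap` all
#'   map to the top of the colour scale (default 10).
#' @return data.frame with columns `strain`, `phenotype`, `pos` (relative
#'   position), `status` (significant / covered / uncovered / absent) and
#'   `neglog10p` (clipped to `[-log10(threshold), cap]`; NA unless
#'   significant).
#' @export
heatmap_data <- function(kmers, annotation, phenotype, cluster = NULL,
                         threshold = NULL, cap = 10) {
  if (is.character(kmers) && length(kmers) == 1L) kmers <- read_kmers(kmers)
  if (!is.null(cluster)) kmers <- kmers[kmers$cluster == cluster, , drop = FALSE]
  if (length(unique(kmers$cluster)) > 1L) {
    stop("kmers span several clusters; pass `cluster`")
  }
  if (nrow(kmers) == 0L) {
    stop("no logged positions for cluster '", cluster %||% "?",
         "'; re-run the generator with this cluster in `genes` ",
         "(second pass) and the isolates of interest as targets")
  }
  pheno <- as_phenotype(phenotype)
  thr <- threshold %||%
    (if (inherits(annotation, "association_annotation")) annotation$threshold
     else stop("no threshold available; pass `threshold`"))
  pmap <- assoc_pmap(annotation)

  kmers <- kmers[kmers$strain %in% pheno$strain, , drop = FALSE]
  kmers$p_value <- unname(pmap[kmers$hash_id])
  rng <- c(min(kmers$rel_start), max(kmers$rel_end))
  pos <- rng[1]:(rng[2] - 1L)

  cells <- lapply(pheno$strain, function(s) {
    d <- kmers[kmers$strain == s, , drop = FALSE]
    if (nrow(d) == 0L) {
      return(data.frame(strain = s, pos = pos, status = "absent",
                        neglog10p = NA_real_, stringsAsFactors = FALSE))
    }
    k <- d$rel_end[1] - d$rel_start[1]
    cell_pos <- rep(d$rel_start, each = k) + 0:(k - 1L)
    cell_p <- rep(d$p_value, each = k)
    best <- vapply(split(cell_p, cell_pos),
                   function(p) if (all(is.na(p))) NA_real_ else min(p, na.rm = TRUE),
                   0)
    covered <- as.integer(names(best))
    status <- rep("uncovered", length(pos))
    nlp <- rep(NA_real_, length(pos))
    at <- match(covered, pos)
    sig <- !is.na(best) & best < thr
    status[at] <- ifelse(sig, "significant", "covered")
    nlp[at][sig] <- pmin(pmax(-log10(best[sig]), -log10(thr)), cap)
    data.frame(strain = s, pos = pos, status = status, neglog10p = nlp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, cells)
  out$phenotype <- pheno$phenotype[match(out$strain, pheno$strain)]
  out[, c("strain", "phenotype", "pos", "status", "neglog10p")]
}

#' Association heatmap for one gene cluster
#'
#' Isolate-by-position heatmap of a cluster's significant k-mers:
#' rows are isolates (phenotype-positive group on top, then panel order),
#' the x-axis is the position relative to the gene start codon (negative
#' = upstream/promoter), and cells are coloured by `-log10(p)` of the best
#' covering k-mer, from the significance threshold up to `10^-cap`.
#' Non-significant covered bases are light grey, bases not covered for an
#' isolate — or isolates not encoding the gene — dark grey. A vertical
#' line marks the annotated gene start, a horizontal line separates the
#' phenotype groups.
#'
#' @inheritParams heatmap_data
#' @param path optional output file (`.png`, `.svg`, `.pdf`).
#' @param max_isolates cap on figure rows; larger panels are drawn but a
#'   warning notes the squeeze.
#' @return the ggplot object (invisibly when saved).
#' @export
cluster_heatmap <- function(kmers, annotation, phenotype, cluster = NULL,
                            threshold = NULL, cap = 10, path = NULL,
                            max_isolates = 500L) {
  thr <- threshold %||%
    (if (inherits(annotation, "association_annotation")) annotation$threshold
     else stop("no threshold available; pass `threshold`"))
  df <- heatmap_data(kmers, annotation, phenotype, cluster = cluster,
                     threshold = thr, cap = cap)
  pheno <- as_phenotype(phenotype)
  # phenotype-positive group on top, panel order within groups
  row_order <- pheno$strain[order(-pheno$phenotype, seq_len(nrow(pheno)))]
  df$strain <- factor(df$strain, levels = rev(row_order))
  n_top <- sum(pheno$phenotype == 1)
  if (nrow(pheno) > max_isolates) {
    warning("plotting ", nrow(pheno), " isolates; rows will be thin")
  }

  grey <- df[df$status %in% c("uncovered", "absent"), , drop = FALSE]
  light <- df[df$status == "covered", , drop = FALSE]
  sig <- df[df$status == "significant", , drop = FALSE]
  p <- ggplot2::ggplot(mapping = ggplot2::aes(x = .data$pos + 0.5,
                                              y = .data$strain)) +
    ggplot2::geom_tile(data = grey, fill = "grey35") +
    ggplot2::geom_tile(data = light, fill = "grey85") +
    ggplot2::geom_tile(data = sig, ggplot2::aes(fill = .data$neglog10p)) +
    ggplot2::scale_fill_gradient(
      name = expression(-log[10](italic(p))),
      low = "#ffe08a", high = "#b2182b",
      limits = c(-log10(thr), cap), oob = scales_squish) +
    ggplot2::geom_vline(xintercept = 0, colour = "black", linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = nrow(pheno) - n_top + 0.5,
                        colour = "black", linewidth = 0.6) +
    ggplot2::labs(x = "position relative to start codon", y = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
  if (!is.null(path)) {
    save_figure(p, path, width = 8,
                height = max(2, min(0.25 * nrow(pheno) + 1.5, 12)))
    return(invisible(p))
  }
  p
}

#' Nucleotide sequence panel around a position of interest
#'
#' Reconstructs, from the positional k-mer log alone, the nucleotide each
#' isolate carries at every relative position in a window, and draws a
#' letter panel (one fixed colour per base) aligned on the start-codon
#' coordinate. Isolates whose logged k-mers do not reach a position show a
#' grey gap there; an optional highlighted position is boxed.
#'
#' @inheritParams heatmap_data
#' @param window integer length-2 vector: relative positions
#'   `[from, to)` to display.
#' @param highlight optional relative position to box (e.g. a SNP at -7).
#' @param phenotype optional; orders rows as in [cluster_heatmap()].
#' @param path optional output file.
#' @return the ggplot object (invisibly when saved).
#' @export
sequence_panel <- function(kmers, window, cluster = NULL, highlight = NULL,
                           phenotype = NULL, path = NULL) {
  if (is.character(kmers) && length(kmers) == 1L) kmers <- read_kmers(kmers)
  if (!is.null(cluster)) kmers <- kmers[kmers$cluster == cluster, , drop = FALSE]
  stopifnot(length(window) == 2L, window[2] > window[1])
  bases <- kmer_bases(kmers)
  bases <- bases[bases$pos >= window[1] & bases$pos < window[2], , drop = FALSE]
  if (nrow(bases) == 0L) {
    stop("no logged sequence inside the window [", window[1], ", ",
         window[2], ")")
  }
  if (!is.null(phenotype)) {
    pheno <- as_phenotype(phenotype)
    lv <- rev(pheno$strain[order(-pheno$phenotype, seq_len(nrow(pheno)))])
    bases$strain <- factor(bases$strain, levels = lv)
  }
  base_cols <- c(A = "#33a02c", C = "#1f78b4", G = "#ff7f00", T = "#e31a1c",
                 N = "grey60")
  p <- ggplot2::ggplot(bases, ggplot2::aes(x = .data$pos + 0.5,
                                           y = .data$strain)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$base), colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$base), size = 2.5) +
    ggplot2::scale_fill_manual(values = base_cols, na.value = "grey60") +
    ggplot2::labs(x = "position relative to start codon", y = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(panel.grid = ggplot2::element_blank(),
                   legend.position = "none")
  if (!is.null(highlight)) {
    p <- p + ggplot2::annotate(
      "rect", xmin = highlight, xmax = highlight + 1,
      ymin = 0.5, ymax = length(unique(bases$strain)) + 0.5,
      colour = "red", fill = NA, linewidth = 0.8)
  }
  if (!is.null(path)) {
    save_figure(p, path, width = max(4, 0.25 * diff(window) + 2),
                height = max(2, 0.25 * length(unique(bases$strain)) + 1))
    return(invisible(p))
  }
  p
}

# per-(strain, relative position) nucleotide from the positional log;
# strand '+' rows carry the canonical sequence as read in gene orientation,
# '-' rows its reverse complement
kmer_bases <- function(kmers) {
  if (nrow(kmers) == 0L) {
    return(data.frame(strain = character(), pos = integer(),
                      base = character(), stringsAsFactors = FALSE))
  }
  w <- ifelse(kmers$strand == "+", kmers$canonical_sequence,
              revcomp(kmers$canonical_sequence))
  k <- nchar(w[1])
  df <- data.frame(
    strain = rep(kmers$strain, each = k),
    pos = rep(kmers$rel_start, each = k) + 0:(k - 1L),
    base = unlist(strsplit(w, "", fixed = TRUE), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  unique(df[, c("strain", "pos", "base")])
}

# hash_id -> p-value lookup from an annotation or a bare data.frame
assoc_pmap <- function(annotation) {
  df <- if (inherits(annotation, "association_annotation")) annotation$records
        else annotation
  stats::setNames(as.numeric(df$p_value), df$hash_id)
}

as_phenotype <- function(phenotype) {
  if (is.data.frame(phenotype)) {
    stopifnot(all(c("strain", "phenotype") %in% colnames(phenotype)))
    data.frame(strain = as.character(phenotype$strain),
               phenotype = as.integer(phenotype$phenotype),
               stringsAsFactors = FALSE)
  } else {
    data.frame(strain = names(phenotype),
               phenotype = as.integer(phenotype),
               stringsAsFactors = FALSE)
  }
}

# minimal squish (avoid a scales dependency beyond ggplot2's own)
scales_squish <- function(x, range = c(0, 1), only.finite = TRUE) {
  force <- if (only.finite) is.finite(x) else !is.na(x)
  x[force & x < range[1]] <- range[1]
  x[force & x > range[2]] <- range[2]
  x
}
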