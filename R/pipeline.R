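#' Generate gene-cluster-centric k-mers for a strain panel
#'
#' The main pipeline: iterates over the gene presence/absence matrix, pulls
#' every cluster's gene sequences (with optional flanks) from the per-strain
#' annotations, extracts canonical k-mers with base-resolution coordinates,
#' hashes the unique presence/absence patterns, and streams the three
#' output files (`kmers.tsv`, `kmers_to_hashes.tsv`,
#' `hashes_to_patterns.tsv`; see [open_output_bundle()] for the layouts).
#' `hashes_to_patterns.tsv` is directly usable as pyseer `--rtab` input.
#'
#' With `cores >= 3` the per-cluster work is spread over `cores - 2` forked
#' workers (mirroring a reader / workers / writer split); clusters are
#' processed in chunks and always written in input order, so serial and
#' parallel runs produce byte-identical files. `targets = character(0)`
#' gives the low-footprint first pass of the two-pass workflow: patterns
#' are complete but no positions are logged.
#'
#' @param presence_absence path to a `gene_presence_absence.csv` or a
#'   `gene_cluster_table` from [read_presence_absence()].
#' @param gff either a directory containing `<strain>.gff` (or `.gff3`)
#'   files for every strain in the panel, or a named character vector of
#'   annotation paths keyed by strain.
#' @param output_dir where the three TSV files are written.
#' @param k k-mer length (default 31).
#' @param upstream,downstream flank lengths in bases added 5' and 3' of the
#'   gene in gene orientation (default 0); truncated at contig edges.
#' @param filter drop k-mers whose presence/absence pattern equals their
#'   cluster's own pattern (default TRUE; FALSE is the `--no-filter`
#'   behaviour needed when gene presence itself may be causal).
#' @param targets strains whose k-mer positions are logged to `kmers.tsv`
#'   (default NULL = all panel strains; `character(0)` = none).
#' @param genes optional cluster subset to process (the `--genes` second
#'   pass); unknown identifiers are an error.
#' @param cores total cores; `cores - 2` workers are used when `cores >= 3`,
#'   otherwise the run is serial.
#' @param compress write gzip-compressed outputs.
#' @param chunk_size clusters processed (and held in memory) per scheduling
#'   chunk; bounds the writer's in-flight data.
#' @param verbose log progress to stderr.
#' @return list of class `pankmer_run`: `paths` to the three files, `stats`
#'   (clusters, kmer records, occurrences, unique patterns, filtered
#'   k-mers), `panel`, `targets`, and `missing_ids` (gene identifiers from
#'   the matrix that had no annotation feature; also raised as a warning).
#' @examples
#' \dontrun{
#' run <- generate_kmers("gene_presence_absence.csv", "gffs/", "out/",
#'                       k = 31, upstream = 100)
#' run$stats$patterns
#' }
#' @export
generate_kmers <- function(presence_absence, gff, output_dir, k = 31L,
                           upstream = 0L, downstream = 0L, filter = TRUE,
                           targets = NULL, genes = NULL, cores = 1L,
                           compress = FALSE, chunk_size = 64L,
                           verbose = FALSE) {
  stopifnot(k >= 1L, upstream >= 0L, downstream >= 0L, cores >= 1L)
  tab <- if (inherits(presence_absence, "gene_cluster_table")) presence_absence
         else read_presence_absence(presence_absence)
  panel <- tab$strains
  gff_paths <- resolve_gff_paths(gff, panel)

  targets <- if (is.null(targets)) panel else as.character(targets)
  bad_t <- setdiff(targets, panel)
  if (length(bad_t)) {
    stop("target strains not in the panel: ", paste(bad_t, collapse = ", "))
  }
  cluster_ids <- tab$clusters
  if (!is.null(genes)) {
    bad_g <- setdiff(genes, cluster_ids)
    if (length(bad_g)) {
      stop("gene clusters not in the presence/absence table: ",
           paste(bad_g, collapse = ", "))
    }
    cluster_ids <- cluster_ids[cluster_ids %in% genes]
  }

  # fail on unwritable output before any heavy computation
  bundle <- open_output_bundle(output_dir, panel, compress = compress)

  pk_log("indexing ", length(panel), " annotation(s)", verbose = verbose)
  ann <- lapply(gff_paths, read_annotation)

  workers <- if (cores >= 3L) cores - 2L else 1L
  process_one <- function(cid) {
    seqs <- list()
    missing <- character(0)
    for (strain in intersect(names(tab$genes[[cid]]), panel)) {
      feats <- ann[[strain]]$features
      ids <- tab$genes[[cid]][[strain]]
      hit <- match(ids, feats$gene_id)
      if (anyNA(hit)) {
        missing <- c(missing, paste0(strain, ":", ids[is.na(hit)]))
        hit <- hit[!is.na(hit)]
      }
      if (!length(hit)) next
      # paralogous copies in genomic-coordinate order
      hit <- hit[order(feats$contig[hit], feats$start[hit])]
      for (j in hit) {
        os <- extract_oriented_sequence(feats[j, ], ann[[strain]]$contigs,
                                        upstream, downstream)
        os$strain <- strain
        seqs[[length(seqs) + 1L]] <- os
      }
    }
    ck <- extract_cluster_kmers(cid, seqs, panel, k = k, targets = targets)
    cl_presence <- as.integer(panel %in%
                                vapply(seqs, `[[`, "", "strain"))
    n_before <- length(ck$kmers)
    ck <- filter_cluster_identical(ck, cl_presence, filter = filter)
    list(ck = ck, n_filtered = n_before - length(ck$kmers), missing = missing)
  }

  all_missing <- character(0)
  idx_chunks <- split(cluster_ids,
                      ceiling(seq_along(cluster_ids) / max(1L, chunk_size)))
  for (chunk in idx_chunks) {
    res <- if (workers > 1L) {
      parallel::mclapply(chunk, process_one, mc.cores = workers)
    } else {
      lapply(chunk, process_one)
    }
    for (r in res) {
      if (inherits(r, "try-error") || is.null(r$ck)) {
        close_output_bundle(bundle)
        stop("worker failed: ", attr(r, "condition")$message %||% "unknown error")
      }
      write_cluster_output(bundle, r$ck, r$n_filtered)
      all_missing <- c(all_missing, r$missing)
    }
  }
  out <- close_output_bundle(bundle)
  if (length(all_missing)) {
    warning("gene identifiers in the presence/absence matrix without an ",
            "annotation feature (treated as absent): ",
            paste(unique(all_missing), collapse = ", "))
  }
  pk_log("done: ", out$stats$clusters, " clusters, ", out$stats$kmers,
         " k-mer records, ", out$stats$patterns, " unique patterns, ",
         out$stats$filtered, " filtered", verbose = verbose)
  structure(
    list(paths = out$paths, stats = out$stats, panel = panel,
         targets = targets, missing_ids = unique(all_missing)),
    class = "pankmer_run"
  )
}

#' @export
print.pankmer_run <- function(x, ...) {
  cat("pankmer run:", x$stats$clusters, "clusters,", x$stats$kmers,
      "k-mer records,", x$stats$patterns, "unique patterns,",
      x$stats$filtered, "filtered\n")
  invisible(x)
}

# map strains to annotation files; hard error listing strains with none
resolve_gff_paths <- function(gff, panel) {
  if (length(gff) == 1L && is.null(names(gff)) && dir.exists(gff)) {
    cand <- vapply(panel, function(s) {
      for (ext in c(".gff", ".gff3")) {
        p <- file.path(gff, paste0(s, ext))
        if (file.exists(p)) return(p)
      }
      NA_character_
    }, "")
    if (anyNA(cand)) {
      stop("no annotation file for strain(s): ",
           paste(panel[is.na(cand)], collapse = ", "), " in ", gff)
    }
    return(cand)
  }
  missing <- setdiff(panel, names(gff))
  if (length(missing)) {
    stop("no annotation file for strain(s): ", paste(missing, collapse = ", "))
  }
  absent <- !file.exists(gff[panel])
  if (any(absent)) {
    stop("annotation file(s) not found: ",
         paste(gff[panel][absent], collapse = ", "))
  }
  gff[panel]
}

#' Validate pipeline inputs without running the pipeline
#'
#' Dry-run check of a configuration: existence and parseability of the
#' presence/absence matrix, availability of an annotation per strain,
#' membership of target strains and gene subsets, and parameter sanity.
#' All problems are collected and reported at once.
#'
#' @inheritParams generate_kmers
#' @return data.frame with columns `check` and `message`; zero rows when
#'   everything is consistent.
#' @export
validate_inputs <- function(presence_absence, gff, k = 31L, upstream = 0L,
                            downstream = 0L, targets = NULL, genes = NULL) {
  findings <- list()
  note <- function(check, msg) {
    findings[[length(findings) + 1L]] <<- data.frame(
      check = check, message = msg, stringsAsFactors = FALSE)
  }
  if (k < 1L) note("k", paste0("k-mer length must be >= 1, got ", k))
  if (upstream < 0L) note("upstream", "upstream flank must be >= 0")
  if (downstream < 0L) note("downstream", "downstream flank must be >= 0")
  tab <- NULL
  if (inherits(presence_absence, "gene_cluster_table")) {
    tab <- presence_absence
  } else if (!file.exists(presence_absence)) {
    note("presence_absence", paste0("file not found: ", presence_absence))
  } else {
    tab <- tryCatch(read_presence_absence(presence_absence),
                    error = function(e) {
                      note("presence_absence", conditionMessage(e))
                      NULL
                    })
  }
  if (!is.null(tab)) {
    tryCatch(resolve_gff_paths(gff, tab$strains),
             error = function(e) note("gff", conditionMessage(e)))
    for (s in setdiff(targets, tab$strains)) {
      note("targets", paste0("target strain not in panel: ", s))
    }
    for (g in setdiff(genes, tab$clusters)) {
      note("genes", paste0("gene cluster not in table: ", g))
    }
  }
  if (length(findings)) do.call(rbind, findings)
  else data.frame(check = character(), message = character(),
                  stringsAsFactors = FALSE)
}
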