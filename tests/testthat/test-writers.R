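fixture_run <- function(dir, filter = FALSE, targets = NULL, genes = NULL,
                        cores = 1, k = 3, csv_dir = tempfile()) {
  # two strains, a shared cluster, a strain-private cluster and a paralog
  dir.create(csv_dir, showWarnings = FALSE, recursive = TRUE)
  clusters <- list(
    g1 = list(A = "A_001", B = "B_001"),
    g2 = list(A = "A_002"),
    g3 = list(A = c("A_003", "A_004"))
  )
  csv <- write_fixture_csv(file.path(csv_dir, "gpa.csv"), clusters, c("A", "B"))
  ctg_a <- c(A_c1 = "TTATGCAGGACCTATGCAGTTTGACCAATGGC")
  write_fixture_gff(file.path(csv_dir, "A.gff"), ctg_a, data.frame(
    gene_id = c("A_001", "A_002", "A_003", "A_004"),
    contig = "A_c1", start = c(2L, 13L, 21L, 27L), end = c(7L, 19L, 26L, 31L),
    strand = c("+", "-", "+", "+"), stringsAsFactors = FALSE))
  ctg_b <- c(B_c1 = "GGATGCAGTT")
  write_fixture_gff(file.path(csv_dir, "B.gff"), ctg_b, data.frame(
    gene_id = "B_001", contig = "B_c1", start = 2L, end = 7L, strand = "+",
    stringsAsFactors = FALSE))
  generate_kmers(csv, csv_dir, dir, k = k, filter = filter, targets = targets,
                 genes = genes, cores = cores)
}

test_that("the three output files keep referential integrity and the Rtab contract", {
  out <- tempfile()
  run <- fixture_run(out)
  km <- read_kmers(run$paths[["kmers"]])
  k2h <- read_kmers_to_hashes(run$paths[["kmers_to_hashes"]])
  rtab <- read_rtab(run$paths[["hashes_to_patterns"]])

  expect_identical(colnames(rtab), c("A", "B"))
  expect_true(all(rtab %in% 0:1))
  # each hash exactly once in the Rtab; every mapped hash resolves
  expect_false(anyDuplicated(rownames(rtab)) > 0)
  expect_true(all(k2h$hash_id %in% rownames(rtab)))
  # every positional row resolves through (cluster, sequence)
  key <- paste(km$cluster, km$canonical_sequence)
  expect_true(all(key %in% paste(k2h$cluster, k2h$canonical_sequence)))
  expect_identical(km$hash_id,
                   k2h$hash_id[match(key, paste(k2h$cluster,
                                                k2h$canonical_sequence))])
  # re-hashing each Rtab row reproduces its own identifier
  expect_identical(unname(hash_pattern(rtab)), rownames(rtab))
  # abs interval width is always k, also for - strand observations
  expect_true(all(km$abs_end - km$abs_start == 3L))
  expect_true(all(km$rel_end - km$rel_start == 3L))
})

test_that("a shared sequence under two clusters yields two rows with distinct hashes", {
  out <- tempfile()
  run <- fixture_run(out)
  k2h <- read_kmers_to_hashes(run$paths[["kmers_to_hashes"]])
  # ATGCAG occurs in g1 (A+B) and in g2 (A only, reverse strand)
  shared <- k2h[k2h$canonical_sequence == "ATG", ]
  expect_true(all(c("g1", "g2") %in% shared$cluster))
  expect_gt(length(unique(shared$hash_id)), 1)
})

test_that("row order follows cluster input order, panel order and position", {
  out <- tempfile()
  run <- fixture_run(out)
  km <- read_kmers(run$paths[["kmers"]])
  expect_identical(unique(km$cluster), intersect(c("g1", "g2", "g3"),
                                                 km$cluster))
  one <- km[km$cluster == "g1", ]
  expect_identical(one$strain, sort(one$strain))
  a <- one[one$strain == "A", ]
  expect_identical(a$abs_start, sort(a$abs_start))
})

test_that("zero targets give a header-only positional log but full patterns", {
  out_all <- tempfile(); out_none <- tempfile()
  full <- fixture_run(out_all, csv_dir = tempfile())
  none <- fixture_run(out_none, targets = character(0), csv_dir = tempfile())
  expect_identical(readLines(none$paths[["kmers"]]),
                   readLines(full$paths[["kmers"]])[1])
  expect_identical(readLines(none$paths[["hashes_to_patterns"]]),
                   readLines(full$paths[["hashes_to_patterns"]]))
})

test_that("repeated runs are byte-identical and compression is transparent", {
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  r1 <- fixture_run(d1, csv_dir = tempfile())
  r2 <- fixture_run(d2, csv_dir = tempfile())
  for (f in names(r1$paths)) {
    expect_identical(readLines(r1$paths[[f]]), readLines(r2$paths[[f]]))
  }
  csv_dir <- tempfile()
  rz <- fixture_run(d3, csv_dir = csv_dir)
  # same inputs, gz suffix: decompressed content identical
  rz2 <- generate_kmers(file.path(csv_dir, "gpa.csv"), csv_dir,
                        tempfile(), k = 3, filter = FALSE, compress = TRUE)
  expect_match(rz2$paths[["kmers"]], "\\.gz$")
  expect_identical(readLines(gzfile(rz2$paths[["kmers"]])),
                   readLines(rz$paths[["kmers"]]))
})

test_that("filtered k-mers appear in no output file", {
  csv_dir <- tempfile()
  unf <- fixture_run(tempfile(), filter = FALSE, csv_dir = csv_dir)
  fil <- generate_kmers(file.path(csv_dir, "gpa.csv"), csv_dir, tempfile(),
                        k = 3, filter = TRUE)
  k2h_u <- read_kmers_to_hashes(unf$paths[["kmers_to_hashes"]])
  k2h_f <- read_kmers_to_hashes(fil$paths[["kmers_to_hashes"]])
  expect_lt(nrow(k2h_f), nrow(k2h_u))
  # whatever was dropped had exactly its cluster's pattern; rest is intact
  expect_true(all(paste(k2h_f$cluster, k2h_f$canonical_sequence) %in%
                    paste(k2h_u$cluster, k2h_u$canonical_sequence)))
  km_f <- read_kmers(fil$paths[["kmers"]])
  expect_true(all(paste(km_f$cluster, km_f$canonical_sequence) %in%
                    paste(k2h_f$cluster, k2h_f$canonical_sequence)))
})

test_that("unwritable output paths fail before computation", {
  expect_error(suppressWarnings(open_output_bundle("/dev/null/nope", c("A"))),
               "cannot|create")
})
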