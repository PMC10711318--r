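make_oseq <- function(bases, strain, up = 0L, start = 0L, strand = "+",
                      contig = "c1") {
  structure(list(bases = bases, up_obtained = up, down_obtained = 0L,
                 contig = contig, start = start,
                 end = start + nchar(bases) - up, strand = strand,
                 strain = strain),
            class = "oriented_sequence")
}

test_that("canonicalisation picks the lexicographic minimum and flags invalid windows", {
  res <- canonical_kmers(c("ACGT", "TTT", "AAC", "ANG"))
  expect_identical(res$canonical, c("ACGT", "AAA", "AAC", NA))
  expect_identical(res$rc, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("cluster k-mer extraction matches the worked toy example", {
  ck <- extract_cluster_kmers("g1", list(make_oseq("ATGCA", "A")),
                              panel = c("A", "B"), k = 3)
  expect_setequal(ck$kmers, c("ATG", "GCA"))
  # GCA occurs twice: from TGC (reverse complemented) and GCA itself
  gca <- ck$occurrences[ck$occurrences$kmer == "GCA", ]
  expect_identical(gca$rel_start, c(1L, 2L))
  expect_identical(gca$strand, c("-", "+"))
  expect_identical(unname(ck$presence["ATG", ]), c(1L, 0L))
  expect_identical(unname(ck$presence["GCA", ]), c(1L, 0L))

  # shared k-mer across strains: single record, presence (1,1)
  ck2 <- extract_cluster_kmers("g1",
                               list(make_oseq("ATG", "A"), make_oseq("ATG", "B")),
                               panel = c("A", "B"), k = 3)
  expect_identical(ck2$kmers, "ATG")
  expect_identical(unname(ck2$presence[1, ]), c(1L, 1L))

  # windows containing non-ACGT bases are skipped entirely
  ck3 <- extract_cluster_kmers("g1", list(make_oseq("ANG", "A")),
                               panel = "A", k = 3)
  expect_length(ck3$kmers, 0)

  # too-short sequences and empty input yield empty output, no error
  expect_length(extract_cluster_kmers("g1", list(make_oseq("AT", "A")),
                                      panel = "A", k = 3)$kmers, 0)
  expect_length(extract_cluster_kmers("g1", list(), panel = "A", k = 3)$kmers, 0)
})

test_that("presence is the OR over gene copies but every occurrence is logged", {
  ck <- extract_cluster_kmers("g1",
    list(make_oseq("ATGC", "A", contig = "c1"),
         make_oseq("ATGC", "A", start = 50L, contig = "c1")),
    panel = c("A", "B"), k = 4)
  expect_identical(unname(ck$presence["ATGC", ]), c(1L, 0L))
  expect_identical(nrow(ck$occurrences), 2L)
  expect_identical(sort(ck$occurrences$abs_start), c(0L, 50L))
})

test_that("targets restrict positional logging but never the patterns", {
  seqs <- list(make_oseq("ATGCA", "A"), make_oseq("ATGCA", "B"))
  full <- extract_cluster_kmers("g1", seqs, panel = c("A", "B"), k = 3)
  only_b <- extract_cluster_kmers("g1", seqs, panel = c("A", "B"), k = 3,
                                  targets = "B")
  none <- extract_cluster_kmers("g1", seqs, panel = c("A", "B"), k = 3,
                                targets = character(0))
  expect_identical(only_b$presence, full$presence)
  expect_identical(none$presence, full$presence)
  expect_identical(unique(only_b$occurrences$strain), "B")
  expect_identical(nrow(none$occurrences), 0L)
})

test_that("pattern hashing is deterministic, order-sensitive and cluster-blind", {
  h <- hash_pattern(rbind(c(1L, 0L), c(0L, 1L), c(1L, 0L)))
  expect_identical(h[1], h[3])
  expect_false(h[1] == h[2])
  expect_match(h, "^[0-9a-f]{32}$")
  # stable across calls (no per-run salt)
  expect_identical(hash_pattern(c(1L, 0L)), h[1])
})

test_that("the cluster-identity filter drops only pattern-identical k-mers", {
  seqs <- list(make_oseq("ATGCA", "A"), make_oseq("ATGGA", "B"))
  ck <- extract_cluster_kmers("g1", seqs, panel = c("A", "B"), k = 3)
  cl_pres <- c(1L, 1L)
  kept <- filter_cluster_identical(ck, cl_pres, filter = TRUE)
  # ATG is in both strains = cluster pattern -> dropped; private ones kept
  expect_false("ATG" %in% kept$kmers)
  expect_true(all(rowSums(kept$presence) == 1))
  expect_false("ATG" %in% kept$occurrences$kmer)
  # disabled filter returns the input unchanged
  expect_identical(filter_cluster_identical(ck, cl_pres, filter = FALSE), ck)
  # fully conserved core gene: everything filtered, empty output is fine
  core <- extract_cluster_kmers("g1",
    list(make_oseq("ATGCA", "A"), make_oseq("ATGCA", "B")),
    panel = c("A", "B"), k = 3)
  expect_length(filter_cluster_identical(core, c(1L, 1L))$kmers, 0)
})

test_that("a k-mer shared by two clusters keeps independent presence patterns", {
  panel <- c("A", "B", "C")
  ck1 <- extract_cluster_kmers("g1",
    list(make_oseq("ATGC", "A"), make_oseq("ATGC", "B")), panel, k = 4)
  ck2 <- extract_cluster_kmers("g2", list(make_oseq("ATGC", "C")), panel, k = 4)
  expect_identical(ck1$kmers, ck2$kmers)
  expect_false(identical(unname(ck1$presence[1, ]), unname(ck2$presence[1, ])))
  expect_false(hash_pattern(ck1$presence) == hash_pattern(ck2$presence))
})

test_that("engine output equals the brute-force oracle on random pangenomes", {
  set.seed(101)
  for (rep in 1:30) {
    pg <- random_pangenome()
    k <- sample(c(3L, 5L, 31L), 1)
    up <- sample(c(0L, 7L), 1)
    down <- sample(c(0L, 4L), 1)
    for (cid in pg$cluster_ids) {
      genes <- oracle_genes(pg, cid)
      if (is.null(genes)) next
      expected <- oracle_cluster(genes, pg$contigs, pg$strains, k, up, down)
      got <- {
        seqs <- lapply(seq_len(nrow(genes)), function(i) {
          g <- genes[i, ]
          os <- extract_oriented_sequence(
            list(contig = g$contig_id, start = g$start, end = g$end,
                 strand = g$strand), pg$contigs[[g$strain]], up, down)
          os$strain <- g$strain
          os
        })
        extract_cluster_kmers(cid, seqs, pg$strains, k = k)
      }
      expect_identical(sort_occ(got$occurrences), sort_occ(expected$occurrences))
      expect_setequal(got$kmers, rownames(expected$presence))
      expect_identical(got$presence[order(got$kmers), , drop = FALSE],
                       expected$presence[order(rownames(expected$presence)), ,
                                         drop = FALSE])
    }
  }
})
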