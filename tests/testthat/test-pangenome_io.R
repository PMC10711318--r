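test_that("presence/absence parsing handles lenient tables, paralogs and empties", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("Gene,A,B",
               "g1,A_0001,B_0007",
               "g2,A_0002,",
               "g3,A_0003;A_0004,"), csv)
  tab <- read_presence_absence(csv)
  expect_s3_class(tab, "gene_cluster_table")
  expect_identical(tab$strains, c("A", "B"))
  expect_identical(unname(tab$presence["g1", ]), c(1L, 1L))
  expect_identical(unname(tab$presence["g2", ]), c(1L, 0L))
  # ;-separated paralogs all retained, still presence 1
  expect_identical(tab$genes$g3$A, c("A_0003", "A_0004"))
  expect_identical(unname(tab$presence["g3", ]), c(1L, 0L))

  # empty body: empty table, no error
  writeLines("Gene,A,B", csv)
  empty <- read_presence_absence(csv)
  expect_length(empty$clusters, 0)
  expect_identical(dim(empty$presence), c(0L, 2L))
})

test_that("presence/absence parsing accepts the full Roary header", {
  csv <- tempfile(fileext = ".csv")
  meta <- c("Gene", "Non-unique Gene name", "Annotation", "No. isolates",
            "No. sequences", "Avg sequences per isolate", "Genome Fragment",
            "Order within Fragment", "Accessory Fragment",
            "Accessory Order with Fragment", "QC", "Min group size nuc",
            "Max group size nuc", "Avg group size nuc")
  writeLines(c(
    paste(c(sprintf("\"%s\"", meta), "\"A\"", "\"B\""), collapse = ","),
    paste(c("\"g1\"", rep("\"\"", 13), "\"A_0001\"", "\"B_0001\""),
          collapse = ",")), csv)
  tab <- read_presence_absence(csv)
  expect_identical(tab$strains, c("A", "B"))
  expect_identical(tab$genes$g1$B, "B_0001")
})

test_that("malformed headers and duplicate clusters are rejected by name", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("Cluster,A,B", "g1,x,y"), csv)
  expect_error(read_presence_absence(csv), "Cluster")
  writeLines(c("Gene,A,A", "g1,x,y"), csv)
  expect_error(read_presence_absence(csv), "duplicated strain")
  writeLines(c("Gene,A,B", "g1,x,y", "g1,z,"), csv)
  expect_error(read_presence_absence(csv), "duplicate cluster.*g1")
})

test_that("annotation indexing converts GFF3 coordinates and reads both FASTA layouts", {
  ctg <- paste(rep("ACGTGGTTCA", 10), collapse = "")
  feats <- data.frame(gene_id = c("A_0001", "A_0002"),
                      contig = "c1", start = c(10L, 24L), end = c(19L, 33L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  for (embed in c(TRUE, FALSE)) {
    gff <- tempfile(fileext = ".gff")
    write_fixture_gff(gff, c(c1 = tolower(ctg)), feats, embed_fasta = embed)
    ann <- if (embed) read_annotation(gff)
           else read_annotation(gff, sub("\\.gff$", ".fasta", gff))
    # GFF3 1-based inclusive (11..19) -> 0-based half-open [10, 19)
    expect_identical(ann$features$start, c(10L, 24L))
    expect_identical(ann$features$end, c(19L, 33L))
    expect_identical(ann$features$strand, c("+", "-"))
    # sequence uppercased on read
    expect_identical(ann$contigs[["c1"]], ctg)
  }
})

test_that("annotation indexing fails on missing sequence or unknown contig", {
  gff <- tempfile(fileext = ".gff")
  feats <- data.frame(gene_id = "A_0001", contig = "c1", start = 0L,
                      end = 9L, strand = "+", stringsAsFactors = FALSE)
  write_fixture_gff(gff, c(c1 = "ACGTACGTAC"), feats, embed_fasta = FALSE)
  file.remove(sub("\\.gff$", ".fasta", gff))
  expect_error(read_annotation(gff), "no sequence")

  feats$contig <- "ghost"
  write_fixture_gff(gff, c(c1 = "ACGTACGTAC"), feats, embed_fasta = TRUE)
  expect_error(read_annotation(gff), "ghost")
})

test_that("oriented extraction matches hand-checked slices and truncates flanks", {
  ctg <- c(ctg1 = "AAATGCCC")
  plus <- extract_oriented_sequence(
    list(contig = "ctg1", start = 2L, end = 5L, strand = "+"), ctg, 2, 1)
  expect_identical(plus$bases, "AAATGC")
  expect_identical(plus$up_obtained, 2L)
  expect_identical(plus$down_obtained, 1L)

  minus <- extract_oriented_sequence(
    list(contig = "ctg1", start = 2L, end = 5L, strand = "-"), ctg, 0, 0)
  expect_identical(minus$bases, "CAT")

  # gene at contig start: upstream truncated silently, recorded
  trunc <- extract_oriented_sequence(
    list(contig = "ctg1", start = 1L, end = 4L, strand = "+"), ctg, 5, 0)
  expect_identical(trunc$up_obtained, 1L)
  expect_identical(trunc$bases, "AAAT")
})

test_that("oriented sequences round-trip to the forward-strand contig substring", {
  set.seed(11)
  ctg <- c(c1 = paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                      collapse = ""))
  for (strand in c("+", "-")) {
    for (u in c(0, 3, 100)) {
      os <- extract_oriented_sequence(
        list(contig = "c1", start = 20L, end = 35L, strand = strand),
        ctg, u, 2)
      fwd_start <- if (strand == "-") os$start - os$down_obtained
                   else os$start - os$up_obtained
      fwd_len <- os$up_obtained + (os$end - os$start) + os$down_obtained
      fwd <- substr(ctg[["c1"]], fwd_start + 1, fwd_start + fwd_len)
      reproj <- if (strand == "-") oracle_revcomp(os$bases) else os$bases
      expect_identical(reproj, fwd)
      expect_identical(nchar(os$bases), fwd_len)
      # position 0 of bases maps to forward coordinate end-1 when u = 0
      if (u == 0 && strand == "-") {
        expect_identical(substr(os$bases, 1, 1),
                         oracle_revcomp(substr(ctg[["c1"]], os$end, os$end)))
      }
    }
  }
})
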