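test_that("GTF parsing unions exons and converts to 0-based half-open", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\tgene\t101\t300\t.\t+\t.\tgene_id "g1";',
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1";',
    'chr1\tsrc\texon\t151\t300\t.\t+\t.\tgene_id "g1";',
    'chr2\tsrc\tgene\t1001\t1500\t.\t-\t.\tgene_id "g2";',
    'chr2\tsrc\texon\t1001\t1100\t.\t-\t.\tgene_id "g2";',
    'chr2\tsrc\texon\t1301\t1500\t.\t-\t.\tgene_id "g2";'), gtf)
  g <- read_gene_annotation(gtf)
  g1 <- g[g$gene_id == "g1", ]
  expect_equal(g1$start, 100L)
  expect_equal(g1$end, 300L)
  expect_equal(g1$exon_length, 200L)  # union of [100,200) and [150,300)
  g2 <- g[g$gene_id == "g2", ]
  expect_equal(g2$strand, "-")
  expect_equal(g2$exon_length, 100L + 200L)  # disjoint exons
})

test_that("duplicate gene ids and missing strand are rejected", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\tgene\t1\t100\t.\t+\t.\tgene_id "g1";',
    'chr1\tsrc\tgene\t200\t300\t.\t.\t.\tgene_id "g2";'), gtf)
  expect_error(read_gene_annotation(gtf), "strand")
})

test_that("BED is read as-is and round-trips through write_gene_bed", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t999\t2000\tgeneA\t0\t+", bed)
  g <- read_gene_annotation(bed)
  expect_equal(g$start, 999L)
  expect_equal(g$end, 2000L)
  expect_equal(g$exon_length, 1001L)

  models <- data.frame(
    gene_id = c("gB", "gA"), chrom = c("chr2", "chr1"),
    start = c(50L, 10L), end = c(500L, 300L), strand = c("-", "+"),
    exon_length = c(450L, 290L), stringsAsFactors = FALSE)
  out <- tempfile(fileext = ".bed")
  write_gene_bed(models, out)
  back <- read_gene_annotation(out)
  back <- back[match(models$gene_id, back$gene_id), ]
  rownames(back) <- NULL
  expect_equal(back, models)
})

test_that("fixture GTF round-trips through the parser", {
  w <- small_world()
  g <- read_gene_annotation(w$gtf)
  expect_setequal(g$gene_id, w$models$gene_id)
  m <- w$models[match(g$gene_id, w$models$gene_id), ]
  expect_equal(g$start, m$start)
  expect_equal(g$end, m$end)
  expect_equal(g$strand, m$strand)
})

test_that("expression reader drops NA rows and validates shape", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\tNA\t3", "g3\t4\t5"), tsv)
  expect_message(tab <- read_expression(tsv, "CPM"), "1 row")
  expect_equal(tab$gene_ids, c("g1", "g3"))
  expect_equal(unname(tab$values["g3", ]), c(4, 5))

  one_col <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1", "g1\t1"), one_col)
  expect_error(read_expression(one_col, "CPM"), "2 sample")

  neg <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t-1\t2"), neg)
  expect_error(read_expression(neg, "CPM"), "negative")
})

test_that("fixture expression table round-trips bit-equal", {
  w <- small_world()
  tab <- read_expression(w$expression, "CPM")
  raw <- utils::read.delim(w$expression)
  expect_identical(unname(tab$values), unname(as.matrix(raw[, -1])))
})

test_that("FPKM/TPM rescaling multiplies by exon length in kb", {
  models <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                       start = c(0L, 5000L), end = c(2000L, 6000L),
                       strand = "+", exon_length = c(2000L, 500L),
                       stringsAsFactors = FALSE)
  tab <- expression_table(matrix(c(10, 8, 20, 4), 2,
                                 dimnames = list(c("g1", "g2"), c("a", "b"))),
                          units = "FPKM")
  out <- to_cpm_like(tab, models)
  expect_equal(out$units, "CPM")
  expect_equal(unname(out$values["g1", ]), c(10, 20) * 2)
  expect_equal(unname(out$values["g2", ]), c(8, 4) * 0.5)

  cpm <- expression_table(tab$values, units = "CPM")
  expect_identical(to_cpm_like(cpm, models), cpm)

  zero <- models
  zero$exon_length[1] <- 0L
  expect_error(to_cpm_like(tab, zero), "exon_length 0")
})

test_that("FPKM-converted values are exactly proportional to counts CPM", {
  set.seed(42)
  n <- 200
  len <- sample(200:5000, n)
  counts <- matrix(rpois(n * 3, lambda = 50), n,
                   dimnames = list(sprintf("g%03d", 1:n), c("a", "b", "c")))
  lib <- colSums(counts)
  cpm_true <- t(t(counts) / lib * 1e6)
  fpkm <- cpm_true / (len / 1000)
  models <- data.frame(gene_id = rownames(counts), chrom = "chr1",
                       start = 0L, end = max(len), strand = "+",
                       exon_length = len, stringsAsFactors = FALSE)
  out <- to_cpm_like(expression_table(fpkm, units = "FPKM"), models)
  for (s in colnames(counts)) {
    expect_equal(stats::cor(out$values[, s], cpm_true[, s]), 1.0,
                 tolerance = 1e-12)
  }
  # within-gene sample ratios are preserved exactly (per-gene scaling)
  expect_equal(out$values[, "a"] / out$values[, "b"],
               fpkm[, "a"] / fpkm[, "b"])
})
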