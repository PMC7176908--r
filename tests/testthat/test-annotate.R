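write_gff3 <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gff3",
                                .local_envir = parent.frame())
  writeLines(c("##gff-version 3", lines), path)
  path
}

demo_region <- function(chrom, start, end) {
  # a bare interval region (inner = outer) for annotation lookups
  structure(list(chrom = chrom, inner_start_bp = start, inner_end_bp = end,
                 outer_start_bp = start, outer_end_bp = end,
                 concordant_markers = character(0)),
            class = "candidate_region")
}

test_that("GFF3 import keeps gene features only and reads confidence labels", {
  gff <- write_gff3(c(
    sprintf("chr2H\tsrc\tgene\t%d\t%d\t.\t+\t.\tID=g%d;primary_confidence_class=%s",
            c(100, 500, 900), c(200, 600, 1000), 1:3, c("HC", "HC", "LC")),
    sprintf("chr2H\tsrc\tmRNA\t%d\t%d\t.\t+\t.\tID=t%d;Parent=g1",
            seq(100, 700, by = 100), seq(150, 750, by = 100), 1:7)))
  genes <- read_annotation(gff)
  expect_equal(nrow(genes), 3)
  expect_setequal(genes$gene_id, c("g1", "g2", "g3"))
  expect_equal(genes$confidence[genes$gene_id == "g3"], "LC")
})

test_that("BED import converts to 1-based inclusive coordinates", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr2H\t99\t199\tg1", bed)
  genes <- read_annotation(bed)
  expect_equal(genes$start_bp, 100)
  expect_equal(genes$end_bp, 199)
  expect_equal(genes$gene_id, "g1")
})

test_that("empty and malformed annotation files are handled", {
  empty <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_equal(nrow(read_annotation(empty)), 0)
  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "chr2H\tonly\tthree"), bad)
  expect_error(read_annotation(bad), "failed to parse")
})

test_that("region-gene intersection counts overlapping genes", {
  genes <- data.frame(
    gene_id = paste0("g", 1:5), chrom = "chr2H",
    start_bp = c(50, 150, 250, 350, 450),
    end_bp = c(120, 220, 320, 420, 520),
    strand = "+", confidence = c("HC", "HC", "LC", "HC", "HC"),
    stringsAsFactors = FALSE)
  region <- demo_region("chr2H", 100, 360)
  hit <- genes_in_region(region, genes)
  expect_equal(hit$count, 4)  # g1..g4 overlap, g5 does not
  expect_equal(hit$span_bp, 261)
  expect_equal(genes_in_region(region, genes, rule = "within")$count, 2)
  expect_equal(genes_in_region(region, genes, confidence = "HC")$count, 3)
})

test_that("genes abutting the region edge from outside are excluded", {
  genes <- data.frame(gene_id = "g1", chrom = "chr2H", start_bp = 90,
                      end_bp = 99, strand = "+", confidence = NA,
                      stringsAsFactors = FALSE)
  expect_equal(genes_in_region(demo_region("chr2H", 100, 199), genes)$count, 0)
  genes$end_bp <- 100
  expect_equal(genes_in_region(demo_region("chr2H", 100, 199), genes)$count, 1)
})

test_that("empty annotations give zero counts; unknown chromosomes error", {
  empty <- data.frame(gene_id = character(), chrom = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      strand = character(), confidence = character(),
                      stringsAsFactors = FALSE)
  expect_equal(genes_in_region(demo_region("chr2H", 1, 100), empty)$count, 0)
  genes <- data.frame(gene_id = "g1", chrom = "chr1H", start_bp = 1,
                      end_bp = 10, strand = "+", confidence = NA,
                      stringsAsFactors = FALSE)
  expect_error(genes_in_region(demo_region("chr9H", 1, 100), genes),
               "absent from annotation.*chr1H")
})

test_that("gene count grows monotonically as the region widens", {
  set.seed(71)
  genes <- data.frame(gene_id = paste0("g", 1:50), chrom = "chr2H",
                      start_bp = sort(sample.int(1e6, 50)),
                      strand = "+", confidence = NA, stringsAsFactors = FALSE)
  genes$end_bp <- genes$start_bp + sample.int(5e4, 50)
  prev <- -1L
  for (half in c(1e4, 1e5, 3e5, 5e5)) {
    r <- demo_region("chr2H", 5e5 - half, 5e5 + half)
    n_any <- genes_in_region(r, genes)$count
    n_within <- genes_in_region(r, genes, rule = "within")$count
    expect_gte(n_any, n_within)
    expect_gte(n_any, prev)
    prev <- n_any
  }
})
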