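test_that("encoding maps progeny calls onto parental origin codes", {
  raw <- matrix(c("AA", "BB", "AB", NA,
                  "BB", "AA", "AB", "AA"), nrow = 2, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("m1", "m2", "m3", "m4")))
  rec <- c("AA", "BB", "AA", "BB")
  don <- c("BB", "AA", "BB", "AA")
  enc <- encode_genotypes(raw, rec, don)
  expect_identical(unname(enc["s1", ]), c("A", "A", "H", NA))
  expect_identical(unname(enc["s2", ]), c("B", "B", "H", "B"))
  expect_equal(attr(enc, "n_unresolved"), 0L)
})

test_that("encoding requires opposite homozygous parents and resolves every valid token", {
  raw <- matrix("AA", 1, 1, dimnames = list("s1", "m1"))
  expect_error(encode_genotypes(raw, "BB", "AB"), "opposite homozygous")
  expect_error(encode_genotypes(raw, "AA", "AA"), "opposite homozygous")
  # with opposite homozygous parents every legal token maps to A, B or H
  raw2 <- matrix(c("AA", "BB", "AB"), 1, 3,
                 dimnames = list("s1", c("m1", "m2", "m3")))
  enc2 <- encode_genotypes(raw2, rep("BB", 3), rep("AA", 3))
  expect_false(anyNA(enc2))
  expect_equal(attr(enc2, "n_unresolved"), 0L)
  expect_error(encode_genotypes(matrix("XY", 1, 1, dimnames = list("s1", "m1")),
                                "AA", "BB"),
               "unknown progeny call")
})

test_that("the hand-traced run A A B B H A gives one 3-marker segment [30, 50]", {
  info <- tiny_marker_info(6)
  row <- stats::setNames(c("A", "A", "B", "B", "H", "A"), info$marker)
  segs <- call_segments(row, info)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start_bp, 30)
  expect_equal(segs$end_bp, 50)
  expect_equal(segs$n_markers, 3L)
  expect_equal(segs$state, "contains_donor_hom")
  expect_identical(segs$start_marker, info$marker[3])
})

test_that("all-recurrent rows give no segments; F1-like rows give one per chromosome", {
  info <- rbind(tiny_marker_info(5, "c1"), tiny_marker_info(5, "c2"))
  info$marker <- sprintf("m%03d", 1:10)
  all_a <- stats::setNames(rep("A", 10), info$marker)
  expect_equal(nrow(call_segments(all_a, info)), 0)
  all_h <- stats::setNames(rep("H", 10), info$marker)
  segs <- call_segments(all_h, info)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$state, rep("het_only", 2))
  expect_equal(segs$start_bp, c(10, 10))
  expect_equal(segs$end_bp, c(50, 50))
})

test_that("missing calls never break a run; A breaks unless budget remains", {
  info <- tiny_marker_info(5)
  row_na <- stats::setNames(c("B", NA, "B", "A", "A"), info$marker)
  expect_equal(nrow(call_segments(row_na, info)), 1)
  row_a <- stats::setNames(c("B", "A", "B", "A", "B"), info$marker)
  expect_equal(nrow(call_segments(row_a, info, max_interruptions = 0)), 3)
  # isolated single-A gaps are absorbed; each gap is judged on its own length
  expect_equal(nrow(call_segments(row_a, info, max_interruptions = 1)), 1)
  info6 <- tiny_marker_info(6)
  row_gap2 <- stats::setNames(c("B", "A", "A", "B", "A", "B"), info6$marker)
  expect_equal(nrow(call_segments(row_gap2, info6, max_interruptions = 1)), 2)
  expect_equal(nrow(call_segments(row_gap2, info6, max_interruptions = 2)), 1)
})

test_that("segment calling matches the brute-force marker-wise oracle", {
  set.seed(51)
  info <- tiny_marker_info(60)
  for (rep in 1:300) {
    row <- random_row(60)
    k <- sample(0:2, 1)
    got <- call_segments(row, info, max_interruptions = k)
    want <- oracle_segments_chrom(unname(row), info$pos_bp, k)
    expect_equal(got$start_bp, want$start_bp)
    expect_equal(got$end_bp, want$end_bp)
    expect_equal(got$n_markers, want$n_markers)
    expect_equal(got$state, want$state)
  }
})

test_that("segment count is monotone non-increasing in the interruption budget", {
  set.seed(52)
  info <- tiny_marker_info(80)
  for (rep in 1:50) {
    row <- random_row(80)
    counts <- vapply(0:4, function(k) {
      nrow(call_segments(row, info, max_interruptions = k))
    }, integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("called segments equal true donor segments at marker resolution", {
  study <- simulate_mapping_study(
    breeding = breeding_config(),
    chromosomes = chromosome_spec(c("chr2H", "chr5H"), c(80e6, 80e6), c(90, 90)),
    n_markers_per_chromosome = 120,
    n_transformable_min = 3, n_non_transformable_min = 1, seed = 53)
  mi <- study$marker_info
  for (s in rownames(study$matrix)) {
    got <- call_segments(study$matrix[s, ], mi)
    truth <- true_donor_intervals(study$population[[s]])
    # expected segments: runs of markers whose cM position lies in a true interval
    expected <- do.call(rbind, lapply(unique(mi$chrom), function(cn) {
      sub <- mi[mi$chrom == cn, ]
      tr <- truth[truth$chrom == cn, , drop = FALSE]
      covered <- vapply(sub$pos_cM, function(p) {
        any(p > tr$start_cM & p <= tr$end_cM)
      }, logical(1))
      if (!any(covered)) return(NULL)
      r <- rle(covered)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      keep <- which(r$values)
      data.frame(chrom = cn, start_bp = sub$pos_bp[starts[keep]],
                 end_bp = sub$pos_bp[ends[keep]])
    }))
    expect_equal(got$chrom, expected$chrom)
    expect_equal(got$start_bp, expected$start_bp)
    expect_equal(got$end_bp, expected$end_bp)
  }
})

test_that("donor fraction counts homozygous and heterozygous calls correctly", {
  expect_equal(donor_fraction(c("A", "A", "A")), 0)
  expect_equal(donor_fraction(c("H", "H")), 0.5)
  expect_equal(donor_fraction(c("B", "B", "A", "A")), 0.5)
  expect_equal(donor_fraction(c("B", NA, "A")), 0.5)
  expect_error(donor_fraction(c(NA_character_, NA)), "all calls missing")
})
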