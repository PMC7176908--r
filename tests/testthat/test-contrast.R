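mini_phen <- function(tr, nt) {
  data.frame(sample = c(tr, nt),
             class = c(rep("transformable", length(tr)),
                       rep("non_transformable", length(nt))),
             stringsAsFactors = FALSE)
}

test_that("single-marker concordance follows the co-segregation rule", {
  phen <- mini_phen(c("t1", "t2", "t3"), c("n1", "n2"))
  col <- c(t1 = "B", t2 = "H", t3 = "B", n1 = "A", n2 = "A")
  expect_equal(marker_concordance(col, phen)$status, "concordant")
  col_bad_t <- c(t1 = "A", t2 = "H", t3 = "B", n1 = "A", n2 = "A")
  expect_equal(marker_concordance(col_bad_t, phen)$status, "discordant")
  col_bad_n <- c(t1 = "B", t2 = "H", t3 = "B", n1 = "A", n2 = "H")
  expect_equal(marker_concordance(col_bad_n, phen)$status, "discordant")
  # class entirely missing -> non-evaluable, not discordant
  col_na <- c(t1 = NA, t2 = NA, t3 = NA, n1 = "A", n2 = "A")
  expect_equal(marker_concordance(col_na, phen)$status, "non_evaluable")
  # too much missingness within a class
  col_miss <- c(t1 = "B", t2 = NA, t3 = "B", n1 = "A", n2 = "A")
  expect_equal(marker_concordance(col_miss, phen,
                                  max_missing_fraction = 0.1)$status,
               "non_evaluable")
  expect_equal(marker_concordance(col_miss, phen,
                                  max_missing_fraction = 0.5)$status,
               "concordant")
})

test_that("heterozygous support can be disabled by the strict-homozygous mode", {
  phen <- mini_phen(c("t1", "t2"), "n1")
  col <- c(t1 = "B", t2 = "H", n1 = "A")
  expect_equal(marker_concordance(col, phen)$status, "concordant")
  expect_equal(marker_concordance(col, phen, het_as_donor = FALSE)$status,
               "discordant")
})

test_that("unknown-class samples are ignored and empty classes are an error", {
  phen <- rbind(mini_phen("t1", "n1"),
                data.frame(sample = "u1", class = "unknown"))
  col <- c(t1 = "B", n1 = "A", u1 = "A")
  expect_equal(marker_concordance(col, phen)$status, "concordant")
  expect_error(marker_concordance(c(t1 = "B"), mini_phen("t1", character(0))),
               "each informative phenotype class")
})

test_that("scan merges concordant runs, broken by discordant but not non-evaluable markers", {
  phen <- mini_phen(c("t1", "t2"), c("n1", "n2"))
  # 8 markers on c1: conc conc nonEval conc disc conc conc conc
  mat <- rbind(
    t1 = c("B", "B", NA,  "B", "A", "B", "B", "B"),
    t2 = c("B", "H", NA,  "H", "B", "B", "H", "B"),
    n1 = c("A", "A", NA,  "A", "A", "A", "A", "A"),
    n2 = c("A", "A", NA,  "A", "A", "A", "A", "A"))
  colnames(mat) <- sprintf("m%03d", 1:8)
  info <- tiny_marker_info(8)
  regions <- scan_genome(mat, phen, info)
  expect_length(regions, 2)
  # both runs have 3 concordant markers; the wider physical span ranks first
  expect_equal(regions[[1]]$inner_start_bp, 10)
  expect_equal(regions[[1]]$inner_end_bp, 40)
  expect_length(regions[[1]]$concordant_markers, 3)
  expect_equal(regions[[2]]$inner_start_bp, 60)
  expect_equal(regions[[2]]$inner_end_bp, 80)
  # outer bounds: nearest discordant marker, else chromosome terminal marker
  expect_equal(regions[[1]]$outer_start_bp, 10)
  expect_equal(regions[[1]]$outer_end_bp, 50)
  expect_equal(regions[[2]]$outer_start_bp, 50)
  expect_equal(regions[[2]]$outer_end_bp, 80)
})

test_that("a single transformable / single non-transformable pair is a valid limit case", {
  phen <- mini_phen("t1", "n1")
  mat <- rbind(t1 = c("B", "A", "H"), n1 = c("A", "A", "A"))
  colnames(mat) <- sprintf("m%03d", 1:3)
  regions <- scan_genome(mat, phen, tiny_marker_info(3))
  expect_length(regions, 2)  # markers 1 and 3 concordant, split by marker 2
})

test_that("genome scan equals the brute-force per-marker oracle on random matrices", {
  set.seed(61)
  for (rep in 1:25) {
    n_s <- sample(4:8, 1)
    n_m <- 40
    classes <- c(rep("transformable", ceiling(n_s / 2)),
                 rep("non_transformable", floor(n_s / 2)))
    ids <- sprintf("s%02d", seq_len(n_s))
    mat <- matrix(sample(c("A", "B", "H", NA), n_s * n_m, replace = TRUE,
                         prob = c(.5, .25, .15, .1)),
                  n_s, n_m, dimnames = list(ids, sprintf("m%03d", 1:n_m)))
    phen <- data.frame(sample = ids, class = classes, stringsAsFactors = FALSE)
    info <- rbind(tiny_marker_info(20, "c1"), tiny_marker_info(20, "c2"))
    info$marker <- sprintf("m%03d", 1:40)
    got <- regions_table(scan_genome(mat, phen, info))
    want <- oracle_scan_regions(mat, classes, info)
    # oracle is unranked; compare as sorted sets of intervals
    o <- order(got$chrom, got$inner_start_bp)
    w <- order(want$chrom, want$inner_start_bp)
    expect_equal(got$chrom[o], want$chrom[w])
    expect_equal(got$inner_start_bp[o], want$inner_start_bp[w])
    expect_equal(got$inner_end_bp[o], want$inner_end_bp[w])
    expect_equal(got$n_markers[o], want$n_markers[w])
  }
})

test_that("adding a sample never widens the concordant marker set", {
  set.seed(62)
  info <- tiny_marker_info(30)
  ids <- sprintf("s%02d", 1:8)
  mat <- matrix(sample(c("A", "B", "H"), 8 * 30, replace = TRUE,
                       prob = c(.4, .35, .25)),
                8, 30, dimnames = list(ids, info$marker))
  phen <- data.frame(sample = ids,
                     class = rep(c("transformable", "non_transformable"), 4),
                     stringsAsFactors = FALSE)
  conc_markers <- function(m, p) {
    unlist(lapply(scan_genome(m, p, info), `[[`, "concordant_markers"))
  }
  for (n_keep in c(4, 6, 8)) {
    sub <- conc_markers(mat[ids[1:n_keep], , drop = FALSE],
                        phen[1:n_keep, ])
    if (n_keep > 4) expect_true(all(sub %in% prev))
    prev <- sub
  }
})

test_that("minimal region is the intersection of transformable donor spans", {
  # spans [10,80] and [30,100] over markers every 10 bp -> inner [30,80]
  info <- tiny_marker_info(10)
  in_span <- function(lo, hi) ifelse(info$pos_bp >= lo & info$pos_bp <= hi, "B", "A")
  mat <- rbind(t1 = in_span(10, 80), t2 = in_span(30, 100),
               n1 = rep("A", 10))
  colnames(mat) <- info$marker
  phen <- mini_phen(c("t1", "t2"), "n1")
  regions <- scan_genome(mat, phen, info)
  top <- delimit_minimal_region(regions[[1]], mat, phen, info)
  expect_equal(top$inner_start_bp, 30)
  expect_equal(top$inner_end_bp, 80)
  expect_equal(top$boundary_samples$left, "t2")
  expect_equal(top$boundary_samples$right, "t1")
  # outer flank: first A beyond each inner bound in any transformable sample
  expect_equal(top$outer_start_bp, 20)  # t2 is A at 20
  expect_equal(top$outer_end_bp, 90)    # t1 is A at 90
})

test_that("a nested donor span sets both bounds", {
  info <- tiny_marker_info(10)
  in_span <- function(lo, hi) ifelse(info$pos_bp >= lo & info$pos_bp <= hi, "B", "A")
  mat <- rbind(t1 = in_span(40, 60), t2 = in_span(10, 100),
               n1 = rep("A", 10))
  colnames(mat) <- info$marker
  phen <- mini_phen(c("t1", "t2"), "n1")
  regions <- scan_genome(mat, phen, info)
  top <- delimit_minimal_region(regions[[1]], mat, phen, info)
  expect_equal(top$inner_start_bp, 40)
  expect_equal(top$inner_end_bp, 60)
  expect_setequal(top$boundary_samples$left, "t1")
  expect_setequal(top$boundary_samples$right, "t1")
})

test_that("a simulated study recovers the planted causal locus and skips the selection locus", {
  study <- simulate_mapping_study(seed = 63)
  res <- map_study_locus(study)
  expect_true(res$contains_causal)
  expect_equal(res$top$chrom, study$truth$causal$chrom)
  # the selection-locus region is shared by non-transformable lines, so it
  # must never be reported whenever such a line carries donor there
  sel <- study$truth$selection
  nt <- study$phenotypes$sample[study$phenotypes$class == "non_transformable"]
  nt_carries <- any(vapply(nt, function(s) {
    donor_dosage(study$population[[s]], sel$chrom, sel$cM) > 0L
  }, logical(1)))
  expect_true(nt_carries)  # guaranteed here by the phenotypic screen
  on_5h <- vapply(res$regions, function(r) {
    r$chrom == sel$chrom && sel$bp >= r$inner_start_bp && sel$bp <= r$inner_end_bp
  }, logical(1))
  expect_false(any(on_5h))
})

test_that("permuting phenotype labels destroys the candidate region", {
  study <- simulate_mapping_study(seed = 64)
  set.seed(65)
  perm <- study$phenotypes
  perm$class <- sample(perm$class)
  regions <- scan_genome(study$matrix, perm, study$marker_info)
  # a random labelling should leave (almost) no perfectly concordant markers
  expect_lte(sum(vapply(regions, function(r) length(r$concordant_markers),
                        integer(1))), 2)
})
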