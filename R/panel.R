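# Parental calls use allele-pair tokens: "AA", "BB" (the two homozygotes of
# the array alleles at a marker), "AB" (heterozygous) and NA (no call).

CALL_TOKENS <- c("AA", "BB", "AB")

#' Configuration of a SNP-array marker panel
#'
#' Category counts for the synthetic panel: `informative` markers carry
#' opposite homozygous parental calls and are mapped; the other four
#' categories reproduce the exclusion classes seen when two inbred parents
#' are assayed on a fixed array (monomorphic, a call for one parent only,
#' unplaced on the physical map, heterozygous in a parent).
#'
#' @param informative,monomorphic,single_parent,unmapped,parent_het
#'   Non-negative marker counts per category. Defaults reproduce a 44,040
#'   marker array with 9,456 informative markers.
#' @param genotyping_error_rate Per-progeny-call probability of corruption
#'   to a uniformly random different call (default 0).
#' @param missing_rate Per-progeny-call probability of a no-call (default 0).
#' @return A `panel_config` list.
#' @export
panel_config <- function(informative = 9456L, monomorphic = 31925L,
                         single_parent = 2535L, unmapped = 45L,
                         parent_het = 79L,
                         genotyping_error_rate = 0, missing_rate = 0) {
  counts <- c(informative = informative, monomorphic = monomorphic,
              single_parent = single_parent, unmapped = unmapped,
              parent_het = parent_het)
  if (any(counts < 0)) stop("category counts must be >= 0")
  stopifnot(genotyping_error_rate >= 0, genotyping_error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  structure(list(counts = stats::setNames(as.integer(counts), names(counts)),
                 genotyping_error_rate = genotyping_error_rate,
                 missing_rate = missing_rate),
            class = "panel_config")
}

#' Build a synthetic marker panel with known category truth
#'
#' Emits exactly the configured number of markers per category, assigning
#' mapped categories to distinct positions of the genetic map and leaving
#' `unmapped` markers without a chromosome. Informative markers carry
#' opposite homozygous parental calls (which parent carries "AA" is random);
#' the ground-truth category of every marker is stored so that triage can be
#' checked against construction.
#'
#' @param config A [panel_config()].
#' @param map A `genetic_map` with at least as many markers as the mapped
#'   categories require.
#' @param parents Length-2 character vector `c(recurrent, donor)` naming the
#'   call columns (default `c("recurrent", "donor")`).
#' @param seed Optional integer seed.
#' @return A `data.frame` (class `marker_panel`) with columns `marker`,
#'   `chrom`, `pos_bp`, `pos_cM`, `p1`, `p2`, `truth`; attribute `parents`.
#' @export
build_marker_panel <- function(config, map, parents = c("recurrent", "donor"),
                               seed = NULL) {
  stopifnot(inherits(config, "panel_config"), length(parents) == 2L)
  if (!is.null(seed)) set.seed(seed)
  cnt <- config$counts
  n_mapped <- sum(cnt) - cnt[["unmapped"]]
  if (n_mapped > nrow(map$markers)) {
    stop("requested ", n_mapped, " mapped markers but map holds only ",
         nrow(map$markers))
  }
  slots <- sample.int(nrow(map$markers), n_mapped)
  mk <- map$markers[slots, , drop = FALSE]
  truth <- rep(names(cnt)[names(cnt) != "unmapped"],
               cnt[names(cnt) != "unmapped"])
  truth <- sample(truth)
  n <- length(truth)
  p1 <- character(n); p2 <- character(n)
  hom <- c("AA", "BB")
  for (cat in unique(truth)) {
    i <- which(truth == cat)
    k <- length(i)
    if (cat == "informative") {
      a <- sample(hom, k, replace = TRUE)
      p1[i] <- a
      p2[i] <- ifelse(a == "AA", "BB", "AA")
    } else if (cat == "monomorphic") {
      a <- sample(hom, k, replace = TRUE)
      p1[i] <- a; p2[i] <- a
    } else if (cat == "single_parent") {
      a <- sample(hom, k, replace = TRUE)
      miss_first <- sample(c(TRUE, FALSE), k, replace = TRUE)
      p1[i] <- ifelse(miss_first, NA, a)
      p2[i] <- ifelse(miss_first, a, NA)
    } else if (cat == "parent_het") {
      het_first <- sample(c(TRUE, FALSE), k, replace = TRUE)
      other <- sample(CALL_TOKENS, k, replace = TRUE)
      p1[i] <- ifelse(het_first, "AB", other)
      p2[i] <- ifelse(het_first, other, "AB")
    }
  }
  mapped <- data.frame(marker = mk$marker, chrom = mk$chrom,
                       pos_bp = mk$pos_bp, pos_cM = mk$pos_cM,
                       p1 = p1, p2 = p2, truth = truth,
                       stringsAsFactors = FALSE)
  if (cnt[["unmapped"]] > 0L) {
    k <- cnt[["unmapped"]]
    a <- sample(hom, k, replace = TRUE)
    unm <- data.frame(marker = sprintf("UNM_M%04d", seq_len(k)),
                      chrom = NA_character_, pos_bp = NA_real_,
                      pos_cM = NA_real_,
                      p1 = a, p2 = ifelse(a == "AA", "BB", "AA"),
                      truth = "unmapped", stringsAsFactors = FALSE)
    mapped <- rbind(mapped, unm)
  }
  ord <- order(is.na(mapped$chrom), mapped$chrom, mapped$pos_bp)
  panel <- mapped[ord, , drop = FALSE]
  rownames(panel) <- NULL
  attr(panel, "parents") <- parents
  class(panel) <- c("marker_panel", "data.frame")
  panel
}

# Raw progeny token for an informative marker given donor dosage 0/1/2,
# where p1 is the recurrent parent's homozygous call.
token_from_dosage <- function(dosage, p1, p2) {
  ifelse(dosage == 0L, p1, ifelse(dosage == 2L, p2, "AB"))
}

#' Genotype a simulated population on a marker panel
#'
#' Produces the raw array call matrix (samples x panel markers, allele-pair
#' tokens). Informative and parent-heterozygous-free categories behave as a
#' real assay would: informative calls reflect the two haplotype origins at
#' the marker position (donor/donor -> donor homozygote, mixed ->
#' heterozygote), monomorphic markers return the shared parental call,
#' single-parent markers return the parent call that exists, and unmapped or
#' parent-heterozygous markers return no-calls. Each call is then
#' independently set missing with `missing_rate` and corrupted to a
#' uniformly chosen different token with `genotyping_error_rate`.
#'
#' @param population A `bc_population` (or list of `diploid_genome`s named
#'   by sample).
#' @param panel A `marker_panel`.
#' @param map A `genetic_map`.
#' @param config A [panel_config()] supplying the noise rates.
#' @param seed Optional integer seed.
#' @return Character matrix, rownames = sample ids, colnames = markers.
#' @export
genotype_population <- function(population, panel, map, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genomes <- if (inherits(population, "bc_population")) {
    stats::setNames(lapply(population$lines, `[[`, "genome"),
                    population_ids(population))
  } else population
  if (!length(genomes)) stop("population is empty")
  n_s <- length(genomes)
  n_m <- nrow(panel)
  calls <- matrix(NA_character_, n_s, n_m,
                  dimnames = list(names(genomes), panel$marker))
  info <- panel$truth == "informative"
  mono <- panel$truth == "monomorphic"
  single <- panel$truth == "single_parent"
  # chromosome-wise dosage lookup for informative markers
  for (s in seq_len(n_s)) {
    g <- genomes[[s]]
    if (any(mono)) calls[s, mono] <- panel$p1[mono]
    if (any(single)) {
      calls[s, single] <- ifelse(is.na(panel$p1[single]),
                                 panel$p2[single], panel$p1[single])
    }
    for (cn in unique(panel$chrom[info])) {
      i <- which(info & panel$chrom == cn)
      pair <- g[[cn]]
      dos <- origin_at(pair[[1]], panel$pos_cM[i]) +
        origin_at(pair[[2]], panel$pos_cM[i])
      calls[s, i] <- token_from_dosage(dos, panel$p1[i], panel$p2[i])
    }
  }
  n_cells <- length(calls)
  if (config$genotyping_error_rate > 0) {
    flip <- which(stats::runif(n_cells) < config$genotyping_error_rate &
                    !is.na(calls))
    if (length(flip)) {
      calls[flip] <- vapply(calls[flip], function(v) {
        sample(setdiff(CALL_TOKENS, v), 1L)
      }, character(1))
    }
  }
  if (config$missing_rate > 0) {
    calls[stats::runif(n_cells) < config$missing_rate] <- NA_character_
  }
  calls
}
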