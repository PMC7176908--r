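#' Configuration of a marker-assisted backcross program
#'
#' Describes a donor x recurrent cross followed by `n_backcrosses` rounds of
#' backcrossing to the recurrent parent and
#' `selfing_generations_after_last_cross` rounds of self-pollination. During
#' each selfing round a phenotypic screen at `selection_locus` (the
#' large-embryo / shrunken-endosperm proxy on 5H in the motivating program)
#' retains homozygous-donor plants always, heterozygotes with probability
#' `selection_misclassification_rate`, and homozygous-recurrent plants
#' never. A second, causal locus (`causal_locus`) controls the binary
#' transformability phenotype under `dominance_mode`.
#'
#' @param n_backcrosses Integer >= 0.
#' @param selfing_generations_after_last_cross Integer >= 0; screening is
#'   applied only in these selfing generations (F2 onward).
#' @param selection_locus `list(chrom=, cM=)` or `NULL` to disable screening.
#' @param selection_misclassification_rate Probability a heterozygote passes
#'   the visual screen. Default 0.1: the screen is imperfect and lets some
#'   heterozygotes through.
#' @param causal_locus `list(chrom=, cM=)` for the transformability locus.
#' @param dominance_mode `"dominant"` (one donor allele suffices, the
#'   default) or `"recessive"` (two required).
#' @param te_if_carrier Per-embryo probability that an embryo of a
#'   transformable line yields at least one transgenic plant (default 0.13).
#' @param n_embryos_per_line Embryos cultured per line per experiment
#'   (default 50).
#' @param rng_seed Optional integer seed applied by [run_breeding_scheme()].
#' @return A `breeding_config` list.
#' @export
breeding_config <- function(n_backcrosses = 1L,
                            selfing_generations_after_last_cross = 1L,
                            selection_locus = list(chrom = "chr5H", cM = 40),
                            selection_misclassification_rate = 0.1,
                            causal_locus = list(chrom = "chr2H", cM = 65),
                            dominance_mode = c("dominant", "recessive"),
                            te_if_carrier = 0.13,
                            n_embryos_per_line = 50L,
                            rng_seed = NULL) {
  dominance_mode <- match.arg(dominance_mode)
  n_backcrosses <- as.integer(n_backcrosses)
  selfings <- as.integer(selfing_generations_after_last_cross)
  stopifnot(n_backcrosses >= 0L, selfings >= 0L,
            te_if_carrier >= 0, te_if_carrier <= 1,
            selection_misclassification_rate >= 0,
            selection_misclassification_rate <= 1,
            n_embryos_per_line >= 1L)
  structure(list(
    n_backcrosses = n_backcrosses,
    selfing_generations_after_last_cross = selfings,
    selection_locus = selection_locus,
    selection_misclassification_rate = selection_misclassification_rate,
    causal_locus = causal_locus,
    dominance_mode = dominance_mode,
    te_if_carrier = te_if_carrier,
    n_embryos_per_line = as.integer(n_embryos_per_line),
    rng_seed = rng_seed
  ), class = "breeding_config")
}

check_loci_on_map <- function(config, map) {
  for (locus in list(config$selection_locus, config$causal_locus)) {
    if (is.null(locus)) next
    i <- match(locus$chrom, map$chromosomes$name)
    if (is.na(i)) stop("locus chromosome not on map: ", locus$chrom)
    if (locus$cM < 0 || locus$cM > map$chromosomes$length_cM[i]) {
      stop("locus position outside chromosome ", locus$chrom)
    }
  }
  invisible(config)
}

# One screened plant passes the selection locus screen?
passes_screen <- function(genome, config) {
  if (is.null(config$selection_locus)) return(TRUE)
  d <- donor_dosage(genome, config$selection_locus$chrom, config$selection_locus$cM)
  if (d == 2L) return(TRUE)
  if (d == 1L) return(stats::runif(1) < config$selection_misclassification_rate)
  FALSE
}

# Realise one pedigree: cross -> backcrosses -> screened selfings.
# Returns NULL (with attr "failed_at") when screening exhausts candidates.
breed_one_line <- function(config, map, donor, recurrent, n_screened) {
  plant <- make_offspring(donor, recurrent, map)  # F1
  for (b in seq_len(config$n_backcrosses)) {
    plant <- make_offspring(plant, recurrent, map)
  }
  gen <- if (config$n_backcrosses > 0) paste0("BC", config$n_backcrosses) else ""
  for (s in seq_len(config$selfing_generations_after_last_cross)) {
    label <- paste0(gen, "F", s + 1L)
    if (!is.null(config$selection_locus) &&
        donor_dosage(plant, config$selection_locus$chrom,
                     config$selection_locus$cM) == 0L) {
      # no selfed grain can carry the donor allele: the screen rejects all
      return(structure(list(), failed_at = label))
    }
    found <- NULL
    for (k in seq_len(n_screened)) {
      cand <- make_offspring(plant, plant, map)
      if (passes_screen(cand, config)) { found <- cand; break }
    }
    if (is.null(found)) return(structure(list(), failed_at = label))
    plant <- found
  }
  plant
}

#' Run a backcross breeding scheme
#'
#' Simulates `n_lines` independent lineages through the configured program:
#' primary cross, backcrosses to the recurrent parent, then screened selfing
#' generations. During each selfing round up to `n_screened` selfed grains
#' are examined and the first that passes the phenotypic screen at the
#' selection locus continues the lineage; a lineage in which no grain passes
#' is restarted from the primary cross (up to `max_attempts` times, after
#' which an extinct-lineage error names the failing generation).
#'
#' @param config A [breeding_config()].
#' @param map A `genetic_map`.
#' @param n_lines Number of lines to return.
#' @param n_screened Grains screened per selfing round (default 50).
#' @param max_attempts Lineage restarts allowed per line (default 100).
#' @return A `bc_population`: list with `lines` (each `id`, `genome`,
#'   `generation`, `n_attempts`), plus the `config` used.
#' @export
run_breeding_scheme <- function(config, map, n_lines,
                                n_screened = 50L, max_attempts = 100L) {
  stopifnot(inherits(config, "breeding_config"), n_lines >= 1L)
  check_loci_on_map(config, map)
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  donor <- founder_genome(map, ORIGIN_DONOR)
  recurrent <- founder_genome(map, ORIGIN_RECURRENT)
  gen_label <- paste0(
    if (config$n_backcrosses > 0) paste0("BC", config$n_backcrosses) else "",
    "F", config$selfing_generations_after_last_cross + 1L)
  lines <- vector("list", n_lines)
  for (i in seq_len(n_lines)) {
    plant <- NULL
    failed_at <- NULL
    for (a in seq_len(max_attempts)) {
      res <- breed_one_line(config, map, donor, recurrent, n_screened)
      if (inherits(res, "diploid_genome")) { plant <- res; attempts <- a; break }
      failed_at <- attr(res, "failed_at")
    }
    if (is.null(plant)) {
      stop("extinct lineage: selection eliminated all candidates at generation ",
           failed_at)
    }
    lines[[i]] <- list(id = sprintf("%s-%03d", gen_label, i),
                       genome = plant, generation = gen_label,
                       n_attempts = attempts)
  }
  structure(list(lines = lines, config = config), class = "bc_population")
}

#' @export
print.bc_population <- function(x, ...) {
  cat("<bc_population>", length(x$lines), "lines,",
      if (length(x$lines)) x$lines[[1]]$generation else "", "\n")
  invisible(x)
}

#' Sample ids of a population
#' @param population A `bc_population`.
#' @return Character vector.
#' @export
population_ids <- function(population) {
  vapply(population$lines, `[[`, character(1), "id")
}

#' Classify a genome as transformable or not at the causal locus
#'
#' Under the dominant model a line is transformable iff it carries at least
#' one donor allele at the causal locus; under the recessive model both
#' alleles must be donor.
#'
#' @param genome A `diploid_genome`.
#' @param config A [breeding_config()].
#' @return `"transformable"` or `"non_transformable"`.
#' @export
assign_transformability <- function(genome, config) {
  d <- donor_dosage(genome, config$causal_locus$chrom, config$causal_locus$cM)
  need <- if (config$dominance_mode == "dominant") 1L else 2L
  if (d >= need) "transformable" else "non_transformable"
}

#' Simulate a transformation assay for one line
#'
#' For a transformable line each of `n_embryos_per_line` cultured embryos
#' independently yields at least one transgenic plant with probability
#' `te_if_carrier`; a non-transformable line yields none.
#'
#' @param sample_class `"transformable"` or `"non_transformable"`.
#' @param config A [breeding_config()].
#' @return `data.frame` row with `n_embryos`, `n_transgenic`, `te_percent`.
#' @export
simulate_assay <- function(sample_class, config) {
  stopifnot(sample_class %in% c("transformable", "non_transformable"))
  n <- config$n_embryos_per_line
  k <- if (sample_class == "transformable") {
    stats::rbinom(1L, n, config$te_if_carrier)
  } else 0L
  data.frame(n_embryos = n, n_transgenic = k,
             te_percent = compute_te(n, k))
}
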