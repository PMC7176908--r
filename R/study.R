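#' Simulate a complete introgression-mapping study
#'
#' Generates everything the mapping pipeline consumes, with known truth:
#' a marker map, a backcross population bred (line by line, with phenotypic
#' selection) until at least `n_transformable_min` transformable and
#' `n_non_transformable_min` non-transformable lines exist, array genotypes
#' with the configured noise, encoded graphical genotypes over the retained
#' markers, phenotypes, and per-line transformation assays.
#'
#' @param breeding A [breeding_config()].
#' @param panel_cfg A [panel_config()]; the default is an informative-only
#'   panel of `7 * n_markers_per_chromosome` markers, suitable for mapping
#'   simulations (use the full five-category default of [panel_config()]
#'   to emulate a complete array).
#' @param chromosomes Chromosome table (default [barley_chromosomes()]).
#' @param n_markers_per_chromosome Markers placed per chromosome
#'   (default 500).
#' @param n_transformable_min,n_non_transformable_min Minimum class sizes
#'   to breed (defaults 10 and 3).
#' @param max_lines Safety cap on bred lines (default 400).
#' @param seed Optional integer seed governing the whole study.
#' @return List with `map`, `panel`, `raw` (token matrix), `matrix`
#'   (encoded A/B/H matrix over retained markers), `marker_info`,
#'   `phenotypes`, `assays`, `population`, `truth`
#'   (`causal` = chrom/cM/bp, `selection` = chrom/cM/bp or NULL).
#' @export
simulate_mapping_study <- function(breeding = breeding_config(),
                                   panel_cfg = NULL,
                                   chromosomes = barley_chromosomes(),
                                   n_markers_per_chromosome = 500L,
                                   n_transformable_min = 10L,
                                   n_non_transformable_min = 3L,
                                   max_lines = 400L,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  map <- build_map(chromosomes, n_markers_per_chromosome)
  if (is.null(panel_cfg)) {
    panel_cfg <- panel_config(
      informative = nrow(chromosomes) * n_markers_per_chromosome,
      monomorphic = 0L, single_parent = 0L, unmapped = 0L, parent_het = 0L)
  }
  panel <- build_marker_panel(panel_cfg, map)
  check_loci_on_map(breeding, map)
  donor <- founder_genome(map, ORIGIN_DONOR)
  recurrent <- founder_genome(map, ORIGIN_RECURRENT)
  lines <- list()
  n_tr <- 0L; n_nt <- 0L
  while ((n_tr < n_transformable_min || n_nt < n_non_transformable_min) &&
         length(lines) < max_lines) {
    plant <- NULL
    for (a in 1:100) {
      res <- breed_one_line(breeding, map, donor, recurrent, n_screened = 50L)
      if (inherits(res, "diploid_genome")) { plant <- res; break }
    }
    if (is.null(plant)) stop("extinct lineage while simulating study")
    cls <- assign_transformability(plant, breeding)
    if (cls == "transformable") n_tr <- n_tr + 1L else n_nt <- n_nt + 1L
    gen <- paste0(if (breeding$n_backcrosses > 0)
      paste0("BC", breeding$n_backcrosses) else "",
      "F", breeding$selfing_generations_after_last_cross + 1L)
    lines[[length(lines) + 1L]] <- list(
      id = sprintf("%s-%03d", gen, length(lines) + 1L),
      genome = plant, generation = gen, class = cls)
  }
  if (n_tr < n_transformable_min || n_nt < n_non_transformable_min) {
    stop("could not reach requested class sizes within ", max_lines, " lines")
  }
  genomes <- stats::setNames(lapply(lines, `[[`, "genome"),
                             vapply(lines, `[[`, character(1), "id"))
  raw <- genotype_population(genomes, panel, map, panel_cfg)
  tri <- triage_panel(panel)
  retained <- tri$retained
  enc <- encode_genotypes(raw[, retained$marker, drop = FALSE],
                          retained$p1, retained$p2)
  phenotypes <- data.frame(
    sample = names(genomes),
    class = vapply(lines, `[[`, character(1), "class"),
    generation = vapply(lines, `[[`, character(1), "generation"),
    stringsAsFactors = FALSE)
  assays <- do.call(rbind, lapply(seq_along(lines), function(i) {
    cbind(data.frame(line = lines[[i]]$id, experiment = 1L,
                     stringsAsFactors = FALSE),
          simulate_assay(lines[[i]]$class, breeding))
  }))
  causal <- breeding$causal_locus
  causal$bp <- cm_to_bp(map, causal$chrom, causal$cM)
  selection <- breeding$selection_locus
  if (!is.null(selection)) {
    selection$bp <- cm_to_bp(map, selection$chrom, selection$cM)
  }
  list(map = map, panel = panel, raw = raw, matrix = enc,
       marker_info = retained[, c("marker", "chrom", "pos_bp", "pos_cM")],
       phenotypes = phenotypes, assays = assays,
       population = genomes, triage = tri$report,
       truth = list(causal = causal, selection = selection))
}

#' Map the causal locus in a (simulated or real) study
#'
#' Runs the full contrast stage: genome scan for phenotype-concordant
#' regions, minimal-region delimitation of the top-ranked region, and — for
#' simulated studies carrying truth — whether the refined outer interval
#' contains the causal locus.
#'
#' @param study Output of [simulate_mapping_study()], or a list with
#'   `matrix`, `phenotypes`, `marker_info` (and optionally `truth`).
#' @param max_interruptions Passed to [delimit_minimal_region()].
#' @param max_missing_fraction Passed to [scan_genome()].
#' @return List: `regions` (ranked scan output), `top` (refined top region
#'   or `NULL`), `contains_causal` (logical or `NA` when no truth).
#' @export
map_study_locus <- function(study, max_interruptions = 0L,
                            max_missing_fraction = 0.1) {
  regions <- scan_genome(study$matrix, study$phenotypes, study$marker_info,
                         max_missing_fraction = max_missing_fraction)
  if (!length(regions)) {
    return(list(regions = regions, top = NULL, contains_causal = FALSE))
  }
  top <- delimit_minimal_region(regions[[1]], study$matrix, study$phenotypes,
                                study$marker_info, max_interruptions)
  contains <- NA
  if (!is.null(study$truth)) {
    ca <- study$truth$causal
    contains <- identical(top$chrom, ca$chrom) &&
      ca$bp >= top$outer_start_bp && ca$bp <= top$outer_end_bp
  }
  list(regions = regions, top = top, contains_causal = contains)
}

#' Locus-recovery rate over repeated simulated studies
#'
#' Repeats [simulate_mapping_study()] + [map_study_locus()] `n_sims` times
#' and reports the fraction of runs in which the refined outer interval of
#' the top-ranked region contains the planted causal locus.
#'
#' @param n_sims Number of simulated studies.
#' @param seed Integer seed; run `i` is seeded deterministically from it.
#' @param genotyping_error_rate,missing_rate Noise applied to array calls.
#' @param max_interruptions Interruption tolerance during delimitation.
#' @param ... Further arguments to [simulate_mapping_study()].
#' @return List: `rate` (fraction of hits), `hits` (logical vector).
#' @export
locus_recovery_rate <- function(n_sims, seed,
                                genotyping_error_rate = 0,
                                missing_rate = 0,
                                max_interruptions = 0L, ...) {
  args <- list(...)
  n_mpc <- args$n_markers_per_chromosome
  if (is.null(n_mpc)) n_mpc <- 500L
  chroms <- args$chromosomes
  if (is.null(chroms)) chroms <- barley_chromosomes()
  pc <- panel_config(informative = nrow(chroms) * n_mpc,
                     monomorphic = 0L, single_parent = 0L, unmapped = 0L,
                     parent_het = 0L,
                     genotyping_error_rate = genotyping_error_rate,
                     missing_rate = missing_rate)
  hits <- vapply(seq_len(n_sims), function(i) {
    study <- do.call(simulate_mapping_study,
                     c(list(panel_cfg = pc,
                            seed = (seed * 1009L + i) %% .Machine$integer.max),
                       args))
    isTRUE(map_study_locus(study, max_interruptions)$contains_causal)
  }, logical(1))
  list(rate = mean(hits), hits = hits)
}
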