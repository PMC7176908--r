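#' Transformation efficiency
#'
#' The percentage of cultured immature embryos that give rise to one or
#' more independent transgenic plants: `100 * n_transgenic / n_embryos`.
#' Stored exact; round only for display.
#'
#' @param n_embryos Embryos cultured (> 0); vectorised.
#' @param n_transgenic Embryos yielding at least one transgenic plant
#'   (`0 <= n_transgenic <= n_embryos`).
#' @return Percentage (numeric).
#' @examples
#' compute_te(50, 0)    # 0
#' compute_te(200, 26)  # 13
#' @export
compute_te <- function(n_embryos, n_transgenic) {
  if (any(n_embryos == 0)) stop("transformation efficiency undefined for 0 embryos")
  if (any(n_embryos < 0 | n_transgenic < 0 | n_transgenic > n_embryos)) {
    stop("need 0 <= n_transgenic <= n_embryos")
  }
  100 * n_transgenic / n_embryos
}

#' Aggregate transformation assays per line
#'
#' Returns per-experiment efficiencies and, per line, both the mean of the
#' per-experiment percentages and the pooled-count efficiency
#' (`100 * sum(n_transgenic) / sum(n_embryos)`); summaries of "mean
#' efficiency" can legitimately mean either, so both are reported.
#'
#' @param assays `data.frame` with `line`, `experiment`, `n_embryos`,
#'   `n_transgenic`.
#' @return List: `per_experiment` (input plus `te_percent`), `per_line`
#'   (`line`, `n_experiments`, `n_embryos`, `n_transgenic`,
#'   `te_mean_of_experiments`, `te_pooled`).
#' @export
aggregate_te <- function(assays) {
  stopifnot(all(c("line", "experiment", "n_embryos", "n_transgenic")
                %in% names(assays)))
  assays$te_percent <- compute_te(assays$n_embryos, assays$n_transgenic)
  per_line <- do.call(rbind, lapply(split(assays, assays$line), function(d) {
    data.frame(line = d$line[1], n_experiments = nrow(d),
               n_embryos = sum(d$n_embryos),
               n_transgenic = sum(d$n_transgenic),
               te_mean_of_experiments = mean(d$te_percent),
               te_pooled = compute_te(sum(d$n_embryos), sum(d$n_transgenic)),
               stringsAsFactors = FALSE)
  }))
  rownames(per_line) <- NULL
  list(per_experiment = assays, per_line = per_line)
}

#' Summarise a phenotyped cohort
#'
#' Counts samples per phenotype class, with a per-generation breakdown when
#' the phenotype table carries a `generation` column. Samples present in
#' the genotype matrix but absent from the phenotype table are counted as
#' unknown with a warning; unknowns are excluded from class totals.
#'
#' @param phenotypes `data.frame` with `sample`, `class`, optionally
#'   `generation`.
#' @param matrix Optional encoded genotype matrix whose rownames define the
#'   cohort; defaults to the phenotype table itself.
#' @return List: `class_counts` (named integer vector over the three
#'   classes), `by_generation` (`data.frame` generation x class counts, or
#'   `NULL`), `n_samples`.
#' @export
summarize_cohort <- function(phenotypes, matrix = NULL) {
  check_phenotypes(phenotypes)
  ph <- phenotypes
  if (!is.null(matrix)) {
    extra <- setdiff(rownames(matrix), ph$sample)
    if (length(extra)) {
      warning(length(extra), " sample(s) in matrix absent from phenotype ",
              "table; treated as unknown: ", paste(extra, collapse = ", "))
      add <- data.frame(sample = extra, class = "unknown",
                        stringsAsFactors = FALSE)
      for (nm in setdiff(names(ph), names(add))) add[[nm]] <- NA
      ph <- rbind(ph[names(ph)], add[names(ph)])
    }
    ph <- ph[ph$sample %in% rownames(matrix), , drop = FALSE]
  }
  cls <- factor(ph$class, levels = PHENOTYPE_CLASSES)
  class_counts <- table(cls)
  by_gen <- NULL
  if ("generation" %in% names(ph)) {
    by_gen <- as.data.frame.matrix(table(ph$generation, cls))
    by_gen <- cbind(generation = rownames(by_gen), by_gen)
    rownames(by_gen) <- NULL
  }
  list(class_counts = stats::setNames(as.integer(class_counts), names(class_counts)),
       by_generation = by_gen, n_samples = nrow(ph))
}
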