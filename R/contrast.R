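PHENOTYPE_CLASSES <- c("transformable", "non_transformable", "unknown")

check_phenotypes <- function(phenotypes, samples = NULL) {
  stopifnot(is.data.frame(phenotypes),
            all(c("sample", "class") %in% names(phenotypes)))
  if (!all(phenotypes$class %in% PHENOTYPE_CLASSES)) {
    stop("phenotype class must be one of: ",
         paste(PHENOTYPE_CLASSES, collapse = ", "))
  }
  if (anyDuplicated(phenotypes$sample)) stop("duplicate sample ids in phenotype table")
  if (!is.null(samples)) {
    missing <- setdiff(samples, phenotypes$sample)
    if (length(missing)) {
      stop("samples absent from phenotype table: ",
           paste(missing, collapse = ", "))
    }
  }
  invisible(phenotypes)
}

#' Test one marker for perfect phenotype concordance
#'
#' A marker is concordant when every non-missing call of a transformable
#' sample carries donor material (`"B"`, or `"H"` unless
#' `het_as_donor = FALSE`), every non-missing call of a non-transformable
#' sample is `"A"`, and within each class the missing fraction does not
#' exceed `max_missing_fraction`. Unknown-class samples are ignored. A
#' marker whose evidence is insufficient (a class entirely missing, or too
#' many missing calls) is `"non_evaluable"`, distinct from `"discordant"`.
#'
#' @param column Named character vector of calls for one marker.
#' @param phenotypes Phenotype table (`sample`, `class`).
#' @param max_missing_fraction Tolerated per-class missing fraction
#'   (default 0.1).
#' @param het_as_donor Accept `"H"` as donor-carrying in transformable
#'   samples (default TRUE, the dominance-compatible rule).
#' @return List: `status` (`"concordant"`, `"discordant"`,
#'   `"non_evaluable"`), `n_transformable`, `n_non_transformable`
#'   (non-missing calls per class).
#' @export
marker_concordance <- function(column, phenotypes,
                               max_missing_fraction = 0.1,
                               het_as_donor = TRUE) {
  check_phenotypes(phenotypes, names(column))
  cls <- phenotypes$class[match(names(column), phenotypes$sample)]
  tr <- column[cls == "transformable"]
  nt <- column[cls == "non_transformable"]
  if (!length(tr) || !length(nt)) {
    stop("need at least one sample in each informative phenotype class")
  }
  donor_ok <- if (het_as_donor) c("B", "H") else "B"
  violated <- any(!is.na(tr) & !tr %in% donor_ok) ||
    any(!is.na(nt) & nt != "A")
  status <- if (violated) {
    "discordant"
  } else if (all(is.na(tr)) || all(is.na(nt)) ||
             mean(is.na(tr)) > max_missing_fraction ||
             mean(is.na(nt)) > max_missing_fraction) {
    "non_evaluable"
  } else "concordant"
  list(status = status,
       n_transformable = sum(!is.na(tr)),
       n_non_transformable = sum(!is.na(nt)))
}

# vectorised status over all columns of an encoded matrix
concordance_statuses <- function(matrix, phenotypes,
                                 max_missing_fraction = 0.1,
                                 het_as_donor = TRUE) {
  check_phenotypes(phenotypes, rownames(matrix))
  cls <- phenotypes$class[match(rownames(matrix), phenotypes$sample)]
  Mt <- matrix[cls == "transformable", , drop = FALSE]
  Mn <- matrix[cls == "non_transformable", , drop = FALSE]
  if (!nrow(Mt) || !nrow(Mn)) {
    stop("need at least one sample in each informative phenotype class")
  }
  bad_t <- if (het_as_donor) Mt == "A" else Mt != "B"
  violated <- colSums(bad_t, na.rm = TRUE) > 0L |
    colSums(Mn != "A", na.rm = TRUE) > 0L
  miss_t <- colMeans(is.na(Mt))
  miss_n <- colMeans(is.na(Mn))
  insufficient <- miss_t == 1 | miss_n == 1 |
    miss_t > max_missing_fraction | miss_n > max_missing_fraction
  status <- rep("concordant", ncol(matrix))
  status[insufficient] <- "non_evaluable"
  status[violated] <- "discordant"
  names(status) <- colnames(matrix)
  status
}

new_candidate_region <- function(chrom, inner_start, inner_end,
                                 outer_start, outer_end, markers,
                                 n_tr, n_nt, boundary_samples = NULL) {
  structure(list(chrom = chrom,
                 inner_start_bp = inner_start, inner_end_bp = inner_end,
                 outer_start_bp = outer_start, outer_end_bp = outer_end,
                 concordant_markers = markers,
                 boundary_samples = boundary_samples,
                 n_transformable_support = n_tr,
                 n_non_transformable_support = n_nt),
            class = "candidate_region")
}

#' @export
print.candidate_region <- function(x, ...) {
  cat(sprintf("<candidate_region> %s inner [%s, %s] outer [%s, %s] (%d markers)\n",
              x$chrom, format(x$inner_start_bp, big.mark = ","),
              format(x$inner_end_bp, big.mark = ","),
              format(x$outer_start_bp, big.mark = ","),
              format(x$outer_end_bp, big.mark = ","),
              length(x$concordant_markers)))
  invisible(x)
}

#' Scan the genome for phenotype-concordant candidate regions
#'
#' Evaluates every marker with [marker_concordance()] and merges maximal
#' runs of consecutive concordant markers per chromosome into candidate
#' regions. Non-evaluable markers neither support nor break a run;
#' discordant markers break it. Inner bounds are the first and last
#' concordant marker of the run; outer bounds are the nearest flanking
#' discordant markers (or the chromosome's terminal markers). Regions are
#' ranked by concordant-marker count, ties broken by physical span, both
#' descending.
#'
#' @param matrix Encoded genotype matrix (`"A"`/`"B"`/`"H"`/`NA`).
#' @param phenotypes Phenotype table (`sample`, `class`).
#' @param marker_info `data.frame` with `marker`, `chrom`, `pos_bp` for the
#'   matrix columns.
#' @param max_missing_fraction,het_as_donor See [marker_concordance()].
#' @return List of `candidate_region` objects (possibly empty), ranked.
#' @export
scan_genome <- function(matrix, phenotypes, marker_info,
                        max_missing_fraction = 0.1, het_as_donor = TRUE) {
  status <- concordance_statuses(matrix, phenotypes,
                                 max_missing_fraction, het_as_donor)
  cls <- phenotypes$class[match(rownames(matrix), phenotypes$sample)]
  n_tr <- sum(cls == "transformable")
  n_nt <- sum(cls == "non_transformable")
  mi <- marker_info[match(colnames(matrix), marker_info$marker), , drop = FALSE]
  regions <- list()
  for (cn in unique(mi$chrom)) {
    sel <- which(mi$chrom == cn)
    st <- status[sel]
    pos <- mi$pos_bp[sel]
    mark <- mi$marker[sel]
    evaluable <- st != "non_evaluable"
    idx_eval <- which(evaluable)
    if (!length(idx_eval)) next
    runs <- donor_runs(st[idx_eval] == "concordant", budget = 0L)
    for (r in runs) {
      first <- idx_eval[r$first]; last <- idx_eval[r$last]
      # outer flank: nearest discordant marker beyond the run, else terminal
      left_disc <- idx_eval[idx_eval < first & st[idx_eval] == "discordant"]
      right_disc <- idx_eval[idx_eval > last & st[idx_eval] == "discordant"]
      outer_start <- if (length(left_disc)) pos[max(left_disc)] else pos[1L]
      outer_end <- if (length(right_disc)) pos[min(right_disc)] else pos[length(pos)]
      in_run <- idx_eval[idx_eval >= first & idx_eval <= last]
      conc <- in_run[st[in_run] == "concordant"]
      regions[[length(regions) + 1L]] <- new_candidate_region(
        cn, pos[first], pos[last], outer_start, outer_end,
        markers = mark[conc], n_tr = n_tr, n_nt = n_nt)
    }
  }
  if (!length(regions)) return(regions)
  n_mark <- vapply(regions, function(r) length(r$concordant_markers), integer(1))
  span <- vapply(regions, function(r) r$inner_end_bp - r$inner_start_bp + 1, numeric(1))
  regions[order(-n_mark, -span)]
}

#' Delimit the minimal candidate region from boundary recombinants
#'
#' Refines a scanned region using the donor-carrying spans of the
#' transformable samples: the inner bounds are the intersection of each
#' sample's introgression span overlapping the region (so the samples with
#' the shortest contributions — the boundary recombinants — set the
#' bounds), and the outer bounds are the nearest markers beyond the inner
#' bounds at which any transformable sample carries a recurrent-homozygous
#' call (or the chromosome's terminal markers).
#'
#' @param region A `candidate_region` from [scan_genome()].
#' @param matrix Encoded genotype matrix.
#' @param phenotypes Phenotype table.
#' @param marker_info Marker `data.frame` (`marker`, `chrom`, `pos_bp`).
#' @param max_interruptions Passed to [call_segments()].
#' @return The refined `candidate_region`, with `boundary_samples` =
#'   `list(left =, right =)` naming the samples attaining each inner bound.
#' @export
delimit_minimal_region <- function(region, matrix, phenotypes, marker_info,
                                   max_interruptions = 0L) {
  check_phenotypes(phenotypes, rownames(matrix))
  cls <- phenotypes$class[match(rownames(matrix), phenotypes$sample)]
  tr_samples <- rownames(matrix)[cls == "transformable"]
  if (!length(tr_samples)) stop("no transformable samples")
  starts <- numeric(0); ends <- numeric(0); who <- character(0)
  for (s in tr_samples) {
    segs <- call_segments(matrix[s, ], marker_info, max_interruptions)
    segs <- segs[segs$chrom == region$chrom &
                   segs$start_bp <= region$inner_end_bp &
                   segs$end_bp >= region$inner_start_bp, , drop = FALSE]
    if (!nrow(segs)) next  # span invisible (e.g. all calls missing there)
    ov <- pmin(segs$end_bp, region$inner_end_bp) -
      pmax(segs$start_bp, region$inner_start_bp)
    best <- which.max(ov)
    starts <- c(starts, segs$start_bp[best])
    ends <- c(ends, segs$end_bp[best])
    who <- c(who, s)
  }
  if (!length(starts)) {
    stop("no transformable sample shows a donor span over the region; ",
         "inconsistent with upstream concordance")
  }
  inner_start <- max(starts)
  inner_end <- min(ends)
  if (inner_start > inner_end) {
    stop("donor spans of transformable samples do not intersect; ",
         "discordance missed upstream")
  }
  boundary <- list(left = who[starts == inner_start],
                   right = who[ends == inner_end])
  mi <- marker_info[marker_info$chrom == region$chrom, , drop = FALSE]
  mi <- mi[order(mi$pos_bp), , drop = FALSE]
  Mt <- matrix[tr_samples, mi$marker, drop = FALSE]
  any_a <- colSums(Mt == "A", na.rm = TRUE) > 0L
  left_a <- which(mi$pos_bp < inner_start & any_a)
  right_a <- which(mi$pos_bp > inner_end & any_a)
  outer_start <- if (length(left_a)) mi$pos_bp[max(left_a)] else mi$pos_bp[1L]
  outer_end <- if (length(right_a)) mi$pos_bp[min(right_a)] else mi$pos_bp[nrow(mi)]
  conc <- region$concordant_markers
  new_candidate_region(region$chrom, inner_start, inner_end,
                       min(outer_start, inner_start),
                       max(outer_end, inner_end),
                       markers = conc,
                       n_tr = region$n_transformable_support,
                       n_nt = region$n_non_transformable_support,
                       boundary_samples = boundary)
}

#' Summarise candidate regions as a data frame
#'
#' @param regions List of `candidate_region` objects.
#' @return `data.frame`, one row per region, with bounds, spans and counts.
#' @export
regions_table <- function(regions) {
  if (!length(regions)) {
    return(data.frame(chrom = character(), inner_start_bp = numeric(),
                      inner_end_bp = numeric(), outer_start_bp = numeric(),
                      outer_end_bp = numeric(), n_markers = integer(),
                      inner_span_bp = numeric(), outer_span_bp = numeric()))
  }
  do.call(rbind, lapply(regions, function(r) {
    data.frame(chrom = r$chrom, inner_start_bp = r$inner_start_bp,
               inner_end_bp = r$inner_end_bp, outer_start_bp = r$outer_start_bp,
               outer_end_bp = r$outer_end_bp,
               n_markers = length(r$concordant_markers),
               inner_span_bp = r$inner_end_bp - r$inner_start_bp + 1,
               outer_span_bp = r$outer_end_bp - r$outer_start_bp + 1,
               stringsAsFactors = FALSE)
  }))
}
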