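MARKER_CATEGORIES <- c("MONOMORPHIC", "SINGLE_PARENT", "UNMAPPED",
                       "PARENT_HET", "RETAINED")

normalize_call <- function(x, context = "call") {
  x[x %in% c("", "NA", "NN", "--", "./.")] <- NA_character_
  bad <- !is.na(x) & !x %in% CALL_TOKENS
  if (any(bad)) {
    stop("unknown ", context, " symbol: ", paste(unique(x[bad]), collapse = ", "))
  }
  x
}

#' Classify one marker against the two parental calls
#'
#' Applies the exclusion precedence MONOMORPHIC, SINGLE_PARENT, UNMAPPED,
#' PARENT_HET; only a mapped marker with opposite homozygous parental calls
#' is RETAINED (informative for tracing parental origin). A marker with no
#' call in either parent is folded into SINGLE_PARENT (insufficient parental
#' information) with a warning.
#'
#' @param parent1_call,parent2_call Calls in `"AA"`, `"BB"`, `"AB"` or `NA`.
#' @param has_chromosome Logical: is the marker placed on the physical map?
#' @return One of `"MONOMORPHIC"`, `"SINGLE_PARENT"`, `"UNMAPPED"`,
#'   `"PARENT_HET"`, `"RETAINED"`.
#' @examples
#' classify_marker("AA", "BB", TRUE)   # RETAINED
#' classify_marker("AA", "AA", TRUE)   # MONOMORPHIC
#' @export
classify_marker <- function(parent1_call, parent2_call, has_chromosome) {
  p1 <- normalize_call(parent1_call, "parent call")
  p2 <- normalize_call(parent2_call, "parent call")
  classify_marker_vec(p1, p2, has_chromosome)
}

# vectorised core, inputs already normalized
classify_marker_vec <- function(p1, p2, mapped) {
  hom <- c("AA", "BB")
  both <- !is.na(p1) & !is.na(p2)
  out <- rep(NA_character_, length(p1))
  out[both & p1 == p2 & p1 %in% hom] <- "MONOMORPHIC"
  n_missing <- is.na(p1) + is.na(p2)
  if (any(filled <- is.na(out) & n_missing == 2L)) {
    warning("marker(s) with no call in either parent classified SINGLE_PARENT")
    out[filled] <- "SINGLE_PARENT"
  }
  out[is.na(out) & n_missing == 1L] <- "SINGLE_PARENT"
  out[is.na(out) & !mapped] <- "UNMAPPED"
  out[is.na(out) & (p1 == "AB" | p2 == "AB")] <- "PARENT_HET"
  rest <- is.na(out)
  if (any(rest)) {
    opposite <- (p1[rest] == "AA" & p2[rest] == "BB") |
      (p1[rest] == "BB" & p2[rest] == "AA")
    if (!all(opposite)) stop("unclassifiable marker call combination")
    out[rest] <- "RETAINED"
  }
  out
}

#' Triage a marker panel against its parental calls
#'
#' Classifies every marker into the five categories, returns the retained
#' (informative) sub-panel ordered by chromosome and physical position, and
#' a report whose per-category counts partition the panel exactly.
#'
#' @param panel A `marker_panel` (or data.frame with `marker`, `chrom`,
#'   `pos_bp`, `p1`, `p2`).
#' @return List with `retained` (sub-panel) and `report` (`triage_report`:
#'   `total`, named `counts`, `retained_markers`, `by_chromosome`).
#' @export
triage_panel <- function(panel) {
  if (anyDuplicated(panel$marker)) {
    stop("duplicate marker names: ",
         paste(unique(panel$marker[duplicated(panel$marker)]), collapse = ", "))
  }
  p1 <- normalize_call(panel$p1, "parent call")
  p2 <- normalize_call(panel$p2, "parent call")
  category <- classify_marker_vec(p1, p2, !is.na(panel$chrom))
  counts <- vapply(MARKER_CATEGORIES, function(k) sum(category == k), integer(1))
  retained <- panel[category == "RETAINED", , drop = FALSE]
  ord <- order(retained$chrom, retained$pos_bp)
  retained <- retained[ord, , drop = FALSE]
  rownames(retained) <- NULL
  by_chrom <- table(factor(retained$chrom))
  report <- structure(list(total = nrow(panel), counts = counts,
                           retained_markers = retained$marker,
                           by_chromosome = by_chrom),
                      class = "triage_report")
  stopifnot(sum(report$counts) == report$total)
  list(retained = retained, report = report)
}

#' @export
print.triage_report <- function(x, ...) {
  cat("Marker triage:", x$total, "markers evaluated\n")
  for (k in names(x$counts)) {
    cat(sprintf("  %-13s %6d\n", tolower(k), x$counts[[k]]))
  }
  invisible(x)
}
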