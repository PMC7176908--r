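GENO_CODES <- c("A", "B", "H")

#' Encode progeny calls against the parents (graphical genotypes)
#'
#' Recodes raw allele-pair progeny calls at retained markers relative to
#' the parental calls: equal to the recurrent parent -> `"A"`, equal to the
#' donor -> `"B"`, heterozygous -> `"H"`, no-call -> `NA`. A call matching
#' neither parent and not heterozygous (possible only with call errors
#' upstream) is counted, reported via attribute `n_unresolved`, and set
#' missing.
#'
#' @param raw Character matrix of raw calls (samples x markers, tokens
#'   `"AA"`, `"BB"`, `"AB"`, `NA`).
#' @param recurrent_call,donor_call Per-marker parental calls, aligned to
#'   the columns of `raw`; must be opposite homozygotes.
#' @return Character matrix with entries `"A"`, `"B"`, `"H"`, `NA`
#'   (attribute `n_unresolved` = number of calls matching neither parent).
#' @export
encode_genotypes <- function(raw, recurrent_call, donor_call) {
  stopifnot(is.matrix(raw), length(recurrent_call) == ncol(raw),
            length(donor_call) == ncol(raw))
  rc <- normalize_call(recurrent_call, "recurrent parent call")
  dc <- normalize_call(donor_call, "donor parent call")
  opposite <- (rc == "AA" & dc == "BB") | (rc == "BB" & dc == "AA")
  if (any(is.na(opposite)) || !all(opposite)) {
    stop("markers must carry opposite homozygous parental calls; run triage first")
  }
  raw <- matrix(normalize_call(c(raw), "progeny call"), nrow(raw), ncol(raw),
                dimnames = dimnames(raw))
  enc <- matrix(NA_character_, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  rc_m <- matrix(rc, nrow(raw), ncol(raw), byrow = TRUE)
  dc_m <- matrix(dc, nrow(raw), ncol(raw), byrow = TRUE)
  enc[!is.na(raw) & raw == rc_m] <- "A"
  enc[!is.na(raw) & raw == dc_m] <- "B"
  enc[!is.na(raw) & raw == "AB"] <- "H"
  n_unresolved <- sum(!is.na(raw) & is.na(enc))
  if (n_unresolved > 0L) {
    warning(n_unresolved, " progeny call(s) match neither parent; set missing")
  }
  attr(enc, "n_unresolved") <- n_unresolved
  enc
}

#' Call donor introgression segments in one sample
#'
#' Scans one encoded sample row for maximal runs of consecutive markers
#' carrying donor material (`"B"` or `"H"`). Missing calls are absence of
#' evidence: they never interrupt a run and never support one. A
#' recurrent-homozygous (`"A"`) call terminates a run unless it is part of
#' an isolated interruption: gaps of at most `max_interruptions` consecutive
#' `"A"` markers are absorbed inside a segment (default 0 = strict). Segment
#' bounds are the physical positions of the first and last supporting
#' marker (1-based inclusive bp).
#'
#' @param row Named character vector of `"A"`/`"B"`/`"H"`/`NA` calls, names
#'   = marker names in map order.
#' @param marker_info `data.frame` with `marker`, `chrom`, `pos_bp` aligned
#'   to the row (any order; matched by name).
#' @param max_interruptions Maximum length (in markers) of an `"A"` gap
#'   absorbed inside one segment.
#' @return `data.frame` with one row per segment: `chrom`, `start_bp`,
#'   `end_bp`, `n_markers` (supporting `"B"`/`"H"` markers), `state`
#'   (`"contains_donor_hom"` or `"het_only"`), `start_marker`, `end_marker`.
#' @examples
#' row <- c(m1 = "A", m2 = "A", m3 = "B", m4 = "B", m5 = "H", m6 = "A")
#' info <- data.frame(marker = names(row), chrom = "c1",
#'                    pos_bp = c(10, 20, 30, 40, 50, 60))
#' call_segments(row, info)  # one segment [30, 50], 3 markers
#' @export
call_segments <- function(row, marker_info, max_interruptions = 0L) {
  mi <- marker_info[match(names(row), marker_info$marker), , drop = FALSE]
  if (anyNA(mi$marker)) stop("row contains markers absent from marker_info")
  out <- list()
  for (cn in unique(mi$chrom)) {
    sel <- which(mi$chrom == cn)
    calls <- row[sel]
    pos <- mi$pos_bp[sel]
    mark <- mi$marker[sel]
    keep <- !is.na(calls)               # MISSING neither breaks nor supports
    calls <- calls[keep]; pos <- pos[keep]; mark <- mark[keep]
    if (!length(calls)) next
    segs <- donor_runs(calls == "B" | calls == "H", max_interruptions)
    for (sg in segs) {
      idx <- sg$first:sg$last
      supp <- idx[calls[idx] != "A"]
      out[[length(out) + 1L]] <- data.frame(
        chrom = cn, start_bp = pos[sg$first], end_bp = pos[sg$last],
        n_markers = length(supp),
        state = if (any(calls[supp] == "B")) "contains_donor_hom" else "het_only",
        start_marker = mark[sg$first], end_marker = mark[sg$last],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), n_markers = integer(),
                      state = character(), start_marker = character(),
                      end_marker = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Run merging over a logical vector (TRUE = donor-carrying call): runs of
# TRUE are merged across any gap of at most `budget` consecutive FALSE
# positions (isolated interruptions), so a run may absorb several gaps as
# long as each is short enough. Returns list of list(first=, last=)
# indices; runs always start and end at TRUE positions.
donor_runs <- function(is_donor, budget = 0L) {
  r <- rle(is_donor)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs)) return(list())
  out <- list()
  cur_first <- starts[runs[1]]
  cur_last <- ends[runs[1]]
  for (k in runs[-1]) {
    gap <- starts[k] - cur_last - 1L
    if (gap <= budget) {
      cur_last <- ends[k]
    } else {
      out[[length(out) + 1L]] <- list(first = cur_first, last = cur_last)
      cur_first <- starts[k]
      cur_last <- ends[k]
    }
  }
  out[[length(out) + 1L]] <- list(first = cur_first, last = cur_last)
  out
}

#' Donor-genome fraction estimated from encoded calls
#'
#' `(#B + 0.5 #H) / #non-missing`, the observable analogue of the true
#' donor-genome fraction; a routine QC statistic for backcross depth.
#'
#' @param row Character vector of `"A"`/`"B"`/`"H"`/`NA` calls.
#' @return Numeric in `[0, 1]`.
#' @export
donor_fraction <- function(row) {
  n <- sum(!is.na(row))
  if (n == 0L) stop("donor fraction undefined: all calls missing")
  (sum(row == "B", na.rm = TRUE) + 0.5 * sum(row == "H", na.rm = TRUE)) / n
}
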