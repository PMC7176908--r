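# Independent brute-force implementations used as oracles. These are
# deliberately written as plain per-marker state machines, sharing no code
# with the package internals they check.

# Marker-by-marker segment scan over one chromosome. `k` = maximum length
# of a gap of "A" calls a segment may absorb.
oracle_segments_chrom <- function(calls, pos, k = 0L) {
  keep <- !is.na(calls)
  calls <- calls[keep]; pos <- pos[keep]
  segs <- list()
  n <- length(calls)
  i <- 1L
  while (i <= n) {
    if (calls[i] %in% c("B", "H")) {
      first <- i; last <- i
      pending <- 0L
      j <- i + 1L
      while (j <= n) {
        if (calls[j] %in% c("B", "H")) {
          last <- j
          pending <- 0L
          j <- j + 1L
        } else {
          if (pending + 1L > k) break
          pending <- pending + 1L
          j <- j + 1L
        }
      }
      idx <- first:last
      supp <- idx[calls[idx] != "A"]
      segs[[length(segs) + 1L]] <- data.frame(
        start_bp = pos[first], end_bp = pos[last],
        n_markers = length(supp),
        state = if (any(calls[supp] == "B")) "contains_donor_hom" else "het_only",
        stringsAsFactors = FALSE)
      i <- last + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(segs)) {
    return(data.frame(start_bp = numeric(), end_bp = numeric(),
                      n_markers = integer(), state = character()))
  }
  do.call(rbind, segs)
}

# Per-marker triage category as an explicit if/else chain.
oracle_category <- function(p1, p2, mapped) {
  hom <- c("AA", "BB")
  if (!is.na(p1) && !is.na(p2) && p1 == p2 && p1 %in% hom) return("MONOMORPHIC")
  if (is.na(p1) || is.na(p2)) return("SINGLE_PARENT")
  if (!mapped) return("UNMAPPED")
  if (p1 == "AB" || p2 == "AB") return("PARENT_HET")
  "RETAINED"
}

# Per-marker concordance status as a plain loop over samples.
oracle_status <- function(column, classes, max_missing = 0.1) {
  tr <- column[classes == "transformable"]
  nt <- column[classes == "non_transformable"]
  bad <- FALSE
  for (v in tr) if (!is.na(v) && !v %in% c("B", "H")) bad <- TRUE
  for (v in nt) if (!is.na(v) && v != "A") bad <- TRUE
  if (bad) return("discordant")
  if (all(is.na(tr)) || all(is.na(nt))) return("non_evaluable")
  if (mean(is.na(tr)) > max_missing || mean(is.na(nt)) > max_missing) {
    return("non_evaluable")
  }
  "concordant"
}

# Brute-force genome scan: per-marker status loop + run merging by scanning.
oracle_scan_regions <- function(mat, classes, marker_info, max_missing = 0.1) {
  status <- vapply(colnames(mat), function(m) {
    oracle_status(mat[, m], classes, max_missing)
  }, character(1))
  out <- list()
  for (cn in unique(marker_info$chrom)) {
    sel <- which(marker_info$chrom == cn)
    st <- status[sel]; pos <- marker_info$pos_bp[sel]
    open <- FALSE
    for (i in seq_along(st)) {
      if (st[i] == "concordant") {
        if (!open) { open <- TRUE; first <- i; nmark <- 0L }
        last <- i
        nmark <- nmark + 1L
      } else if (st[i] == "discordant" && open) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = cn, inner_start_bp = pos[first], inner_end_bp = pos[last],
          n_markers = nmark, stringsAsFactors = FALSE)
        open <- FALSE
      }
    }
    if (open) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = cn, inner_start_bp = pos[first], inner_end_bp = pos[last],
        n_markers = nmark, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), inner_start_bp = numeric(),
                      inner_end_bp = numeric(), n_markers = integer()))
  }
  do.call(rbind, out)
}

# Random encoded row with realistic run structure.
random_row <- function(n, p_missing = 0.1) {
  calls <- sample(c("A", "B", "H"), n, replace = TRUE,
                  prob = c(0.6, 0.25, 0.15))
  calls[runif(n) < p_missing] <- NA
  names(calls) <- sprintf("m%03d", seq_len(n))
  calls
}

tiny_marker_info <- function(n, chrom = "c1", step = 10) {
  data.frame(marker = sprintf("m%03d", seq_len(n)), chrom = chrom,
             pos_bp = seq(step, by = step, length.out = n),
             stringsAsFactors = FALSE)
}

# Small two-chromosome map for unit tests.
tiny_map <- function(n_markers = 20, seed = 1) {
  build_map(chromosome_spec(c("c1", "c2"), c(50e6, 40e6), c(80, 60)),
            n_markers, seed = seed)
}
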