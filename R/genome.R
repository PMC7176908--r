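# Haplotypes are run-length encodings of parental origin along the genetic
# axis of one chromosome: list(end = increasing cM breakpoints ending at the
# chromosome length, origin = integer vector, 1 = donor, 0 = recurrent).
# Segment j covers (end[j-1], end[j]] with end[0] = 0. Adjacent segments
# always differ in origin.

#' Origin codes for haplotype segments
#'
#' Integer codes used in haplotype segment encodings: `ORIGIN_DONOR` (1) and
#' `ORIGIN_RECURRENT` (0).
#' @name origins
#' @export
ORIGIN_DONOR <- 1L

#' @rdname origins
#' @export
ORIGIN_RECURRENT <- 0L

new_haplotype <- function(end, origin) {
  list(end = as.numeric(end), origin = as.integer(origin))
}

#' Construct a founder (pure-line) diploid genome
#'
#' Both haplotypes of every chromosome consist of a single segment of the
#' given origin, as for the recurrent or donor parent of a backcross program.
#'
#' @param map A `genetic_map`.
#' @param origin `ORIGIN_DONOR` or `ORIGIN_RECURRENT`.
#' @return A `diploid_genome`: per chromosome a list of two haplotypes.
#' @export
founder_genome <- function(map, origin) {
  stopifnot(origin %in% c(ORIGIN_DONOR, ORIGIN_RECURRENT))
  ch <- map$chromosomes
  g <- lapply(seq_len(nrow(ch)), function(i) {
    h <- new_haplotype(ch$length_cM[i], origin)
    list(h, h)
  })
  names(g) <- ch$name
  structure(g, class = "diploid_genome",
            lengths_cM = stats::setNames(ch$length_cM, ch$name))
}

#' Validate a diploid genome
#'
#' Asserts the segment-tiling invariant for every haplotype: segments cover
#' `[0, length_cM]` exactly with no gaps or overlaps, and adjacent segments
#' differ in origin.
#'
#' @param genome A `diploid_genome`.
#' @return The genome, invisibly; errors otherwise.
#' @export
validate_genome <- function(genome) {
  stopifnot(inherits(genome, "diploid_genome"))
  lens <- attr(genome, "lengths_cM")
  for (cn in names(genome)) {
    for (h in genome[[cn]]) {
      if (length(h$end) != length(h$origin)) stop("haplotype length mismatch on ", cn)
      if (any(diff(h$end) <= 0)) stop("non-increasing breakpoints on ", cn)
      if (abs(h$end[length(h$end)] - lens[[cn]]) > 1e-9) {
        stop("haplotype does not tile chromosome ", cn)
      }
      if (length(h$origin) > 1L && any(diff(h$origin) == 0L)) {
        stop("adjacent segments share origin on ", cn)
      }
      if (!all(h$origin %in% c(0L, 1L))) stop("invalid origin code on ", cn)
    }
  }
  invisible(genome)
}

# Origin of a haplotype at genetic positions (vectorised).
origin_at <- function(hap, pos_cM) {
  idx <- findInterval(pos_cM, hap$end, left.open = TRUE) + 1L
  idx[idx > length(hap$origin)] <- length(hap$origin)
  hap$origin[idx]
}

#' Donor origin dosage at a locus
#'
#' Number of donor alleles (0, 1 or 2) carried by a genome at a genetic
#' position.
#'
#' @param genome A `diploid_genome`.
#' @param chrom Chromosome name.
#' @param cM Genetic position.
#' @return Integer in 0..2.
#' @export
donor_dosage <- function(genome, chrom, cM) {
  if (!chrom %in% names(genome)) stop("locus chromosome not in genome: ", chrom)
  pair <- genome[[chrom]]
  origin_at(pair[[1]], cM) + origin_at(pair[[2]], cM)
}

#' Donor-genome fraction of a diploid genome
#'
#' Fraction of the total genetic map length (over both haplotypes) that
#' derives from the donor parent. Halves in expectation with every
#' backcross: 1/2 in the F1, `2^-(n+1)` after `n` backcrosses.
#'
#' @param genome A `diploid_genome`.
#' @return Numeric in `[0, 1]`.
#' @export
donor_genome_fraction <- function(genome) {
  tot <- 2 * sum(attr(genome, "lengths_cM"))
  donor <- 0
  for (cn in names(genome)) {
    for (h in genome[[cn]]) {
      start <- c(0, h$end[-length(h$end)])
      donor <- donor + sum((h$end - start)[h$origin == ORIGIN_DONOR])
    }
  }
  donor / tot
}

#' True donor-carrying intervals of a genome
#'
#' Genetic intervals (per chromosome) where at least one haplotype is of
#' donor origin; the latent truth behind observed introgression segments.
#'
#' @param genome A `diploid_genome`.
#' @return `data.frame` with `chrom`, `start_cM`, `end_cM`, `dosage_max`.
#' @export
true_donor_intervals <- function(genome) {
  out <- list()
  for (cn in names(genome)) {
    pair <- genome[[cn]]
    cuts <- sort(unique(c(0, pair[[1]]$end, pair[[2]]$end)))
    if (length(cuts) < 2) next
    mid <- (cuts[-1] + cuts[-length(cuts)]) / 2
    dos <- origin_at(pair[[1]], mid) + origin_at(pair[[2]], mid)
    carrier <- dos > 0L
    if (!any(carrier)) next
    r <- rle(carrier)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1L
    keep <- which(r$values)
    for (k in keep) {
      seg <- starts_idx[k]:ends_idx[k]
      out[[length(out) + 1L]] <- data.frame(
        chrom = cn, start_cM = cuts[starts_idx[k]], end_cM = cuts[ends_idx[k] + 1L],
        dosage_max = max(dos[seg]), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start_cM = numeric(),
                      end_cM = numeric(), dosage_max = integer()))
  }
  do.call(rbind, out)
}

#' @export
print.diploid_genome <- function(x, ...) {
  cat("<diploid_genome>", length(x), "chromosomes; donor fraction",
      signif(donor_genome_fraction(x), 3), "\n")
  invisible(x)
}
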