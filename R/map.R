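#' Chromosome specification table
#'
#' Builds the chromosome table used by [build_map()] and the simulator: one
#' row per chromosome with its physical length (bp) and genetic length (cM).
#'
#' @param name Character vector of chromosome labels.
#' @param length_bp Numeric vector of physical lengths in base pairs (> 0).
#' @param length_cM Numeric vector of map lengths in centiMorgans (>= 0).
#' @return A `data.frame` with columns `name`, `length_bp`, `length_cM`.
#' @examples
#' chromosome_spec("chr2H", 600e6, 85)
#' @export
chromosome_spec <- function(name, length_bp, length_cM) {
  name <- as.character(name)
  if (anyDuplicated(name)) stop("duplicate chromosome names")
  if (any(!is.finite(length_bp)) || any(length_bp <= 0)) {
    stop("chromosome length_bp must be positive")
  }
  if (any(!is.finite(length_cM)) || any(length_cM < 0)) {
    stop("chromosome length_cM must be non-negative")
  }
  data.frame(name = name, length_bp = as.numeric(length_bp),
             length_cM = as.numeric(length_cM), stringsAsFactors = FALSE)
}

#' Default barley-like chromosome set
#'
#' Seven chromosomes (1H-7H) of 600 Mbp each, 600 cM genetic length in
#' total, a coarse stand-in for the barley physical map used when no
#' chromosome table is supplied.
#'
#' @return A chromosome specification `data.frame` (see [chromosome_spec()]).
#' @export
barley_chromosomes <- function() {
  chromosome_spec(paste0("chr", 1:7, "H"),
                  rep(600e6, 7), rep(600 / 7, 7))
}

#' Build a marker map over a chromosome set
#'
#' Places `n_markers_per_chromosome` markers uniformly at random along the
#' physical axis of each chromosome and derives genetic positions by linear
#' bp-to-cM scaling (`pos_cM = pos_bp * length_cM / length_bp`). Markers are
#' named `<chrom>_M<index>` in physical order.
#'
#' @param chromosomes Chromosome table from [chromosome_spec()].
#' @param n_markers_per_chromosome Integer >= 1.
#' @param seed Optional integer seed for reproducible placement.
#' @return A `genetic_map` object: a list with elements `chromosomes` and
#'   `markers` (`data.frame` with `marker`, `chrom`, `pos_bp`, `pos_cM`,
#'   sorted by chromosome then position).
#' @examples
#' map <- build_map(chromosome_spec("c1", 100e6, 150), 10, seed = 1)
#' all.equal(map$markers$pos_cM, map$markers$pos_bp * 1.5e-6)
#' @export
build_map <- function(chromosomes, n_markers_per_chromosome, seed = NULL) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length_bp", "length_cM") %in% names(chromosomes)))
  if (any(chromosomes$length_bp <= 0)) stop("chromosome length_bp must be positive")
  n <- as.integer(n_markers_per_chromosome)
  if (is.na(n) || n < 1L) stop("n_markers_per_chromosome must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  markers <- do.call(rbind, lapply(seq_len(nrow(chromosomes)), function(i) {
    ch <- chromosomes[i, ]
    pos <- sort(sample.int(ch$length_bp, n))
    data.frame(marker = sprintf("%s_M%04d", ch$name, seq_len(n)),
               chrom = ch$name,
               pos_bp = as.numeric(pos),
               pos_cM = pos * ch$length_cM / ch$length_bp,
               stringsAsFactors = FALSE)
  }))
  rownames(markers) <- NULL
  map <- structure(list(chromosomes = chromosomes, markers = markers),
                   class = "genetic_map")
  validate_map(map)
  map
}

#' Validate a genetic map
#'
#' Checks the map invariants: markers sorted by (chromosome, bp), genetic
#' position monotone non-decreasing with physical position within each
#' chromosome, and positions within chromosome bounds.
#'
#' @param map A `genetic_map`.
#' @return The map, invisibly; errors otherwise.
#' @export
validate_map <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  m <- map$markers
  ch <- map$chromosomes
  if (!all(m$chrom %in% ch$name)) stop("marker on unknown chromosome")
  for (cn in unique(m$chrom)) {
    sub <- m[m$chrom == cn, ]
    if (is.unsorted(sub$pos_bp)) stop("markers not sorted by position on ", cn)
    if (is.unsorted(sub$pos_cM)) stop("pos_cM not monotone with pos_bp on ", cn)
    len_bp <- ch$length_bp[ch$name == cn]
    len_cM <- ch$length_cM[ch$name == cn]
    if (any(sub$pos_bp < 0 | sub$pos_bp > len_bp)) stop("pos_bp out of range on ", cn)
    if (any(sub$pos_cM < 0 | sub$pos_cM > len_cM + 1e-9)) stop("pos_cM out of range on ", cn)
  }
  invisible(map)
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("<genetic_map>", nrow(x$chromosomes), "chromosomes,",
      nrow(x$markers), "markers\n")
  invisible(x)
}

chrom_length_cM <- function(map, chrom) {
  i <- match(chrom, map$chromosomes$name)
  if (any(is.na(i))) stop("unknown chromosome: ", paste(chrom[is.na(i)], collapse = ", "))
  map$chromosomes$length_cM[i]
}

#' Convert genetic to physical coordinates under the map's linear scaling
#'
#' @param map A `genetic_map`.
#' @param chrom Chromosome name.
#' @param cM Genetic position(s) in centiMorgans.
#' @return Physical position(s) in bp.
#' @export
cm_to_bp <- function(map, chrom, cM) {
  i <- match(chrom, map$chromosomes$name)
  if (any(is.na(i))) stop("unknown chromosome: ", chrom)
  cM * map$chromosomes$length_bp[i] / map$chromosomes$length_cM[i]
}
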