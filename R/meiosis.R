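# Meiosis under the Haldane (no-interference) model: crossover counts are
# Poisson with mean length_cM / 100, positions uniform on the genetic axis,
# and the starting chromatid is a fair coin. No obligate chiasma.

cross_one_chromosome <- function(h1, h2, len_cM) {
  n_xo <- stats::rpois(1L, len_cM / 100)
  first <- sample.int(2L, 1L)
  if (n_xo == 0L) return(if (first == 1L) h1 else h2)
  xo <- sort(stats::runif(n_xo, 0, len_cM))
  haps <- list(h1, h2)
  bounds <- c(xo, len_cM)
  lo <- 0
  cur <- first
  end_out <- numeric(0)
  ori_out <- integer(0)
  for (hi in bounds) {
    if (hi > lo) {
      h <- haps[[cur]]
      j1 <- findInterval(lo, h$end) + 1L                   # first segment meeting [lo, hi)
      j2 <- findInterval(hi, h$end, left.open = TRUE) + 1L # segment containing hi
      j2 <- min(j2, length(h$end))
      idx <- j1:j2
      end_out <- c(end_out, pmin(h$end[idx], hi))
      ori_out <- c(ori_out, h$origin[idx])
      lo <- hi
    }
    cur <- 3L - cur
  }
  # merge adjacent segments of equal origin introduced at crossover points
  n <- length(ori_out)
  if (n > 1L) {
    keep <- c(ori_out[-n] != ori_out[-1L], TRUE)
    end_out <- end_out[keep]
    ori_out <- ori_out[keep]
  }
  new_haplotype(end_out, ori_out)
}

#' Simulate one gamete from a diploid parent
#'
#' Draws, for each chromosome, a Poisson number of crossovers with mean
#' `length_cM / 100`, places them uniformly on the genetic axis, and returns
#' the recombinant haplotype that alternates between the two parental
#' haplotypes at the crossover points, starting from a randomly chosen one.
#'
#' @param parent A `diploid_genome`.
#' @param map A `genetic_map` (chromosome structure must match the parent).
#' @return A gamete: named list of haplotypes, one per chromosome.
#' @export
simulate_gamete <- function(parent, map) {
  lens <- attr(parent, "lengths_cM")
  stopifnot(identical(names(lens), map$chromosomes$name))
  g <- lapply(names(parent), function(cn) {
    pair <- parent[[cn]]
    cross_one_chromosome(pair[[1]], pair[[2]], lens[[cn]])
  })
  names(g) <- names(parent)
  g
}

#' Cross two plants (or self one)
#'
#' The offspring receives one simulated gamete from each parent; passing the
#' same genome twice models self-pollination.
#'
#' @param mother,father `diploid_genome` objects with identical chromosome
#'   structure.
#' @param map A `genetic_map`.
#' @return A `diploid_genome`.
#' @export
make_offspring <- function(mother, father, map) {
  if (!identical(attr(mother, "lengths_cM"), attr(father, "lengths_cM"))) {
    stop("parents have different chromosome structures")
  }
  gm <- simulate_gamete(mother, map)
  gf <- simulate_gamete(father, map)
  g <- lapply(names(gm), function(cn) list(gm[[cn]], gf[[cn]]))
  names(g) <- names(gm)
  structure(g, class = "diploid_genome", lengths_cM = attr(mother, "lengths_cM"))
}
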