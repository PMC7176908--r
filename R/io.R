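# Internal coordinates are 1-based inclusive bp everywhere; conversion to
# BED's 0-based half-open convention happens only in the BED writer/reader.

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(nf)) > 1L) {
    stop("ragged table ", path, ": row ", which(nf != nf[1])[1],
         " has ", nf[nf != nf[1]][1], " fields, expected ", nf[1])
  }
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""))
}

#' Read a genotype matrix from a tab-delimited file
#'
#' First column sample id, remaining header = marker names; cells are raw
#' allele-pair tokens (`AA`/`BB`/`AB`) or encoded codes (`A`/`B`/`H`), with
#' `NA` for no-calls. Duplicate sample or marker names and unknown call
#' tokens are rejected.
#'
#' @param path File path.
#' @return Character matrix, rownames = samples, colnames = markers.
#' @export
read_genotype_table <- function(path) {
  d <- read_tsv_checked(path)
  if (ncol(d) < 2L) stop("genotype table needs a sample column plus markers")
  markers <- colnames(d)[-1]
  if (anyDuplicated(markers)) {
    stop("duplicate marker columns: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "))
  }
  samples <- as.character(d[[1]])
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  m <- as.matrix(d[, -1, drop = FALSE])
  mode(m) <- "character"
  dimnames(m) <- list(samples, markers)
  bad <- !is.na(m) & !m %in% c(CALL_TOKENS, GENO_CODES)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("unknown call token \"", m[bad][1], "\" at sample ",
         samples[w[1]], ", marker ", markers[w[2]])
  }
  m
}

#' Write a genotype matrix as tab-delimited text
#' @param matrix Character matrix (samples x markers).
#' @param path Output path.
#' @export
write_genotype_table <- function(matrix, path) {
  d <- data.frame(sample = rownames(matrix), matrix, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a marker map table
#'
#' Tab-delimited with columns `marker`, `chrom`, `pos_bp` and optionally
#' `pos_cM`; unplaced markers leave `chrom` empty.
#'
#' @param path File path.
#' @return `data.frame` sorted by (chrom, pos_bp), unplaced markers last.
#' @export
read_map_table <- function(path) {
  d <- read_tsv_checked(path)
  need <- c("marker", "chrom", "pos_bp")
  if (!all(need %in% names(d))) {
    stop("map table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(d$marker)) stop("duplicate marker names in map")
  d$pos_bp <- as.numeric(d$pos_bp)
  if (!"pos_cM" %in% names(d)) d$pos_cM <- NA_real_
  d <- d[order(is.na(d$chrom), d$chrom, d$pos_bp), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Write a marker map table
#' @param markers `data.frame` with `marker`, `chrom`, `pos_bp`, `pos_cM`
#'   (a `genetic_map` is also accepted).
#' @param path Output path.
#' @export
write_map_table <- function(markers, path) {
  if (inherits(markers, "genetic_map")) markers <- markers$markers
  utils::write.table(markers, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a phenotype table
#'
#' Tab-delimited with columns `sample`, `class`
#' (transformable/non_transformable/unknown), optional `generation`.
#'
#' @param path File path.
#' @return `data.frame`.
#' @export
read_phenotype_table <- function(path) {
  d <- read_tsv_checked(path)
  if (!all(c("sample", "class") %in% names(d))) {
    stop("phenotype table must have columns sample, class")
  }
  check_phenotypes(d)
  d
}

#' Read a transformation assay table
#'
#' Tab-delimited with columns `line`, `experiment`, `n_embryos`,
#' `n_transgenic`.
#'
#' @param path File path.
#' @return `data.frame`.
#' @export
read_assay_table <- function(path) {
  d <- read_tsv_checked(path)
  need <- c("line", "experiment", "n_embryos", "n_transgenic")
  if (!all(need %in% names(d))) {
    stop("assay table must have columns: ", paste(need, collapse = ", "))
  }
  d$n_embryos <- as.integer(d$n_embryos)
  d$n_transgenic <- as.integer(d$n_transgenic)
  d
}

#' Write candidate regions as BED
#'
#' Converts the chosen interval of each region from internal 1-based
#' inclusive coordinates to BED's 0-based half-open convention and writes
#' with `rtracklayer`.
#'
#' @param regions List of `candidate_region` objects (or a `data.frame`
#'   with `chrom`, `start_bp`, `end_bp`, optional `name`).
#' @param path Output path.
#' @param which `"inner"` or `"outer"` interval (for region objects).
#' @export
write_region_bed <- function(regions, path, which = c("inner", "outer")) {
  which <- match.arg(which)
  if (is.data.frame(regions)) {
    df <- regions
    if (!"name" %in% names(df)) {
      df$name <- sprintf("region_%02d", seq_len(nrow(df)))
    }
  } else {
    df <- do.call(rbind, lapply(seq_along(regions), function(i) {
      r <- regions[[i]]
      data.frame(chrom = r$chrom,
                 start_bp = if (which == "inner") r$inner_start_bp else r$outer_start_bp,
                 end_bp = if (which == "inner") r$inner_end_bp else r$outer_end_bp,
                 name = sprintf("region_%02d_%s", i, which),
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(df) || !nrow(df)) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start_bp, df$end_bp),
                               name = df$name)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read intervals from a BED file (to 1-based inclusive coordinates)
#'
#' @param path BED path.
#' @return `data.frame` with `chrom`, `start_bp`, `end_bp`, `name`.
#' @export
read_region_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), name = character(),
                      stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = "BED")
  d <- as.data.frame(gr)
  data.frame(chrom = as.character(d$seqnames), start_bp = as.numeric(d$start),
             end_bp = as.numeric(d$end),
             name = if ("name" %in% names(d)) as.character(d$name) else NA_character_,
             stringsAsFactors = FALSE)
}

#' Write a structured JSON run report
#'
#' Adds the package version, a timestamp and the seed/config echo expected
#' of every pipeline output.
#'
#' @param report Named list of report content.
#' @param path Output path.
#' @param seed Seed used for the run (echoed), or `NULL`.
#' @param config Config echo (named list), or `NULL`.
#' @export
write_report <- function(report, path, seed = NULL, config = NULL) {
  body <- c(list(tool = "introscan",
                 version = as.character(utils::packageVersion("introscan")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 seed = seed, config = config),
            report)
  jsonlite::write_json(body, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a run configuration file (YAML)
#'
#' @param path YAML file holding breeding/panel/study settings and a seed.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
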