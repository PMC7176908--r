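#' Read a gene annotation from GFF3 or BED
#'
#' Parses the file with `rtracklayer` and returns gene-level records in
#' 1-based inclusive coordinates (BED's 0-based half-open intervals are
#' converted on import). For GFF3 only features of type `"gene"` are kept;
#' a `confidence` column is populated from a GFF3 attribute named
#' `primary_confidence_class` or `confidence` when present (the
#' high-confidence / low-confidence labelling of plant reference
#' annotations), otherwise left `NA`.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return `data.frame` with `gene_id`, `chrom`, `start_bp`, `end_bp`,
#'   `strand`, `confidence`.
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3"),
    error = function(e) stop("failed to parse ", path, " as ", toupper(format),
                             ": ", conditionMessage(e), call. = FALSE))
  md <- as.data.frame(gr)
  if (format == "gff3") {
    if ("type" %in% names(md)) md <- md[md$type == "gene", , drop = FALSE]
    id <- if ("ID" %in% names(md)) md$ID else md$Name
    conf <- if ("primary_confidence_class" %in% names(md)) {
      md$primary_confidence_class
    } else if ("confidence" %in% names(md)) md$confidence else NA_character_
  } else {
    id <- if ("name" %in% names(md)) md$name else
      sprintf("gene_%04d", seq_len(nrow(md)))
    conf <- NA_character_
  }
  if (!nrow(md)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      strand = character(), confidence = character(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(gene_id = as.character(id),
                    chrom = as.character(md$seqnames),
                    start_bp = as.numeric(md$start),
                    end_bp = as.numeric(md$end),
                    strand = as.character(md$strand),
                    confidence = as.character(conf),
                    stringsAsFactors = FALSE)
  if (any(out$start_bp > out$end_bp)) stop("gene with start > end in ", path)
  rownames(out) <- NULL
  out
}

#' Genes intersecting a candidate region
#'
#' Intersects the outer (default) or inner interval of a candidate region
#' with a gene list. `rule = "any"` keeps genes overlapping the interval by
#' at least one bp; `rule = "within"` requires full containment. An
#' optional confidence filter (e.g. `"HC"`) restricts to genes carrying
#' that label.
#'
#' @param region A `candidate_region`.
#' @param genes Gene `data.frame` from [read_annotation()].
#' @param which `"outer"` or `"inner"` interval of the region.
#' @param rule `"any"` (default) or `"within"`.
#' @param confidence Optional confidence label to require.
#' @return List: `genes` (subset data.frame), `count`, `span_bp`
#'   (`end - start + 1` of the chosen interval).
#' @export
genes_in_region <- function(region, genes, which = c("outer", "inner"),
                            rule = c("any", "within"), confidence = NULL) {
  which <- match.arg(which)
  rule <- match.arg(rule)
  start <- if (which == "outer") region$outer_start_bp else region$inner_start_bp
  end <- if (which == "outer") region$outer_end_bp else region$inner_end_bp
  if (nrow(genes) && !region$chrom %in% genes$chrom) {
    stop("chromosome ", region$chrom, " absent from annotation (known: ",
         paste(unique(genes$chrom), collapse = ", "), ")")
  }
  hit <- genes$chrom == region$chrom &
    (if (rule == "any") genes$end_bp >= start & genes$start_bp <= end
     else genes$start_bp >= start & genes$end_bp <= end)
  if (!is.null(confidence)) {
    hit <- hit & !is.na(genes$confidence) & genes$confidence == confidence
  }
  sel <- genes[which(hit), , drop = FALSE]
  rownames(sel) <- NULL
  list(genes = sel, count = nrow(sel), span_bp = end - start + 1)
}
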