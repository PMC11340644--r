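# Interchange formats: GFF3 coding annotations, trait matrices, taxonomy
# configuration.

#' Write / read a coding annotation as GFF3
#'
#' Exports the CDS rows of a [predict_coding_regions()] annotation through
#' rtracklayer; reading re-derives the in-frame gene and protein sequences
#' from the genome, so the round trip reproduces the annotation.
#'
#' @param annotation coding annotation data.frame.
#' @param seqid sequence identifier to record in the file.
#' @param path GFF3 file.
#' @param genome the genome sequence the annotation refers to.
#' @return `read_annotation_gff3()` returns the annotation data.frame.
#' @export
write_annotation_gff3 <- function(annotation, seqid, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("GenomicRanges", quietly = TRUE)) {
    stop("GFF3 export requires the rtracklayer and GenomicRanges packages")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(start = annotation$start,
                              end = annotation$end),
    strand = if (nrow(annotation)) annotation$strand else character(0))
  if (nrow(annotation) > 0) {
    gr$type <- "CDS"
    gr$ID <- sprintf("%s_cds%d", seqid, seq_len(nrow(annotation)))
    gr$phase <- 0L
  }
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @export
read_annotation_gff3 <- function(path, genome) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("GFF3 import requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "GFF3")
  if (length(gr) == 0) return(empty_annotation())
  cand <- data.frame(
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  cand$strand[!cand$strand %in% c("+", "-")] <- "+"
  finish_annotation(cand[order(cand$start), , drop = FALSE],
                    clean_seq(genome))
}

#' Write / read a trait matrix as TSV
#'
#' Tab-separated with the feature names as header and record ids in the
#' first column.
#'
#' @param traits matrix from [encode_trait_matrix()].
#' @param path TSV file.
#' @return `read_trait_matrix()` returns the numeric matrix.
#' @export
write_trait_matrix <- function(traits, path) {
  df <- data.frame(id = rownames(traits), traits, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trait_matrix
#' @export
read_trait_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}

#' Read a host taxonomy from a configuration file
#'
#' Users may override the default host tree with a JSON or YAML file holding
#' `layer1_labels`, `layer2_labels` and `merged_mammal_label` (and
#' optionally `mammal_labels`). The structure is validated before use.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return A `host_taxonomy` object.
#' @export
read_taxonomy <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML taxonomy files require the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    stop("unsupported taxonomy config format: ", ext)
  }
  required <- c("layer1_labels", "layer2_labels", "merged_mammal_label")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0) {
    stop("taxonomy config lacks field(s): ", paste(missing, collapse = ", "))
  }
  if (length(intersect(cfg$layer1_labels, cfg$layer2_labels)) > 0) {
    stop("layer-1 and layer-2 labels must be disjoint")
  }
  structure(
    list(layer1_labels = as.character(cfg$layer1_labels),
         layer2_labels = as.character(cfg$layer2_labels),
         merged_mammal_label = as.character(cfg$merged_mammal_label),
         mammal_labels = as.character(cfg$mammal_labels %||%
                                        character(0))),
    class = "host_taxonomy")
}
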