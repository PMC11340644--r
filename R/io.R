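# Stable file formats and model persistence.

.BUNDLE_FORMAT_VERSION <- "1"
.METADATA_COLUMNS <- c("id", "order", "family", "genus",
                       "host_layer1", "host_layer2")
.PREDICTION_COLUMNS <- c("id", "order", "layer1_label", "layer1_score",
                         "layer2_label", "layer2_score", "rejected",
                         "status")

#' Read genome sequences from FASTA
#'
#' @param path FASTA file (multi-record allowed).
#' @return Named character vector; names are the first whitespace-delimited
#'   token of each header.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- as.character(set)
  names(out) <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1)
  out
}

#' Write genome sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(unlist(sequences))
  names(set) <- names(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a virus metadata table
#'
#' Tab-separated with header `id, order, family, genus, host_layer1,
#' host_layer2`; empty fields mean absent. Rows are validated against the
#' host taxonomy; a malformed row raises an error naming its line.
#'
#' @param path TSV file.
#' @param taxonomy a [host_taxonomy()].
#' @return A validated record table.
#' @export
read_metadata <- function(path, taxonomy = host_taxonomy()) {
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!identical(names(tab), .METADATA_COLUMNS)) {
    stop("metadata header must be: ",
         paste(.METADATA_COLUMNS, collapse = ", "))
  }
  out <- tryCatch(validate_records(tab, taxonomy), error = function(e) {
    stop("invalid metadata in ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  out
}

#' Write a virus metadata table
#'
#' @param records record table.
#' @param path output TSV.
#' @export
write_metadata <- function(records, path) {
  write.table(records[, .METADATA_COLUMNS], path, sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Cross-check FASTA ids against metadata ids
#'
#' @param sequences named character vector.
#' @param records record table.
#' @return List with `fasta_only` and `metadata_only` orphan id sets;
#'   warns when either is non-empty.
#' @export
check_ids <- function(sequences, records) {
  fasta_only <- setdiff(names(sequences), records$id)
  metadata_only <- setdiff(records$id, names(sequences))
  if (length(fasta_only) > 0 || length(metadata_only) > 0) {
    warning(length(fasta_only), " sequence(s) without metadata; ",
            length(metadata_only), " record(s) without sequence")
  }
  list(fasta_only = fasta_only, metadata_only = metadata_only)
}

#' Write / read prediction tables
#'
#' Round-trip faithful TSV of the prediction data.frame produced by
#' [predict.viralhost()].
#'
#' @param predictions prediction data.frame.
#' @param path TSV file.
#' @return `read_predictions()` returns the data.frame.
#' @export
write_predictions <- function(predictions, path) {
  write.table(predictions[, .PREDICTION_COLUMNS], path, sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!identical(names(tab), .PREDICTION_COLUMNS)) {
    stop("prediction table header mismatch in ", path)
  }
  tab$rejected <- as.logical(tab$rejected)
  tab
}

# xgboost handles are external pointers; swap them for raw bytes so the
# bundle survives serialisation.
freeze_models <- function(object) {
  for (ord in names(object$classifiers)) {
    for (layer in c("layer1", "layer2")) {
      lm <- object$classifiers[[ord]][[layer]]
      if (!is.null(lm) && lm$type == "model" &&
          lm$fit$learner == "xgboost") {
        lm$fit$model_raw <- xgboost::xgb.save.raw(lm$fit$model)
        lm$fit$model <- NULL
        object$classifiers[[ord]][[layer]] <- lm
      }
    }
  }
  object
}

thaw_models <- function(object) {
  for (ord in names(object$classifiers)) {
    for (layer in c("layer1", "layer2")) {
      lm <- object$classifiers[[ord]][[layer]]
      if (!is.null(lm) && lm$type == "model" &&
          lm$fit$learner == "xgboost" && !is.null(lm$fit$model_raw)) {
        lm$fit$model <- xgboost::xgb.load.raw(lm$fit$model_raw)
        lm$fit$model_raw <- NULL
        object$classifiers[[ord]][[layer]] <- lm
      }
    }
  }
  object
}

#' Save / load a fitted model bundle
#'
#' The bundle directory holds a JSON manifest (format and trait-layout
#' versions, configuration, aligner backend, training-data fingerprint) and
#' the serialised classifiers. Loading verifies the versions and fails
#' loudly on mismatch or corruption; a reloaded bundle reproduces identical
#' predictions.
#'
#' @param object a fitted [viralhost()] model.
#' @param dir bundle directory (created if needed).
#' @return `load_bundle()` returns the model.
#' @export
save_bundle <- function(object, dir) {
  stopifnot(inherits(object, "viralhost"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(format_version = .BUNDLE_FORMAT_VERSION,
                   layout_version = object$layout_version,
                   config = object$config,
                   fingerprint = object$fingerprint,
                   n_records = object$n_records)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  saveRDS(freeze_models(object), file.path(dir, "bundle.rds"))
  invisible(dir)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  bpath <- file.path(dir, "bundle.rds")
  if (!file.exists(mpath) || !file.exists(bpath)) {
    stop("not a model bundle directory: ", dir)
  }
  manifest <- jsonlite::read_json(mpath)
  if (!identical(as.character(manifest$format_version),
                 .BUNDLE_FORMAT_VERSION)) {
    stop("incompatible bundle format version: ", manifest$format_version)
  }
  object <- tryCatch(readRDS(bpath), error = function(e) {
    stop("corrupted bundle: ", conditionMessage(e), call. = FALSE)
  })
  if (!inherits(object, "viralhost")) stop("corrupted bundle: wrong payload")
  if (!identical(object$layout_version,
                 as.character(manifest$layout_version))) {
    stop("incompatible trait layout version")
  }
  cur <- attr(trait_layout(object$config$feature_set), "layout_version")
  if (!identical(object$layout_version, cur)) {
    stop("bundle trait layout version ", object$layout_version,
         " differs from installed layout ", cur)
  }
  thaw_models(object)
}
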