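# Alignment-based features: per-host-group reference indexes and best-hit
# score vectors.

# Karlin-Altschul parameters matching blastn's gapped defaults for
# match +2 / mismatch -3, gap open 5, gap extend 2.
.KA_LAMBDA <- 0.625
.KA_K <- 0.41
.BUILTIN_EVALUE_CUTOFF <- 1e-5

#' Build a per-host-group reference index
#'
#' Partitions the reference sequences of one classifier scope (a virus order
#' at a given layer) into disjoint groups by host label. Group order follows
#' the taxonomy's fixed label ordering, so homology vectors are reproducible.
#'
#' @param records screened records of the scope.
#' @param sequences named character vector of reference genome sequences.
#' @param layer `"layer1"` or `"layer2"`: which host label defines groups.
#' @param taxonomy a [host_taxonomy()].
#' @return Object of class `group_index`: list with `layer`, `labels`
#'   (ordered), `groups` (named list of record ids) and `sequences`.
#' @export
build_group_index <- function(records, sequences,
                              layer = c("layer1", "layer2"),
                              taxonomy = host_taxonomy()) {
  layer <- match.arg(layer)
  lab <- if (layer == "layer1") records$host_layer1 else records$host_layer2
  if (anyNA(lab)) {
    stop("every record must carry a ", layer, " host label")
  }
  missing_seq <- setdiff(records$id, names(sequences))
  if (length(missing_seq) > 0) {
    stop("no sequence for record(s): ", paste(missing_seq, collapse = ", "))
  }
  if (anyDuplicated(records$id)) stop("duplicate record ids in group index")
  labels <- order_labels_canonically(unique(lab), taxonomy)
  groups <- lapply(labels, function(l) records$id[lab == l])
  names(groups) <- labels
  empty <- labels[vapply(groups, length, 0L) == 0]
  if (length(empty) > 0) {
    stop("host group(s) with zero sequences: ", paste(empty, collapse = ", "))
  }
  structure(
    list(layer = layer, labels = labels, groups = groups,
         sequences = unlist(sequences[records$id])),
    class = "group_index")
}

#' @export
print.group_index <- function(x, ...) {
  cat("group index (", x$layer, "): ", length(x$labels), " host groups\n",
      sep = "")
  for (l in x$labels) cat("  ", l, ": ", length(x$groups[[l]]),
                          " sequences\n", sep = "")
  invisible(x)
}

resolve_aligner <- function(backend = c("auto", "blast", "builtin")) {
  backend <- match.arg(backend)
  if (backend == "auto") {
    if (nzchar(find_executable("blastn")) &&
        nzchar(find_executable("makeblastdb"))) "blast" else "builtin"
  } else backend
}

#' Best local-alignment score per host group
#'
#' For each query and each host group, the maximum pairwise local-alignment
#' bitscore of the query against any group member not excluded; groups with
#' no alignment score the default 1. The `"blast"` backend shells out to
#' BLASTN with default parameters; the `"builtin"` backend is a deterministic
#' Smith-Waterman (match +2, mismatch -3, gap open 5, extend 2) whose raw
#' score is converted to a bitscore and admitted only below a conservative
#' e-value cutoff, since exhaustive local alignment (unlike seeded BLASTN)
#' always produces some chance alignment.
#'
#' @param queries named character vector of query sequences.
#' @param index a [build_group_index()].
#' @param exclude_ids either a character vector of reference ids excluded for
#'   every query, or a named list (by query id) of per-query exclusion sets.
#' @param exclude_self also exclude, per query, the reference with the same
#'   id (training-time leakage control).
#' @param backend `"auto"` (blast when available), `"blast"` or `"builtin"`.
#' @return Numeric matrix `queries x groups` of raw scores (>= 1).
#' @export
best_hit_scores <- function(queries, index, exclude_ids = character(0),
                            exclude_self = FALSE,
                            backend = c("auto", "blast", "builtin")) {
  if (length(queries) == 0) stop("no query sequences")
  if (is.null(names(queries))) names(queries) <- paste0("q", seq_along(queries))
  backend <- resolve_aligner(backend)
  excl <- normalize_exclusions(names(queries), exclude_ids, exclude_self)
  if (backend == "blast") {
    best_hit_blast(queries, index, excl)
  } else {
    best_hit_builtin(queries, index, excl)
  }
}

normalize_exclusions <- function(qids, exclude_ids, exclude_self) {
  if (is.list(exclude_ids)) {
    excl <- lapply(qids, function(q) as.character(exclude_ids[[q]] %||% character(0)))
  } else {
    excl <- rep(list(as.character(exclude_ids)), length(qids))
  }
  names(excl) <- qids
  if (exclude_self) excl <- mapply(function(e, q) union(e, q), excl, qids,
                                   SIMPLIFY = FALSE)
  excl
}

best_hit_blast <- function(queries, index, excl) {
  dir <- tempfile("blast_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  qfa <- file.path(dir, "queries.fa")
  write_fasta(queries, qfa)
  scores <- matrix(1, nrow = length(queries), ncol = length(index$labels),
                   dimnames = list(names(queries), index$labels))
  for (g in index$labels) {
    ids <- index$groups[[g]]
    rfa <- file.path(dir, "refs.fa")
    write_fasta(index$sequences[ids], rfa)
    db <- file.path(dir, "db")
    status <- system2(find_executable("makeblastdb"),
                      c("-in", rfa, "-dbtype", "nucl", "-out", db),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0) stop("makeblastdb failed with exit status ", status)
    out <- file.path(dir, "hits.tsv")
    status <- system2(find_executable("blastn"),
                      c("-query", qfa, "-db", db,
                        "-outfmt", shQuote("6 qseqid sseqid bitscore"),
                        "-max_target_seqs", "10000", "-num_threads", "1",
                        "-out", out),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0 || !file.exists(out)) {
      stop("blastn failed with exit status ", status)
    }
    if (file.size(out) > 0) {
      hits <- read.delim(out, header = FALSE,
                         col.names = c("qseqid", "sseqid", "bitscore"),
                         stringsAsFactors = FALSE)
      for (q in unique(hits$qseqid)) {
        h <- hits[hits$qseqid == q & !(hits$sseqid %in% excl[[q]]), ,
                  drop = FALSE]
        if (nrow(h) > 0) scores[q, g] <- max(1, max(h$bitscore))
      }
    }
  }
  scores
}

builtin_pair_bitscore <- function(query, subject) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  s <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = sm,
    gapOpening = 5, gapExtension = 2, scoreOnly = TRUE)
  bits <- (.KA_LAMBDA * s - log(.KA_K)) / log(2)
  evalue <- .KA_K * nchar(query) * nchar(subject) * exp(-.KA_LAMBDA * s)
  if (evalue > .BUILTIN_EVALUE_CUTOFF) return(NA_real_)
  bits
}

best_hit_builtin <- function(queries, index, excl) {
  scores <- matrix(1, nrow = length(queries), ncol = length(index$labels),
                   dimnames = list(names(queries), index$labels))
  for (qi in seq_along(queries)) {
    q <- names(queries)[qi]
    for (g in index$labels) {
      ids <- setdiff(index$groups[[g]], excl[[q]])
      best <- 1
      for (id in ids) {
        b <- builtin_pair_bitscore(queries[[qi]], index$sequences[[id]])
        if (!is.na(b) && b > best) best <- b
      }
      scores[q, g] <- best
    }
  }
  scores
}

#' Encode raw best-hit scores as a homology vector
#'
#' Applies the log10 transform; the default raw score 1 (no alignment) maps
#' to 0. Raw scores below 1 are clamped to 1 with a warning.
#'
#' @param raw_scores numeric vector or matrix of raw best-hit scores with
#'   group names.
#' @return log10-transformed scores, same shape and names.
#' @export
encode_homology <- function(raw_scores) {
  if (any(raw_scores < 1)) {
    warning("raw alignment scores below 1 clamped to 1")
    raw_scores[raw_scores < 1] <- 1
  }
  log10(raw_scores)
}

#' Concatenate trait and homology features
#'
#' Joins the genomic-trait block and the homology block into the classifier
#' input `X = [S | H]` of length `length(S) + m`. Row names (query ids) must
#' agree between the two blocks.
#'
#' @param trait trait vector or matrix (rows = queries).
#' @param hom homology vector or matrix (rows = queries, columns = groups).
#' @return Feature matrix with preserved feature names.
#' @export
concatenate_features <- function(trait, hom) {
  if (is.null(dim(trait))) trait <- matrix(trait, nrow = 1,
                                           dimnames = list(NULL, names(trait)))
  if (is.null(dim(hom))) hom <- matrix(hom, nrow = 1,
                                       dimnames = list(NULL, names(hom)))
  if (ncol(hom) < 2) stop("homology block must span at least 2 host groups")
  if (nrow(trait) != nrow(hom)) {
    stop("trait and homology blocks describe different query sets")
  }
  if (!is.null(rownames(trait)) && !is.null(rownames(hom)) &&
      !identical(rownames(trait), rownames(hom))) {
    stop("trait and homology blocks describe different query sets")
  }
  colnames(hom) <- paste0("hom_", colnames(hom))
  cbind(trait, hom)
}
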