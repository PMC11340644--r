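# Fixed two-layer host taxonomy, label screening and per-order prediction modes.

.LAYER1 <- c("Chordata", "Invertebrate", "Viridiplantae", "Fungi", "Bacteria")
.LAYER2 <- c("Primates", "Rodentia", "Carnivora", "Artiodactyla", "Chiroptera",
             "Other Mammalia", "Aves", "Reptilia", "Amphibia", "Fish")
.MERGED_MAMMAL <- "Mammalia"
.MAMMAL_CLASSES <- c("Primates", "Rodentia", "Carnivora", "Artiodactyla",
                     "Chiroptera", "Other Mammalia")

#' The fixed two-layer host taxonomy
#'
#' Layer 1 holds five kingdom/phylum branches (Chordata, Invertebrate,
#' Viridiplantae, Fungi, Bacteria). Layer 2 refines Chordata into ten
#' class/order leaves (Primates, Rodentia, Carnivora, Artiodactyla,
#' Chiroptera, Other Mammalia, Aves, Reptilia, Amphibia, Fish). When an
#' order's mammalian records are sparse, the six mammalian leaves collapse
#' into the single merged label `"Mammalia"` (see [screen_labels()]).
#'
#' @return An object of class `host_taxonomy`: a list with `layer1_labels`,
#'   `layer2_labels`, `merged_mammal_label` and `mammal_labels`.
#' @examples
#' tax <- host_taxonomy()
#' length(tax$layer1_labels)  # 5
#' length(tax$layer2_labels)  # 10
#' @export
host_taxonomy <- function() {
  structure(
    list(layer1_labels = .LAYER1,
         layer2_labels = .LAYER2,
         merged_mammal_label = .MERGED_MAMMAL,
         mammal_labels = .MAMMAL_CLASSES),
    class = "host_taxonomy")
}

#' @export
print.host_taxonomy <- function(x, ...) {
  cat("Two-layer host taxonomy\n")
  cat("  layer 1:", paste(x$layer1_labels, collapse = ", "), "\n")
  cat("  layer 2 (under Chordata):", paste(x$layer2_labels, collapse = ", "), "\n")
  cat("  merged mammal label:", x$merged_mammal_label, "\n")
  invisible(x)
}

# All layer-2 labels that may legally appear after screening.
layer2_universe <- function(taxonomy = host_taxonomy()) {
  c(taxonomy$layer2_labels, taxonomy$merged_mammal_label)
}

# Canonical ordering used for deterministic tie-breaks: layer-1 branches
# first, then layer-2 leaves, then the merged mammal label.
canonical_label_order <- function(taxonomy = host_taxonomy()) {
  c(taxonomy$layer1_labels, taxonomy$layer2_labels, taxonomy$merged_mammal_label)
}

order_labels_canonically <- function(labels, taxonomy = host_taxonomy()) {
  canon <- canonical_label_order(taxonomy)
  labels[order(match(labels, canon))]
}

#' Validate a table of virus records
#'
#' A record table has columns `id`, `order`, `family`, `genus`,
#' `host_layer1`, `host_layer2` (family/genus/host_layer2 may be `NA`).
#' Checks label validity against the taxonomy, id uniqueness, and the
#' constraint that a layer-2 host implies `host_layer1 == "Chordata"`.
#'
#' @param records data.frame of virus records.
#' @param taxonomy a [host_taxonomy()].
#' @return The records, with blank strings normalised to `NA`, invisibly
#'   usable downstream.
#' @export
validate_records <- function(records, taxonomy = host_taxonomy()) {
  required <- c("id", "order", "host_layer1")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("record table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("family", "genus", "host_layer2")) {
    if (!col %in% names(records)) records[[col]] <- NA_character_
  }
  for (col in c("id", "order", "family", "genus", "host_layer1", "host_layer2")) {
    records[[col]] <- as.character(records[[col]])
    records[[col]][is_blank(records[[col]])] <- NA_character_
  }
  if (anyNA(records$id)) stop("record ids must be non-empty")
  dup <- records$id[duplicated(records$id)]
  if (length(dup) > 0) {
    stop("duplicated record id(s): ", paste(unique(dup), collapse = ", "))
  }
  # Multi-label metadata (several layer-1 hosts separated by ',' or ';') is
  # legal input here; screen_labels() removes such records.
  multi <- grepl("[,;]", records$host_layer1)
  l1 <- records$host_layer1[!multi]
  bad <- !is.na(l1) & !(l1 %in% taxonomy$layer1_labels)
  if (any(bad)) {
    stop("unknown layer-1 host label for record(s): ",
         paste(records$id[!multi][bad], collapse = ", "))
  }
  l2 <- records$host_layer2
  bad2 <- !is.na(l2) & !(l2 %in% layer2_universe(taxonomy))
  if (any(bad2)) {
    stop("unknown layer-2 host label for record(s): ",
         paste(records$id[bad2], collapse = ", "))
  }
  conflict <- !is.na(l2) & !multi & !is.na(records$host_layer1) &
    records$host_layer1 != "Chordata"
  if (any(conflict)) {
    stop("layer-2 host without Chordata layer-1 label for record(s): ",
         paste(records$id[conflict], collapse = ", "))
  }
  records
}

# Leaf label across the full two-layer tree: the layer-2 label when present,
# otherwise the layer-1 branch.
leaf_label <- function(records) {
  ifelse(is.na(records$host_layer2), records$host_layer1, records$host_layer2)
}

#' Screen reference host labels
#'
#' Applies the reference-curation rules before training. Records whose
#' metadata lists several layer-1 hosts (separated by `,` or `;`) are removed
#' first. Then, per virus order: (i) if the order's mammalian layer-2 records
#' number fewer than `mammal_merge_threshold`, all mammalian leaves are
#' relabelled to the merged `"Mammalia"` node; (ii) in orders with more than
#' `min_order_size` records, host labels carried by fewer than
#' `min_label_count` records are dropped (layer-1 branches and layer-2 leaves
#' are each subject to the count rule; the merged Mammalia node counts as an
#' ordinary layer-2 label). The merge/filter pass is repeated until the
#' dataset is stable, which makes screening idempotent. Orders with at most
#' `min_order_size` records keep all their labels and are flagged `small`.
#'
#' @param records validated record table (see [validate_records()]).
#' @param min_order_size label-count filtering applies only to orders with
#'   strictly more records than this (default 30).
#' @param min_label_count minimum records per retained host label in a large
#'   order (default 10).
#' @param mammal_merge_threshold orders whose mammalian layer-2 records total
#'   fewer than this are merged into `"Mammalia"` (default 50).
#' @param taxonomy a [host_taxonomy()].
#' @return A list with `records` (the screened table) and `report`, a
#'   per-order data.frame of counts in/out, drops, merges and the `small`
#'   flag.
#' @export
screen_labels <- function(records, min_order_size = 30, min_label_count = 10,
                          mammal_merge_threshold = 50,
                          taxonomy = host_taxonomy()) {
  records <- validate_records(records, taxonomy)
  n_start <- table(records$order)

  multi <- grepl("[,;]", records$host_layer1)
  dropped_multi <- table(records$order[multi])
  records <- records[!multi, , drop = FALSE]

  dropped_low <- setNames(rep(0L, length(n_start)), names(n_start))
  merged <- setNames(rep(FALSE, length(n_start)), names(n_start))

  repeat {
    changed <- FALSE
    # Mammal merge: per order, collapse sparse mammalian leaves.
    for (ord in unique(records$order)) {
      sel <- records$order == ord
      is_mam <- sel & !is.na(records$host_layer2) &
        records$host_layer2 %in% taxonomy$mammal_labels
      n_mam <- sum(is_mam)
      if (n_mam > 0 && n_mam < mammal_merge_threshold) {
        records$host_layer2[is_mam] <- taxonomy$merged_mammal_label
        merged[ord] <- TRUE
        changed <- TRUE
      }
    }
    # Label-count filter in orders with more than min_order_size records.
    keep <- rep(TRUE, nrow(records))
    for (ord in unique(records$order)) {
      sel <- which(records$order == ord)
      if (length(sel) <= min_order_size) next
      l1 <- records$host_layer1[sel]
      l2 <- records$host_layer2[sel]
      cnt1 <- table(l1)
      cnt2 <- table(l2[!is.na(l2)])
      low <- cnt1[l1] < min_label_count
      low2 <- !is.na(l2) & cnt2[l2] < min_label_count
      drop_here <- low | low2
      if (any(drop_here)) {
        keep[sel[drop_here]] <- FALSE
        dropped_low[ord] <- dropped_low[ord] + sum(drop_here)
        changed <- TRUE
      }
    }
    records <- records[keep, , drop = FALSE]
    if (!changed) break
  }

  orders <- names(n_start)
  report <- data.frame(
    order = orders,
    n_in = as.integer(n_start),
    dropped_multi_label = as.integer(ifelse(orders %in% names(dropped_multi),
                                            dropped_multi[orders], 0L)),
    dropped_low_count = as.integer(dropped_low[orders]),
    mammal_merged = as.logical(merged[orders]),
    n_out = as.integer(table(factor(records$order, levels = orders))),
    stringsAsFactors = FALSE)
  report$small <- report$n_in <= min_order_size
  rownames(report) <- NULL
  list(records = records, report = report)
}

#' Decide a virus order's prediction mode
#'
#' An order whose reference records carry exactly one distinct leaf label
#' across the two-layer tree is a direct-assignment order: queries routed to
#' it receive that label without a trained model. Orders whose records carry
#' any layer-2 label are two-layer orders (they receive predictions in the
#' second layer; a second layer with a single label degrades to a direct
#' assignment at that layer). All remaining orders are layer-1-only.
#'
#' @param records records of a single virus order, already screened.
#' @return A list of class `order_mode` with `mode` (one of
#'   `"direct_assign"`, `"layer1_only"`, `"two_layer"`) and, for direct
#'   assignment, `direct_label`.
#' @export
order_mode <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop("order_mode() requires at least one record")
  }
  if (length(unique(records$order)) != 1) {
    stop("order_mode() expects records of a single virus order")
  }
  leaves <- unique(leaf_label(records))
  has_l2 <- any(!is.na(records$host_layer2))
  if (length(leaves) == 1) {
    out <- list(mode = "direct_assign", direct_label = leaves)
  } else if (has_l2) {
    out <- list(mode = "two_layer", direct_label = NULL)
  } else {
    out <- list(mode = "layer1_only", direct_label = NULL)
  }
  structure(out, class = "order_mode")
}

#' @export
print.order_mode <- function(x, ...) {
  cat("order mode:", x$mode)
  if (!is.null(x$direct_label)) cat(" ->", x$direct_label)
  cat("\n")
  invisible(x)
}

#' Host homogeneity of a virus family
#'
#' The fraction `r` of a family's members carrying the family's dominant
#' layer-1 host label. Ties between equally frequent labels are broken by the
#' taxonomy's fixed label order, so the statistic is deterministic.
#'
#' @param records records of one virus family (non-empty).
#' @param taxonomy a [host_taxonomy()].
#' @return A number in `[0, 1]`; the dominant label is attached as attribute
#'   `"dominant"`.
#' @export
host_homogeneity <- function(records, taxonomy = host_taxonomy()) {
  if (is.null(records) || nrow(records) == 0) {
    stop("host_homogeneity() requires at least one record")
  }
  counts <- table(records$host_layer1)
  labs <- order_labels_canonically(names(counts), taxonomy)
  counts <- counts[labs]
  dominant <- labs[which.max(counts)]
  r <- as.numeric(max(counts)) / nrow(records)
  structure(r, dominant = dominant)
}

#' Packaged host-distribution table
#'
#' The per-order host-label distribution of the screened 14,500-virus
#' reference corpus: 30 virus orders, total counts and the percentage of
#' records per layer-1 branch and per layer-2 leaf (the `Mammalia` column
#' carries the merged mammal node used where mammalian records were sparse).
#'
#' @return A data.frame, one row per virus order.
#' @export
host_distribution_table <- function() {
  path <- system.file("extdata", "host_distribution.tsv", package = "viralhost")
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' The default virus-order registry
#'
#' @return Character vector of the 30 virus orders supported by default.
#' @export
default_virus_orders <- function() {
  host_distribution_table()$order
}

#' Expand a host-distribution table into pseudo-records
#'
#' Converts each order's percentages back into that many individual records
#' (counts are `round(pct * n / 100)`), so that record-level operations such
#' as [order_mode()] can be applied to the packaged distribution.
#'
#' @param tbl a table as returned by [host_distribution_table()].
#' @param taxonomy a [host_taxonomy()].
#' @return A record table (see [validate_records()]).
#' @export
distribution_to_records <- function(tbl, taxonomy = host_taxonomy()) {
  l1_cols <- taxonomy$layer1_labels
  l2_cols <- layer2_universe(taxonomy)
  rows <- vector("list", nrow(tbl))
  for (i in seq_len(nrow(tbl))) {
    ord <- tbl$order[i]
    n <- tbl$n[i]
    ids <- character(0); l1 <- character(0); l2 <- character(0)
    n_l2_total <- 0L
    for (lab in l2_cols) {
      pct <- tbl[[lab]][i]
      if (!is.na(pct) && pct > 0) {
        k <- round(pct * n / 100)
        l1 <- c(l1, rep("Chordata", k))
        l2 <- c(l2, rep(lab, k))
        n_l2_total <- n_l2_total + k
      }
    }
    for (lab in setdiff(l1_cols, "Chordata")) {
      pct <- tbl[[lab]][i]
      if (!is.na(pct) && pct > 0) {
        k <- round(pct * n / 100)
        l1 <- c(l1, rep(lab, k))
        l2 <- c(l2, rep(NA_character_, k))
      }
    }
    ch <- tbl[["Chordata"]][i]
    if (!is.na(ch) && ch > 0) {
      extra <- round(ch * n / 100) - n_l2_total
      if (extra > 0 && n_l2_total == 0) {
        # Chordata order with no layer-2 breakdown in the table.
        l1 <- c(l1, rep("Chordata", extra))
        l2 <- c(l2, rep(NA_character_, extra))
      }
    }
    rows[[i]] <- data.frame(
      id = sprintf("%s_%05d", ord, seq_along(l1)),
      order = ord, family = NA_character_, genus = NA_character_,
      host_layer1 = l1, host_layer2 = l2, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
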