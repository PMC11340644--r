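# Evaluation harnesses: stratified cross-validation, metric computation,
# fragment-completeness, leave-one-genus-out with null models, challenging
# cases and family-wise homogeneity analysis.

#' Stratified k-fold partition
#'
#' Partitions records into k disjoint folds stratified by host label: within
#' each label the (seed-shuffled) records are dealt to folds in rotation, so
#' per-label fold sizes differ by at most one. Labels with fewer than k
#' members degrade to best-effort allocation with a warning.
#'
#' @param records record table.
#' @param k number of folds (default 5).
#' @param seed integer seed; identical seeds give identical folds.
#' @param label stratification label per record; defaults to the leaf host
#'   label (layer 2 when present, else layer 1).
#' @return List of k elements, each a list with `train` and `test` id sets.
#' @export
stratified_kfold <- function(records, k = 5, seed = 1, label = NULL) {
  if (is.null(label)) label <- leaf_label(records)
  stopifnot(length(label) == nrow(records))
  counts <- table(label)
  if (any(counts < k)) {
    warning("label(s) with fewer than k members: ",
            paste(names(counts)[counts < k], collapse = ", "),
            "; allocation is best-effort")
  }
  fold_of <- integer(nrow(records))
  with_seed(seed, {
    for (lab in names(counts)) {
      idx <- which(label == lab)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  lapply(seq_len(k), function(f) {
    list(train = records$id[fold_of != f], test = records$id[fold_of == f])
  })
}

#' Prediction metrics
#'
#' Accuracy counts rejected queries as incorrect; prediction rate is the
#' fraction of non-rejected queries; precision is the fraction of correct
#' calls among the non-rejected ones. Macro F1 averages per-label F1 scores
#' (a rejected query of label L counts as a false negative for L). Rank-wise
#' accuracies are unweighted means of per-taxon accuracies over the taxa
#' present in the truth. The confusion matrix is row-normalised per true
#' label over the non-rejected predictions.
#'
#' @param truth character vector of true host labels.
#' @param predicted character vector of predicted labels (`NA` when
#'   rejected).
#' @param rejected logical vector (defaults to `is.na(predicted)`).
#' @param order,family,genus optional taxon annotations aligned with
#'   `truth`, enabling the rank-wise accuracies.
#' @param labels label universe for the confusion matrix; defaults to the
#'   union of truth and predictions, taxonomy-ordered.
#' @param taxonomy a [host_taxonomy()].
#' @return A list of class `metric_report`.
#' @export
compute_metrics <- function(truth, predicted, rejected = NULL,
                            order = NULL, family = NULL, genus = NULL,
                            labels = NULL, taxonomy = host_taxonomy()) {
  n <- length(truth)
  stopifnot(length(predicted) == n)
  if (is.null(rejected)) rejected <- is.na(predicted)
  correct <- !rejected & !is.na(predicted) & predicted == truth
  if (is.null(labels)) {
    labels <- order_labels_canonically(
      unique(c(truth, predicted[!is.na(predicted)])), taxonomy)
  }
  acc <- mean(correct)
  pred_rate <- mean(!rejected)
  precision <- if (any(!rejected)) sum(correct) / sum(!rejected) else NA_real_
  f1 <- vapply(order_labels_canonically(unique(truth), taxonomy),
               function(lab) {
    tp <- sum(correct & truth == lab)
    fp <- sum(!rejected & !is.na(predicted) & predicted == lab &
                truth != lab)
    fn <- sum(truth == lab) - tp
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 0)
  macro_f1 <- mean(f1)
  rankwise <- function(taxa) {
    if (is.null(taxa)) return(NA_real_)
    mean(vapply(unique(taxa), function(t) mean(correct[taxa == t]), 0))
  }
  conf <- matrix(0, nrow = length(labels), ncol = length(labels),
                 dimnames = list(truth = labels, predicted = labels))
  sel <- !rejected & !is.na(predicted)
  if (any(sel)) {
    tab <- table(factor(truth[sel], levels = labels),
                 factor(predicted[sel], levels = labels))
    rs <- rowSums(tab)
    conf <- sweep(tab, 1, pmax(rs, 1), "/")
    conf <- as.matrix(conf)
  }
  structure(
    list(n = n, accuracy = acc, prediction_rate = pred_rate,
         precision = precision, macro_f1 = macro_f1, per_label_f1 = f1,
         order_wise_accuracy = rankwise(order),
         family_wise_accuracy = rankwise(family),
         genus_wise_accuracy = rankwise(genus),
         confusion = conf),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("n = %d | accuracy %.4f | prediction rate %.4f | precision %s | macro F1 %.4f\n",
              x$n, x$accuracy, x$prediction_rate,
              ifelse(is.na(x$precision), "NA", sprintf("%.4f", x$precision)),
              x$macro_f1))
  if (!is.na(x$order_wise_accuracy)) {
    cat(sprintf("  order-wise %.4f", x$order_wise_accuracy))
    if (!is.na(x$family_wise_accuracy)) {
      cat(sprintf(" | family-wise %.4f", x$family_wise_accuracy))
    }
    if (!is.na(x$genus_wise_accuracy)) {
      cat(sprintf(" | genus-wise %.4f", x$genus_wise_accuracy))
    }
    cat("\n")
  }
  invisible(x)
}

layer2_truth_correct <- function(records, pred) {
  ok1 <- !pred$rejected & !is.na(pred$layer1_label) &
    pred$layer1_label == records$host_layer1
  ok2 <- !is.na(pred$layer2_label) & !is.na(records$host_layer2) &
    pred$layer2_label == records$host_layer2
  ok1 & ok2
}

#' Stratified cross-validation of the full pipeline
#'
#' Screens the references once, then runs k-fold cross-validation: per fold
#' a model is fitted on the training records (homology references drawn from
#' the training fold only) and evaluated on the held-out fold. Layer-2
#' evaluation is restricted to records carrying a layer-2 label and
#' compounds layer-1 errors (a layer-1 miss counts as a layer-2 error).
#' Models are fitted without rejection calibration so the metrics describe
#' the raw classifier.
#'
#' @param records record table.
#' @param sequences named character vector of genome sequences.
#' @param k folds (default 5).
#' @param seed integer seed.
#' @param ... passed on to [viralhost()] (e.g. `feature_set`, `aligner`).
#' @return List with `predictions`, `metrics_layer1`, `metrics_layer2`,
#'   `folds`.
#' @export
cross_validate <- function(records, sequences, k = 5, seed = 1, ...) {
  records <- validate_records(records)
  sc <- screen_labels(records)
  records <- sc$records
  dots <- list(...)
  feature_set <- dots$feature_set %||% "sbias"
  traits <- encode_trait_matrix(sequences[records$id],
                                feature_set = feature_set)
  folds <- stratified_kfold(records, k = k, seed = seed)
  preds <- list()
  for (f in seq_len(k)) {
    stopifnot(length(intersect(folds[[f]]$train, folds[[f]]$test)) == 0)
    tr <- records[records$id %in% folds[[f]]$train, , drop = FALSE]
    te <- records[records$id %in% folds[[f]]$test, , drop = FALSE]
    args <- c(list(records = tr, sequences = sequences, seed = seed,
                   screen = FALSE, calibrate = FALSE,
                   trait_matrix = traits), dots)
    fit <- do.call(viralhost, args)
    p <- predict(fit, sequences[te$id], orders = te$order)
    p$fold <- f
    preds[[f]] <- p
  }
  pred <- do.call(rbind, preds)
  pred <- pred[match(records$id, pred$id), , drop = FALSE]
  m1 <- compute_metrics(records$host_layer1, pred$layer1_label,
                        rejected = pred$rejected, order = records$order,
                        family = records$family, genus = records$genus)
  has_l2 <- !is.na(records$host_layer2)
  m2 <- NULL
  if (any(has_l2)) {
    r2 <- records[has_l2, , drop = FALSE]
    p2 <- pred[has_l2, , drop = FALSE]
    correct2 <- layer2_truth_correct(r2, p2)
    eff_pred <- ifelse(correct2, r2$host_layer2,
                       ifelse(is.na(p2$layer2_label), NA, p2$layer2_label))
    m2 <- compute_metrics(r2$host_layer2, eff_pred,
                          rejected = p2$rejected | is.na(p2$layer2_label),
                          order = r2$order, family = r2$family,
                          genus = r2$genus)
  }
  list(predictions = pred, metrics_layer1 = m1, metrics_layer2 = m2,
       folds = folds)
}

#' Generate fragmented query contigs
#'
#' For each completeness ratio, cuts exactly one contig per input sequence:
#' a contiguous substring of length `round(ratio * L)` whose start position
#' is uniform at random under the fixed seed.
#'
#' @param sequences named character vector (each >= 100 bp).
#' @param ratios completeness ratios (defaults 0.90, 0.75, 0.60, 0.45).
#' @param seed integer seed; identical seeds give identical contigs.
#' @return Named list (one element per ratio, named e.g. `"90"`) of named
#'   character vectors of contigs.
#' @export
fragment_queries <- function(sequences, ratios = c(0.90, 0.75, 0.60, 0.45),
                             seed = 1) {
  if (any(nchar(sequences) < 100)) stop("sequences must be at least 100 bp")
  out <- list()
  with_seed(seed, {
    for (r in ratios) {
      frag <- vapply(sequences, function(sq) {
        L <- nchar(sq)
        len <- round(r * L)
        start <- sample.int(L - len + 1, 1)
        substring(sq, start, start + len - 1)
      }, character(1))
      names(frag) <- names(sequences)
      out[[sprintf("%g", 100 * r)]] <- frag
    }
  })
  out
}

#' Empirical host-label distribution
#'
#' @param records record table.
#' @param layer `"layer1"` or `"layer2"`.
#' @param taxonomy a [host_taxonomy()].
#' @return Named numeric vector of label frequencies in the taxonomy's fixed
#'   label order (so argmax ties break deterministically).
#' @export
label_distribution <- function(records, layer = "layer1",
                               taxonomy = host_taxonomy()) {
  lab <- layer_labels(records, layer)
  lab <- lab[!is.na(lab)]
  if (length(lab) == 0) stop("no labels at ", layer)
  tab <- table(lab)
  labs <- order_labels_canonically(names(tab), taxonomy)
  p <- as.numeric(tab[labs]) / sum(tab)
  setNames(p, labs)
}

#' Null model 1: sample labels from the training distribution
#'
#' @param distribution named numeric label distribution
#'   (see [label_distribution()]).
#' @param n_queries number of labels to draw.
#' @param seed integer seed.
#' @return Character vector of sampled labels.
#' @export
null_model_1 <- function(distribution, n_queries, seed = 1) {
  if (length(distribution) == 0) stop("empty label distribution")
  with_seed(seed, sample(names(distribution), n_queries, replace = TRUE,
                         prob = distribution))
}

#' Null model 2: always the dominant training label
#'
#' Ties between equally frequent labels break by the distribution's fixed
#' label order.
#'
#' @param distribution named numeric label distribution.
#' @return Single label.
#' @export
null_model_2 <- function(distribution) {
  if (length(distribution) == 0) stop("empty label distribution")
  names(distribution)[which.max(distribution)]
}

#' Flag challenging genera
#'
#' Case 1: the genus's dominant layer-1 host label differs from its order's.
#' Case 2: it differs from its family's. Case 3: the genus's members infect
#' hosts of at least two layer-1 branches. Cases are not mutually exclusive;
#' dominant labels are computed on layer 1 with taxonomy-ordered
#' tie-breaking.
#'
#' @param records record table with order/family/genus annotations.
#' @param taxonomy a [host_taxonomy()].
#' @return data.frame: one row per genus with `order`, `family`, `genus`,
#'   `dominant`, `case1`, `case2`, `case3`.
#' @export
tag_challenging_cases <- function(records, taxonomy = host_taxonomy()) {
  if (anyNA(records$genus)) stop("genus annotations required")
  dom_of <- function(key) {
    vapply(split(records$host_layer1, key), function(l) {
      tab <- table(l)
      cl <- order_labels_canonically(names(tab), taxonomy)
      cl[which.max(tab[cl])]
    }, "")
  }
  dom_order <- dom_of(records$order)
  dom_family <- dom_of(records$family)
  dom_genus <- dom_of(records$genus)
  genera <- unique(records[, c("order", "family", "genus")])
  n_l1 <- vapply(split(records$host_layer1, records$genus),
                 function(l) length(unique(l)), 0L)
  data.frame(
    order = genera$order, family = genera$family, genus = genera$genus,
    dominant = unname(dom_genus[genera$genus]),
    case1 = unname(dom_genus[genera$genus] != dom_order[genera$order]),
    case2 = unname(dom_genus[genera$genus] != dom_family[genera$family]),
    case3 = unname(n_l1[genera$genus] >= 2),
    stringsAsFactors = FALSE)
}

#' Leave-one-genus-out evaluation
#'
#' For each genus of each order, a model is trained on the order's remaining
#' records -- the held-out genus absent from both the training folds and the
#' homology reference index, and training records' homology features
#' computed with their whole genus excluded -- and evaluated on the held-out
#' genus, emulating a novel-virus query. A genus spanning its entire order
#' (or leaving fewer than two layer-1 labels behind) is skipped with a
#' warning. The aggregate is the unweighted genus-wise mean accuracy per
#' layer; accuracies of the two null models and of the alignment-only
#' baseline (argmax of the homology vector) are reported alongside.
#'
#' @param records screened record table with genus annotations.
#' @param sequences named character vector of genome sequences.
#' @param seed integer seed.
#' @param baseline also compute the homology-only baseline (default `TRUE`).
#' @param ... passed to [viralhost()].
#' @return List with `per_genus` (data.frame), `aggregate` (named numeric),
#'   `skipped` (character), `predictions`.
#' @export
leave_one_genus_out <- function(records, sequences, seed = 1,
                                baseline = TRUE, ...) {
  records <- validate_records(records)
  if (anyNA(records$genus)) stop("genus annotations required")
  dots <- list(...)
  feature_set <- dots$feature_set %||% "sbias"
  traits <- encode_trait_matrix(sequences[records$id],
                                feature_set = feature_set)
  per <- list(); skipped <- character(0); all_pred <- list()
  for (ord in unique(records$order)) {
    orecs <- records[records$order == ord, , drop = FALSE]
    dist1 <- label_distribution(orecs, "layer1")
    for (gen in unique(orecs$genus)) {
      tr <- orecs[orecs$genus != gen, , drop = FALSE]
      te <- orecs[orecs$genus == gen, , drop = FALSE]
      if (nrow(tr) == 0 || length(unique(tr$host_layer1)) < 2) {
        warning("genus ", gen, " skipped: insufficient training data")
        skipped <- c(skipped, gen)
        next
      }
      stopifnot(length(intersect(tr$id, te$id)) == 0)
      args <- c(list(records = tr, sequences = sequences, seed = seed,
                     screen = FALSE, calibrate = FALSE,
                     exclude_genus = TRUE, trait_matrix = traits), dots)
      fit <- do.call(viralhost, args)
      idx1 <- fit$classifiers[[ord]]$layer1$index
      if (!is.null(idx1) && length(intersect(te$id,
                                             unlist(idx1$groups))) > 0) {
        stop("held-out genus leaked into the homology index")
      }
      p <- predict(fit, sequences[te$id], orders = ord)
      all_pred[[gen]] <- p
      acc1 <- mean(!p$rejected & !is.na(p$layer1_label) &
                     p$layer1_label == te$host_layer1)
      has2 <- !is.na(te$host_layer2)
      acc2 <- if (any(has2)) {
        mean(layer2_truth_correct(te[has2, , drop = FALSE],
                                  p[has2, , drop = FALSE]))
      } else NA_real_
      null1 <- null_model_1(dist1, nrow(te), seed = seed)
      null2 <- null_model_2(dist1)
      base_acc <- NA_real_
      if (baseline) {
        clf <- fit$classifiers[[ord]]
        if (!is.null(clf$layer1$index)) {
          raw <- best_hit_scores(sequences[te$id], clf$layer1$index,
                                 backend = fit$config$aligner)
          blab <- colnames(raw)[apply(raw, 1, which.max)]
          base_acc <- mean(blab == te$host_layer1)
        }
      }
      per[[gen]] <- data.frame(
        order = ord, genus = gen, n = nrow(te),
        accuracy_layer1 = acc1, accuracy_layer2 = acc2,
        null1_accuracy = mean(null1 == te$host_layer1),
        null2_accuracy = mean(null2 == te$host_layer1),
        baseline_accuracy = base_acc, stringsAsFactors = FALSE)
    }
  }
  if (length(per) == 0) {
    return(list(per_genus = NULL, aggregate = NULL, skipped = skipped,
                predictions = all_pred))
  }
  per_genus <- do.call(rbind, per)
  rownames(per_genus) <- NULL
  aggregate <- c(
    accuracy_layer1 = mean(per_genus$accuracy_layer1),
    accuracy_layer2 = mean(per_genus$accuracy_layer2, na.rm = TRUE),
    null1_accuracy = mean(per_genus$null1_accuracy),
    null2_accuracy = mean(per_genus$null2_accuracy),
    baseline_accuracy = mean(per_genus$baseline_accuracy, na.rm = TRUE))
  list(per_genus = per_genus, aggregate = aggregate, skipped = skipped,
       predictions = all_pred)
}

#' Family-wise homogeneity analysis
#'
#' Computes the homogeneity `r` of every family (fraction of members
#' carrying the family's dominant layer-1 label), splits families at
#' `r >= threshold` (a family exactly at the threshold is
#' high-homogeneity), attributes layer-1 prediction errors to the two
#' partitions, and emits the row-normalised layer-1 confusion matrix.
#'
#' @param records record table with family annotations.
#' @param predictions prediction table aligned by `id` (as returned by
#'   [predict.viralhost()] or [cross_validate()]).
#' @param threshold homogeneity threshold (default 0.9).
#' @param taxonomy a [host_taxonomy()].
#' @return List with `per_family`, `partition_summary`, `confusion`.
#' @export
family_wise_analysis <- function(records, predictions, threshold = 0.9,
                                 taxonomy = host_taxonomy()) {
  if (anyNA(records$family)) stop("family annotations required")
  predictions <- predictions[match(records$id, predictions$id), ,
                             drop = FALSE]
  correct <- !predictions$rejected & !is.na(predictions$layer1_label) &
    predictions$layer1_label == records$host_layer1
  fams <- unique(records$family)
  per <- do.call(rbind, lapply(fams, function(f) {
    sel <- records$family == f
    r <- host_homogeneity(records[sel, , drop = FALSE], taxonomy)
    data.frame(family = f, n = sum(sel), r = as.numeric(r),
               dominant = attr(r, "dominant"),
               errors = sum(!correct[sel]),
               error_rate = mean(!correct[sel]), stringsAsFactors = FALSE)
  }))
  per$high_homogeneity <- per$r >= threshold
  summary <- data.frame(
    partition = c(sprintf("r >= %g", threshold),
                  sprintf("r < %g", threshold)),
    n_families = c(sum(per$high_homogeneity), sum(!per$high_homogeneity)),
    errors = c(sum(per$errors[per$high_homogeneity]),
               sum(per$errors[!per$high_homogeneity])),
    stringsAsFactors = FALSE)
  m <- compute_metrics(records$host_layer1, predictions$layer1_label,
                       rejected = predictions$rejected,
                       taxonomy = taxonomy)
  list(per_family = per, partition_summary = summary,
       confusion = m$confusion)
}
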