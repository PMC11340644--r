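# Hierarchical per-order host classifiers: training, prediction and
# confidence-based rejection.

default_config <- function(feature_set = "sbias", learner = "xgboost",
                           aligner = "auto", seed = 1, nrounds = 100,
                           calibrate = TRUE, rejection_target = 0.95,
                           exclude_genus = FALSE) {
  list(feature_set = feature_set, learner = learner, aligner = aligner,
       seed = as.integer(seed), nrounds = nrounds, calibrate = calibrate,
       rejection_target = rejection_target, exclude_genus = exclude_genus)
}

fit_learner <- function(X, y, config) {
  labels <- levels(y)
  m <- length(labels)
  if (all(apply(X, 2, function(col) length(unique(col)) == 1))) {
    warning("all features are constant; the classifier cannot discriminate")
  }
  if (config$learner == "xgboost") {
    dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
    params <- list(objective = "multi:softprob", num_class = m,
                   eta = 0.3, max_depth = 6, nthread = 1,
                   seed = config$seed)
    model <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = config$nrounds, verbose = 0)
    list(learner = "xgboost", labels = labels, model = model)
  } else if (config$learner == "rf") {
    if (!requireNamespace("randomForest", quietly = TRUE)) {
      stop("learner 'rf' requires the randomForest package")
    }
    model <- with_seed(config$seed,
                       randomForest::randomForest(x = X, y = y))
    list(learner = "rf", labels = labels, model = model)
  } else {
    stop("unknown learner: ", config$learner)
  }
}

predict_learner <- function(fit, X) {
  m <- length(fit$labels)
  if (fit$learner == "xgboost") {
    p <- predict(fit$model, xgboost::xgb.DMatrix(X))
    if (is.null(dim(p))) p <- matrix(p, ncol = m, byrow = TRUE)
    colnames(p) <- fit$labels
  } else {
    p <- predict(fit$model, X, type = "prob")
    p <- p[, fit$labels, drop = FALSE]
  }
  rownames(p) <- rownames(X)
  p
}

layer_labels <- function(records, layer) {
  if (layer == "layer1") records$host_layer1 else records$host_layer2
}

# Per-query exclusion sets for training-time homology features: always the
# record itself; optionally its whole genus (leave-one-genus-out setting).
training_exclusions <- function(records, exclude_genus) {
  if (!exclude_genus) return(NULL)
  ex <- lapply(seq_len(nrow(records)), function(i) {
    g <- records$genus[i]
    if (is.na(g)) records$id[i] else records$id[records$genus == g]
  })
  names(ex) <- records$id
  ex
}

train_layer_model <- function(records, sequences, traits, layer, config,
                              taxonomy) {
  lab <- layer_labels(records, layer)
  labels <- order_labels_canonically(unique(lab), taxonomy)
  if (length(labels) == 1) {
    return(list(type = "direct", label = labels, labels = labels))
  }
  index <- build_group_index(records, sequences[records$id], layer = layer,
                             taxonomy = taxonomy)
  excl <- training_exclusions(records, config$exclude_genus)
  raw <- best_hit_scores(sequences[records$id], index,
                         exclude_ids = excl %||% character(0),
                         exclude_self = TRUE, backend = config$aligner)
  H <- encode_homology(raw)
  X <- concatenate_features(traits[records$id, , drop = FALSE], H)
  y <- factor(lab, levels = index$labels)
  fit <- fit_learner(X, y, config)
  out <- list(type = "model", labels = index$labels, index = index,
              fit = fit, cutoff = 0, curve = NULL)
  if (isTRUE(config$calibrate)) {
    cal <- oof_calibration(records, sequences, traits, layer, config,
                           taxonomy)
    if (!is.null(cal)) {
      out$cutoff <- cal$cutoff
      out$curve <- cal$curve
    }
  }
  out
}

# Out-of-fold top scores for rejection calibration: internal stratified
# 3-fold, each fold's model scoring the held-out third.
oof_calibration <- function(records, sequences, traits, layer, config,
                            taxonomy, k = 3) {
  if (nrow(records) < 20) return(NULL)
  folds <- stratified_kfold(records, k = k, seed = config$seed,
                            label = leaf_label(records))
  scores <- numeric(0); correct <- logical(0)
  inner <- config
  inner$calibrate <- FALSE
  for (fold in folds) {
    tr <- records[records$id %in% fold$train, , drop = FALSE]
    te <- records[records$id %in% fold$test, , drop = FALSE]
    if (length(unique(layer_labels(tr, layer))) < 2) next
    sub <- train_layer_model(tr, sequences, traits, layer, inner, taxonomy)
    if (sub$type != "model") next
    p <- score_layer(sub, sequences[te$id], traits[te$id, , drop = FALSE],
                     config)
    top <- apply(p, 1, max)
    pred <- colnames(p)[apply(p, 1, which.max)]
    scores <- c(scores, top)
    correct <- c(correct, pred == layer_labels(te, layer))
  }
  if (length(scores) < 20) return(NULL)
  calibrate_rejection_cutoff(scores, correct,
                             target = config$rejection_target)
}

score_layer <- function(layer_model, sequences, traits, config) {
  raw <- best_hit_scores(sequences, layer_model$index,
                         backend = config$aligner)
  H <- encode_homology(raw)
  X <- concatenate_features(traits, H)
  predict_learner(layer_model$fit, X)
}

#' Train the classifier of one virus order
#'
#' Decides the order's prediction mode, then fits the layer-1 model on all
#' the order's records (genomic traits concatenated with per-host-group
#' best-hit homology scores, the training record's own sequence excluded
#' from its homology features) and, for two-layer orders, the layer-2 model
#' on the Chordata subset with its own group index. Single-label layers are
#' recorded as direct assignments instead of trained models. When
#' calibration is enabled, a per-layer rejection cutoff is derived from
#' out-of-fold validation scores.
#'
#' @param records screened records of one virus order.
#' @param sequences named character vector covering the record ids.
#' @param traits precomputed trait matrix (rows = record ids).
#' @param config a configuration list as assembled by [viralhost()].
#' @param taxonomy a [host_taxonomy()].
#' @return An `order_classifier` object.
#' @export
train_order_classifier <- function(records, sequences, traits, config,
                                   taxonomy = host_taxonomy()) {
  mode <- order_mode(records)
  out <- list(order = records$order[1], mode = mode,
              n_records = nrow(records),
              layer1 = NULL, layer2 = NULL)
  if (mode$mode != "direct_assign") {
    out$layer1 <- train_layer_model(records, sequences, traits, "layer1",
                                    config, taxonomy)
    if (mode$mode == "two_layer") {
      ch <- records[records$host_layer1 == "Chordata" &
                      !is.na(records$host_layer2), , drop = FALSE]
      if (nrow(ch) > 0) {
        out$layer2 <- train_layer_model(ch, sequences, traits, "layer2",
                                        config, taxonomy)
      }
    }
  }
  structure(out, class = "order_classifier")
}

#' Fit a hierarchical virus-host classifier
#'
#' The main fitting function. Reference records are validated and (by
#' default) screened against the host taxonomy, each genome is encoded as a
#' genomic-trait vector, and one classifier per virus order is trained:
#' direct assignment for single-host orders, a layer-1 model over the five
#' kingdom/phylum branches otherwise, plus a layer-2 model over the
#' Chordata class/order leaves for two-layer orders. Classifier inputs
#' concatenate the trait block with log10 best-hit alignment scores against
#' each host group's references. Gradient boosting (library defaults, fixed
#' seed) is the default learner.
#'
#' @param records metadata table: columns `id`, `order`, `family`, `genus`,
#'   `host_layer1`, `host_layer2` (see [validate_records()]).
#' @param sequences named character vector of genome sequences covering the
#'   record ids.
#' @param feature_set `"sbias"` (137 traits, default) or `"bias"`
#'   (adds 3,904 codon-pair scores).
#' @param learner `"xgboost"` (default) or `"rf"`.
#' @param aligner `"auto"`, `"blast"` or `"builtin"` homology backend.
#' @param seed integer seed controlling every random choice in training.
#' @param nrounds boosting rounds for the gradient-boosting learner.
#' @param screen apply [screen_labels()] before training (default `TRUE`).
#' @param calibrate derive per-order, per-layer rejection cutoffs from
#'   out-of-fold validation scores (default `TRUE`).
#' @param rejection_target precision targeted by the rejection cutoff.
#' @param exclude_genus during training feature extraction, exclude a
#'   record's whole genus (not just itself) from its homology references;
#'   used by the leave-one-genus-out harness.
#' @param trait_matrix optional precomputed [encode_trait_matrix()] result.
#' @param taxonomy a [host_taxonomy()].
#' @return An object of class `viralhost` with `predict`, `print`,
#'   `summary` and `plot` methods.
#' @seealso [predict.viralhost()], [cross_validate()],
#'   [leave_one_genus_out()]
#' @export
viralhost <- function(records, sequences,
                      feature_set = c("sbias", "bias"),
                      learner = c("xgboost", "rf"),
                      aligner = c("auto", "blast", "builtin"),
                      seed = 1, nrounds = 100, screen = TRUE,
                      calibrate = TRUE, rejection_target = 0.95,
                      exclude_genus = FALSE, trait_matrix = NULL,
                      taxonomy = host_taxonomy()) {
  feature_set <- match.arg(feature_set)
  learner <- match.arg(learner)
  aligner <- resolve_aligner(match.arg(aligner))
  records <- validate_records(records, taxonomy)
  missing_seq <- setdiff(records$id, names(sequences))
  if (length(missing_seq) > 0) {
    stop("no sequence for record(s): ",
         paste(head(missing_seq, 5), collapse = ", "))
  }
  screening_report <- NULL
  if (screen) {
    sc <- screen_labels(records, taxonomy = taxonomy)
    records <- sc$records
    screening_report <- sc$report
  }
  if (nrow(records) == 0) stop("no records left after screening")
  config <- default_config(feature_set, learner, aligner, seed, nrounds,
                           calibrate, rejection_target, exclude_genus)
  if (is.null(trait_matrix)) {
    trait_matrix <- encode_trait_matrix(sequences[records$id],
                                        feature_set = feature_set)
  }
  classifiers <- list()
  for (ord in unique(records$order)) {
    recs <- records[records$order == ord, , drop = FALSE]
    classifiers[[ord]] <- train_order_classifier(recs, sequences,
                                                 trait_matrix, config,
                                                 taxonomy)
  }
  structure(
    list(taxonomy = taxonomy, classifiers = classifiers, config = config,
         screening_report = screening_report,
         layout_version = attr(trait_layout(feature_set), "layout_version"),
         n_records = nrow(records),
         fingerprint = dataset_fingerprint(records)),
    class = "viralhost")
}

dataset_fingerprint <- function(records) {
  ids <- sort(records$id)
  sprintf("%d records; id range %s .. %s", length(ids),
          ids[1], ids[length(ids)])
}

#' Calibrate a rejection cutoff from validation scores
#'
#' Scans every observed top-score threshold and returns the smallest cutoff
#' whose retained predictions reach the target precision; if the target is
#' unattainable the maximum observed score is returned with a warning. The
#' full precision / prediction-rate trade-off curve is returned alongside.
#'
#' @param scores numeric vector of top prediction scores on validation
#'   queries.
#' @param correct logical vector: was the top prediction correct?
#' @param target precision target in `[0, 1]`.
#' @return List with `cutoff` and `curve` (data.frame of `cutoff`,
#'   `precision`, `prediction_rate`).
#' @export
calibrate_rejection_cutoff <- function(scores, correct, target = 0.95) {
  if (length(scores) == 0) stop("no validation scores")
  stopifnot(length(scores) == length(correct))
  cand <- sort(unique(c(0, scores)))
  prec <- numeric(length(cand)); rate <- numeric(length(cand))
  for (i in seq_along(cand)) {
    sel <- scores >= cand[i]
    rate[i] <- mean(sel)
    prec[i] <- if (any(sel)) mean(correct[sel]) else NA_real_
  }
  curve <- data.frame(cutoff = cand, precision = prec,
                      prediction_rate = rate)
  if (target <= 0) {
    return(list(cutoff = 0, curve = curve))
  }
  obs <- which(cand %in% scores)
  ok <- obs[!is.na(prec[obs]) & prec[obs] >= target]
  if (length(ok) == 0) {
    warning("target precision ", target,
            " unattainable; using the maximum observed score")
    cutoff <- max(scores)
  } else {
    cutoff <- cand[ok[1]]
  }
  list(cutoff = cutoff, curve = curve)
}

direct_label_split <- function(label, taxonomy) {
  if (label %in% taxonomy$layer1_labels) {
    list(l1 = label, l2 = NA_character_)
  } else {
    list(l1 = "Chordata", l2 = label)
  }
}

empty_prediction_rows <- function(ids, orders, status) {
  data.frame(id = ids, order = orders,
             layer1_label = NA_character_, layer1_score = NA_real_,
             layer2_label = NA_character_, layer2_score = NA_real_,
             rejected = TRUE, status = status, stringsAsFactors = FALSE)
}

#' Predict hosts for query genomes
#'
#' Routes each query to its virus order's classifier. Direct-assignment
#' orders return their single host label with score 1. Otherwise the layer-1
#' score vector is computed and the top label taken; a top score below the
#' order's rejection cutoff rejects the query (no labels reported). Queries
#' predicted Chordata in a two-layer order receive an analogous layer-2
#' prediction (a below-cutoff layer 2 leaves the layer-1 call standing and
#' reports no layer-2 label, `status = "layer2_rejected"`). Unknown orders
#' yield an explicit `"unsupported_order"` row rather than an error.
#'
#' @param object a fitted [viralhost()] model.
#' @param sequences named character vector of query genome sequences.
#' @param orders character vector (length 1 or `length(sequences)`) of virus
#'   order labels for the queries.
#' @param apply_cutoff apply the calibrated rejection cutoffs
#'   (default `TRUE`).
#' @param detail if `TRUE`, also return the per-layer score matrices.
#' @param ... unused.
#' @return A data.frame with columns `id`, `order`, `layer1_label`,
#'   `layer1_score`, `layer2_label`, `layer2_score`, `rejected`, `status`
#'   (invisibly a list when `detail = TRUE`).
#' @export
predict.viralhost <- function(object, sequences, orders,
                              apply_cutoff = TRUE, detail = FALSE, ...) {
  ids <- names(sequences)
  if (is.null(ids)) stop("query sequences must be named")
  if (length(orders) == 1) orders <- rep(orders, length(sequences))
  stopifnot(length(orders) == length(sequences))
  taxonomy <- object$taxonomy
  config <- object$config
  rows <- list(); score_detail <- list()
  for (ord in unique(orders)) {
    sel <- which(orders == ord)
    q <- sequences[sel]
    clf <- object$classifiers[[ord]]
    if (is.null(clf)) {
      rows[[ord]] <- empty_prediction_rows(ids[sel], ord,
                                           "unsupported_order")
      next
    }
    if (clf$mode$mode == "direct_assign") {
      dl <- direct_label_split(clf$mode$direct_label, taxonomy)
      rows[[ord]] <- data.frame(
        id = ids[sel], order = ord,
        layer1_label = dl$l1, layer1_score = 1,
        layer2_label = dl$l2, layer2_score = ifelse(is.na(dl$l2), NA, 1),
        rejected = FALSE, status = "ok", stringsAsFactors = FALSE)
      next
    }
    traits <- encode_trait_matrix(q, feature_set = config$feature_set)
    out <- data.frame(id = ids[sel], order = ord,
                      layer1_label = NA_character_, layer1_score = NA_real_,
                      layer2_label = NA_character_, layer2_score = NA_real_,
                      rejected = FALSE, status = "ok",
                      stringsAsFactors = FALSE)
    if (clf$layer1$type == "direct") {
      out$layer1_label <- clf$layer1$label
      out$layer1_score <- 1
    } else {
      p1 <- score_layer(clf$layer1, q, traits, config)
      score_detail[[ord]]$layer1 <- p1
      top <- apply(p1, 1, which.max)
      out$layer1_label <- colnames(p1)[top]
      out$layer1_score <- p1[cbind(seq_len(nrow(p1)), top)]
      if (apply_cutoff && clf$layer1$cutoff > 0) {
        rej <- out$layer1_score < clf$layer1$cutoff
        out$rejected[rej] <- TRUE
        out$status[rej] <- "rejected"
        out$layer1_label[rej] <- NA_character_
        out$layer1_score[rej] <- NA_real_
      }
    }
    if (!is.null(clf$layer2)) {
      go <- !out$rejected & out$layer1_label == "Chordata"
      if (any(go)) {
        if (clf$layer2$type == "direct") {
          out$layer2_label[go] <- clf$layer2$label
          out$layer2_score[go] <- 1
        } else {
          p2 <- score_layer(clf$layer2, q[go], traits[go, , drop = FALSE],
                            config)
          score_detail[[ord]]$layer2 <- p2
          top2 <- apply(p2, 1, which.max)
          lab2 <- colnames(p2)[top2]
          sc2 <- p2[cbind(seq_len(nrow(p2)), top2)]
          if (apply_cutoff && clf$layer2$cutoff > 0) {
            rej2 <- sc2 < clf$layer2$cutoff
            lab2[rej2] <- NA_character_
            sc2[rej2] <- NA_real_
            out$status[go][rej2] <- "layer2_rejected"
          }
          out$layer2_label[go] <- lab2
          out$layer2_score[go] <- sc2
        }
      }
    }
    rows[[ord]] <- out
  }
  res <- do.call(rbind, rows)
  res <- res[match(ids, res$id), , drop = FALSE]
  rownames(res) <- NULL
  if (detail) list(predictions = res, scores = score_detail) else res
}

#' @export
print.viralhost <- function(x, ...) {
  modes <- vapply(x$classifiers, function(c) c$mode$mode, "")
  cat("Hierarchical virus-host classifier\n")
  cat("  reference records:", x$n_records, "\n")
  cat("  virus orders:", length(x$classifiers),
      sprintf("(%d direct, %d layer-1 only, %d two-layer)\n",
              sum(modes == "direct_assign"), sum(modes == "layer1_only"),
              sum(modes == "two_layer")))
  cat("  feature set:", x$config$feature_set,
      "| learner:", x$config$learner,
      "| aligner:", x$config$aligner, "\n")
  cat("  seed:", x$config$seed,
      "| trait layout version:", x$layout_version, "\n")
  invisible(x)
}

#' @export
summary.viralhost <- function(object, ...) {
  modes <- vapply(object$classifiers, function(c) c$mode$mode, "")
  cutoffs <- vapply(object$classifiers, function(c) {
    if (!is.null(c$layer1) && c$layer1$type == "model") c$layer1$cutoff
    else NA_real_
  }, 0)
  out <- list(
    orders = data.frame(order = names(object$classifiers), mode = modes,
                        n_records = vapply(object$classifiers,
                                           function(c) c$n_records, 0L),
                        layer1_cutoff = cutoffs, row.names = NULL,
                        stringsAsFactors = FALSE),
    screening_report = object$screening_report,
    config = object$config)
  class(out) <- "summary.viralhost"
  out
}

#' @export
print.summary.viralhost <- function(x, ...) {
  cat("Per-order classifiers:\n")
  print(x$orders)
  if (!is.null(x$screening_report)) {
    cat("\nLabel screening:\n")
    print(x$screening_report)
  }
  invisible(x)
}

#' Plot rejection trade-off curves
#'
#' Precision against prediction rate over the scanned rejection cutoffs, one
#' curve per order with a calibrated layer-1 cutoff.
#'
#' @param x a fitted [viralhost()] model (with `calibrate = TRUE`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.viralhost <- function(x, ...) {
  curves <- Filter(Negate(is.null), lapply(x$classifiers, function(c) {
    if (!is.null(c$layer1) && c$layer1$type == "model") c$layer1$curve
    else NULL
  }))
  if (length(curves) == 0) {
    stop("no calibration curves available; fit with calibrate = TRUE")
  }
  plot(NA, xlim = c(0, 1), ylim = c(0, 1),
       xlab = "prediction rate", ylab = "precision", ...)
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    graphics::lines(cv$prediction_rate, cv$precision, col = i)
  }
  graphics::legend("bottomleft", legend = names(curves),
                   col = seq_along(curves), lty = 1, cex = 0.8)
  invisible(x)
}
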