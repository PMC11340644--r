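test_that("stratified folds are balanced per label and deterministic", {
  recs <- make_records("O", c(rep("Chordata", 25), rep("Viridiplantae", 25)))
  folds <- stratified_kfold(recs, k = 5, seed = 3)
  for (f in folds) {
    te <- recs[recs$id %in% f$test, ]
    expect_equal(sum(te$host_layer1 == "Chordata"), 5)
    expect_equal(sum(te$host_layer1 == "Viridiplantae"), 5)
    expect_length(intersect(f$train, f$test), 0)
  }
  expect_setequal(unlist(lapply(folds, `[[`, "test")), recs$id)

  odd <- make_records("O", rep("Chordata", 23))
  sizes <- sort(vapply(stratified_kfold(odd, k = 5, seed = 1),
                       function(f) length(f$test), 0L))
  expect_equal(sizes, c(4L, 4L, 5L, 5L, 5L))

  expect_identical(stratified_kfold(recs, k = 5, seed = 42),
                   stratified_kfold(recs, k = 5, seed = 42))
  expect_warning(stratified_kfold(make_records("O", rep("Fungi", 3)),
                                  k = 5, seed = 1), "best-effort")
})

test_that("metrics follow their definitions including rejection handling", {
  truth <- rep(c("Chordata", "Viridiplantae"), each = 5)
  predicted <- c("Chordata", "Chordata", "Chordata", "Viridiplantae",
                 NA, "Viridiplantae", "Viridiplantae", "Viridiplantae",
                 "Chordata", NA)
  m <- compute_metrics(truth, predicted)
  # 10 queries, 8 predicted, 6 of those correct
  expect_equal(m$prediction_rate, 0.8)
  expect_equal(m$precision, 0.75)
  expect_equal(m$accuracy, 0.6)
  expect_equal(rowSums(m$confusion), c(Chordata = 1, Viridiplantae = 1))

  # rank-wise accuracy is an unweighted mean over taxa
  ord <- rep(c("O1", "O2"), each = 5)
  truth2 <- rep("Chordata", 10)
  pred2 <- c(rep("Chordata", 5), rep("Chordata", 2),
             rep("Viridiplantae", 3))  # O1 acc 1.0, O2 acc 0.4
  m2 <- compute_metrics(truth2, pred2, order = ord)
  expect_equal(m2$order_wise_accuracy, 0.7)

  perfect <- compute_metrics(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro_f1, 1)
  expect_equal(unname(diag(perfect$confusion)), c(1, 1))
})

test_that("macro F1 matches a naive per-label confusion oracle", {
  set.seed(8)
  labels <- c("Chordata", "Invertebrate", "Viridiplantae")
  truth <- sample(labels, 60, replace = TRUE)
  predicted <- ifelse(runif(60) < 0.7, truth, sample(labels, 60, TRUE))
  predicted[sample(60, 5)] <- NA  # rejections
  m <- compute_metrics(truth, predicted)
  oracle_f1 <- vapply(unique(truth), function(lab) {
    tp <- sum(!is.na(predicted) & predicted == lab & truth == lab)
    fp <- sum(!is.na(predicted) & predicted == lab & truth != lab)
    fn <- sum(truth == lab) - tp
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 0)
  expect_equal(m$macro_f1, mean(oracle_f1))
})

test_that("fragment generation is exact in count, length and seed", {
  seqs <- setNames(vapply(1:5, function(i) random_dna(1000, i), ""),
                   paste0("s", 1:5))
  frags <- fragment_queries(seqs, seed = 4)
  expect_equal(names(frags), c("90", "75", "60", "45"))
  expect_equal(sum(lengths(frags)), 4 * 5)
  expect_equal(unique(nchar(frags[["45"]])), 450)
  expect_equal(unique(nchar(frags[["90"]])), 900)
  # each contig is a contiguous substring of its source
  for (r in names(frags)) {
    for (id in names(frags[[r]])) {
      expect_true(grepl(frags[[r]][[id]], seqs[[id]], fixed = TRUE))
    }
  }
  expect_identical(fragment_queries(seqs, seed = 4),
                   fragment_queries(seqs, seed = 4))
  expect_error(fragment_queries(c(x = "ACGT")), "100")
})

test_that("null models reproduce the training label distribution", {
  recs <- make_records("O", c(rep("Chordata", 9), "Viridiplantae"))
  dist <- label_distribution(recs)
  expect_equal(unname(dist), c(0.9, 0.1))
  expect_equal(null_model_2(dist), "Chordata")
  # tie: broken by the taxonomy's fixed label order
  tie <- label_distribution(make_records("O", c("Viridiplantae", "Chordata")))
  expect_equal(null_model_2(tie), "Chordata")

  draws <- null_model_1(dist, 10000, seed = 6)
  freq <- table(draws) / 10000
  expect_equal(unname(freq["Chordata"]), 0.9, tolerance = 0.02)
  expect_identical(null_model_1(dist, 50, seed = 1),
                   null_model_1(dist, 50, seed = 1))

  # null-2 accuracy equals the test-set frequency of the dominant label
  test_truth <- c(rep("Chordata", 3), rep("Viridiplantae", 7))
  expect_equal(mean(null_model_2(dist) == test_truth), 0.3)
})

test_that("challenging-case tags follow their definitions", {
  # genus g3 is plant-infecting inside a chordate-dominated order
  recs <- rbind(
    make_records("Pic", rep("Chordata", 8), family = "famA",
                 genus = rep(c("g1", "g2"), each = 4)),
    make_records("Pic", rep("Viridiplantae", 3), family = "famB",
                 genus = "g3"),
    make_records("Pic", c("Chordata", "Invertebrate"), family = "famB",
                 genus = "g4"))
  recs$id <- sprintf("r%02d", seq_len(nrow(recs)))
  tags <- tag_challenging_cases(recs)
  g3 <- tags[tags$genus == "g3", ]
  expect_true(g3$case1)    # differs from the order's dominant (Chordata)
  expect_false(g3$case2)   # famB's dominant is Viridiplantae (3 of 5)
  expect_false(g3$case3)
  g1 <- tags[tags$genus == "g1", ]
  expect_false(any(c(g1$case1, g1$case2, g1$case3)))
  g4 <- tags[tags$genus == "g4", ]
  expect_true(g4$case3)    # members span two layer-1 branches
})

test_that("family-wise analysis partitions at the homogeneity threshold", {
  recs <- rbind(
    make_records("O", rep("Chordata", 10), family = "pure"),
    make_records("O", c(rep("Chordata", 9), "Invertebrate"),
                 family = "boundary"),
    make_records("O", c(rep("Chordata", 5), rep("Invertebrate", 5)),
                 family = "mixed"))
  recs$id <- sprintf("r%02d", seq_len(nrow(recs)))
  pred <- data.frame(id = recs$id, layer1_label = "Chordata",
                     rejected = FALSE, stringsAsFactors = FALSE)
  fw <- family_wise_analysis(recs, pred)
  per <- fw$per_family
  expect_equal(per$r[per$family == "boundary"], 0.9)
  expect_true(per$high_homogeneity[per$family == "boundary"])
  expect_false(per$high_homogeneity[per$family == "mixed"])
  expect_equal(per$errors[per$family == "pure"], 0)
  expect_equal(fw$partition_summary$errors,
               c(1, 5))  # boundary's one miss; mixed's five
})

test_that("cross-validation never leaks ids and reports both layers", {
  sim <- simulate_dataset(sim_config(
    n_orders = 1, n_families = 2, n_genera = 3, n_genomes = 5,
    host_labels = c("Primates", "Aves", "Viridiplantae"),
    bias_strength = 1, mutation_rate = 0.02,
    length_range = c(900, 1200), seed = 41))
  cv <- cross_validate(sim$records, sim$sequences, k = 3, seed = 2)
  for (f in cv$folds) {
    expect_length(intersect(f$train, f$test), 0)
  }
  expect_equal(nrow(cv$predictions), nrow(sim$records))
  expect_s3_class(cv$metrics_layer1, "metric_report")
  expect_s3_class(cv$metrics_layer2, "metric_report")
  expect_gte(cv$metrics_layer1$accuracy, 0.9)
})

test_that("leave-one-genus-out excludes the genus everywhere and recovers hosts", {
  sim <- simulate_dataset(sim_config(
    n_orders = 1, n_families = 8, n_genera = 3, n_genomes = 3,
    host_labels = c("Chordata", "Viridiplantae", "Fungi"),
    bias_strength = 1, mutation_rate = 0.05,
    length_range = c(900, 1200), seed = 43))
  logo <- leave_one_genus_out(sim$records, sim$sequences, seed = 3)
  expect_equal(nrow(logo$per_genus), 24)
  expect_gte(logo$aggregate[["accuracy_layer1"]], 0.9)
  # null baselines are reported and bounded by the trained model here
  expect_true(all(is.finite(logo$per_genus$null1_accuracy)))
  expect_true(all(is.finite(logo$per_genus$null2_accuracy)))
  expect_true(all(is.finite(logo$per_genus$baseline_accuracy)))
  # degenerate: a genus spanning its whole order is skipped with a warning
  one <- make_records("solo", rep("Chordata", 4), genus = "gX")
  one$host_layer1[1:2] <- "Fungi"
  seqs <- setNames(vapply(1:4, function(i) random_dna(700, i), ""), one$id)
  expect_warning(leave_one_genus_out(one, seqs, seed = 1, baseline = FALSE),
                 "skipped")
})
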