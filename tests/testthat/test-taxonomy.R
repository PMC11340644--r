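test_that("the default taxonomy has the fixed two-layer structure", {
  tax <- host_taxonomy()
  expect_length(tax$layer1_labels, 5)
  expect_setequal(tax$layer1_labels,
                  c("Chordata", "Invertebrate", "Viridiplantae", "Fungi",
                    "Bacteria"))
  expect_length(tax$layer2_labels, 10)
  expect_true(all(c("Primates", "Fish", "Other Mammalia") %in%
                    tax$layer2_labels))
  # every layer-2 leaf lives under Chordata and shadows no layer-1 branch
  expect_length(intersect(tax$layer1_labels, tax$layer2_labels), 0)
  expect_identical(tax$merged_mammal_label, "Mammalia")
})

test_that("record validation rejects malformed labels and structure", {
  recs <- make_records("OrdA", c("Chordata", "Viridiplantae"))
  expect_silent(validate_records(recs))
  bad <- recs; bad$host_layer1[1] <- "Martian"
  expect_error(validate_records(bad), "v001")
  bad2 <- recs; bad2$host_layer2[2] <- "Primates"  # layer1 not Chordata
  expect_error(validate_records(bad2), "v002")
  dup <- recs; dup$id[2] <- dup$id[1]
  expect_error(validate_records(dup), "duplicated")
})

test_that("label screening drops sparse labels only in large orders", {
  recs <- make_records("OrdA", c(rep("Chordata", 25),
                                 rep("Viridiplantae", 12), rep("Fungi", 3)))
  out <- screen_labels(recs)
  expect_equal(nrow(out$records), 37)
  expect_false("Fungi" %in% out$records$host_layer1)
  expect_equal(out$report$dropped_low_count, 3)

  small <- make_records("OrdB", c(rep("Chordata", 18), rep("Fungi", 2)))
  out2 <- screen_labels(small)
  expect_equal(nrow(out2$records), 20)
  expect_true(out2$report$small)
})

test_that("sparse mammalian leaves merge into Mammalia", {
  recs <- make_records("OrdA",
                       rep("Chordata", 35),
                       layer2 = c(rep("Primates", 20), rep("Rodentia", 15)))
  out <- screen_labels(recs)
  expect_true(all(out$records$host_layer2 == "Mammalia"))
  expect_true(out$report$mammal_merged)
  # merging can rescue labels that were individually below the count rule
  recs2 <- make_records("OrdC",
                        rep("Chordata", 40),
                        layer2 = c(rep("Primates", 6), rep("Rodentia", 6),
                                   rep("Aves", 28)))
  out2 <- screen_labels(recs2)
  expect_equal(sum(out2$records$host_layer2 == "Mammalia"), 12)
  expect_equal(nrow(out2$records), 40)
})

test_that("multi-label records are removed before counting", {
  recs <- make_records("OrdA", c(rep("Chordata", 12),
                                 "Chordata;Viridiplantae",
                                 rep("Viridiplantae", 11)))
  out <- screen_labels(recs)
  expect_equal(nrow(out$records), 23)
  expect_equal(out$report$dropped_multi_label, 1)
})

test_that("screening is idempotent", {
  set.seed(42)
  recs <- make_records("OrdA",
                       sample(c(rep("Chordata", 60), rep("Viridiplantae", 14),
                                rep("Fungi", 6))),
                       layer2 = NA_character_)
  recs$host_layer2[recs$host_layer1 == "Chordata"] <-
    sample(c("Primates", "Rodentia", "Aves"), 60, replace = TRUE)
  once <- screen_labels(recs)
  twice <- screen_labels(once$records)
  expect_identical(once$records, twice$records)
  # every retained (order, label) pair in a large order meets the count rule
  counts1 <- table(once$records$host_layer1)
  expect_true(all(counts1 >= 10))
  l2 <- once$records$host_layer2
  expect_true(all(table(l2[!is.na(l2)]) >= 10))
})

test_that("order modes follow the leaf-label structure", {
  direct <- make_records("Pat", rep("Viridiplantae", 5))
  m <- order_mode(direct)
  expect_equal(m$mode, "direct_assign")
  expect_equal(m$direct_label, "Viridiplantae")

  l1only <- make_records("Tym", c(rep("Viridiplantae", 5),
                                  rep("Invertebrate", 3), rep("Fungi", 2)))
  expect_equal(order_mode(l1only)$mode, "layer1_only")

  two <- make_records("Pic", rep("Chordata", 6),
                      layer2 = c(rep("Primates", 3), rep("Aves", 3)))
  expect_equal(order_mode(two)$mode, "two_layer")

  # a single merged layer-2 label still routes the order through layer 2
  merged <- make_records("Mar", c(rep("Viridiplantae", 5),
                                  rep("Chordata", 3)),
                         layer2 = c(rep(NA, 5), rep("Mammalia", 3)))
  expect_equal(order_mode(merged)$mode, "two_layer")
  expect_error(order_mode(make_records("X", character(0))), "at least one")
})

test_that("host homogeneity is the dominant-label fraction", {
  expect_equal(as.numeric(host_homogeneity(
    make_records("O", rep("Chordata", 10)))), 1.0)
  even <- host_homogeneity(make_records("O", c(rep("Chordata", 5),
                                               rep("Invertebrate", 5))))
  expect_equal(as.numeric(even), 0.5)
  # tie broken by the taxonomy's fixed order: Chordata before Invertebrate
  expect_equal(attr(even, "dominant"), "Chordata")
  # a vector-borne-like family: 68 of 120 members infect invertebrates
  fam <- make_records("O", c(rep("Invertebrate", 68), rep("Chordata", 40),
                             rep("Viridiplantae", 12)))
  expect_equal(as.numeric(host_homogeneity(fam)), 68 / 120, tolerance = 1e-9)
  # r is never below 1 / number of distinct labels
  set.seed(1)
  for (i in 1:20) {
    labs <- sample(host_taxonomy()$layer1_labels, sample(2:30, 1),
                   replace = TRUE)
    r <- as.numeric(host_homogeneity(make_records("O", labs)))
    expect_gte(r, 1 / length(unique(labs)))
  }
})

test_that("the packaged host-distribution table matches its printed totals", {
  tbl <- host_distribution_table()
  expect_equal(nrow(tbl), 30)
  expect_equal(sum(tbl$n), 14500)
  expect_identical(default_virus_orders(), tbl$order)
  # layer-1 percentages sum to ~100 per order
  l1 <- as.matrix(tbl[, c("Chordata", "Invertebrate", "Viridiplantae",
                          "Fungi", "Bacteria")])
  sums <- rowSums(l1, na.rm = TRUE)
  expect_true(all(abs(sums - 100) < 1))
  # layer-2 percentages sum to the Chordata percentage
  l2cols <- c("Primates", "Rodentia", "Carnivora", "Artiodactyla",
              "Chiroptera", "Other Mammalia", "Aves", "Reptilia",
              "Amphibia", "Fish", "Mammalia")
  l2 <- rowSums(as.matrix(tbl[, l2cols]), na.rm = TRUE)
  ch <- ifelse(is.na(tbl$Chordata), 0, tbl$Chordata)
  expect_true(all(abs(l2 - ch) < 1))
})

test_that("order modes on the packaged distribution match the corpus", {
  recs <- distribution_to_records(host_distribution_table())
  modes <- vapply(split(recs, recs$order),
                  function(r) order_mode(r)$mode, "")
  expect_equal(sum(modes == "direct_assign"), 12)
  expect_equal(sum(modes == "two_layer"), 13)
  expect_equal(sum(modes == "layer1_only"), 5)
  direct_orders <- sort(names(modes)[modes == "direct_assign"])
  expect_equal(direct_orders,
               sort(c("Patatavirales", "Cryppavirales", "Jingchuvirales",
                      "Nodamuvirales", "Wolframvirales", "Mindivirales",
                      "Norzivirales", "Serpentovirales", "Muvirales",
                      "Yadokarivirales", "Goujianvirales", "Timlovirales")))
  expect_equal(order_mode(recs[recs$order == "Patatavirales", ])$direct_label,
               "Viridiplantae")
  expect_equal(order_mode(recs[recs$order == "Tymovirales", ])$mode,
               "layer1_only")
  expect_equal(order_mode(recs[recs$order == "Picornavirales", ])$mode,
               "two_layer")
})
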