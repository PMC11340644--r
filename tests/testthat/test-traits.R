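test_that("composition counts match brute-force string scanning", {
  # fixed toy cases
  cc <- count_compositions("ACACACACAC", NULL)
  expect_equal(unname(cc$nt[c("A", "C")]), c(5, 5))
  expect_equal(unname(cc$dinuc[c("AC", "CA")]), c(5, 4))

  ann <- data.frame(start = 1, end = 6, strand = "+", gene = "AAAAAA",
                    protein = "KK", stringsAsFactors = FALSE)
  cc2 <- count_compositions("AAAAAA", ann)
  expect_equal(unname(cc2$codon["AAA"]), 2)
  expect_equal(unname(cc2$aa["K"]), 2)
  expect_equal(unname(cc2$codon_pair["AAAAAA"]), 1)
  expect_equal(unname(cc2$aa_pair["KK"]), 1)

  cc3 <- count_compositions("ACGTACGT", NULL)
  expect_equal(sum(cc3$codon), 0)
  expect_equal(sum(cc3$aa), 0)
  expect_length(cc3$codon_pair, 0)

  # randomized property: counts equal a naive re-count on short sequences
  for (seed in 1:5) {
    sq <- random_dna(300 + seed * 37, seed)
    cc <- count_compositions(sq, NULL)
    expect_equal(unname(cc$nt), unname(oracle_char_counts(sq, c("A", "C", "G", "T"))))
    expect_equal(unname(cc$dinuc), unname(oracle_dinuc_counts(sq)))
  }
})

test_that("counting skips ambiguous bases and pools segments", {
  cc <- count_compositions("ACGNNACG", NULL)
  expect_equal(sum(cc$nt), 6)
  # windows containing N and windows across segment boundaries don't count
  expect_equal(sum(cc$dinuc), 4)
  two_seg <- count_compositions(c("AC", "GT"), NULL)
  expect_equal(sum(two_seg$dinuc), 2)
  expect_equal(sum(two_seg$nt), 4)
})

test_that("nucleotide and amino-acid preferences are normalised frequencies", {
  expect_equal(unname(nucleotide_preference(
    count_compositions("AAAA", NULL))["A"]), 1.0)
  expect_equal(unname(nucleotide_preference(
    count_compositions("ACGT", NULL))), rep(0.25, 4))
  p <- nucleotide_preference(count_compositions("AACG", NULL))
  expect_equal(unname(p[c("A", "C", "G", "T")]), c(0.5, 0.25, 0.25, 0))

  ann <- data.frame(start = 1, end = 6, strand = "+", gene = "ATGAAA",
                    protein = "MK", stringsAsFactors = FALSE)
  aa <- amino_acid_usage(count_compositions("ATGAAA", ann))
  expect_equal(unname(aa["M"]), 0.5)
  expect_equal(unname(aa["K"]), 0.5)
  expect_equal(sum(aa), 1)
})

test_that("dinucleotide preference is the composition odds ratio", {
  dp <- dinucleotide_preference(count_compositions("ACACACACAC", NULL))
  expect_equal(unname(dp["AC"]), (5 / 9) / (0.5 * 0.5))
  expect_equal(unname(dp["CA"]), (4 / 9) / (0.5 * 0.5))
  expect_equal(unname(dinucleotide_preference(
    count_compositions("AAAA", NULL))["AA"]), 1.0)
  # i.i.d. uniform sequence: all 16 odds ratios near 1
  sq <- random_dna(200000, 99)
  dp2 <- dinucleotide_preference(count_compositions(sq, NULL))
  expect_true(all(abs(dp2 - 1) < 0.05))
})

test_that("codon usage is synonymous-normalised", {
  gene <- paste(rep("CTG", 7), collapse = "")
  ann <- data.frame(start = 1, end = nchar(gene), strand = "+", gene = gene,
                    protein = strrep("L", 7), stringsAsFactors = FALSE)
  cu <- codon_usage(count_compositions(gene, ann))
  expect_equal(unname(cu["CTG"]), 1.0)
  expect_equal(unname(cu["CTA"]), 0.0)

  ann2 <- data.frame(start = 1, end = 6, strand = "+", gene = "AAAAAG",
                     protein = "KK", stringsAsFactors = FALSE)
  cu2 <- codon_usage(count_compositions("AAAAAG", ann2))
  expect_equal(unname(cu2[c("AAA", "AAG")]), c(0.5, 0.5))

  # per amino acid, synonymous codon usage sums to 1 when observed
  sim <- small_separable_sim(seed = 5, n_genomes = 1)
  sq <- sim$sequences[[1]]
  ann3 <- predict_coding_regions(sq)
  cu3 <- codon_usage(count_compositions(sq, ann3))
  gc <- Biostrings::GENETIC_CODE
  for (a in unique(gc[gc != "*"])) {
    cods <- names(gc)[gc == a]
    vals <- cu3[intersect(cods, names(cu3))]
    if (!anyNA(vals)) expect_equal(sum(vals), 1, tolerance = 1e-9)
  }
  # empty annotation: all codons unobserved
  expect_true(all(is.na(codon_usage(count_compositions("ACGTACGT", NULL)))))
})

test_that("codon-pair scores match exhaustive enumeration on toy genes", {
  ann <- data.frame(start = 1, end = 9, strand = "+", gene = "AAAAAAAAA",
                    protein = "KKK", stringsAsFactors = FALSE)
  cps <- codon_pair_score(count_compositions("AAAAAAAAA", ann))
  expect_equal(unname(cps["AAAAAA"]), 1.0)

  # alternating AAA/AAG: enumerate pairs by hand
  gene <- "AAAAAGAAAAAG"  # AAA AAG AAA AAG
  ann2 <- data.frame(start = 1, end = 12, strand = "+", gene = gene,
                     protein = "KKKK", stringsAsFactors = FALSE)
  cc <- count_compositions(gene, ann2)
  cps2 <- codon_pair_score(cc)
  # oracle: 3 adjacent pairs (AAA,AAG), (AAG,AAA), (AAA,AAG); n_KK = 3;
  # P_AAA = P_AAG = 0.5
  expect_equal(unname(cps2["AAAAAG"]), 2 / (3 * 0.5 * 0.5))
  expect_equal(unname(cps2["AAGAAA"]), 1 / (3 * 0.5 * 0.5))
  # observed amino-acid pair, unobserved synonymous codon pair: true zero
  expect_equal(unname(cps2["AAAAAA"]), 0)

  # single-codon gene: no pairs
  ann3 <- data.frame(start = 1, end = 3, strand = "+", gene = "AAA",
                     protein = "K", stringsAsFactors = FALSE)
  expect_true(all(is.na(codon_pair_score(count_compositions("AAA", ann3)))))
})

test_that("normalize_and_log floors unobserved values at 1e-4", {
  expect_equal(normalize_and_log(c(1, 2, 0.5)), c(0, 1, -1))
  expect_equal(normalize_and_log(0), log2(1e-4))
  expect_equal(normalize_and_log(NA_real_), log2(1e-4))
  expect_equal(normalize_and_log(c(a = 0))[["a"]], log2(1e-4))
  expect_error(normalize_and_log(-1), "non-negative")
})

test_that("trait vectors have the documented layout and dimension", {
  layout <- trait_layout("sbias")
  expect_length(layout, 137)
  expect_length(trait_layout("bias"), 137 + 3904)
  expect_false(anyDuplicated(layout) > 0)

  sim <- small_separable_sim(seed = 3, n_genomes = 1)
  sq <- sim$sequences[[1]]
  tv <- encode_traits(sq)
  expect_length(tv, 137)
  expect_identical(names(tv), as.character(layout))
  expect_true(all(is.finite(tv)))
  tvb <- encode_traits(sq, feature_set = "bias")
  expect_length(tvb, 4041)

  # determinism, case-invariance, trailing-N invariance
  expect_identical(tv, encode_traits(sq))
  expect_equal(unname(encode_traits(tolower(sq))), unname(tv))
  expect_equal(unname(encode_traits(paste0(sq, "NNNN"))), unname(tv))
})

test_that("a genome with no ORF falls back to unobserved coding traits", {
  # stop codons in every frame on both strands, and no start codon anywhere
  sq <- paste(rep("TAATAGTGACC", 30), collapse = "")
  tv <- encode_traits(sq)
  expect_true(all(tv[grepl("^cod_|^aa_", names(tv))] == log2(1e-4)))
  expect_true(all(is.finite(tv)))
})
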