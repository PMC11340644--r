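# Independent brute-force oracles (plain string scanning, no shared code
# with the package internals) and small fixture builders.

oracle_char_counts <- function(sq, alphabet) {
  chars <- strsplit(toupper(sq), "")[[1]]
  vapply(alphabet, function(a) sum(chars == a), 0L)
}

oracle_dinuc_counts <- function(sq, alphabet = c("A", "C", "G", "T")) {
  chars <- strsplit(toupper(sq), "")[[1]]
  pairs <- if (length(chars) >= 2) {
    paste0(chars[-length(chars)], chars[-1])
  } else character(0)
  combos <- as.vector(outer(alphabet, alphabet, paste0))
  vapply(combos, function(d) sum(pairs == d), 0L)
}

oracle_codons <- function(gene) {
  gene <- toupper(gene)
  n <- nchar(gene) %/% 3
  vapply(seq_len(n), function(i) substr(gene, 3 * i - 2, 3 * i), "")
}

oracle_translate <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

make_records <- function(orders, layer1, layer2 = NULL, family = NULL,
                         genus = NULL) {
  n <- length(layer1)
  data.frame(
    id = sprintf("v%03d", seq_len(n)),
    order = rep_len(orders, length.out = n),
    family = if (is.null(family)) rep(NA_character_, n) else rep_len(family, n),
    genus = if (is.null(genus)) rep(NA_character_, n) else rep_len(genus, n),
    host_layer1 = layer1,
    host_layer2 = if (is.null(layer2)) rep(NA_character_, n) else rep_len(layer2, n),
    stringsAsFactors = FALSE)
}

# A small two-host dataset with strong host signal, reused by model tests.
small_separable_sim <- function(seed = 11, n_genomes = 8) {
  simulate_dataset(sim_config(
    n_orders = 1, n_families = 2, n_genera = 2, n_genomes = n_genomes,
    host_labels = c("Chordata", "Viridiplantae"),
    bias_strength = 1, mutation_rate = 0.02,
    length_range = c(1000, 1400), seed = seed))
}
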