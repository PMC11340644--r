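# Synthetic viral genomes with controllable host-signal strength: host
# profiles shape codon usage, amino-acid composition and UTR nucleotide
# composition; genus-level ancestry makes homology features informative.

#' Simulation configuration
#'
#' @param n_orders number of virus orders.
#' @param n_families families per order.
#' @param n_genera genera per family.
#' @param n_genomes genomes per genus.
#' @param host_labels character vector of host labels cycled over the genera
#'   of each order. Layer-1 branch names are used as-is; layer-2 leaf names
#'   imply `host_layer1 = "Chordata"`.
#' @param bias_strength host-signal strength in `[0, 1]`: 0 gives uniform,
#'   host-independent composition; 1 gives near-deterministic host-specific
#'   synonymous codon choice.
#' @param mutation_rate per-site substitution probability applied to each
#'   genus member relative to the genus ancestor, in `[0, 0.5]`.
#' @param length_range genome length range in nt (min, max).
#' @param plant_case1 if `TRUE`, the last genus of the first order is given a
#'   minority host label while all other genera of that order share the
#'   dominant one, planting a genus whose host differs from its order's.
#' @param seed integer seed; all simulator randomness flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_orders = 1, n_families = 2, n_genera = 2,
                       n_genomes = 5,
                       host_labels = c("Chordata", "Viridiplantae"),
                       bias_strength = 1, mutation_rate = 0.02,
                       length_range = c(1200, 1800), plant_case1 = FALSE,
                       seed = 1) {
  stopifnot(n_orders >= 1, n_families >= 1, n_genera >= 1, n_genomes >= 1,
            bias_strength >= 0, bias_strength <= 1,
            mutation_rate >= 0, mutation_rate <= 0.5,
            length_range[1] >= 600)
  structure(list(n_orders = n_orders, n_families = n_families,
                 n_genera = n_genera, n_genomes = n_genomes,
                 host_labels = host_labels, bias_strength = bias_strength,
                 mutation_rate = mutation_rate, length_range = length_range,
                 plant_case1 = plant_case1, seed = as.integer(seed)),
            class = "sim_config")
}

# Synonymous codon families of the 20 amino acids.
codon_families <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc)[gc != "*"], gc[gc != "*"])
}

#' Host composition profiles
#'
#' One profile per host label. At strength 0 every profile is identical and
#' unbiased: synonymous codons equiprobable, amino acids uniform, UTR
#' nucleotides uniform and independent. At strength 1 each amino acid has one
#' label-specific preferred codon with probability >= 0.97, and amino-acid
#' and UTR nucleotide compositions are label-specific. The dinucleotide tilt
#' parameter scales with strength; tilt 0 yields independent (i.i.d.) UTR
#' composition.
#'
#' @param labels character vector of host labels.
#' @param bias_strength in `[0, 1]`.
#' @param seed integer seed; profiles are deterministic given it.
#' @return Named list of `host_profile` objects.
#' @export
make_host_profiles <- function(labels, bias_strength, seed = 1) {
  stopifnot(bias_strength >= 0, bias_strength <= 1)
  fams <- codon_families()
  s <- bias_strength
  with_seed(seed, {
    profiles <- lapply(seq_along(labels), function(i) {
      codon_dist <- lapply(fams, function(cods) {
        k <- length(cods)
        p <- rep(1 / k, k)
        if (k > 1 && s > 0) {
          pref <- sample.int(k, 1)
          p_pref <- (1 - s) / k + 0.98 * s
          p <- rep((1 - p_pref) / (k - 1), k)
          p[pref] <- p_pref
        }
        setNames(p, cods)
      })
      # Host selection acts on synonymous codon choice and nucleotide
      # background; protein (amino-acid) composition tracks the viral
      # lineage, not the host, so the profile carries a neutral base that
      # the dataset simulator perturbs per genus.
      aa_dist <- setNames(rep(1 / length(fams), length(fams)), names(fams))
      # Background (UTR) nucleotide composition carries only a mild host
      # tilt: host-driven composition bias is subtle at the mononucleotide
      # level, while the dominant signal sits in synonymous codon choice.
      nt_spec <- rgamma(4, shape = 6)
      nt_spec <- nt_spec / sum(nt_spec)
      w <- 0.25 * s
      nt_dist <- setNames((1 - w) * 0.25 + w * nt_spec,
                          c("A", "C", "G", "T"))
      structure(list(label = labels[i], codon_dist = codon_dist,
                     aa_dist = aa_dist, nt_dist = nt_dist, tilt = 0.3 * s),
                class = "host_profile")
    })
    names(profiles) <- labels
    profiles
  })
}

# Untranslated region as a first-order Markov chain: with probability tilt
# the next base repeats the current one, otherwise it is drawn i.i.d. from
# the profile's nucleotide distribution. tilt = 0 is exact independence.
sample_utr <- function(n, nt_dist, tilt) {
  if (n <= 0) return("")
  bases <- names(nt_dist)
  out <- character(n)
  out[1] <- sample(bases, 1, prob = nt_dist)
  if (n > 1) {
    repeat_flag <- runif(n - 1) < tilt
    draws <- sample(bases, n - 1, replace = TRUE, prob = nt_dist)
    for (i in 2:n) {
      out[i] <- if (repeat_flag[i - 1]) out[i - 1] else draws[i - 1]
    }
  }
  paste(out, collapse = "")
}

#' Simulate a single viral genome
#'
#' The genome is a 5' UTR, one open reading frame covering at least 80% of
#' the genome (ATG start, amino acids drawn from the profile's composition,
#' codons from its synonymous-codon distributions, TAA stop), and a 3' UTR.
#' The true coding annotation is returned alongside the sequence.
#'
#' @param profile a `host_profile` from [make_host_profiles()].
#' @param length total genome length in nt (>= 600).
#' @param seed integer seed.
#' @return List with `sequence` (character) and `annotation` (the true
#'   single-gene annotation, same shape as [predict_coding_regions()]).
#' @export
simulate_genome <- function(profile, length, seed = 1) {
  stopifnot(length >= 600)
  with_seed(seed, simulate_genome_impl(profile, length))
}

simulate_genome_impl <- function(profile, length) {
  n_cod <- floor(0.88 * length / 3)
  orf_nt <- 3 * n_cod
  n_aa <- n_cod - 1               # codons minus the stop
  aa <- c("M", sample(names(profile$aa_dist), n_aa - 1, replace = TRUE,
                      prob = profile$aa_dist))
  codons <- vapply(aa, function(a) {
    d <- profile$codon_dist[[a]]
    sample(names(d), 1, prob = d)
  }, character(1))
  codons[1] <- "ATG"
  orf <- paste(c(codons, "TAA"), collapse = "")
  utr5_len <- (length - orf_nt) %/% 2
  utr3_len <- length - orf_nt - utr5_len
  utr5 <- sample_utr(utr5_len, profile$nt_dist, profile$tilt)
  utr3 <- sample_utr(utr3_len, profile$nt_dist, profile$tilt)
  sq <- paste0(utr5, orf, utr3)
  ann <- data.frame(start = utr5_len + 1L, end = utr5_len + orf_nt,
                    strand = "+", gene = orf,
                    protein = paste(aa, collapse = ""),
                    stringsAsFactors = FALSE)
  list(sequence = sq, annotation = ann)
}

mutate_sequence <- function(sq, rate) {
  if (rate <= 0) return(sq)
  n <- nchar(sq)
  k <- rbinom(1, n, rate)
  if (k == 0) return(sq)
  pos <- sample.int(n, k)
  chars <- strsplit(sq, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Simulate a full reference dataset
#'
#' Builds a virus taxonomy (`order_*` / `fam_*` / `gen_*`), assigns each
#' genus a host label by cycling the configured labels, draws one ancestor
#' genome per genus from its host profile and derives the genus members as
#' independently mutated copies of that ancestor (substitutions only), so
#' same-genus sequences are alignable and homology features informative.
#'
#' @param config a [sim_config()].
#' @return List with `records` (metadata table), `sequences` (named
#'   character vector), `profiles` and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  labels <- config$host_labels
  tax <- host_taxonomy()
  l2u <- layer2_universe(tax)
  profiles <- make_host_profiles(labels, config$bias_strength,
                                 seed = config$seed)
  with_seed(config$seed + 1L, {
    recs <- list(); seqs <- character(0)
    for (o in seq_len(config$n_orders)) {
      ord <- sprintf("order_%d", o)
      g_idx <- 0L
      n_gen_total <- config$n_families * config$n_genera
      for (f in seq_len(config$n_families)) {
        fam <- sprintf("fam_%d_%d", o, f)
        for (g in seq_len(config$n_genera)) {
          g_idx <- g_idx + 1L
          gen <- sprintf("gen_%d_%d_%d", o, f, g)
          if (config$plant_case1 && o == 1) {
            lab <- if (g_idx == n_gen_total && length(labels) > 1) {
              labels[2]
            } else {
              labels[1]
            }
          } else {
            lab <- labels[((g_idx - 1) %% length(labels)) + 1]
          }
          L <- sample(seq(config$length_range[1], config$length_range[2]), 1)
          # Genus-specific protein composition, independent of the host.
          prof <- profiles[[lab]]
          jitter <- rgamma(length(prof$aa_dist), shape = 8)
          prof$aa_dist <- prof$aa_dist * jitter / sum(prof$aa_dist * jitter)
          ancestor <- simulate_genome_impl(prof, L)$sequence
          for (v in seq_len(config$n_genomes)) {
            id <- sprintf("%s_v%d", gen, v)
            seqs[[id]] <- mutate_sequence(ancestor, config$mutation_rate)
            if (lab %in% l2u) {
              l1 <- "Chordata"; l2 <- lab
            } else {
              l1 <- lab; l2 <- NA_character_
            }
            recs[[length(recs) + 1L]] <- data.frame(
              id = id, order = ord, family = fam, genus = gen,
              host_layer1 = l1, host_layer2 = l2, stringsAsFactors = FALSE)
          }
        }
      }
    }
    list(records = do.call(rbind, recs), sequences = seqs,
         profiles = profiles, config = config)
  })
}
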