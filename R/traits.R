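# Genomic-trait features: coding-region prediction, composition counting and
# the log2-transformed usage-preference vector.

.NUCS <- c("A", "C", "G", "T")
.DINUCS <- as.vector(outer(.NUCS, .NUCS, function(a, b) paste0(a, b)))
.STOP_CODONS <- c("TAA", "TAG", "TGA")
.ALL_CODONS <- as.vector(outer(as.vector(outer(.NUCS, .NUCS, paste0)), .NUCS, paste0))
.SENSE_CODONS <- sort(setdiff(.ALL_CODONS, .STOP_CODONS))
.AA20 <- sort(setdiff(unique(Biostrings::GENETIC_CODE), "*"))
# Codon pairs: first codon must not be a stop; 61 x 64 = 3904 entries.
.CODON_PAIRS <- as.vector(t(outer(.SENSE_CODONS, sort(.ALL_CODONS), paste0)))
.TRAIT_LAYOUT_VERSION <- "1"

#' Trait-vector feature layout
#'
#' The trait vector quantifies, in fixed order: whole-genome nucleotide
#' preferences (4), whole-genome dinucleotide preferences (16), synonymous
#' codon usage (61), amino-acid usage (20), coding-region nucleotide
#' preferences (4), coding-region dinucleotide preferences (16) and
#' codon-boundary ("bridge") dinucleotide preferences (16) -- 137 entries for
#' the `"sbias"` set. The `"bias"` set appends the 3,904 codon-pair scores
#' (pairs led by a stop codon are excluded). The layout is versioned; the
#' version travels with every fitted model.
#'
#' @param feature_set `"sbias"` (default, 137 traits) or `"bias"`
#'   (137 + 3904).
#' @return Ordered character vector of feature names, with attribute
#'   `"layout_version"`.
#' @export
trait_layout <- function(feature_set = c("sbias", "bias")) {
  feature_set <- match.arg(feature_set)
  nm <- c(paste0("nt_", .NUCS),
          paste0("din_", .DINUCS),
          paste0("cod_", .SENSE_CODONS),
          paste0("aa_", .AA20),
          paste0("cnt_", .NUCS),
          paste0("cdin_", .DINUCS),
          paste0("bdin_", .DINUCS))
  if (feature_set == "bias") nm <- c(nm, paste0("cps_", .CODON_PAIRS))
  structure(nm, layout_version = .TRAIT_LAYOUT_VERSION)
}

clean_seq <- function(x) toupper(as.character(x))

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

split_codons <- function(gene) {
  n <- nchar(gene) %/% 3
  if (n == 0) return(character(0))
  i <- 3 * (seq_len(n) - 1) + 1
  substring(gene, i, i + 2)
}

translate_codons <- function(codons) {
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- NA_character_
  aa
}

# ORFs in one strand of a sequence: first ATG after the previous in-frame
# stop, through the next in-frame stop, total span (including the stop
# codon) >= min_len. With allow_partial, edge-truncated candidates (no
# leading ATG before the first in-frame stop; no stop after the last
# in-frame ATG) are also reported, marked partial, the way metagenomic gene
# callers report genes running off a contig edge.
orfs_one_strand <- function(sq, min_len, allow_partial = FALSE) {
  L <- nchar(sq)
  out <- list()
  for (frame in 0:2) {
    n_cod <- (L - frame) %/% 3
    if (n_cod < 2) next
    i <- frame + 3 * (seq_len(n_cod) - 1) + 1
    codons <- substring(sq, i, i + 2)
    stops <- which(codons %in% .STOP_CODONS)
    prev <- 0L
    for (s in stops) {
      seg <- (prev + 1L):s
      starts <- seg[codons[seg] == "ATG"]
      if (length(starts) > 0) {
        a <- starts[1]
        span <- 3 * (s - a + 1)
        if (span >= min_len) {
          out[[length(out) + 1L]] <- c(start = i[a], end = i[s] + 2L,
                                       partial = 0)
        }
      }
      prev <- s
    }
    if (allow_partial) {
      # 5'-truncated: the frame start through the first stop (or the whole
      # open frame when no stop occurs).
      first_stop <- if (length(stops) > 0) stops[1] else n_cod
      span <- 3 * first_stop
      if (span >= min_len) {
        out[[length(out) + 1L]] <- c(start = i[1],
                                     end = i[first_stop] + 2L, partial = 1)
      }
      # 3'-truncated: the first ATG after the last stop through the end.
      if (length(stops) > 0 && stops[length(stops)] < n_cod) {
        seg <- (stops[length(stops)] + 1L):n_cod
        starts <- seg[codons[seg] == "ATG"]
        if (length(starts) > 0) {
          span <- 3 * (n_cod - starts[1] + 1)
          if (span >= min_len) {
            out[[length(out) + 1L]] <- c(start = i[starts[1]],
                                         end = i[n_cod] + 2L, partial = 1)
          }
        }
      }
    }
  }
  out
}

#' Predict coding regions in a viral genome
#'
#' The built-in `"naive_orf"` backend reports open reading frames of at least
#' `min_orf_len` nt (ATG through in-frame stop, both strands), selected
#' longest-first with greedy non-overlap; it is fully deterministic and needs
#' no external software. The `"prodigal"` backend delegates to the Prodigal
#' gene caller in metagenomic mode when that executable is available.
#'
#' @param genome nucleotide sequence (character or `DNAString`), alphabet
#'   `A/C/G/T/N`.
#' @param backend `"naive_orf"` (default) or `"prodigal"`.
#' @param min_orf_len minimum ORF span in nt, stop codon included
#'   (default 300).
#' @param prodigal_path path to the prodigal executable.
#' @param allow_partial also report edge-truncated genes (missing start or
#'   stop at a sequence boundary), the way metagenomic gene callers handle
#'   genes running off a contig edge; complete ORFs always take precedence.
#'   Default `FALSE`.
#' @return A data.frame with one row per gene: `start`, `end` (1-based,
#'   inclusive, on the forward genome), `strand`, `gene` (in-frame nucleotide
#'   sequence including the stop codon) and `protein` (stop excluded). Zero
#'   rows when no ORF is found.
#' @export
predict_coding_regions <- function(genome, backend = c("naive_orf", "prodigal"),
                                   min_orf_len = 300,
                                   prodigal_path = "prodigal",
                                   allow_partial = FALSE) {
  backend <- match.arg(backend)
  sq <- clean_seq(genome)
  if (nchar(sq) < 60) stop("genome shorter than 60 nt")
  if (backend == "prodigal") {
    return(prodigal_annotation(sq, prodigal_path))
  }
  L <- nchar(sq)
  fwd <- orfs_one_strand(sq, min_orf_len, allow_partial)
  rc <- revcomp(sq)
  rev <- orfs_one_strand(rc, min_orf_len, allow_partial)
  cand <- data.frame(start = integer(0), end = integer(0),
                     strand = character(0), partial = integer(0),
                     stringsAsFactors = FALSE)
  if (length(fwd) > 0) {
    m <- do.call(rbind, fwd)
    cand <- rbind(cand, data.frame(start = m[, "start"], end = m[, "end"],
                                   strand = "+", partial = m[, "partial"],
                                   stringsAsFactors = FALSE))
  }
  if (length(rev) > 0) {
    m <- do.call(rbind, rev)
    # Map coordinates on the reverse complement back to the forward genome.
    cand <- rbind(cand, data.frame(start = L - m[, "end"] + 1L,
                                   end = L - m[, "start"] + 1L,
                                   strand = "-", partial = m[, "partial"],
                                   stringsAsFactors = FALSE))
  }
  if (nrow(cand) == 0) return(empty_annotation())
  len <- cand$end - cand$start + 1L
  # Complete ORFs first, then partial candidates, longest first within each.
  cand <- cand[order(cand$partial, -len, cand$start, cand$strand), ,
               drop = FALSE]
  chosen <- logical(nrow(cand))
  occupied <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- cand$end[i]
    if (nrow(occupied) == 0 ||
        all(e < occupied[, 1] | s > occupied[, 2])) {
      chosen[i] <- TRUE
      occupied <- rbind(occupied, c(s, e))
    }
  }
  cand <- cand[chosen, , drop = FALSE]
  cand <- cand[order(cand$start), , drop = FALSE]
  finish_annotation(cand[, c("start", "end", "strand")], sq)
}

empty_annotation <- function() {
  data.frame(start = integer(0), end = integer(0), strand = character(0),
             gene = character(0), protein = character(0),
             stringsAsFactors = FALSE)
}

finish_annotation <- function(cand, sq) {
  gene <- character(nrow(cand)); protein <- character(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    g <- substring(sq, cand$start[i], cand$end[i])
    if (cand$strand[i] == "-") g <- revcomp(g)
    g <- substring(g, 1, (nchar(g) %/% 3) * 3)
    cods <- split_codons(g)
    # Trim trailing stop from the translation.
    if (length(cods) > 0 && cods[length(cods)] %in% .STOP_CODONS) {
      aa <- translate_codons(cods[-length(cods)])
    } else {
      aa <- translate_codons(cods)
    }
    gene[i] <- g
    protein[i] <- paste(ifelse(is.na(aa), "X", aa), collapse = "")
  }
  cand$gene <- gene
  cand$protein <- protein
  rownames(cand) <- NULL
  cand
}

prodigal_annotation <- function(sq, prodigal_path) {
  exe <- find_executable(prodigal_path)
  if (!nzchar(exe)) {
    stop("prodigal executable not found: ", prodigal_path,
         " (configuration error)")
  }
  dir <- tempfile("prodigal_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  fa <- file.path(dir, "in.fa")
  writeLines(c(">query", sq), fa)
  genes_fa <- file.path(dir, "genes.fna")
  status <- system2(exe, c("-i", fa, "-p", "meta", "-d", genes_fa,
                           "-o", file.path(dir, "out.gbk"), "-q"),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("prodigal failed with exit status ", status)
  if (!file.exists(genes_fa) || file.size(genes_fa) == 0) {
    return(empty_annotation())
  }
  genes <- Biostrings::readDNAStringSet(genes_fa)
  hdr <- names(genes)
  parts <- strsplit(hdr, "\\s*#\\s*")
  cand <- data.frame(
    start = as.integer(vapply(parts, `[[`, "", 2)),
    end = as.integer(vapply(parts, `[[`, "", 3)),
    strand = ifelse(vapply(parts, `[[`, "", 4) == "1", "+", "-"),
    stringsAsFactors = FALSE)
  finish_annotation(cand, sq)
}

#' Count sequence compositions
#'
#' Nucleotide and overlapping dinucleotide occurrences are counted over the
#' full genome (all segments pooled; windows never span a segment boundary;
#' ambiguous bases are skipped). Codon, amino-acid and adjacent-codon-pair
#' occurrences are counted over the predicted in-frame genes: stop codons are
#' excluded from the amino-acid tally and pairs led by a stop codon are
#' excluded. Coding-region and codon-boundary ("bridge") nucleotide and
#' dinucleotide occurrences are counted separately to support the full trait
#' layout.
#'
#' @param genome character vector of one or more nucleotide sequences
#'   (segments of a single virus).
#' @param annotation a coding annotation as returned by
#'   [predict_coding_regions()]; pass a zero-row annotation for a genome with
#'   no predicted genes.
#' @return An object of class `composition_counts`: a list of named integer
#'   vectors `nt`, `dinuc`, `codon`, `aa`, `codon_pair`, `aa_pair`,
#'   `coding_nt`, `coding_dinuc`, `bridge_dinuc`.
#' @export
count_compositions <- function(genome, annotation = NULL) {
  sqs <- clean_seq(genome)
  if (is.null(annotation)) annotation <- empty_annotation()
  set <- Biostrings::DNAStringSet(sqs)
  nt <- colSums(Biostrings::letterFrequency(set, .NUCS))
  dinuc <- colSums(Biostrings::dinucleotideFrequency(set, step = 1))[.DINUCS]

  codon <- setNames(integer(length(.ALL_CODONS)), sort(.ALL_CODONS))
  cp <- integer(0)
  aap <- integer(0)
  genes <- clean_seq(annotation$gene)
  coding_nt <- setNames(numeric(4), .NUCS)
  coding_dinuc <- setNames(numeric(16), .DINUCS)
  bridge_dinuc <- setNames(numeric(16), .DINUCS)
  for (g in genes) {
    cods <- split_codons(g)
    # Trailing stop belongs to the gene span but not to the codon tallies
    # beyond marking the end; internal stops stay countable as codons.
    valid <- cods %in% .ALL_CODONS
    tab <- table(cods[valid])
    codon[names(tab)] <- codon[names(tab)] + as.integer(tab)
    # Adjacent (overlapping chain) codon pairs within this gene; a pair is
    # dropped if either codon is ambiguous or its leading codon is a stop.
    if (length(cods) >= 2) {
      a <- cods[-length(cods)]; b <- cods[-1]
      ok <- a %in% .SENSE_CODONS & b %in% .ALL_CODONS & !(b %in% .STOP_CODONS)
      if (any(ok)) {
        pr <- paste0(a[ok], b[ok])
        tp <- table(pr)
        cp <- add_counts(cp, tp)
        aa_a <- translate_codons(a[ok]); aa_b <- translate_codons(b[ok])
        ta <- table(paste0(aa_a, aa_b))
        aap <- add_counts(aap, ta)
      }
    }
    gset <- Biostrings::DNAStringSet(g)
    coding_nt <- coding_nt + Biostrings::letterFrequency(gset, .NUCS)[1, ]
    coding_dinuc <- coding_dinuc +
      Biostrings::dinucleotideFrequency(gset, step = 1)[1, .DINUCS]
    # Bridge dinucleotides: the pair spanning each codon boundary
    # (positions 3k, 3k+1).
    n_cod <- length(cods)
    if (n_cod >= 2) {
      i <- 3 * seq_len(n_cod - 1)
      br <- substring(g, i, i + 1)
      br <- br[br %in% .DINUCS]
      tb <- table(br)
      bridge_dinuc[names(tb)] <- bridge_dinuc[names(tb)] + as.integer(tb)
    }
  }
  aa_counts <- setNames(numeric(length(.AA20)), .AA20)
  for (cdn in .SENSE_CODONS) {
    aa <- unname(Biostrings::GENETIC_CODE[cdn])
    aa_counts[aa] <- aa_counts[aa] + codon[cdn]
  }
  structure(
    list(nt = nt, dinuc = dinuc, codon = codon, aa = aa_counts,
         codon_pair = cp, aa_pair = aap,
         coding_nt = coding_nt, coding_dinuc = coding_dinuc,
         bridge_dinuc = bridge_dinuc),
    class = "composition_counts")
}

add_counts <- function(acc, tab) {
  if (length(tab) == 0) return(acc)
  new <- setdiff(names(tab), names(acc))
  if (length(new) > 0) acc[new] <- 0L
  acc[names(tab)] <- acc[names(tab)] + as.integer(tab)
  acc
}

#' Nucleotide usage preference
#'
#' `P_x = n_x / sum(n_x)`. A zero total flags every entry as unobserved
#' (`NA`), later floored by [normalize_and_log()].
#'
#' @param counts a [count_compositions()] result.
#' @param scope `"genome"` (default) or `"coding"`.
#' @return Named numeric vector over A, C, G, T.
#' @export
nucleotide_preference <- function(counts, scope = c("genome", "coding")) {
  scope <- match.arg(scope)
  n <- if (scope == "genome") counts$nt else counts$coding_nt
  tot <- sum(n)
  if (tot == 0) return(setNames(rep(NA_real_, 4), .NUCS))
  n / tot
}

#' Dinucleotide usage preference (odds ratio)
#'
#' `P_xy = (n_xy / sum(n_xy)) / (P_x * P_y)`: the observed overlapping
#' dinucleotide frequency divided by the product of the component nucleotide
#' frequencies of the same scope. Values near 1 indicate independent
#' composition; unobserved pairs are `NA`.
#'
#' @param counts a [count_compositions()] result.
#' @param scope `"genome"` (whole-genome windows), `"coding"` (within-gene
#'   windows) or `"bridge"` (codon-boundary windows, normalised by coding
#'   nucleotide frequencies).
#' @return Named numeric vector over the 16 dinucleotides.
#' @export
dinucleotide_preference <- function(counts,
                                    scope = c("genome", "coding", "bridge")) {
  scope <- match.arg(scope)
  n_xy <- switch(scope, genome = counts$dinuc, coding = counts$coding_dinuc,
                 bridge = counts$bridge_dinuc)
  p_nt <- nucleotide_preference(counts,
                                if (scope == "genome") "genome" else "coding")
  tot <- sum(n_xy)
  out <- setNames(rep(NA_real_, 16), .DINUCS)
  if (tot == 0 || anyNA(p_nt)) return(out)
  for (d in .DINUCS) {
    px <- p_nt[substring(d, 1, 1)]; py <- p_nt[substring(d, 2, 2)]
    if (n_xy[d] == 0) {
      out[d] <- if (px > 0 && py > 0) 0 else NA_real_
    } else if (px > 0 && py > 0) {
      out[d] <- (n_xy[d] / tot) / (px * py)
    }
  }
  out
}

#' Synonymous codon usage
#'
#' `P_xyz = n_xyz / n_A`, where codon `xyz` encodes amino acid `A`. For each
#' amino acid with observed codons, its synonymous codons' values sum to 1;
#' amino acids with `n_A = 0` have all their codons flagged unobserved.
#'
#' @param counts a [count_compositions()] result.
#' @return Named numeric vector over the 61 sense codons.
#' @export
codon_usage <- function(counts) {
  out <- setNames(rep(NA_real_, length(.SENSE_CODONS)), .SENSE_CODONS)
  for (cdn in .SENSE_CODONS) {
    aa <- unname(Biostrings::GENETIC_CODE[cdn])
    n_a <- counts$aa[aa]
    if (n_a > 0) out[cdn] <- counts$codon[cdn] / n_a
  }
  out
}

#' Amino-acid usage
#'
#' `P_A = n_A / sum(n_A)` over the 20 standard amino acids (stops excluded).
#'
#' @param counts a [count_compositions()] result.
#' @return Named numeric vector over the 20 amino acids.
#' @export
amino_acid_usage <- function(counts) {
  tot <- sum(counts$aa)
  if (tot == 0) return(setNames(rep(NA_real_, length(.AA20)), .AA20))
  counts$aa / tot
}

#' Codon-pair score
#'
#' `CPS(c1, c2) = n_{c1 c2} / (n_{AB} * P_{c1} * P_{c2})`, where codons `c1`,
#' `c2` encode amino acids `A`, `B`, `n_{AB}` counts adjacent amino-acid
#' pairs and `P` is the synonymous codon usage of [codon_usage()]. Pairs led
#' by a stop codon are excluded (3,904 entries). Pairs with `n_{AB} = 0` are
#' unobserved.
#'
#' @param counts a [count_compositions()] result.
#' @return Named numeric vector over the 3,904 codon pairs.
#' @export
codon_pair_score <- function(counts) {
  p_cod <- codon_usage(counts)
  out <- setNames(rep(NA_real_, length(.CODON_PAIRS)), .CODON_PAIRS)
  if (length(counts$codon_pair) == 0) return(out)
  for (pair in names(counts$codon_pair)) {
    c1 <- substring(pair, 1, 3); c2 <- substring(pair, 4, 6)
    if (!(c1 %in% .SENSE_CODONS) || !(c2 %in% .SENSE_CODONS)) next
    aa1 <- unname(Biostrings::GENETIC_CODE[c1])
    aa2 <- unname(Biostrings::GENETIC_CODE[c2])
    n_ab <- counts$aa_pair[paste0(aa1, aa2)]
    if (is.na(n_ab) || n_ab == 0) next
    p1 <- p_cod[c1]; p2 <- p_cod[c2]
    if (!is.na(p1) && !is.na(p2) && p1 > 0 && p2 > 0) {
      out[pair] <- counts$codon_pair[pair] / (n_ab * p1 * p2)
    }
  }
  # Observed amino-acid pairs make their unobserved synonymous codon pairs a
  # true zero rather than missing.
  for (pair in .CODON_PAIRS) {
    if (!is.na(out[pair])) next
    c1 <- substring(pair, 1, 3); c2 <- substring(pair, 4, 6)
    if (!(c2 %in% .SENSE_CODONS)) next
    aa1 <- unname(Biostrings::GENETIC_CODE[c1])
    aa2 <- unname(Biostrings::GENETIC_CODE[c2])
    n_ab <- counts$aa_pair[paste0(aa1, aa2)]
    if (!is.na(n_ab) && n_ab > 0) out[pair] <- 0
  }
  out
}

#' Floor and log2-transform trait values
#'
#' Zero and missing values are replaced by a small floor (1e-4 by default)
#' and all values are log2-transformed, so positive outputs mark
#' overrepresented traits and negative outputs underrepresented ones.
#'
#' @param values non-negative numeric vector (NA = unobserved).
#' @param floor replacement for zero/missing values.
#' @return Numeric vector of the same length and names.
#' @export
normalize_and_log <- function(values, floor = 1e-4) {
  v <- as.numeric(values)
  if (any(!is.na(v) & v < 0)) stop("trait values must be non-negative")
  v[is.na(v)] <- 0
  out <- log2(pmax(v, floor))
  names(out) <- names(values)
  out
}

#' Encode a genome as a trait vector
#'
#' Computes the composition counts, the five usage-preference maps and
#' concatenates them in the fixed [trait_layout()] order, floored and
#' log2-transformed. The `"sbias"` set has 137 entries; `"bias"` appends the
#' 3,904 codon-pair scores. Encoding is invariant to input case and to
#' trailing ambiguous bases, and deterministic.
#'
#' @param genome character vector of nucleotide sequences (segments pooled).
#' @param annotation optional precomputed coding annotation; predicted with
#'   the naive ORF backend when absent.
#' @param feature_set `"sbias"` or `"bias"`.
#' @param floor floor for unobserved values (see [normalize_and_log()]).
#' @return Named numeric vector following [trait_layout()], with attributes
#'   `feature_set` and `layout_version`.
#' @export
encode_traits <- function(genome, annotation = NULL,
                          feature_set = c("sbias", "bias"), floor = 1e-4) {
  feature_set <- match.arg(feature_set)
  sqs <- clean_seq(genome)
  if (is.null(annotation)) {
    # Partial (edge-truncated) genes are admitted here so that fragmented
    # contigs keep their coding traits.
    ann_list <- lapply(sqs, function(s) {
      if (nchar(s) >= 60) {
        predict_coding_regions(s, allow_partial = TRUE)
      } else {
        empty_annotation()
      }
    })
    annotation <- do.call(rbind, ann_list)
  }
  counts <- count_compositions(sqs, annotation)
  vals <- c(nucleotide_preference(counts, "genome"),
            dinucleotide_preference(counts, "genome"),
            codon_usage(counts),
            amino_acid_usage(counts),
            nucleotide_preference(counts, "coding"),
            dinucleotide_preference(counts, "coding"),
            dinucleotide_preference(counts, "bridge"))
  if (feature_set == "bias") vals <- c(vals, codon_pair_score(counts))
  layout <- trait_layout(feature_set)
  out <- normalize_and_log(vals, floor)
  names(out) <- layout
  attr(out, "feature_set") <- feature_set
  attr(out, "layout_version") <- attr(layout, "layout_version")
  out
}

#' Encode many genomes as a trait matrix
#'
#' @param sequences named character vector (or list of character vectors for
#'   multi-segment viruses) of genome sequences.
#' @param feature_set `"sbias"` or `"bias"`.
#' @param annotations optional named list of precomputed annotations.
#' @return Numeric matrix, one row per sequence, columns per
#'   [trait_layout()].
#' @export
encode_trait_matrix <- function(sequences, feature_set = c("sbias", "bias"),
                                annotations = NULL) {
  feature_set <- match.arg(feature_set)
  ids <- names(sequences)
  if (is.null(ids)) stop("sequences must be named by record id")
  layout <- trait_layout(feature_set)
  out <- matrix(NA_real_, nrow = length(sequences), ncol = length(layout),
                dimnames = list(ids, as.character(layout)))
  for (i in seq_along(sequences)) {
    ann <- if (!is.null(annotations)) annotations[[ids[i]]] else NULL
    out[i, ] <- encode_traits(sequences[[i]], annotation = ann,
                              feature_set = feature_set)
  }
  out
}
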