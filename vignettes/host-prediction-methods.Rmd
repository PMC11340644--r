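---
title: "Methods: hierarchical host prediction for RNA viruses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical host prediction for RNA viruses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Metagenomic sequencing yields RNA virus genomes whose hosts are unknown;
assigning a likely host from sequence alone is the task this package
addresses. The prediction is hierarchical over a fixed two-layer host
taxonomy: layer 1 distinguishes five kingdom/phylum branches (Chordata,
Invertebrate, Viridiplantae, Fungi, Bacteria); layer 2 refines Chordata into
ten class/order leaves (Primates, Rodentia, Carnivora, Artiodactyla,
Chiroptera, Other Mammalia, Aves, Reptilia, Amphibia, Fish). Because
different virus orders have disjoint biology and host ranges, one classifier
is trained per virus order; queries are routed by their order annotation.

Each genome is represented by two concatenated blocks:

* **Genomic traits** `S` (137 values, the `sbias` set). The working
  assumption is genomic mimicry: viruses under long-term selection drift
  toward the composition biases of their hosts. The block holds
  log2-transformed usage preferences: nucleotide frequencies
  `P_x = n_x / sum(n_x)`; dinucleotide odds ratios
  `P_xy = (n_xy / sum(n_xy)) / (P_x P_y)` over overlapping windows;
  synonymous codon usage `P_xyz = n_xyz / n_A` (codon `xyz` encoding amino
  acid `A`); amino-acid usage `P_A = n_A / sum(n_A)`; plus the same
  nucleotide and dinucleotide statistics restricted to predicted coding
  regions and to codon-boundary ("bridge") windows. The optional `bias` set
  appends 3,904 codon-pair scores
  `CPS(c1, c2) = n_{c1 c2} / (n_AB P_{c1} P_{c2})`, excluding pairs led by a
  stop codon.
* **Sequence homology** `H` (`m` values): for each of the `m` host groups of
  the order's reference set, the log10 of the best local-alignment bitscore
  of the query against any member of that group, with 1 (hence log10 = 0)
  when no alignment is found. Related viruses tend to infect related hosts,
  so the best hit per host group is a strong, complementary signal.

The classifier input is `X = [S | H]` of length `137 + m`. The default
learner is gradient boosting (xgboost, multi-class softprob, library
defaults: `eta = 0.3`, `max_depth = 6`, 100 rounds, single thread, fixed
seed); a random-forest alternative is selectable for architecture
comparisons. Per-layer score vectors are probabilities summing to one.

## The 137-trait layout

The plain reading of the trait families gives 4 + 16 + 61 + 20 = 101 values.
The shipped layout reaches exactly 137 by adding coding-region nucleotide
preferences (4), coding-region dinucleotide preferences (16) and bridge
dinucleotide preferences (16), all well-defined from the same counting pass.
The layout is a versioned constant (`trait_layout()`); the version travels
with every fitted bundle, and a bundle whose layout version differs from the
installed one refuses to load. If an authoritative enumeration of the 137
traits becomes available the layout can be revised under a new version
without silent incompatibility.

# Label screening

Reference corpora are biased toward human-associated viruses, so host labels
are screened per virus order before training (`screen_labels()`):

1. records whose metadata lists several layer-1 hosts are removed — their
   composition reflects conflicting selection pressures;
2. within an order whose mammalian layer-2 records total fewer than 50, the
   six mammalian leaves collapse into a single `Mammalia` node;
3. in orders with more than 30 records, host labels carried by fewer than 10
   records are dropped (both layers; the merged `Mammalia` node is an
   ordinary layer-2 label for this rule).

Merging runs before filtering because a merged mammal node can clear the
count threshold its components would fail individually. The merge/filter
pass repeats until the dataset is stable: filtering can push a previously
safe mammal count below the merge threshold, and iterating to a fixed point
is what makes screening idempotent — a property the test suite asserts.
Orders with at most 30 records keep all labels and are only flagged "small";
with so few references any count rule would be arbitrary.

## Order prediction modes

An order whose references carry exactly one distinct leaf label across the
whole tree is a *direct-assignment* order: queries receive that label with
score 1 and no model is trained. An order with any layer-2-labelled records
is a *two-layer* order; note a two-layer order may still have a single
distinct layer-2 label (the merged `Mammalia` rows) — it then receives a
direct assignment at layer 2 while layer 1 is modelled normally. Everything
else is *layer-1-only*. On the packaged host-distribution table this yields
12 direct-assignment, 13 two-layer and 5 layer-1-only orders over the
30-order registry.

# Coding-region prediction

The default gene caller is a deterministic ORF scanner: ATG through in-frame
stop on both strands, minimum span 300 nt, longest-first greedy non-overlap
selection. Inside the trait encoder (and only there) edge-truncated genes
are also admitted — an open frame running off a contig edge without its
start or stop — because metagenome-assembled fragments routinely cut genes;
complete ORFs always take precedence. An external Prodigal backend (meta
mode) is available where the executable is configured; the naive scanner
keeps the package fully testable without external software.

# Alignment backends

Homology features use BLASTN with default parameters when the executables
are on the path (`aligner = "auto"`), writing one database per host group.
The built-in fallback is an exhaustive Smith–Waterman (match +2, mismatch
−3, gap open 5, extend 2) whose raw score is converted to a bitscore with
the Karlin–Altschul parameters matching those penalties (λ = 0.625,
K = 0.41). Because exhaustive local alignment always produces some chance
alignment — unlike seeded BLASTN, which simply reports no hit — the fallback
admits a hit only below an e-value of 1e-5; otherwise the group keeps the
no-alignment default of 1. The two backends need not agree on scores; the
contract, asserted by a test, is agreement on the best-scoring group.

During training, a record's own sequence is excluded from its homology
references (and in leave-one-genus-out runs, its whole genus), otherwise
every training feature would contain a perfect self-hit. At prediction time
the full reference set is used.

# Rejection of out-of-distribution queries

Queries whose hosts fall outside the label list should be rejected rather
than mislabelled. Each order/layer gets an empirical score cutoff: the
smallest observed out-of-fold validation top score at which the retained
predictions reach a configurable precision target (default 0.95). The
out-of-fold scores come from an internal stratified 3-fold pass inside
`viralhost()` (skipped below 20 validation points, where the estimate would
be noise). The full precision / prediction-rate trade-off curve is kept on
the fitted object and drawn by `plot()`. The cross-validation harness fits
*without* calibration: its metrics describe the raw classifier, and the
rejection mechanism is evaluated by its own threshold-scan test instead.

# Evaluation harnesses

* `stratified_kfold()` deals each host label's records to k folds in
  rotation after a seeded shuffle, so per-label fold sizes differ by at most
  one; `cross_validate()` refits per fold, with homology references drawn
  from the training fold only. Layer-2 metrics compound layer-1 errors.
* `compute_metrics()`: accuracy counts rejected queries as errors;
  prediction rate is the fraction of non-rejected queries; precision is
  computed among non-rejected predictions only; macro F1 averages per-label
  F1 with rejections as false negatives; rank-wise accuracies are unweighted
  means over the taxa present.
* `fragment_queries()` cuts exactly one contig per sequence per completeness
  ratio (90/75/60/45%), contiguous, uniformly placed under the seed. Uniform
  placement is the unbiased choice where nothing is known about which genome
  region survives assembly.
* `leave_one_genus_out()` removes an entire genus from both the training
  records and the homology index, emulating a novel-genus query; null model
  1 samples labels from the training distribution, null model 2 always
  answers the dominant label, and the alignment-only baseline takes the
  argmax of the homology vector.
* `host_homogeneity()` and `family_wise_analysis()` split families at
  r = 0.9 (a family exactly at the threshold counts as high-homogeneity;
  both readings appear in the literature and the inclusive one is fixed
  here and documented).
* Dominant-label ties anywhere (homogeneity, null model 2, challenge tags)
  break by the taxonomy's fixed label order, for determinism.

# The synthetic-data generator

Real reference corpora cannot ship with the package, so every harness runs
on simulated data with a controllable host signal (`simulate_dataset()`).
Each host label gets a profile; `bias_strength` interpolates between no
signal (0) and a strong one (1):

* synonymous codon usage: at strength 1 each amino acid has one
  label-preferred codon with probability 0.98, at strength 0 all synonymous
  codons are equiprobable — this is the main host signal, mirroring
  host-driven codon-usage mimicry;
* background (UTR) nucleotide composition carries only a mild label tilt
  (mixing weight 0.25 × strength toward a label-specific distribution),
  because real host-driven bias is subtle at the mononucleotide level; an
  early version with a fully label-specific background let boosted trees
  separate the training hosts on three nucleotide features alone, which
  generalised poorly to fragments and held-out genera — exactly the failure
  the weaker tilt avoids;
* amino-acid composition is deliberately host-independent: protein content
  tracks viral lineage and function, not host adaptation, so each genus
  ancestor draws its own composition jitter. Host signal must therefore be
  read from synonymous choice, not from protein composition;
* a dinucleotide tilt (first-order Markov repeat bias, 0.3 × strength; 0
  gives exact independence) perturbs the UTRs.

Genomes are a 5' UTR, one ORF covering ≥ 80% of the genome, and a 3' UTR.
Each genus draws one ancestor and derives members as independently mutated
copies (substitutions only — no indels, so the naive ORF caller stays valid
on descendants), making same-genus sequences alignable and homology features
informative. Genus labels cycle over the configured hosts; a "challenging"
genus whose host differs from its order's dominant one can be planted on
request.

What the simulator does *not* emulate: real phylogenetic structure,
recombination, segment reassortment, genome architecture beyond a single
ORF, amino-acid-level host signals, and realistic within-order diversity.
Passing tests therefore demonstrate that the machinery — encoding, routing,
training, rejection, evaluation — behaves correctly under a known signal,
not that the published accuracy levels transfer to any real corpus.

# Problem sizes and numerical choices

The test suite runs at desk scale, chosen so the full suite finishes in a
few minutes: the cross-validation property uses one order with 5 host groups
× 60 genomes (300 genomes of 1.2–1.8 kb, stratified 5-fold, accuracy
≥ 0.95 at strength 1, and chance level within three binomial standard errors
on strength-0 shuffled labels); the leave-one-genus-out property uses 24
genera (8 per host group), where held-out-ancestor generalisation becomes
reliable; the fragment harness uses 18 training genomes per label at four
completeness ratios. Unobserved trait values are floored at 1e-4 before the
log2 transform, so an unobserved trait maps to about −13.29 and zero scores
stay finite. All randomness flows from explicit integer seeds; repeated runs
are byte-identical, which the suite asserts.

# Known limitations

* The query's virus order must be supplied (or inferred upstream); an
  unknown order yields an explicit `unsupported_order` result, not a guess.
* Multi-host viruses are out of scope: one host lineage per query.
* Homology bitscores scale with query length, so models trained on
  full-length genomes see lower absolute scores for short fragments; with
  small reference sets this can clip tree thresholds. Large, length-diverse
  reference sets mitigate it.
* The rejection cutoffs are empirical and only as good as the out-of-fold
  score distribution; orders with few references get no cutoff (0, accept
  everything).
* Host-label noise in references (vector species recorded as hosts, carrier
  detections) propagates into training; the screening rules reduce but do
  not remove it.
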