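# viralhost

Host prediction for RNA viruses from genome sequence alone.

Novel RNA viruses pour out of metagenomic and metatranscriptomic surveys,
but the host of a virus assembled from an environmental sample is rarely
known — and the sample of origin is not a reliable proxy. `viralhost` is an
R implementation of a hierarchical machine-learning framework for this task,
aimed at virologists and microbiome researchers who need a fast,
sequence-only host call for assembled viral genomes or contigs.

## The method

Prediction runs along a fixed two-layer host taxonomy. Layer 1 holds five
kingdom/phylum branches — Chordata, Invertebrate, Viridiplantae, Fungi,
Bacteria — and layer 2 refines Chordata into ten class/order leaves
(Primates, Rodentia, Carnivora, Artiodactyla, Chiroptera, Other Mammalia,
Aves, Reptilia, Amphibia, Fish). One classifier is trained per virus order;
queries are routed by their order. Orders whose references all share a
single leaf label are handled by direct assignment.

Each genome is encoded as `X = [S | H] ∈ R^(137+m)`:

* `S ∈ R^137` — genomic traits: log2-transformed usage preferences of
  nucleotides (`P_x = n_x / Σ n_x`), dinucleotides
  (`P_xy = (n_xy / Σ n_xy) / (P_x P_y)`), synonymous codons
  (`P_xyz = n_xyz / n_A`) and amino acids (`P_A = n_A / Σ n_A`), computed
  over the genome and its predicted coding regions; an extended `bias` set
  appends 3,904 codon-pair scores
  (`CPS = n_{c1c2} / (n_AB · P_{c1} · P_{c2})`).
* `H ∈ R^m` — per host group, the log10 best local-alignment bitscore of
  the query against that group's references (0 when no alignment), via
  BLASTN or a built-in Smith–Waterman fallback.

Gradient boosting (xgboost, default parameters, fixed seed) maps `X` to
per-layer host probabilities; a per-order empirical score cutoff rejects
out-of-distribution queries rather than mislabelling them. Label screening,
stratified cross-validation, family-wise homogeneity analysis (`r`, the
dominant-host fraction of a family), fragment-completeness and
leave-one-genus-out harnesses with null models, and a synthetic-genome
simulator with controllable host-signal strength are all included — see the
methods vignette (`vignettes/host-prediction-methods.Rmd`).

## Worked example

Simulate a small reference set with a strong host signal, fit the
classifier, and predict hosts for three 75%-complete contigs:

```r
library(viralhost)

sim <- simulate_dataset(sim_config(
  n_orders = 1, n_families = 2, n_genera = 3, n_genomes = 6,
  host_labels = c("Chordata", "Viridiplantae", "Fungi"),
  bias_strength = 1, seed = 7))

fit <- viralhost(sim$records, sim$sequences, seed = 1)
print(fit)
#> Hierarchical virus-host classifier
#>   reference records: 36
#>   virus orders: 1 (0 direct, 1 layer-1 only, 0 two-layer)
#>   feature set: sbias | learner: xgboost | aligner: blast
#>   seed: 1 | trait layout version: 1

contigs <- fragment_queries(sim$sequences[c(1, 13, 25)],
                            ratios = 0.75, seed = 2)[["75"]]
predict(fit, contigs, orders = "order_1")[,
  c("id", "layer1_label", "layer1_score", "rejected")]
#>             id  layer1_label layer1_score rejected
#> 1 gen_1_1_1_v1      Chordata    0.9586737    FALSE
#> 2 gen_1_1_3_v1         Fungi    0.9586737    FALSE
#> 3 gen_1_2_2_v1 Viridiplantae    0.9586737    FALSE
```

All three contigs recover their simulated host group with high confidence
(`layer1_score` is the winning class probability; a query scoring below the
order's calibrated cutoff would come back with `rejected = TRUE` and no
label). Cross-validation of the same references:

```r
cv <- cross_validate(sim$records, sim$sequences, k = 3, seed = 1)
print(cv$metrics_layer1)
#> n = 36 | accuracy 0.9167 | prediction rate 1.0000 | precision 0.9167 | macro F1 0.9182
#>   order-wise 0.9167 | family-wise 0.9167 | genus-wise 0.9167
```

A thin command-line front end (`inst/scripts/viralhost-cli.R`) exposes
`simulate`, `train`, `predict` and `cv` subcommands over FASTA + TSV
metadata files.

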