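# mfpep — multi-label prediction of multi-functional therapeutic peptides

Many therapeutic peptides carry more than one activity at once — a single
sequence can be simultaneously antibacterial, antifungal and
anti-inflammatory. `mfpep` treats peptide function prediction as a
**multi-label** problem: given a peptide of 5–50 standard residues, score
each of M function classes (antibacterial ABP, anticancer ACP, antifungal
AFP, … tumor-homing THP) with an independent probability, and call every
label at probability ≥ 0.5.

The core of the package is a neural sequence classifier fitted by
`mfpnet()`:

* token embedding of the 20 amino acids (padding frozen at zero),
* multi-scale 1-D convolutions with kernel sizes {2, 3, 8} + max pooling,
* a bidirectional LSTM over the pooled features,
* multi-head scaled dot-product self-attention,
  `Attention(Q,K,V) = softmax(QKᵀ/√d_k)V`,
* global max pooling, dropout, and a dense sigmoid head,

trained with mini-batch Adam on a **class-weighted** binary cross-entropy.
The weights counter label imbalance (real benchmarks are skewed up to
~37:1): class *i* with nᵢ of N training peptides gets

    W_i = φ · [log₁₀(N / n_i)]^θ ,   1 ≤ θ ≤ (ln X − ln Y) / ln(log_Y X)

with X = N/min(nᵢ), Y = N/max(nᵢ), so rare classes weigh more. The whole
forward/backward pass is implemented in the package in base R matrix
algebra and verified against finite-difference gradients; no deep-learning
runtime is required.

Around the model sit the pieces needed to work with this kind of data:
multi-label FASTA IO (`>id|CODE1,CODE2` headers), benchmark-style curation
(`curate_peptides()`: standard residues, length 5–50, classes with ≥ 40
members), the five set-theoretic multi-label metrics
(`multilabel_metrics()`: precision, coverage, accuracy, absolute true,
absolute false), repeated-subsample evaluation with paired t-tests, a
motif-planted synthetic data generator with controllable imbalance and
label co-occurrence (`generate_peptides()`), ensembling, grid-search CV
and ablation runners, and a small CLI (`inst/cli/mfpep.R`).

## Worked example

Generate a synthetic 2-class peptide set (each class signalled by a planted
motif), train a small model, and evaluate:

```r
library(mfpep)

ds  <- generate_peptides(synth_spec(c(ABP = 150, ACP = 100),
                                    co_occurrence = 0.15,
                                    length_range = c(10, 30), seed = 7))
sp  <- split_train_test(ds$records, ratio = 0.8, seed = 7)
cfg <- model_config(n_labels = 2, L = 30, embed_dim = 16, filters = 8,
                    hidden = 12, heads = 2, d_k = 8, dropout = 0.2)
fit <- mfpnet(sp$train, ds$vocab, cfg, epochs = 60, lr = 3e-3, seed = 1)
fit
#> Multi-label peptide function classifier (mfpnet)
#>   200 training peptides, 2 classes, variant 'full'
#>   weight scheme: cw [positive mode] (phi = 1, theta = 1.000, log base 10)
#>   training loss: 0.35065 (epoch 1) -> 0.00042 (epoch 60)

truth <- encode_peptides(sp$test, ds$vocab, L = 30)$labels
multilabel_metrics(truth, predict(fit, sp$test, type = "label"))
#> Multi-label metrics (n = 50)
#>   Precision ↑       0.950
#>   Coverage ↑        0.990
#>   Accuracy ↑        0.940
#>   Absolute true ↑   0.880
#>   Absolute false ↓  0.060
```

The loss line shows the class-weighted BCE falling over training; the
metric block is the standard five-score report — *absolute true* is the
strictest (exact label-set match), *absolute false* the per-peptide
normalized symmetric difference (lower is better). On this separable
synthetic task the model recovers almost every label set exactly.

Class weights themselves are ordinary numbers you can inspect:

```r
cw_weights(c(ABP = 2154, AEP = 58), N = 7872)
#>       ABP       AEP 
#> 0.3439817 4.0804908 
#> attr(,"phi") 1   attr(,"theta") 1.856714   attr(,"base") 10
```

the rare anti-endotoxin class (58 of 7872 training peptides) is weighted
about 12 times more heavily than the large antibacterial class.

## Not in scope

Re-collection of published benchmark datasets, pretrained weights, ranking
based multi-label metrics, oversampling methods, and web deployment.
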