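# malsite

Sequence-based prediction of lysine malonylation sites in proteins.

Lysine malonylation is an acidic post-translational modification linked to
metabolic regulation and disease. Experimentally mapping modified lysines
by mass spectrometry is slow and expensive, so biologists screening
candidate proteins want a predictor that, given primary sequence alone,
ranks each lysine by its plausibility as a malonylation site. `malsite`
implements such a predictor end to end — for bioinformaticians building or
evaluating PTM-site models, and for bench scientists who just want a
ranked site table from a FASTA file.

## The method

Each candidate lysine is represented by its sequence window
*R*₋₆…*R*₋₁ **K** *R*₊₁…*R*₊₉ (a 16-mer; positions beyond a protein
terminus are filled with the dummy residue X). The window is encoded into
a 687-dimensional feature vector:

* **k-gram spectrum** (k = 1, 2): 21 + 21² = 462 occurrence counts over
  the 21-symbol alphabet;
* **position-specific residue codes**: the numeric code (1–20
  alphabetically, X = 21) at each of the 15 non-center positions;
* **physicochemical profile**: 14 amino-acid property scales
  (hydrophobicity, polarity, molecular weight, …) at each of the 15
  positions, 210 values, with X ≡ 0.

Dataset-constant features are dropped, the remainder min-max scaled, and
greedy **mRMR** (minimum-Redundancy-Maximum-Relevance) selects the 50
features maximizing mutual information with the class label while
penalizing redundancy, I(f; y) − (1/|S|) Σ_{s∈S} I(f; s). A
probability-output **RBF-kernel SVM** (libsvm, γ = 0.0125, C = 1, Platt
calibration) scores each window; sites with Pr(positive) > θ = 0.5 are
called malonylated. Evaluation supports leave-one-out and repeated
stratified k-fold cross-validation with Sn/Sp/Ac/MCC and ROC/AUC, the
whole preprocessing chain refitted inside every training fold. A
synthetic-data module generates benchmarks with planted positional
enrichments so the entire pipeline is testable without downloads, and a
motif module reports per-position residue enrichments between positive and
negative sets (two-sample Welch t-test on occurrence indicators).

See the methods vignette (`vignettes/methods.Rmd`) for the model's
assumptions, tunables and limitations.

## Worked example

```r
library(malsite)

# a labeled synthetic benchmark: 60 positive, 240 negative 16-mers
ds <- generate_windows(synthetic_spec(n_positive = 60, n_negative = 240),
                       seed = 1)
model <- mal_fit(ds, pipeline = mal_pipeline(n_features = 25), seed = 1)
model
#> mal_model: trained on 300 windows (60 positive / 240 negative)
#>   687 -> 657 features after constant removal; 25 selected by mRMR (MID)
#> mal_pipeline: 16-mer windows, count k-grams, 25 mRMR features (MID),
#>   gamma = 0.0125, C = 1, theta = 0.5, scaling on, selection per fold

# score every lysine of a query protein
prot <- "MSKGEELFTGVVPILVELDGDVNGHKFSVSGEGEGDATYGKLTLKFICTTGKLPVPWPTLVTTF"
pos <- as.integer(gregexpr("K", prot)[[1]])
windows <- vapply(pos, function(p) extract_window(prot, p), character(1))
cbind(position = pos, classify(model, windows))
#>   position          peptide probability     call
#> 1        3 XXXXMSKGEELFTGVV   0.1959348 negative
#> 2       26 GDVNGHKFSVSGEGEG   0.2369537 negative
#> 3       41 GDATYGKLTLKFICTT   0.6933360 positive
#> 4       45 YGKLTLKFICTTGKLP   0.4896806 negative
#> 5       52 FICTTGKLPVPWPTLV   0.7875511 positive

# cross-validated performance of the full chain
res <- run_kfold(ds, pipeline = mal_pipeline(n_features = 25),
                 plan = cv_plan("kfold", k = 6, repeats = 5, seed = 1))
res
#> 6-fold x 5 cross-validation: AUC = 0.7467 (sd 0.0133 over repeats)
#> Sn = 0.3500  Sp = 0.9500  Ac = 0.8300  MCC = 0.3835
```

The probability column is Pr(malonylated | window); note the
terminus-padded window at position 3. The low sensitivity at θ = 0.5 under
1:4 imbalance is expected — ranking quality (AUC) is the primary metric,
and θ can be lowered for more permissive screening.

The same workflow is available from a shell via the bundled CLI
(`inst/scripts/malsite`): `simulate`, `build-dataset`, `encode`,
`select-features`, `train`, `predict`, `evaluate`, `logo`; every command
takes `--seed` and logs its resolved configuration, and the model-level
commands accept a YAML `--config` file whose values sit below explicit
flags.

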