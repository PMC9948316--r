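# fp2mol — translating structural fingerprints back into molecules

Structural fingerprints (MACCS keys, Avalon, atom pairs, topological
torsions, path-based and circular/Morgan fingerprints) encode a molecule
as a lossy *set* of substructure features. `fp2mol` inverts that
encoding by treating it as machine translation: the sorted fingerprint
feature identifiers form the source sentence, and a transformer
encoder–decoder learns to emit the molecule's SMILES or SELFIES string

```
molecule --featurize--> {f1, f2, ..., fk}  --transformer-->  "CC(=O)Oc1ccccc1C(=O)O"
```

Reconstruction quality is judged by set-Tanimoto similarity
`Tc(A, B) = |A ∩ B| / |A ∪ B|` between the fingerprints of prediction
and ground truth; the headline statistic is the **Tanimoto exactness**,
the percentage of top-1 predictions with `Tc = 1` under a chosen metric
fingerprint. Because a single metric is biased toward its own feature
type, exactness is recomputed across 15 metric fingerprints (a bias
matrix), accuracy is broken down into string-exact / non-canonical /
stereo / other / invalid categories, and raw similarities are
calibrated against the `Tc` value that only 1% of random molecule pairs
exceed (the p = 0.01 significance threshold). Integrated gradients and
cross-attention maps attribute each predicted token to the fingerprint
features that drove it.

The package is audience-complete for method development at desk scale:
it ships a synthetic drug-like corpus generator (a stand-in for the
millions-scale public corpora used at full scale), all thirteen
fingerprint featurizers, SMILES/SELFIES codecs including a robust
SELFIES-style language whose every token sequence decodes to a valid
molecule, a pure-R transformer (with an Rcpp attention kernel and
finite-difference-verified backpropagation), token-count batching, the
cyclic decayed learning-rate schedule, beam-search decoding, the full
evaluation suite and attribution maps.

## Worked example

```r
library(fp2mol)

# a reproducible synthetic corpus: <=50 heavy atoms, ~30% with stereo
mols <- generate_molecules(corpus_config(n_molecules = 300, seed = 42))
sp   <- split_corpus(mols, test_size = 50, seed = 43)

# fit a reduced translator: sparse radius-1 atom environments -> SMILES
fit <- fp_translator(
  sp$train, spec = "AEs", representation = "SMILES",
  model_cfg = model_config(n_layers = 2, n_heads = 4, d_model = 128,
                           d_ff = 256, max_len_src = 160, max_len_tgt = 120),
  train_cfg = train_config(tokens_per_batch = 800, max_steps = 1500, seed = 7),
  sched_cfg = sched_config(warmup_steps = 500, cycle_steps = 11000))
print(fit)
#> Fingerprint-to-molecule translator
#>   source fingerprint: AEs (circular, sparse)
#>   target: SMILES  |  vocabulary 936 -> 33 tokens
#>   transformer: 2 layers, 4 heads, d_model 128 (788,257 parameters)
#>   trained 1500 steps on 250 molecules; final loss 0.0322

preds <- predict(fit, sp$test, beam_size = 5)
tanimoto_exactness(preds, "AEs")     # % of held-out predictions with Tc = 1
#> [1] 14
breakdown(preds)
#> Breakdown of top-1 accuracy (n = 50)
#>   Tc = 1.0          14.0%
#>     String exact    12.0%
#>     Stereo           0.0%
#>     Non-canonical    0.0%
#>     Others           2.0%
#>   Invalid            6.0%
#>   Mean Tc           0.429

# calibration: the similarity only 1% of random pairs reach
significance_threshold(mols, "AEs", p = 0.01, n_pairs = 1000, seed = 1)
#> Tc threshold (AEs, p = 0.01, 1000 pairs): 0.3125

# why did the model emit this token? (targets x source features)
src <- featurize(sp$train$smiles[1], fit$spec)$tokens
tgt <- tokenize_smiles(sp$train$smiles[1])
ig  <- integrated_gradients(fit$model, fit$src_vocab, fit$tgt_vocab, src, tgt)
```

(All printed numbers come from running this exact script; held-out
exactness grows with corpus size and training length — a 14% top-1
exact-reconstruction rate after 1,500 steps on 250 molecules is the
desk-scale analogue of the corpus-scale accuracies full training
reaches.)

A thin command-line wrapper over the same functions lives in
`inst/cli/fp2mol.R` (`build-corpus`, `featurize`, `train`, `translate`,
`evaluate`, `attribute`).

## Package layout

| module | where |
|---|---|
| synthetic corpus (generate / filter / diversify / split) | `R/corpus.R` |
| chemistry kernel (canonicalization, validity, graphs) | `R/chem.R`, `R/parse.R` |
| SELFIES-style robust codec | `R/selfies.R` |
| 13 featurizers + Tanimoto | `R/fingerprints.R` |
| transformer + backprop | `R/transformer.R`, `src/attention.cpp` |
| training engine (schedule, batching, Adam) | `R/train.R` |
| beam-search decoding | `R/decode.R` |
| evaluation suite | `R/evaluate.R` |
| attribution (integrated gradients, attention) | `R/attribution.R` |
| model interface (`fp_translator`, S3 methods) | `R/fit.R` |
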