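# dticross

Binary drug–target interaction (DTI) prediction from a SMILES string and a
protein amino-acid sequence, using **two drug modalities** — a rendered 2D
structure image and a pharmacophore "chemical text" — fused with learnable
scalar weights and exchanged with the target through **bi-directional
multi-head cross-attention decoders**. The same machinery handles
drug–drug interaction (DDI) prediction, where the partner is a second
SMILES encoded by the same multimodal drug encoder.

## Who this is for

Computational chemists and ML practitioners who want a fully inspectable,
dependency-light R implementation of a multimodal cross-attention
interaction model: every stage — featurisation, attention, fusion,
training — is ordinary R/Rcpp code with analytic gradients that are
checked against finite differences in the test suite. A seeded synthetic
benchmark with a *planted interaction rule* makes the whole pipeline
(training, evaluation, ablations) runnable and testable in minutes on one
CPU, with no external downloads.

## The model

For a drug with SMILES `s` and a target with sequence `t`:

1. **Image branch.** `s` is rendered as an `h x h` RGB depiction and passed
   through a 4-stage conv / batch-norm / ReLU / max-pool backbone; the
   `(h/16)^2` spatial cells become tokens, `x_v = Conv(P)`, refined by a
   pre-norm multi-head self-attention (MSA) block into `X_img`.
2. **Text branch.** A chemical feature factory emits, per pharmacophore
   feature, the family word, type word and atom tuple (e.g. `Donor`,
   `SingleAtomDonor`, `(13)`); the word sequence is k-gram tokenised
   against a first-appearance dictionary, embedded, and refined by MSA
   into `X_txt`.
3. **Modality fusion.** `X_drug = lambda_1 * X_img + lambda_2 * X_txt`,
   with the two scalars learnable (initialised at 1, 1).
4. **Target branch.** The amino-acid sequence is tokenised per residue,
   embedded and refined by MSA into `X_tgt`.
5. **Decoders.** Each of the drug and target decoders applies MSA to its
   own stream, then a multi-head cross-attention (MCA) block whose
   queries come from its own stream and keys/values from the other,
   yielding interaction maps `Z_drug->target` and `Z_target->drug`.
6. **Fusion head.** The two maps are stacked channel-wise and reduced by
   `FC(MLP(Conv1D(Conv2D(.))))` to a logit; the logistic function gives
   the interaction probability, trained with binary cross-entropy and
   Adam under a step-decayed learning rate.

## Worked example

```r
library(dticross)

# a seeded synthetic benchmark: positives pair a carboxylic-acid-bearing
# drug with a protein containing the motif "HKH"
train <- gen_dataset(800, seed = 101)
valid <- gen_dataset(200, seed = 301)
test  <- gen_dataset(200, seed = 201)

fit <- train_model(model_config(), train_config(epochs = 30, seed = 1),
                   train, valid)
ev <- evaluate_model(fit, test)
str(ev)
#> List of 5
#>  $ roc_auc: num 0.964
#>  $ pr_auc : num 0.94
#>  $ recall : num 0.93
#>  $ f1     : num 0.916
#>  $ n      : int 200
round(fit$model$params$lambda, 3)
#> [1] 0.983 1.011
```

The ROC-AUC near 1 says the model has recovered the planted
substructure-AND-motif rule on unseen proteins; the two lambda weights
staying close to (1, 1) say both modalities keep contributing — the same
diagnostic the learnable-weight design is meant to expose on real data.
(Numbers above are from this exact script with these seeds; other seeds
move the metrics by about ±0.01.)

Single pairs work too:

```r
m <- fit$model
r <- interaction_maps(m, "CC(=O)Oc1ccccc1C(=O)O", "MAVHKHLDERTKWGI")
r$p          # interaction probability
dim(r$Z_dt)  # drug-decoder interaction map, L_drug x d_model
```

A thin command-line wrapper covering `synth`, `prepare`, `train`,
`evaluate` and `ablate` is installed at `inst/cli/dticross.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/dticross.R", package="dticross"))')" \
  synth --n 1000 --seed 7 --out data/
```

## Package layout

- `R/datasets.R` — pair tables, Davis-style Kd binarisation, seeded splits
- `R/molecule.R`, `R/pharmacophore.R`, `R/featurization.R` — SMILES
  parsing (ChemmineR/OpenBabel), structure rasteriser, feature factory,
  k-gram vocabulary/encoding
- `R/nn-core.R`, `src/attention.cpp`, `R/network.R` — layer primitives
  with forward/backward passes (attention, conv and pooling kernels in
  C++), model assembly
- `R/training.R`, `R/evaluation.R` — Adam loop, checkpointing, grid
  search; ranking metrics with exact tie handling; ablation builder
- `R/synthetic.R` — the planted-rule benchmark generator
- `vignettes/methods.Rmd` — model, assumptions, parameter choices and
  limitations
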