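# O(n^2) all-pairs oracle for ROC-AUC (Mann-Whitney with half ties).
roc_auc_oracle <- function(scores, labels) {
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  s <- 0
  for (i in pos) for (j in neg)
    s <- s + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  s / (length(pos) * length(neg))
}

# Step-sum oracle for average precision: explicit walk over descending
# unique thresholds.
pr_auc_oracle <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1L)
  prev_rec <- 0; ap <- 0
  for (t in th) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1L)
    rec <- tp / n1
    prec <- tp / sum(pred)
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

test_that("ROC-AUC handles perfect rankings and ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_error(roc_auc(c(0.2, 0.8), c(1, 1)), "both classes")
})

test_that("ROC-AUC equals the all-pairs oracle on random data", {
  set.seed(31)
  for (rep in 1:3) {
    s <- round(runif(50), 2)  # rounding forces ties
    y <- rbinom(50, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    expect_equal(roc_auc(s, y), roc_auc_oracle(s, y), tolerance = 1e-10)
  }
})

test_that("ROC-AUC is invariant under monotone transforms and flips class", {
  set.seed(32)
  s <- runif(40); y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  a <- roc_auc(s, y)
  expect_equal(roc_auc(qlogis(s), y), a, tolerance = 1e-12)
  expect_equal(roc_auc(100 * s + 3, y), a, tolerance = 1e-12)
  expect_equal(roc_auc(s, 1 - y) + a, 1, tolerance = 1e-12)
})

test_that("PR-AUC: perfect ranking gives 1, constant scores give prevalence", {
  expect_equal(pr_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  y <- c(rep(1, 3), rep(0, 7))
  expect_equal(pr_auc(rep(0.5, 10), y), 0.3)
  expect_error(pr_auc(c(0.1, 0.9), c(0, 0)), "no positive")
})

test_that("PR-AUC equals the step-sum oracle on random tied data", {
  set.seed(33)
  for (rep in 1:3) {
    s <- round(runif(50), 2)
    y <- rbinom(50, 1, 0.3)
    if (sum(y) == 0) y[1] <- 1
    expect_equal(pr_auc(s, y), pr_auc_oracle(s, y), tolerance = 1e-10)
  }
})

test_that("recall and F1 follow the contingency table at threshold 0.5", {
  r <- recall_f1(c(0.9, 0.1), c(1, 0))
  expect_equal(r$recall, 1.0)
  expect_equal(r$f1, 1.0)
  expect_equal(recall_f1(0.4, 1)$recall, 0)
  # TP=3, FP=1, FN=1 -> recall .75, precision .75, f1 .75
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.2)
  labels <- c(1, 1, 1, 0, 1)
  r2 <- recall_f1(scores, labels)
  expect_equal(r2$recall, 0.75)
  expect_equal(r2$f1, 0.75)
  expect_equal(recall_f1(c(0.1, 0.2), c(1, 1))$f1, 0)
})

test_that("run aggregation reports mean, sample sd and pretty strings", {
  mk <- function(v) list(roc_auc = v, pr_auc = v, recall = v, f1 = v, n = 10)
  agg <- aggregate_runs(list(mk(0.9), mk(0.8)))
  expect_equal(agg$mean$roc_auc, 0.85)
  expect_equal(agg$sd$roc_auc, sd(c(0.9, 0.8)))
  expect_match(agg$pretty[["roc_auc"]], "^0\\.850 ± 0\\.071$")
  one <- aggregate_runs(list(mk(0.9)))
  expect_equal(one$sd$roc_auc, 0)
  five <- aggregate_runs(rep(list(mk(0.7)), 5))
  expect_equal(five$sd$f1, 0)
  expect_equal(five$n_runs, 5L)
})

test_that("ablation variants map to the right architecture deltas", {
  base <- tiny_model_cfg()
  expect_equal(build_ablation("full", base)$modalities, c("image", "text"))
  expect_equal(build_ablation("image+smiles", base)$text_source, "smiles")
  expect_equal(build_ablation("text", base)$modalities, "text")
  expect_equal(build_ablation("image", base)$modalities, "image")
  expect_false(build_ablation("-mca", base)$use_mca)
  v <- build_ablation("-mca-image", base)
  expect_false(v$use_mca); expect_equal(v$modalities, "text")
  v2 <- build_ablation("-mca-text", base)
  expect_false(v2$use_mca); expect_equal(v2$modalities, "image")
  expect_error(build_ablation("bogus", base), "unknown")

  vs <- tiny_vocabs()
  n_full <- param_count(dti_model(base, vs$txt, vs$tgt, seed = 1))
  n_nomca <- param_count(dti_model(build_ablation("-mca", base), vs$txt,
                                   vs$tgt, seed = 1))
  expect_lt(n_nomca, n_full)
  m_txt <- dti_model(build_ablation("text", base), vs$txt, vs$tgt, seed = 1)
  expect_null(m_txt$params$conv)
})

test_that("image+smiles uses SMILES characters through the k-gram machinery", {
  expect_equal(smiles_text("CCO"), c("C", "C", "O"))
  cfg <- build_ablation("image+smiles", tiny_model_cfg())
  ns <- asNamespace("dticross")
  ph <- ns$drug_text_phrases("CCO", cfg)
  expect_equal(ph, c("C", "C", "O"))
})
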