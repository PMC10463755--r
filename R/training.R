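#' Binary cross-entropy loss
#'
#' Mean negative log-likelihood of Bernoulli labels,
#' `-(1/N) * sum(y*log(p) + (1-y)*log(1-p))`, with probabilities clamped
#' `1e-7` away from 0 and 1 where the loss is undefined.
#'
#' @param p Predicted probabilities.
#' @param y 0/1 labels, same length.
#' @return Non-negative scalar loss.
#' @export
bce_loss <- function(p, y) {
  if (length(p) == 0L || length(p) != length(y))
    stop("p and y must be non-empty and of equal length")
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# ---- Adam -----------------------------------------------------------------

par_zero <- function(p) {
  if (is.list(p)) lapply(p, par_zero) else p * 0
}

adam_update <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999,
                        eps = 1e-8, skip = character()) {
  rec <- function(p, g, m, v, path) {
    if (is.list(p)) {
      keys <- if (is.null(names(p))) seq_along(p) else names(p)
      for (k in keys) {
        gk <- if (is.null(g)) NULL else g[[k]]
        r <- rec(p[[k]], gk, m[[k]], v[[k]],
                 c(path, as.character(k)))
        p[[k]] <- r$p; m[[k]] <- r$m; v[[k]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    if (is.null(g) || paste(path, collapse = "/") %in% skip)
      return(list(p = p, m = m, v = v))
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    mh <- m / (1 - b1^t)
    vh <- v / (1 - b2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  rec(p, g, m, v, character())
}

# ---- training loop --------------------------------------------------------

#' Train an interaction model
#'
#' Fits vocabularies on the training split, featurises every unique drug
#' and partner once, initialises the model and optimises the binary
#' cross-entropy with Adam over shuffled mini-batches. The learning rate
#' follows the step decay of [lr_at()]. After every epoch the validation
#' ROC-AUC is recorded and the parameters of the best validation epoch are
#' kept as the returned checkpoint. The entire run is a pure function of
#' the configurations, data and `train_cfg$seed`.
#'
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param train_set,valid_set Example data frames (`drug_smiles`,
#'   `partner`, `label`).
#' @param verbose Print per-epoch progress.
#' @return An object of class `dti_fit`: list with `model` (best
#'   checkpoint), `history` (one row per epoch: `epoch`, `train_loss`,
#'   `valid_auc`, `lr`, `lambda1`, `lambda2`), `best_epoch`, `train_cfg`.
#' @export
train_model <- function(model_cfg, train_cfg, train_set,
                        valid_set = NULL, verbose = FALSE) {
  if (nrow(train_set) == 0L) stop("empty training set")
  with_seed(train_cfg$seed, {
    vocabs <- fit_vocabs(model_cfg, train_set)
    all_ex <- rbind(train_set[, c("drug_smiles", "partner", "label")],
                    if (!is.null(valid_set))
                      valid_set[, c("drug_smiles", "partner", "label")])
    attr(all_ex, "task") <- model_cfg$task
    store <- build_feature_store(model_cfg, all_ex, vocabs$txt, vocabs$tgt)
    model <- dti_model(model_cfg, vocabs$txt, vocabs$tgt,
                       seed = train_cfg$seed)
    m_st <- par_zero(model$params); v_st <- par_zero(model$params)
    skip <- if (!is.null(model$params$lambda) &&
                model_cfg$lambda_mode == "fixed") "lambda" else character()
    n <- nrow(train_set)
    E <- train_cfg$epochs
    hist <- data.frame(epoch = seq_len(E), train_loss = NA_real_,
                       valid_auc = NA_real_, lr = NA_real_,
                       lambda1 = NA_real_, lambda2 = NA_real_)
    best <- list(auc = -Inf, params = model$params,
                 buffers = model$buffers, epoch = 1L)
    t_adam <- 0L
    for (epoch in seq_len(E)) {
      lr <- lr_at(epoch - 1L, train_cfg)
      ord <- sample.int(n)
      losses <- c(); sizes <- c()
      i <- 1L
      while (i <= n) {
        j <- min(i + train_cfg$batch_size - 1L, n)
        rows <- ord[i:j]
        batch <- make_batch(store, train_set[rows, , drop = FALSE])
        fwd <- model_forward(model, batch, train = TRUE)
        model$buffers <- fwd$buffers
        loss <- bce_loss(fwd$p, batch$y)
        if (!is.finite(loss))
          stop("non-finite loss at epoch ", epoch, "; aborting")
        losses <- c(losses, loss); sizes <- c(sizes, batch$B)
        dlogits <- (fwd$p - batch$y) / batch$B
        grads <- model_backward(model, fwd, dlogits)
        t_adam <- t_adam + 1L
        upd <- adam_update(model$params, grads, m_st, v_st, lr, t_adam,
                           skip = skip)
        model$params <- upd$p; m_st <- upd$m; v_st <- upd$v
        i <- j + 1L
      }
      hist$train_loss[epoch] <- sum(losses * sizes) / sum(sizes)
      hist$lr[epoch] <- lr
      if (!is.null(model$params$lambda)) {
        hist$lambda1[epoch] <- model$params$lambda[1L]
        hist$lambda2[epoch] <- model$params$lambda[2L]
      }
      if (!is.null(valid_set) && nrow(valid_set) > 0L) {
        pv <- predict_store(model, store, valid_set, train_cfg$batch_size)
        auc <- tryCatch(roc_auc(pv, valid_set$label), error = function(e) NA)
        hist$valid_auc[epoch] <- auc
        if (!is.na(auc) && auc > best$auc) {
          best <- list(auc = auc, params = model$params,
                       buffers = model$buffers, epoch = epoch)
        }
      }
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  valid auc %s", epoch,
                        hist$train_loss[epoch],
                        format(hist$valid_auc[epoch], digits = 4)))
    }
    if (is.finite(best$auc)) {
      model$params <- best$params
      model$buffers <- best$buffers
    } else best$epoch <- E
    structure(list(model = model, history = hist, best_epoch = best$epoch,
                   train_cfg = train_cfg),
              class = "dti_fit")
  })
}

predict_store <- function(model, store, examples, batch_size) {
  n <- nrow(examples); p <- numeric(n); i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    fwd <- model_forward(model,
                         make_batch(store, examples[i:j, , drop = FALSE]),
                         train = FALSE)
    p[i:j] <- fwd$p
    i <- j + 1L
  }
  p
}

#' @export
print.dti_fit <- function(x, ...) {
  cat("Trained interaction model; best epoch", x$best_epoch, "of",
      nrow(x$history), "\n")
  ba <- x$history$valid_auc[x$best_epoch]
  if (!is.na(ba)) cat("Best validation ROC-AUC:", format(ba, digits = 4), "\n")
  invisible(x)
}

# ---- grid search ----------------------------------------------------------

#' Two-phase grid-search schedule
#'
#' Phase 1 crosses learning rate with batch size (decay and dropout at
#' their defaults); phase 2 fixes the phase-1 winners and crosses dropout
#' with decay.
#'
#' @param grid List with candidate vectors `lr`, `lr_decay`, `batch_size`,
#'   `dropout` (each non-empty).
#' @return Data frame of evaluation cells with a `phase` column.
#' @export
grid_plan <- function(grid) {
  for (k in c("lr", "lr_decay", "batch_size", "dropout"))
    if (length(grid[[k]]) < 1L) stop_config("empty candidate list: ", k)
  p1 <- expand.grid(lr = grid$lr, batch_size = grid$batch_size,
                    lr_decay = NA_real_, dropout = NA_real_)
  p1$phase <- 1L
  p2 <- expand.grid(lr = NA_real_, batch_size = NA_real_,
                    lr_decay = grid$lr_decay, dropout = grid$dropout)
  p2$phase <- 2L
  rbind(p1, p2)
}

#' Grid search over optimisation hyperparameters
#'
#' Runs the two-phase protocol of [grid_plan()] with short budgeted
#' trainings, scoring each cell by validation ROC-AUC; ties are broken by
#' lower learning rate, then smaller batch size.
#'
#' @param grid Candidate lists (see [grid_plan()]).
#' @param model_cfg Base [model_config()] (its `dropout` is overridden in
#'   phase 2).
#' @param train_set,valid_set Example data frames.
#' @param budget_epochs Epochs per search run.
#' @param seed Seed shared by every run.
#' @return List with `best` (a [train_config()]), `best_dropout`, and
#'   `results` (the evaluated plan with a `valid_auc` column).
#' @export
grid_search <- function(grid, model_cfg, train_set, valid_set,
                        budget_epochs = 5L, seed = 0L) {
  plan <- grid_plan(grid)
  plan$valid_auc <- NA_real_
  defaults <- train_config()
  run_cell <- function(lr, batch, decay, dropout) {
    mc <- model_cfg; mc$dropout <- dropout
    tc <- train_config(lr = lr, lr_decay = decay, batch_size = batch,
                       epochs = budget_epochs, seed = seed)
    fit <- train_model(mc, tc, train_set, valid_set)
    max(fit$history$valid_auc, na.rm = TRUE)
  }
  p1 <- which(plan$phase == 1L)
  for (i in p1) {
    plan$valid_auc[i] <- run_cell(plan$lr[i], plan$batch_size[i],
                                  defaults$lr_decay, model_cfg$dropout)
  }
  w1 <- plan[p1, ]
  w1 <- w1[order(-w1$valid_auc, w1$lr, w1$batch_size), ][1L, ]
  p2 <- which(plan$phase == 2L)
  for (i in p2) {
    plan$valid_auc[i] <- run_cell(w1$lr, w1$batch_size, plan$lr_decay[i],
                                  plan$dropout[i])
  }
  w2 <- plan[p2, ]
  w2 <- w2[order(-w2$valid_auc, w2$lr_decay, w2$dropout), ][1L, ]
  list(best = train_config(lr = w1$lr, lr_decay = w2$lr_decay,
                           batch_size = w1$batch_size, seed = seed),
       best_dropout = w2$dropout,
       results = plan)
}
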