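# Small feed-forward baseline classifier on flattened BLOSUM50 encodings.
#
# Deliberately modest: one ReLU hidden layer on concatenated padded
# encodings, trained by minibatch Adam — big enough to memorize sequence
# identities, small enough for minutes-scale CPU training. It is a probe for
# the benchmark, not a production predictor.

#' Baseline training settings
#'
#' Training runs for at most `max_epochs` passes; after every epoch the
#' model is scored on an internal stratified validation split of the
#' training table, and the weights of the epoch with the highest validation
#' AUROC are the ones returned (early-stopping model selection). `patience`
#' stops training once the validation AUROC has not improved for that many
#' epochs.
#'
#' @param max_epochs Maximum training epochs (default 1000).
#' @param val_frac Fraction of the training table held out, stratified by
#'   label, for model selection (default 0.2).
#' @param seed Integer seed governing the validation split, initialization
#'   and minibatch order.
#' @param hidden Hidden-layer width (default 32).
#' @param learning_rate Adam step size (default 3e-3).
#' @param batch_size Minibatch size (default 256).
#' @param patience Early-stopping patience in epochs (default 25;
#'   `Inf` trains the full budget).
#' @return A `train_config` list.
#' @export
train_config <- function(max_epochs = 1000L, val_frac = 0.2, seed = 1L,
                         hidden = 32L, learning_rate = 3e-3,
                         batch_size = 256L, patience = 25L) {
  if (val_frac <= 0 || val_frac >= 1) {
    tb_stop("tcrbench_config_error", "val_frac must be in (0, 1)")
  }
  structure(list(max_epochs = as.integer(max_epochs), val_frac = val_frac,
                 selection_metric = "val_auroc", seed = as.integer(seed),
                 hidden = as.integer(hidden), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), patience = patience),
            class = "train_config")
}

mlp_forward <- function(W, X) {
  a1 <- pmax(sweep(X %*% W$W1, 2, W$b1, "+"), 0)
  z2 <- drop(a1 %*% W$W2) + W$b2
  1 / (1 + exp(-z2))
}

#' Train the baseline sequence classifier
#'
#' Fits the feed-forward scorer on the setting's concatenated BLOSUM50
#' encodings, selecting the epoch that maximizes AUROC on an internal
#' stratified validation split. Deterministic given `cfg$seed`.
#'
#' @param train A [sample_table()] containing both classes.
#' @param cfg A [train_config()].
#' @param enc An [encoding_config()].
#' @return An object of class `tcr_baseline` with the selected weights, the
#'   per-epoch validation history, and the configuration; use
#'   [predict.tcr_baseline()] to score new tables.
#' @export
train_baseline <- function(train, cfg = train_config(),
                           enc = encoding_config()) {
  stopifnot(inherits(train, "sample_table"))
  y_all <- train$label
  if (length(unique(y_all)) < 2L) {
    tb_stop("tcrbench_single_class",
            "training table must contain both classes")
  }
  st <- tbl_setting(train)
  X_all <- encode_table(train, enc, st)
  d <- ncol(X_all)
  H <- cfg$hidden

  with_seed(cfg$seed, {
    # stratified validation split
    val_idx <- unlist(lapply(c(0L, 1L), function(cl) {
      i <- which(y_all == cl)
      sample(i, max(1L, round(cfg$val_frac * length(i))))
    }))
    tr_idx <- setdiff(seq_len(nrow(X_all)), val_idx)
    X <- X_all[tr_idx, , drop = FALSE]
    y <- y_all[tr_idx]
    Xv <- X_all[val_idx, , drop = FALSE]
    yv <- y_all[val_idx]
    if (length(unique(y)) < 2L || length(unique(yv)) < 2L) {
      tb_stop("tcrbench_single_class",
              "stratified validation split left a single-class side")
    }

    W <- list(W1 = matrix(stats::rnorm(d * H, sd = sqrt(2 / d)), d, H),
              b1 = numeric(H),
              W2 = matrix(stats::rnorm(H, sd = sqrt(1 / H)), H, 1),
              b2 = 0)
    m <- lapply(W, function(w) w * 0)
    v <- lapply(W, function(w) w * 0)
    b1t <- 1; b2t <- 1
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

    n <- nrow(X)
    best <- list(auroc = -Inf, epoch = 0L, W = W)
    history <- numeric(0)
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      for (s in starts) {
        b <- ord[s:min(s + cfg$batch_size - 1L, n)]
        Xb <- X[b, , drop = FALSE]
        yb <- y[b]
        z1 <- sweep(Xb %*% W$W1, 2, W$b1, "+")
        a1 <- pmax(z1, 0)
        p <- 1 / (1 + exp(-(drop(a1 %*% W$W2) + W$b2)))
        dz2 <- (p - yb) / length(b)
        g <- list(W2 = crossprod(a1, dz2), b2 = sum(dz2))
        dz1 <- tcrossprod(dz2, drop(W$W2)) * (z1 > 0)
        g$W1 <- crossprod(Xb, dz1)
        g$b1 <- colSums(dz1)
        b1t <- b1t * beta1; b2t <- b2t * beta2
        for (k in names(W)) {
          m[[k]] <- beta1 * m[[k]] + (1 - beta1) * g[[k]]
          v[[k]] <- beta2 * v[[k]] + (1 - beta2) * g[[k]]^2
          W[[k]] <- W[[k]] - cfg$learning_rate *
            (m[[k]] / (1 - b1t)) / (sqrt(v[[k]] / (1 - b2t)) + eps)
        }
      }
      val_auroc <- auroc_mw(yv, mlp_forward(W, Xv))
      history <- c(history, val_auroc)
      if (val_auroc > best$auroc) {
        best <- list(auroc = val_auroc, epoch = epoch, W = W)
      }
      if (epoch - best$epoch >= cfg$patience) break
    }
  })

  structure(list(weights = best$W, best_epoch = best$epoch,
                 val_auroc = best$auroc,
                 history = data.frame(epoch = seq_along(history),
                                      val_auroc = history),
                 setting = st, enc = enc, cfg = cfg),
            class = "tcr_baseline")
}

#' Score samples with a trained baseline
#'
#' @param object A `tcr_baseline` from [train_baseline()].
#' @param table A [sample_table()] encodable under the model's settings.
#' @param ... Unused.
#' @return Numeric scores in `[0, 1]`, one per row, order-aligned.
#' @export
predict.tcr_baseline <- function(object, table, ...) {
  if (nrow(table) == 0L) return(numeric(0))
  X <- encode_table(table, object$enc, object$setting)
  as.numeric(mlp_forward(object$weights, X))
}

#' @export
print.tcr_baseline <- function(x, ...) {
  cat(sprintf(
    "<tcr_baseline> hidden %d; best epoch %d/%d (val AUROC %.4f); fields: %s\n",
    x$cfg$hidden, x$best_epoch, nrow(x$history), x$val_auroc,
    paste(unclass(x$setting), collapse = ", ")))
  invisible(x)
}
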