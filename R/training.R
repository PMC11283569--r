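#' Warmup-plus-cosine learning-rate schedule
#'
#' Linear ramp from 0 to `peak_lr` over `warmup_steps` (one epoch of warmup in
#' the published schedule), then cosine decay to 0 at `total_steps`. Steps
#' beyond `total_steps` clamp to 0.
#'
#' @param step Current optimizer step (0-based).
#' @param total_steps Total steps in the run.
#' @param warmup_steps Warmup steps; must be < `total_steps`.
#' @param peak_lr Peak learning rate (default 1e-4).
#' @return The learning rate at `step`.
#' @examples
#' lr_schedule(0, 100, 10)        # 0
#' lr_schedule(10, 100, 10)       # 1e-4
#' lr_schedule(100, 100, 10)      # 0
#' @export
lr_schedule <- function(step, total_steps, warmup_steps, peak_lr = 1e-4) {
  if (warmup_steps >= total_steps) {
    abort("`warmup_steps` must be smaller than `total_steps`.",
          class = "endmotif_error_parameter")
  }
  if (step >= total_steps) return(0)
  if (step <= warmup_steps) return(peak_lr * step / warmup_steps)
  frac <- (step - warmup_steps) / (total_steps - warmup_steps)
  peak_lr * 0.5 * (1 + cos(pi * frac))
}

# Masked-LM loss and gradients for one batch. sel_rows index into the
# sequence-major (B*n) x d hidden matrix; targets are 1-based vocab ids.
txf_loss_grads <- function(ids, mask, sel_rows, targets, params, config,
                           dropout = 0) {
  fw <- txf_encode(ids, mask, params, config, dropout = dropout,
                   keep_cache = TRUE)
  hf <- head_forward(fw$H, params, rows = sel_rows)
  m <- length(targets)
  P <- row_softmax(hf$logits)
  idx <- cbind(seq_len(m), targets)
  loss <- -mean(log(pmax(P[idx], 1e-300)))
  dlogits <- P
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / m

  g <- list()
  g$Hw2 <- t(hf$Un) %*% dlogits
  g$Hb2 <- colSums(dlogits)
  dUn <- dlogits %*% t(params$Hw2)
  lb <- ln_backward(dUn, hf$lnh, params$Hg)
  g$Hg <- lb$dgamma; g$Ho <- lb$dbeta
  dUpre <- lb$dx * (hf$Upre > 0)
  g$Hw1 <- t(hf$Z) %*% dUpre
  g$Hb1 <- colSums(dUpre)
  dZs <- dUpre %*% t(params$Hw1)

  B <- fw$B; n <- fw$n
  d <- config$hidden_size; h <- config$num_heads; dk <- d / h
  dH <- matrix(0, B * n, d)
  dH[sel_rows, ] <- dZs
  head_cols <- lapply(seq_len(h), function(j) ((j - 1L) * dk + 1L):(j * dk))
  for (l in rev(seq_len(config$num_layers))) {
    cc <- fw$caches[[l]]
    lb2 <- ln_backward(dH, cc$ln2, params[[paste0("g2_", l)]])
    g[[paste0("g2_", l)]] <- lb2$dgamma
    g[[paste0("o2_", l)]] <- lb2$dbeta
    dres2 <- lb2$dx
    dffn <- dres2
    dmk <- fw$drop_masks[[paste0("ffn_", l)]]
    if (!is.null(dmk)) dffn <- dffn * dmk
    W2 <- params[[paste0("W2_", l)]]
    g[[paste0("W2_", l)]] <- t(cc$Fact) %*% dffn
    g[[paste0("b2_", l)]] <- colSums(dffn)
    dFpre <- (dffn %*% t(W2)) * (cc$Fact > 0)
    W1 <- params[[paste0("W1_", l)]]
    g[[paste0("W1_", l)]] <- t(cc$H1) %*% dFpre
    g[[paste0("b1_", l)]] <- colSums(dFpre)
    dH1 <- dres2 + dFpre %*% t(W1)
    lb1 <- ln_backward(dH1, cc$ln1, params[[paste0("g1_", l)]])
    g[[paste0("g1_", l)]] <- lb1$dgamma
    g[[paste0("o1_", l)]] <- lb1$dbeta
    dres1 <- lb1$dx
    dO <- dres1
    dmk <- fw$drop_masks[[paste0("attn_", l)]]
    if (!is.null(dmk)) dO <- dO * dmk
    dQ <- matrix(0, B * n, d); dK <- matrix(0, B * n, d); dV <- matrix(0, B * n, d)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * n + 1L):(b * n)
      for (j in seq_len(h)) {
        cols <- head_cols[[j]]
        A <- cc$A[[b]][[j]]
        dOb <- dO[rows, cols, drop = FALSE]
        Vb <- cc$V[rows, cols, drop = FALSE]
        dA <- dOb %*% t(Vb)
        dV[rows, cols] <- t(A) %*% dOb
        dS <- A * (dA - rowSums(dA * A))
        dQ[rows, cols] <- dS %*% cc$K[rows, cols, drop = FALSE] / sqrt(dk)
        dK[rows, cols] <- t(dS) %*% cc$Q[rows, cols, drop = FALSE] / sqrt(dk)
      }
    }
    H_in <- cc$H_in
    g[[paste0("Wq_", l)]] <- t(H_in) %*% dQ
    g[[paste0("Wk_", l)]] <- t(H_in) %*% dK
    g[[paste0("Wv_", l)]] <- t(H_in) %*% dV
    dH <- dres1 +
      dQ %*% t(params[[paste0("Wq_", l)]]) +
      dK %*% t(params[[paste0("Wk_", l)]]) +
      dV %*% t(params[[paste0("Wv_", l)]])
  }
  dmk <- fw$drop_masks$emb
  if (!is.null(dmk)) dH <- dH * dmk
  agg <- rowsum(dH, group = fw$ids_flat)
  dWx <- matrix(0, config$vocab_size, d)
  dWx[as.integer(rownames(agg)), ] <- agg
  g$Wx <- dWx
  aggp <- rowsum(dH, group = fw$pos_flat)
  dWp <- matrix(0, config$max_positions, d)
  dWp[as.integer(rownames(aggp)), ] <- aggp
  g$Wp <- dWp
  list(loss = loss, grads = g)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# Adam with decoupled weight decay; decay applies to weight matrices only,
# not biases or layer-norm parameters.
adam_step <- function(params, grads, state, lr, weight_decay = 0.01,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    gg <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gg
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gg * gg
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (is.matrix(params[[nm]]) && weight_decay > 0) {
      upd <- upd + weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

#' Pretrain the motif transformer with the masked-token objective
#'
#' Holds out `holdout_n` sequences (seeded, never trained on), then optimizes
#' the masked-token cross-entropy with Adam and decoupled weight decay under a
#' one-epoch-warmup + cosine learning-rate schedule. Each training epoch
#' applies fresh corruption; the holdout set is corrupted once so the
#' per-epoch exponentiated cross-entropy (ECE) curve is comparable across
#' epochs. Published-scale defaults: batch 256, weight decay 0.01, peak
#' learning rate 1e-4, 40 epochs; all overridable for smaller runs.
#'
#' @param corpus List of `end_motif_sequence` of equal length.
#' @param config A [transformer_config()].
#' @param dictionary A [motif_dictionary()]; defaults to `motif_dictionary(k)`
#'   for the corpus's motif length.
#' @param epochs,batch_size,peak_lr,weight_decay Optimizer hyperparameters.
#' @param holdout_n Held-out sequences for ECE monitoring. Default: 5000 when
#'   the corpus has at least 50,000 sequences, otherwise 10% capped at 200.
#' @param seed Single run seed; initialization, holdout split, shuffling,
#'   corruption and dropout all flow from it, so runs are reproducible on one
#'   thread.
#' @param verbose Print per-epoch ECE.
#'
#' @return A `pretrain_run`: list with `model` (a `motif_transformer`),
#'   `metrics` (per-epoch tibble: `epoch`, `train_loss`, `holdout_ece`,
#'   `lr`), `steps` (per-step tibble), `holdout_ids`, `seed`.
#' @export
pretrain_transformer <- function(corpus, config, dictionary = NULL,
                                 epochs = 40, batch_size = 256,
                                 peak_lr = 1e-4, weight_decay = 0.01,
                                 holdout_n = NULL, seed = 1L, verbose = FALSE) {
  n_corpus <- length(corpus)
  if (n_corpus < 2L) {
    abort("Corpus must contain at least 2 sequences.",
          class = "endmotif_error_configuration")
  }
  if (is.null(dictionary)) dictionary <- motif_dictionary(corpus[[1]]$k)
  if (is.null(holdout_n)) {
    holdout_n <- if (n_corpus >= 50000L) 5000L else max(1L, min(200L, n_corpus %/% 10L))
  }
  holdout_n <- check_positive_int(holdout_n, "holdout_n")
  if (holdout_n >= n_corpus) {
    abort("`holdout_n` must be smaller than the corpus.",
          class = "endmotif_error_configuration")
  }
  lens <- lengths(lapply(corpus, `[[`, "tokens"))
  if (length(unique(lens)) != 1L) {
    abort("All corpus sequences must have the same padded length.",
          class = "endmotif_error_configuration")
  }
  n <- lens[[1L]]
  if (n > config$max_positions) {
    abort("Sequence length exceeds `max_positions`.",
          class = "endmotif_error_length")
  }
  if (n_corpus - holdout_n < batch_size) {
    abort("Corpus after holdout is smaller than one batch; lower `batch_size` or `holdout_n`.",
          class = "endmotif_error_configuration")
  }
  tokens_all <- lapply(corpus, `[[`, "tokens")

  with_seed(seed, {
    init_seed <- sample.int(.Machine$integer.max - 1L, 1L)
    model <- init_transformer(config, dictionary, seed = init_seed)
    params <- model$params
    holdout_ids <- sort(sample.int(n_corpus, holdout_n))
    train_ids <- setdiff(seq_len(n_corpus), holdout_ids)
    hold_batch <- corrupt_batch(tokens_all[holdout_ids], dictionary)
    steps_per_epoch <- length(train_ids) %/% batch_size
    total_steps <- epochs * steps_per_epoch
    # one epoch of warmup; for single-epoch runs the ramp must still leave
    # room for the cosine decay
    warmup_steps <- max(1L, min(steps_per_epoch, total_steps - 1L))
    opt <- adam_init(params)
    step <- 0L
    step_log <- vector("list", total_steps)
    epoch_log <- vector("list", epochs + 1L)
    ece0 <- holdout_ece(params, config, hold_batch, batch_size)
    epoch_log[[1L]] <- tibble(epoch = 0L, train_loss = NA_real_,
                              holdout_ece = ece0, lr = 0)
    if (verbose) message(sprintf("epoch 0: holdout ECE %.2f", ece0))
    for (ep in seq_len(epochs)) {
      order_ids <- sample(train_ids)
      losses <- numeric(steps_per_epoch)
      for (s in seq_len(steps_per_epoch)) {
        take <- order_ids[((s - 1L) * batch_size + 1L):(s * batch_size)]
        batch <- corrupt_batch(tokens_all[take], dictionary)
        lr <- lr_schedule(step + 1L, total_steps, warmup_steps, peak_lr)
        lg <- txf_loss_grads(batch$ids, batch$mask, batch$sel_rows,
                             batch$targets, params, config,
                             dropout = config$dropout_rate)
        upd <- adam_step(params, lg$grads, opt, lr, weight_decay)
        params <- upd$params; opt <- upd$state
        step <- step + 1L
        losses[s] <- lg$loss
        step_log[[step]] <- tibble(step = step, epoch = ep, lr = lr,
                                   loss = lg$loss)
      }
      ece <- holdout_ece(params, config, hold_batch, batch_size)
      epoch_log[[ep + 1L]] <- tibble(epoch = ep, train_loss = mean(losses),
                                     holdout_ece = ece,
                                     lr = lr_schedule(step, total_steps,
                                                      warmup_steps, peak_lr))
      if (verbose) message(sprintf("epoch %d: loss %.4f holdout ECE %.2f",
                                   ep, mean(losses), ece))
    }
    model$params <- params
    structure(
      list(model = model,
           metrics = dplyr::bind_rows(epoch_log),
           steps = dplyr::bind_rows(step_log),
           holdout_ids = holdout_ids,
           seed = seed),
      class = "pretrain_run"
    )
  })
}

# Corrupt a list of token vectors and assemble batch matrices. Uses the
# current RNG stream.
corrupt_batch <- function(tokens_list, dictionary) {
  B <- length(tokens_list)
  n <- length(tokens_list[[1L]])
  ids <- matrix(0L, B, n)
  mask <- matrix(0L, B, n)
  sel_rows <- integer(0)
  targets <- integer(0)
  for (b in seq_len(B)) {
    tk <- tokens_list[[b]]
    cr <- mask_tokens_impl(tk, dictionary)
    ids[b, ] <- token_index(dictionary, cr$tokens)
    mask[b, ] <- as.integer(tk != "PAD")
    sel <- which(cr$selected)
    sel_rows <- c(sel_rows, (b - 1L) * n + sel)
    targets <- c(targets, token_index(dictionary, tk[sel]))
  }
  list(ids = ids, mask = mask, sel_rows = sel_rows, targets = targets)
}

holdout_ece <- function(params, config, hold_batch, batch_size) {
  B <- nrow(hold_batch$ids)
  n <- ncol(hold_batch$ids)
  ce_sum <- 0; ce_n <- 0L
  for (start in seq(1L, B, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, B)
    rows_global <- hold_batch$sel_rows
    in_chunk <- rows_global > (idx[1L] - 1L) * n & rows_global <= idx[length(idx)] * n
    sel_local <- rows_global[in_chunk] - (idx[1L] - 1L) * n
    tg <- hold_batch$targets[in_chunk]
    fw <- txf_encode(hold_batch$ids[idx, , drop = FALSE],
                     hold_batch$mask[idx, , drop = FALSE],
                     params, config, dropout = 0)
    logits <- head_forward(fw$H, params, rows = sel_local)$logits
    mx <- apply(logits, 1L, max)
    lse <- mx + log(rowSums(exp(logits - mx)))
    ce <- lse - logits[cbind(seq_along(tg), tg)]
    ce_sum <- ce_sum + sum(ce)
    ce_n <- ce_n + length(ce)
  }
  exp(ce_sum / ce_n)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single serialized archive with a schema id, the config,
#' the dictionary's `k`, and all weights; reloading reproduces forward outputs
#' bit-for-bit.
#'
#' @param model A `motif_transformer` (or a `pretrain_run`, whose model is
#'   saved).
#' @param path Checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the `motif_transformer`.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "pretrain_run")) model <- model$model
  stopifnot(inherits(model, "motif_transformer"))
  saveRDS(list(schema = "endmotif/motif_transformer/1",
               config = model$config, k = model$dictionary$k,
               params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "endmotif/motif_transformer/1")) {
    abort("Unrecognized checkpoint schema.", class = "endmotif_error_format")
  }
  structure(list(config = obj$config, dictionary = motif_dictionary(obj$k),
                 params = obj$params),
            class = "motif_transformer")
}
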