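#' Transformer configuration
#'
#' Hyperparameters of the end-motif transformer encoder. The encoder embeds
#' ranked motif tokens and their positions (element-wise sum `X + P`), applies
#' `num_layers` blocks of multi-head scaled-dot-product self-attention (the
#' concatenation of `num_heads` heads of width `d/h`) with residual
#' connections and layer normalization before and after a position-wise
#' feed-forward network, and maps the output through a two-layer projection
#' head (layer normalization between layers) onto the motif vocabulary.
#'
#' The published model family varies `hidden_size` over 384/768/1536 with
#' 6/12/24 heads; desk-scale analyses use much smaller sizes.
#'
#' @param hidden_size Embedding width `d`; must be divisible by `num_heads`.
#' @param num_heads Number of attention heads `h`.
#' @param num_layers Encoder blocks `L` (default 1).
#' @param ffn_dim Feed-forward inner width (default `4 * hidden_size`).
#' @param vocab_size Token vocabulary size (`4^k + 4`).
#' @param max_positions Longest supported sequence (default 258 = 256 motifs
#'   plus CLS/SEP, so every probing length fits one positional table).
#' @param dropout_rate Dropout probability used during training only.
#'
#' @return A `transformer_config` list.
#' @export
transformer_config <- function(hidden_size = 384, num_heads = 6,
                               num_layers = 1, ffn_dim = 4 * hidden_size,
                               vocab_size = 260, max_positions = 258,
                               dropout_rate = 0.1) {
  hidden_size <- check_positive_int(hidden_size, "hidden_size")
  num_heads <- check_positive_int(num_heads, "num_heads")
  num_layers <- check_positive_int(num_layers, "num_layers")
  ffn_dim <- check_positive_int(ffn_dim, "ffn_dim")
  vocab_size <- check_positive_int(vocab_size, "vocab_size")
  max_positions <- check_positive_int(max_positions, "max_positions")
  if (hidden_size %% num_heads != 0) {
    abort("`hidden_size` must be divisible by `num_heads`.",
          class = "endmotif_error_parameter")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort("`dropout_rate` must be in [0, 1).", class = "endmotif_error_parameter")
  }
  structure(
    list(hidden_size = hidden_size, num_heads = num_heads,
         num_layers = num_layers, ffn_dim = ffn_dim, vocab_size = vocab_size,
         max_positions = max_positions, dropout_rate = dropout_rate),
    class = "transformer_config"
  )
}

#' Initialize an untrained motif transformer
#'
#' Weights are drawn N(0, 0.02^2) (embeddings, projections, feed-forward,
#' head); layer-norm scales start at 1 and offsets at 0. Per-head query/key/
#' value projections are stored as `d x d` matrices whose column blocks of
#' width `d/h` are the individual heads.
#'
#' @param config A [transformer_config()].
#' @param dictionary The [motif_dictionary()] the model is bound to.
#' @param seed Integer seed for the initialization draw.
#' @return A `motif_transformer` object (config, dictionary, params).
#' @export
init_transformer <- function(config, dictionary, seed = 1L) {
  if (dict_vocab_size(dictionary) != config$vocab_size) {
    abort("`vocab_size` must equal 4^k + 4 for the dictionary.",
          class = "endmotif_error_parameter")
  }
  d <- config$hidden_size
  V <- config$vocab_size
  f <- config$ffn_dim
  init <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.02), nr, nc)
  params <- with_seed(seed, {
    p <- list(Wx = init(V, d), Wp = init(config$max_positions, d))
    for (l in seq_len(config$num_layers)) {
      p[[paste0("Wq_", l)]] <- init(d, d)
      p[[paste0("Wk_", l)]] <- init(d, d)
      p[[paste0("Wv_", l)]] <- init(d, d)
      p[[paste0("g1_", l)]] <- rep(1, d)
      p[[paste0("o1_", l)]] <- rep(0, d)
      p[[paste0("W1_", l)]] <- init(d, f)
      p[[paste0("b1_", l)]] <- rep(0, f)
      p[[paste0("W2_", l)]] <- init(f, d)
      p[[paste0("b2_", l)]] <- rep(0, d)
      p[[paste0("g2_", l)]] <- rep(1, d)
      p[[paste0("o2_", l)]] <- rep(0, d)
    }
    p$Hw1 <- init(d, d); p$Hb1 <- rep(0, d)
    p$Hg <- rep(1, d);   p$Ho <- rep(0, d)
    p$Hw2 <- init(d, V); p$Hb2 <- rep(0, V)
    p
  })
  structure(list(config = config, dictionary = dictionary, params = params),
            class = "motif_transformer")
}

#' @export
print.motif_transformer <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 1L))
  cat(sprintf("<motif_transformer> d = %d, heads = %d, layers = %d, vocab = %d (%.2fM parameters)\n",
              x$config$hidden_size, x$config$num_heads, x$config$num_layers,
              x$config$vocab_size, n_par / 1e6))
  invisible(x)
}

#' Scaled dot-product attention
#'
#' Computes `A = softmax(Q K' / sqrt(d_k))` row-wise and the attended output
#' `A V`. This is the primitive each attention head applies; `d_k` is the
#' per-head width, taken from `ncol(Q)`.
#'
#' @param Q,K,V Numeric matrices with equal row counts; `Q`/`K` share width
#'   `d_k`.
#' @param mask Optional logical vector over key positions; `FALSE` keys are
#'   excluded from the softmax.
#' @return List with `output` (`A %*% V`) and `A` (rows sum to 1).
#' @examples
#' q <- matrix(0, 3, 2)
#' attention_weights(q, q, diag(2)[c(1, 2, 1), ])$A  # uniform 1/3 rows
#' @export
attention_weights <- function(Q, K, V, mask = NULL) {
  if (ncol(Q) != ncol(K) || nrow(K) != nrow(V)) {
    abort("Q/K/V dimensions are inconsistent.", class = "endmotif_error_shape")
  }
  S <- Q %*% t(K) / sqrt(ncol(Q))
  if (!is.null(mask)) S[, !mask] <- -Inf
  A <- row_softmax(S)
  list(output = A %*% V, A = A)
}

row_softmax <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - mx)
  E[is.nan(E)] <- 0  # rows where all entries are -Inf (fully masked)
  E / pmax(rowSums(E), .Machine$double.eps)
}

#' Position-wise feed-forward network
#'
#' `FFN(x) = max(0, x W1 + b1) W2 + b2`, applied independently at each
#' sequence position (each row of `x`).
#'
#' @param x Matrix of per-position hidden states (rows are positions).
#' @param W1,b1,W2,b2 Weights/biases of the two linear maps.
#' @return Matrix of the same shape as `x %*% W1 %*% W2`.
#' @export
feed_forward <- function(x, W1, b1, W2, b2) {
  if (ncol(x) != nrow(W1) || ncol(W1) != nrow(W2)) {
    abort("feed_forward: shape mismatch.", class = "endmotif_error_shape")
  }
  h <- add_bias(x %*% W1, b1)
  h[h < 0] <- 0
  add_bias(h %*% W2, b2)
}

add_bias <- function(m, b) m + rep(b, each = nrow(m))

ln_forward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  v <- rowMeans(x * x) - mu * mu
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- (x - mu) * inv_sd
  y <- add_bias(xhat * rep(gamma, each = nrow(x)), beta)
  list(y = y, xhat = xhat, inv_sd = inv_sd)
}

ln_backward <- function(dy, cache, gamma) {
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(gamma, each = nrow(dy))
  dx <- cache$inv_sd *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' Run the encoder over a ranked motif sequence
#'
#' Evaluation-mode forward pass (no dropout): embeds tokens and positions,
#' applies the encoder blocks, and returns the representation matrix `Z`
#' (same shape as the embedded input, `(t+2) x d`), per-position vocabulary
#' logits from the projection head, and the per-layer, per-head attention
#' matrices. PAD positions are excluded from attention via the sequence's
#' attention mask, so appending padding never changes real positions.
#'
#' @param model A `motif_transformer`.
#' @param sequence An `end_motif_sequence` (or character token vector).
#' @return List with `Z` (`(t+2) x d`), `logits` (`(t+2) x vocab`), and
#'   `attentions` (list over layers of lists over heads of square matrices
#'   whose non-PAD rows sum to 1).
#' @export
transformer_forward <- function(model, sequence) {
  tokens <- if (inherits(sequence, "end_motif_sequence")) sequence$tokens else sequence
  n <- length(tokens)
  if (n > model$config$max_positions) {
    abort(sprintf("Sequence length %d exceeds max_positions %d.", n,
                  model$config$max_positions),
          class = "endmotif_error_length")
  }
  ids <- token_index(model$dictionary, tokens)
  mask <- matrix(as.integer(tokens != "PAD"), 1L)
  fw <- txf_encode(matrix(ids, 1L), mask, model$params, model$config,
                   dropout = 0, keep_attention = TRUE)
  logits <- head_forward(fw$H, model$params)$logits
  list(Z = fw$H, logits = logits, attentions = fw$attentions)
}

# Batched encoder forward. ids/mask are B x n matrices; rows of the returned
# H matrix are grouped by sequence: row (b-1)*n + i is position i of batch b.
txf_encode <- function(ids, mask, params, config, dropout = 0,
                       keep_attention = FALSE, keep_cache = FALSE) {
  B <- nrow(ids); n <- ncol(ids)
  d <- config$hidden_size; h <- config$num_heads; dk <- d / h
  ids_flat <- as.integer(t(ids))          # sequence-major
  pos_flat <- rep(seq_len(n), B)
  H <- params$Wx[ids_flat, , drop = FALSE] + params$Wp[pos_flat, , drop = FALSE]
  drop_masks <- list()
  if (dropout > 0) {
    dm <- dropout_mask(dim(H), dropout)
    drop_masks$emb <- dm
    H <- H * dm
  }
  key_mask <- t(mask) # n x B, column b is sequence b's mask
  attentions <- if (keep_attention) vector("list", config$num_layers)
  caches <- if (keep_cache) vector("list", config$num_layers)
  head_cols <- lapply(seq_len(h), function(j) ((j - 1L) * dk + 1L):(j * dk))
  for (l in seq_len(config$num_layers)) {
    Wq <- params[[paste0("Wq_", l)]]
    Wk <- params[[paste0("Wk_", l)]]
    Wv <- params[[paste0("Wv_", l)]]
    Q <- H %*% Wq; K <- H %*% Wk; Vv <- H %*% Wv
    O <- matrix(0, B * n, d)
    A_list <- if (keep_attention || keep_cache) vector("list", B)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * n + 1L):(b * n)
      km <- key_mask[, b] == 1L
      Ab <- if (keep_attention || keep_cache) vector("list", h)
      for (j in seq_len(h)) {
        cols <- head_cols[[j]]
        S <- Q[rows, cols, drop = FALSE] %*% t(K[rows, cols, drop = FALSE]) / sqrt(dk)
        S[, !km] <- -Inf
        A <- row_softmax(S)
        O[rows, cols] <- A %*% Vv[rows, cols, drop = FALSE]
        if (!is.null(Ab)) Ab[[j]] <- A
      }
      if (!is.null(A_list)) A_list[[b]] <- Ab
    }
    if (dropout > 0) {
      dm <- dropout_mask(dim(O), dropout)
      drop_masks[[paste0("attn_", l)]] <- dm
      O <- O * dm
    }
    res1 <- H + O
    ln1 <- ln_forward(res1, params[[paste0("g1_", l)]], params[[paste0("o1_", l)]])
    H1 <- ln1$y
    Fpre <- add_bias(H1 %*% params[[paste0("W1_", l)]], params[[paste0("b1_", l)]])
    Fact <- Fpre; Fact[Fact < 0] <- 0
    ffn_out <- add_bias(Fact %*% params[[paste0("W2_", l)]], params[[paste0("b2_", l)]])
    if (dropout > 0) {
      dm <- dropout_mask(dim(ffn_out), dropout)
      drop_masks[[paste0("ffn_", l)]] <- dm
      ffn_out <- ffn_out * dm
    }
    res2 <- H1 + ffn_out
    ln2 <- ln_forward(res2, params[[paste0("g2_", l)]], params[[paste0("o2_", l)]])
    if (keep_attention) {
      attentions[[l]] <- if (B == 1L) A_list[[1L]] else A_list
    }
    if (keep_cache) {
      caches[[l]] <- list(H_in = H, Q = Q, K = K, V = Vv, A = A_list, O = O,
                          ln1 = ln1, H1 = H1, Fact = Fact, ln2 = ln2)
    }
    H <- ln2$y
  }
  list(H = H, attentions = attentions, caches = caches,
       ids_flat = ids_flat, pos_flat = pos_flat, key_mask = key_mask,
       drop_masks = drop_masks, B = B, n = n)
}

dropout_mask <- function(dims, p) {
  matrix((runif(prod(dims)) >= p) / (1 - p), dims[1L], dims[2L])
}

# Projection head: two-layer map with layer normalization between layers.
head_forward <- function(Z, params, rows = NULL, drop_mask = NULL) {
  if (!is.null(rows)) Z <- Z[rows, , drop = FALSE]
  Upre <- add_bias(Z %*% params$Hw1, params$Hb1)
  U <- Upre; U[U < 0] <- 0
  lnh <- ln_forward(U, params$Hg, params$Ho)
  Un <- lnh$y
  if (!is.null(drop_mask)) Un <- Un * drop_mask
  logits <- add_bias(Un %*% params$Hw2, params$Hb2)
  list(logits = logits, Z = Z, Upre = Upre, U = U, lnh = lnh, Un = Un)
}
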