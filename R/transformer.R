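#' Sinusoidal positional encoding
#'
#' Entry `(p, 2i)` is `sin(p / 10000^(2i/dim))` and entry `(p, 2i+1)` is
#' `cos(p / 10000^(2i/dim))`, with `p` and `i` 0-based, so position 0 encodes
#' as the alternating vector `(0, 1, 0, 1, ...)`. Added to the slice-feature
#' inputs so self-attention can use slice order.
#'
#' @param seq_len Number of sequence positions (>= 1).
#' @param dim Encoding dimension (>= 1).
#'
#' @return `seq_len x dim` matrix with entries in \[-1, 1\].
#' @export
#' @examples
#' positional_encoding(50, 64)[1, 1:4]
positional_encoding <- function(seq_len, dim) {
  seq_len <- check_count(seq_len, "seq_len")
  dim <- check_count(dim, "dim")
  p <- seq_len(seq_len) - 1
  pe <- matrix(0, seq_len, dim)
  for (j in seq_len(dim)) {
    i2 <- 2 * ((j - 1) %/% 2)          # the 2i exponent term, 0-based
    ang <- p / 10000^(i2 / dim)
    pe[, j] <- if ((j - 1) %% 2 == 0) sin(ang) else cos(ang)
  }
  pe
}

#' Transformer classifier configuration
#'
#' Defaults target short (length-50) slice-feature sequences on one CPU:
#' 2 pre-layer-norm blocks, 4 heads of width 32, feed-forward width 128,
#' dropout 0.1, Adam at 1e-3, batch size 16, up to 100 epochs with early
#' stopping (patience 10, minimum improvement 1e-4) on validation loss. Input features enter the blocks
#' at their own width: when `d_model` is `NULL` (default) the block width is
#' `feature_dim` and no input projection is used; setting `d_model` to a
#' different width inserts a single linear map.
#'
#' @param feature_dim Input feature dimension per slice.
#' @param seq_len Sequence length the model accepts (default 50).
#' @param n_classes Number of diagnostic classes (default 3).
#' @param n_blocks,n_heads,head_dim,ff_dim Architecture sizes.
#' @param dropout Dropout rate in \[0, 1) on the residual branches.
#' @param pooling `"global_average"` (default) or `"attention"`.
#' @param use_positional_encoding Add sinusoidal positional encoding to the
#'   inputs (default TRUE). With it off and average pooling, the model is
#'   permutation-invariant in the slice order.
#' @param d_model Block width; `NULL` means `feature_dim` (no projection).
#' @param learning_rate,batch_size,max_epochs,patience Training loop controls.
#' @param min_delta Smallest validation-loss improvement that counts as
#'   progress for early stopping (default 1e-4); smaller changes consume
#'   patience.
#' @param seed Governs parameter initialisation, shuffling and dropout.
#'
#' @return An object of class `model_config`.
#' @export
model_config <- function(feature_dim,
                         seq_len = 50L,
                         n_classes = 3L,
                         n_blocks = 2L,
                         n_heads = 4L,
                         head_dim = 32L,
                         ff_dim = 128L,
                         dropout = 0.1,
                         pooling = c("global_average", "attention"),
                         use_positional_encoding = TRUE,
                         d_model = NULL,
                         learning_rate = 1e-3,
                         batch_size = 16L,
                         max_epochs = 100L,
                         patience = 10L,
                         min_delta = 1e-4,
                         seed = 17L) {
  pooling <- match.arg(pooling)
  feature_dim <- check_count(feature_dim, "feature_dim")
  seq_len <- check_count(seq_len, "seq_len")
  n_classes <- check_count(n_classes, "n_classes", min = 2L)
  n_blocks <- check_count(n_blocks, "n_blocks", min = 0L)
  n_heads <- check_count(n_heads, "n_heads")
  head_dim <- check_count(head_dim, "head_dim")
  ff_dim <- check_count(ff_dim, "ff_dim")
  if (!is.numeric(dropout) || dropout < 0 || dropout >= 1) {
    stop_param("`dropout` must lie in [0, 1)")
  }
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    stop_param("`learning_rate` must be positive")
  }
  batch_size <- check_count(batch_size, "batch_size")
  max_epochs <- check_count(max_epochs, "max_epochs", min = 0L)
  patience <- check_count(patience, "patience", min = 0L)
  if (!is.numeric(min_delta) || min_delta < 0) {
    stop_param("`min_delta` must be non-negative")
  }
  if (is.null(d_model)) d_model <- feature_dim
  d_model <- check_count(d_model, "d_model")
  structure(list(feature_dim = feature_dim, seq_len = seq_len,
                 n_classes = n_classes, n_blocks = n_blocks, n_heads = n_heads,
                 head_dim = head_dim, ff_dim = ff_dim, dropout = dropout,
                 pooling = pooling,
                 use_positional_encoding = isTRUE(use_positional_encoding),
                 d_model = d_model, learning_rate = learning_rate,
                 batch_size = batch_size, max_epochs = max_epochs,
                 patience = patience, min_delta = min_delta,
                 seed = as.integer(seed)),
            class = "model_config")
}

# ---- parameter trees ---------------------------------------------------

glorot <- function(fin, fout) {
  matrix(rnorm(fin * fout, sd = sqrt(2 / (fin + fout))), fin, fout)
}

#' Initialise the weights of one transformer block
#'
#' @param d Block width (model dimension).
#' @param n_heads,head_dim,ff_dim Block sizes.
#' @param init `"glorot"` (seeded random) or `"zeros"` (all projection
#'   weights zero, layer-norm gains 1 — the block then reduces to the
#'   identity through its residual paths).
#' @param seed Seed used for `"glorot"`; `NULL` draws from the current RNG
#'   stream (used internally under the model seed).
#'
#' @return Named list of block weights (`g1, b1, Wq, bq, Wk, bk, Wv, bv, Wo,
#'   bo, g2, b2, W1, c1, W2, c2`).
#' @export
init_block_weights <- function(d, n_heads, head_dim, ff_dim,
                               init = c("glorot", "zeros"), seed = 1L) {
  init <- match.arg(init)
  D <- n_heads * head_dim
  mk <- function(fin, fout) {
    if (init == "zeros") matrix(0, fin, fout) else glorot(fin, fout)
  }
  make <- function() {
    list(g1 = rep(1, d), b1 = rep(0, d),
         Wq = mk(d, D), bq = rep(0, D),
         Wk = mk(d, D), bk = rep(0, D),
         Wv = mk(d, D), bv = rep(0, D),
         Wo = mk(D, d), bo = rep(0, d),
         g2 = rep(1, d), b2 = rep(0, d),
         W1 = mk(d, ff_dim), c1 = rep(0, ff_dim),
         W2 = mk(ff_dim, d), c2 = rep(0, d))
  }
  if (init == "glorot" && !is.null(seed)) {
    withr::with_seed(as.integer(seed), make())
  } else {
    make()
  }
}

init_params <- function(config) {
  cfg <- config
  params <- list()
  if (cfg$d_model != cfg$feature_dim) {
    params$W_in <- glorot(cfg$feature_dim, cfg$d_model)
    params$b_in <- rep(0, cfg$d_model)
  }
  params$blocks <- lapply(seq_len(cfg$n_blocks), function(i) {
    init_block_weights(cfg$d_model, cfg$n_heads, cfg$head_dim, cfg$ff_dim,
                       init = "glorot", seed = NULL)
  })
  if (cfg$pooling == "attention") params$w_pool <- rnorm(cfg$d_model, sd = 0.02)
  params$W_out <- glorot(cfg$d_model, cfg$n_classes)
  params$b_out <- rep(0, cfg$n_classes)
  params
}

# elementwise map over two parameter trees with identical structure
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    out
  } else {
    f(a, b)
  }
}

tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, tree_map, f = f) else f(a)
}

# ---- layers ------------------------------------------------------------

LN_EPS <- 1e-5

ln_forward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + LN_EPS)
  xhat <- xc * inv
  list(y = sweep(xhat, 2, g, "*") + matrix(b, nrow(x), length(b), byrow = TRUE),
       xhat = xhat, inv = inv)
}

ln_backward <- function(dy, cache, g) {
  dxhat <- sweep(dy, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dx <- cache$inv * (dxhat - m1 - cache$xhat * m2)
  list(dx = dx, dg = colSums(dy * cache$xhat), db = colSums(dy))
}

softmax_rows <- function(s) {
  s <- s - apply(s, 1, max)
  e <- exp(s)
  e / rowSums(e)
}

# Multi-head scaled dot-product attention forward on a (seq x d) input that
# has already been layer-normed. Returns output, caches per head.
mha_forward <- function(a, w, n_heads, head_dim) {
  D <- n_heads * head_dim
  Q <- a %*% w$Wq + matrix(w$bq, nrow(a), D, byrow = TRUE)
  K <- a %*% w$Wk + matrix(w$bk, nrow(a), D, byrow = TRUE)
  V <- a %*% w$Wv + matrix(w$bv, nrow(a), D, byrow = TRUE)
  O <- matrix(0, nrow(a), D)
  A <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * head_dim + 1L):(h * head_dim)
    S <- (Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE])) / sqrt(head_dim)
    A[[h]] <- softmax_rows(S)
    O[, idx] <- A[[h]] %*% V[, idx, drop = FALSE]
  }
  M <- O %*% w$Wo + matrix(w$bo, nrow(a), ncol(w$Wo), byrow = TRUE)
  list(M = M, Q = Q, K = K, V = V, O = O, A = A)
}

mha_backward <- function(dM, cache, a, w, n_heads, head_dim) {
  dWo <- t(cache$O) %*% dM
  dbo <- colSums(dM)
  dO <- dM %*% t(w$Wo)
  dQ <- matrix(0, nrow(a), n_heads * head_dim)
  dK <- dQ; dV <- dQ
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * head_dim + 1L):(h * head_dim)
    Ah <- cache$A[[h]]
    dOh <- dO[, idx, drop = FALSE]
    dA <- dOh %*% t(cache$V[, idx, drop = FALSE])
    dV[, idx] <- t(Ah) %*% dOh
    dS <- Ah * (dA - rowSums(dA * Ah))
    dQ[, idx] <- (dS %*% cache$K[, idx, drop = FALSE]) / sqrt(head_dim)
    dK[, idx] <- (t(dS) %*% cache$Q[, idx, drop = FALSE]) / sqrt(head_dim)
  }
  da <- dQ %*% t(w$Wq) + dK %*% t(w$Wk) + dV %*% t(w$Wv)
  list(da = da,
       grads = list(Wq = t(a) %*% dQ, bq = colSums(dQ),
                    Wk = t(a) %*% dK, bk = colSums(dK),
                    Wv = t(a) %*% dV, bv = colSums(dV),
                    Wo = dWo, bo = dbo))
}

#' Apply one pre-layer-norm transformer block
#'
#' Computes `y = x + MHA(LN(x))` then `y + FF(LN(y))`, where MHA is standard
#' multi-head scaled dot-product attention (per head
#' `softmax(Q K' / sqrt(head_dim)) V` with learned projections) and FF is a
#' two-layer position-wise ReLU map. Output shape equals input shape. This is
#' the forward map used inside the classifier, exposed for inspection and
#' testing.
#'
#' @param x `seq_len x d` input matrix.
#' @param weights Block weights from [init_block_weights()] (width `d`).
#' @param n_heads,head_dim Attention geometry; `weights` must match.
#' @param return_attention If TRUE, attach the per-head attention weight
#'   matrices as attribute `"attention"`.
#'
#' @return `seq_len x d` matrix.
#' @export
transformer_block <- function(x, weights, n_heads, head_dim,
                              return_attention = FALSE) {
  if (!is.matrix(x)) stop_shape("`x` must be a matrix")
  d <- ncol(x)
  if (length(weights$g1) != d || nrow(weights$Wq) != d ||
      ncol(weights$Wq) != n_heads * head_dim) {
    stop_shape("block weights do not match input width %d with %d heads of %d",
               d, n_heads, head_dim)
  }
  ln1 <- ln_forward(x, weights$g1, weights$b1)
  att <- mha_forward(ln1$y, weights, n_heads, head_dim)
  x1 <- x + att$M
  ln2 <- ln_forward(x1, weights$g2, weights$b2)
  z <- pmax(ln2$y %*% weights$W1 +
              matrix(weights$c1, nrow(x), length(weights$c1), byrow = TRUE), 0)
  f <- z %*% weights$W2 + matrix(weights$c2, nrow(x), d, byrow = TRUE)
  out <- x1 + f
  if (return_attention) attr(out, "attention") <- att$A
  out
}

# ---- full model forward/backward --------------------------------------

# forward pass for one sequence X (seq_len x feature_dim); returns cache for
# backprop. Dropout masks (already scaled by 1/keep) are drawn here when
# training.
st_forward <- function(params, X, cfg, pe, training = FALSE) {
  cache <- list()
  if (!is.null(params$W_in)) {
    x <- X %*% params$W_in + matrix(params$b_in, nrow(X), cfg$d_model, byrow = TRUE)
  } else {
    x <- X
  }
  if (cfg$use_positional_encoding) x <- x + pe
  keep <- 1 - cfg$dropout
  blocks <- vector("list", cfg$n_blocks)
  for (bi in seq_len(cfg$n_blocks)) {
    w <- params$blocks[[bi]]
    c_ <- list(x0 = x)
    c_$ln1 <- ln_forward(x, w$g1, w$b1)
    c_$att <- mha_forward(c_$ln1$y, w, cfg$n_heads, cfg$head_dim)
    M <- c_$att$M
    if (training && cfg$dropout > 0) {
      c_$mask1 <- matrix((runif(length(M)) < keep) / keep, nrow(M), ncol(M))
      M <- M * c_$mask1
    }
    x1 <- x + M
    c_$x1 <- x1
    c_$ln2 <- ln_forward(x1, w$g2, w$b2)
    zpre <- c_$ln2$y %*% w$W1 + matrix(w$c1, nrow(x1), cfg$ff_dim, byrow = TRUE)
    c_$zpre <- zpre
    z <- pmax(zpre, 0)
    c_$z <- z
    f <- z %*% w$W2 + matrix(w$c2, nrow(x1), cfg$d_model, byrow = TRUE)
    if (training && cfg$dropout > 0) {
      c_$mask2 <- matrix((runif(length(f)) < keep) / keep, nrow(f), ncol(f))
      f <- f * c_$mask2
    }
    x <- x1 + f
    blocks[[bi]] <- c_
  }
  cache$blocks <- blocks
  cache$x_final <- x
  if (cfg$pooling == "attention") {
    sc <- as.numeric(x %*% params$w_pool)
    sc <- sc - max(sc)
    alpha <- exp(sc) / sum(exp(sc))
    cache$alpha <- alpha
    pooled <- as.numeric(t(x) %*% alpha)
  } else {
    pooled <- colMeans(x)
  }
  cache$pooled <- pooled
  logits <- as.numeric(pooled %*% params$W_out) + params$b_out
  logits <- logits - max(logits)
  probs <- exp(logits) / sum(exp(logits))
  cache$probs <- probs
  cache$logits <- logits
  cache$X <- X
  cache
}

# backward pass for one sequence given its forward cache and 0-based label y.
# Returns the gradient tree (same structure as params) of the cross-entropy
# loss for this sequence.
st_backward <- function(params, cache, y, cfg) {
  probs <- cache$probs
  dlogits <- probs
  dlogits[y + 1L] <- dlogits[y + 1L] - 1
  grads <- list()
  grads$W_out <- outer(cache$pooled, dlogits)
  grads$b_out <- dlogits
  dpooled <- as.numeric(params$W_out %*% dlogits)
  x <- cache$x_final
  s <- nrow(x)
  if (cfg$pooling == "attention") {
    alpha <- cache$alpha
    dx <- alpha %o% dpooled
    dalpha <- as.numeric(x %*% dpooled)
    dsc <- alpha * (dalpha - sum(dalpha * alpha))
    dx <- dx + dsc %o% params$w_pool
    grads$w_pool <- as.numeric(t(x) %*% dsc)
  } else {
    dx <- matrix(dpooled, s, cfg$d_model, byrow = TRUE) / s
  }
  gblocks <- vector("list", cfg$n_blocks)
  for (bi in rev(seq_len(cfg$n_blocks))) {
    w <- params$blocks[[bi]]
    c_ <- cache$blocks[[bi]]
    df <- dx
    if (!is.null(c_$mask2)) df <- df * c_$mask2
    gW2 <- t(c_$z) %*% df
    gc2 <- colSums(df)
    dz <- df %*% t(w$W2)
    dzpre <- dz * (c_$zpre > 0)
    gW1 <- t(c_$ln2$y) %*% dzpre
    gc1 <- colSums(dzpre)
    du <- dzpre %*% t(w$W1)
    lb2 <- ln_backward(du, c_$ln2, w$g2)
    dx1 <- dx + lb2$dx
    dM <- dx1
    if (!is.null(c_$mask1)) dM <- dM * c_$mask1
    mb <- mha_backward(dM, c_$att, c_$ln1$y, w, cfg$n_heads, cfg$head_dim)
    lb1 <- ln_backward(mb$da, c_$ln1, w$g1)
    dx <- dx1 + lb1$dx
    gblocks[[bi]] <- c(list(g1 = lb1$dg, b1 = lb1$db),
                       mb$grads,
                       list(g2 = lb2$dg, b2 = lb2$db,
                            W1 = gW1, c1 = gc1, W2 = gW2, c2 = gc2))
    # reorder to match params$blocks structure
    gblocks[[bi]] <- gblocks[[bi]][names(w)]
  }
  grads$blocks <- gblocks
  if (!is.null(params$W_in)) {
    grads$W_in <- t(cache$X) %*% dx
    grads$b_in <- colSums(dx)
  }
  grads[names(params)]
}

seq_loss <- function(cache, y) -log(max(cache$probs[y + 1L], 1e-12))

# ---- model object ------------------------------------------------------

#' Build an untrained slice-sequence transformer
#'
#' Composition: optional input projection, add sinusoidal positional
#' encoding, `n_blocks` pre-layer-norm transformer blocks, pooling over the
#' sequence axis (global average by default, attention pooling optional),
#' dense softmax over the classes. Initialisation is seeded by
#' `config$seed`, so two fresh builds from the same config produce identical
#' outputs.
#'
#' @param config A [model_config()].
#'
#' @return An object of class `slice_transformer` (untrained).
#' @export
build_model <- function(config) {
  if (!inherits(config, "model_config")) stop_param("`config` must be a model_config")
  params <- withr::with_seed(config$seed, init_params(config))
  structure(list(config = config,
                 params = params,
                 pe = positional_encoding(config$seq_len, config$d_model),
                 fitted = FALSE,
                 history = tibble(epoch = integer(), train_loss = numeric(),
                                  val_loss = numeric(), val_accuracy = numeric())),
            class = "slice_transformer")
}

#' @export
print.slice_transformer <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<slice_transformer> %s; %d block(s), %d head(s) x %d, ",
                     "ff %d, width %d, seq %d, %d classes, pooling %s\n"),
              if (x$fitted) "trained" else "untrained",
              cfg$n_blocks, cfg$n_heads, cfg$head_dim, cfg$ff_dim, cfg$d_model,
              cfg$seq_len, cfg$n_classes, cfg$pooling))
  if (x$fitted && nrow(x$history) > 0) {
    best <- x$history[which.min(x$history$val_loss), ]
    cat(sprintf("  %d epoch(s); best val loss %.4f (epoch %d), val accuracy %.3f\n",
                nrow(x$history), best$val_loss, best$epoch, best$val_accuracy))
  }
  invisible(x)
}

# coerce input to the internal dataset form:
# list(features = list of seq_len x feature_dim matrices, labels = factor,
#      subject_ids = character)
as_feature_dataset <- function(x) {
  if (is.list(x) && !is.null(x$features) && is.list(x$features)) return(x)
  if (inherits(x, "feature_sequence")) x <- list(x)
  if (!is.list(x) || !all(vapply(x, inherits, logical(1), "feature_sequence"))) {
    stop_param("expected a list of feature_sequence objects or a dataset")
  }
  list(features = lapply(x, `[[`, "features"),
       labels = as_class_factor(vapply(x, `[[`, character(1), "label")),
       subject_ids = vapply(x, `[[`, character(1), "subject_id"))
}

check_dataset_shapes <- function(ds, cfg) {
  for (i in seq_along(ds$features)) {
    dm <- dim(ds$features[[i]])
    if (dm[1] != cfg$seq_len || dm[2] != cfg$feature_dim) {
      stop_shape("sequence %s has shape %dx%d but the model expects %dx%d",
                 ds$subject_ids[i] %||% i, dm[1], dm[2], cfg$seq_len, cfg$feature_dim)
    }
  }
  invisible(ds)
}

dataset_labels_int <- function(ds, cfg) {
  y <- encode_labels(as.character(ds$labels))
  if (any(y < 0 | y >= cfg$n_classes)) {
    stop_data("labels outside [0, %d) found", cfg$n_classes)
  }
  y
}

mean_loss_acc <- function(params, ds, y, cfg, pe) {
  n <- length(ds$features)
  loss <- 0; correct <- 0
  for (i in seq_len(n)) {
    cc <- st_forward(params, ds$features[[i]], cfg, pe, training = FALSE)
    loss <- loss + seq_loss(cc, y[i])
    pred <- which.max(cc$probs) - 1L  # which.max takes the first (lowest) index on ties
    correct <- correct + (pred == y[i])
  }
  c(loss = loss / n, acc = correct / n)
}

#' Train the classifier on one cross-validation fold
#'
#' Minimises categorical cross-entropy on one-hot labels with an Adam
#' optimiser, mini-batches, and early stopping on validation loss with
#' `config$patience`; the best-validation parameters are restored. One config
#' seed governs initialisation, shuffling and dropout, so reruns on equal
#' data reproduce the history.
#'
#' @param train,val Training/validation data: lists of [feature_sequence()]s.
#' @param config A [model_config()].
#' @param verbose Print a line per epoch.
#'
#' @return A fitted `slice_transformer` with a `history` tibble (epoch,
#'   train_loss, val_loss, val_accuracy). With `max_epochs = 0` the
#'   initialised model is returned unchanged with an empty history.
#' @export
train_fold <- function(train, val, config, verbose = FALSE) {
  cfg <- config
  train <- as_feature_dataset(train); val <- as_feature_dataset(val)
  if (length(train$features) == 0 || length(val$features) == 0) {
    stop_data("training and validation sets must be nonempty")
  }
  check_dataset_shapes(train, cfg); check_dataset_shapes(val, cfg)
  ytr <- dataset_labels_int(train, cfg)
  yva <- dataset_labels_int(val, cfg)
  model <- build_model(cfg)
  if (cfg$max_epochs == 0L) return(model)
  params <- model$params
  pe <- model$pe
  mstate <- tree_map(function(p) p * 0, params)
  vstate <- mstate
  tstep <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best_loss <- Inf; best_params <- params; wait <- 0L
  hist <- vector("list", cfg$max_epochs)
  n <- length(train$features)
  withr::with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        bidx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        gsum <- NULL
        bloss <- 0
        for (i in bidx) {
          cc <- st_forward(params, train$features[[i]], cfg, pe, training = TRUE)
          bloss <- bloss + seq_loss(cc, ytr[i])
          g <- st_backward(params, cc, ytr[i], cfg)
          gsum <- if (is.null(gsum)) g else tree_map2(`+`, gsum, g)
        }
        nb <- length(bidx)
        g <- tree_map(function(x) x / nb, gsum)
        tstep <- tstep + 1
        mstate <- tree_map2(function(m, gg) b1 * m + (1 - b1) * gg, mstate, g)
        vstate <- tree_map2(function(v, gg) b2 * v + (1 - b2) * gg^2, vstate, g)
        corr1 <- 1 - b1^tstep; corr2 <- 1 - b2^tstep
        upd <- tree_map2(function(m, v) {
          (m / corr1) / (sqrt(v / corr2) + eps)
        }, mstate, vstate)
        params <- tree_map2(function(p, u) p - cfg$learning_rate * u, params, upd)
        ep_loss <- ep_loss + bloss
      }
      valm <- mean_loss_acc(params, val, yva, cfg, pe)
      hist[[epoch]] <- tibble(epoch = epoch, train_loss = ep_loss / n,
                              val_loss = valm[["loss"]],
                              val_accuracy = valm[["acc"]])
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f  val acc %.3f",
                        epoch, ep_loss / n, valm[["loss"]], valm[["acc"]]))
      }
      if (valm[["loss"]] < best_loss - cfg$min_delta) {
        best_loss <- valm[["loss"]]
        best_params <- params
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait > cfg$patience) break
      }
    }
  })
  model$params <- best_params
  model$fitted <- TRUE
  model$history <- dplyr::bind_rows(hist[!vapply(hist, is.null, logical(1))])
  model
}

#' Predict class probabilities and labels
#'
#' @param object A `slice_transformer`.
#' @param new_data A list of [feature_sequence()]s, a dataset, or one
#'   `seq_len x feature_dim` matrix.
#' @param type `"both"` (default; tibble of probabilities and predicted
#'   class), `"prob"` (probability matrix), `"class"` (factor) or `"logit"`
#'   (pre-softmax logit matrix, shifted per row so the max is 0).
#' @param ... Unused.
#'
#' @return For `type = "both"` a tibble with `subject_id`, one `.pred_<class>`
#'   probability column per class, and `.pred_class`. Probability rows sum to
#'   1; the predicted label is the argmax with ties broken toward the lower
#'   class index.
#' @export
predict.slice_transformer <- function(object, new_data,
                                      type = c("both", "prob", "class", "logit"),
                                      ...) {
  type <- match.arg(type)
  cfg <- object$config
  if (is.matrix(new_data)) {
    new_data <- list(features = list(new_data),
                     labels = factor(rep(NA_character_, 1), levels = class_levels()),
                     subject_ids = "1")
  }
  ds <- as_feature_dataset(new_data)
  check_dataset_shapes(ds, cfg)
  n <- length(ds$features)
  probs <- matrix(0, n, cfg$n_classes)
  logits <- matrix(0, n, cfg$n_classes)
  for (i in seq_len(n)) {
    cc <- st_forward(object$params, ds$features[[i]], cfg, object$pe,
                     training = FALSE)
    probs[i, ] <- cc$probs
    logits[i, ] <- cc$logits
  }
  lev <- class_levels()[seq_len(cfg$n_classes)]
  colnames(probs) <- lev
  pred <- factor(lev[apply(probs, 1, which.max)], levels = lev)
  switch(type,
         prob = probs,
         logit = logits,
         class = pred,
         both = {
           out <- as_tibble(probs, .name_repair = ~ paste0(".pred_", lev))
           out$subject_id <- ds$subject_ids %||% as.character(seq_len(n))
           out$.pred_class <- pred
           dplyr::relocate(out, "subject_id")
         })
}

#' @export
tidy.slice_transformer <- function(x, ...) x$history

#' @export
glance.slice_transformer <- function(x, ...) {
  if (!x$fitted || nrow(x$history) == 0) {
    return(tibble(fitted = x$fitted, n_epochs = 0L,
                  best_val_loss = NA_real_, best_val_accuracy = NA_real_))
  }
  best <- x$history[which.min(x$history$val_loss), ]
  tibble(fitted = TRUE, n_epochs = nrow(x$history),
         best_val_loss = best$val_loss, best_val_accuracy = best$val_accuracy)
}

#' @export
autoplot.slice_transformer <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "series", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
}
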