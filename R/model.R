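# The transformer encoder: sinusoidal positional encoding, masked multi-head
# self-attention, post-norm residual blocks, sequence reduction, and single-
# or multi-level classification heads.
#
# The functions in this file are the readable reference implementations of
# each operation (matrices in, matrices out); training and bulk inference go
# through the fused RcppArmadillo path (cpp_model_pass), which a consistency
# test holds to the reference within tight numeric tolerance.

#' Sinusoidal positional encoding
#'
#' Position p (1-based) gets a d_model-vector with `sin(f_k p)` at even
#' components `j = 2k` and `cos(f_k p)` at odd components `j = 2k + 1`,
#' where `f_k = 10000^(-2k / d_model)` is a geometric progression from 1
#' down to 1/10000.  Wavelengths therefore increase monotonically from 2*pi
#' to 2*pi*10000 across the vector.
#'
#' @param n Number of positions.
#' @param d_model Embedding dimension (must be even).
#' @return An `n x d_model` matrix with entries in `[-1, 1]`.
#' @export
positional_encoding <- function(n, d_model) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (d_model %% 2 != 0) stop("d_model must be even", call. = FALSE)
  p <- seq_len(n)
  kk <- 0:(d_model / 2 - 1)
  f <- 10000^(-2 * kk / d_model)
  P <- matrix(0, n, d_model)
  P[, 2 * kk + 1] <- sin(outer(p, f))
  P[, 2 * kk + 2] <- cos(outer(p, f))
  P
}

#' Combine token embeddings with positional encoding
#'
#' The embedded tokens are scaled by `sqrt(d_model)` and the positional
#' encoding is added point-wise: `E = S * sqrt(d_model) + P`.
#'
#' @param S `n x d_model` matrix of embedded tokens.
#' @param P `n x d_model` positional encoding (see [positional_encoding()]).
#' @return The `n x d_model` input encoding.
#' @export
input_encoding <- function(S, P) {
  if (!all(dim(S) == dim(P)))
    stop("shape mismatch between S and P", call. = FALSE)
  S * sqrt(ncol(S)) + P
}

#' Scaled dot-product attention with padding mask
#'
#' Scores are `Q K' / sqrt(d_k)` with masked columns set to `-Inf` before the
#' row-wise softmax, so masked positions receive exactly zero attention
#' weight and each row's weights sum to 1 over the unmasked positions.
#'
#' @param Q,K `n x d_k` query and key matrices.
#' @param V `n x d_v` value matrix.
#' @param mask Logical vector of length n; `TRUE` marks attendable (real)
#'   positions.  `NULL` means no masking.
#' @return The `n x d_v` attention output.
#' @export
attention <- function(Q, K, V, mask = NULL) {
  d_k <- ncol(Q)
  S <- Q %*% t(K) / sqrt(d_k)
  if (!is.null(mask)) {
    if (!any(mask)) stop("all positions masked: softmax undefined",
                         call. = FALSE)
    S[, !mask] <- -Inf
  }
  mx <- apply(S, 1, max)
  A <- exp(S - mx)
  A <- A / rowSums(A)
  A %*% V
}

#' Multi-head self-attention
#'
#' Each head projects the input into its own `d_k = d_model / h` subspace,
#' applies [attention()], and the concatenated head outputs are mixed by the
#' output projection.  The trainable parameter count is independent of the
#' number of heads.
#'
#' @param E `n x d_model` input encoding.
#' @param params List with `heads` (a list of `list(Wq, Wk, Wv)` per head)
#'   and `Wo` (`(h * d_v) x d_model` output projection).
#' @param mask Logical position mask as in [attention()].
#' @return `n x d_model` matrix.
#' @export
multi_head <- function(E, params, mask = NULL) {
  a <- lapply(params$heads, function(hp)
    attention(E %*% hp$Wq, E %*% hp$Wk, E %*% hp$Wv, mask))
  do.call(cbind, a) %*% params$Wo
}

#' Layer normalization over the feature dimension
#'
#' @param X `n x d` matrix; each row is normalized to zero mean and unit
#'   variance (epsilon-stabilized), then scaled and shifted.
#' @param g,b Gain and bias vectors of length d.
#' @param eps Variance stabilizer.
#' @return Normalized `n x d` matrix.
#' @export
layer_norm <- function(X, g = rep(1, ncol(X)), b = rep(0, ncol(X)),
                       eps = 1e-5) {
  mu <- rowMeans(X)
  v <- rowMeans((X - mu)^2)
  xhat <- (X - mu) / sqrt(v + eps)
  sweep(sweep(xhat, 2, g, "*"), 2, b, "+")
}

#' One transformer encoder block
#'
#' Post-norm design: multi-head self-attention, residual re-addition and
#' layer normalization, position-wise feed-forward MLP (one ReLU hidden
#' layer of width d_ff), and a second residual + layer normalization.
#'
#' @param E `n x d_model` input.
#' @param params List with `att` (see [multi_head()]), `ln1` / `ln2`
#'   (`list(g, b)`), and `mlp` (`list(W1, b1, W2, b2)`).
#' @param mask Logical position mask.
#' @return `n x d_model` block output.
#' @export
encoder_block <- function(E, params, mask = NULL) {
  Z <- multi_head(E, params$att, mask)
  N <- layer_norm(Z + E, params$ln1$g, params$ln1$b)
  H <- pmax(sweep(N %*% params$mlp$W1, 2, params$mlp$b1, "+"), 0)
  M <- sweep(H %*% params$mlp$W2, 2, params$mlp$b2, "+")
  layer_norm(M + N, params$ln2$g, params$ln2$b)
}

#' Reduce a sequence of representations to one vector
#'
#' @param O `n x d_model` encoder output.
#' @param mode `"mean"` (average over unmasked positions), `"cls"` (first
#'   position; requires cls tokenization) or `"concat"` (learned projection
#'   of the flattened sequence; fixed n only).
#' @param mask Logical position mask (mean mode).
#' @param W_red `(n * d_model) x d_model` projection (concat mode; row-vector
#'   convention `x = concat(O_1..O_n) %*% W_red`).
#' @return A d_model vector.
#' @export
reduce_sequence <- function(O, mode = c("mean", "cls", "concat"), mask = NULL,
                            W_red = NULL) {
  mode <- match.arg(mode)
  if (mode == "mean") {
    if (is.null(mask)) mask <- rep(TRUE, nrow(O))
    colSums(O[mask, , drop = FALSE]) / sum(mask)
  } else if (mode == "cls") {
    O[1, ]
  } else {
    if (is.null(W_red)) stop("concat reduction needs W_red", call. = FALSE)
    if (nrow(W_red) != length(O))
      stop("concat reduction requires fixed n = ", nrow(W_red) / ncol(O),
           call. = FALSE)
    as.vector(c(t(O)) %*% W_red)
  }
}

#' Linear classification of a reduced representation
#'
#' @param O_red d_model vector (see [reduce_sequence()]).
#' @param head List with `W` (`d_model x m`) and `b` (length m).
#' @return Unnormalized class scores of length m (softmax is applied only at
#'   inference / loss time).
#' @export
classify_linear <- function(O_red, head) {
  as.vector(O_red %*% head$W + head$b)
}

#' Interconnected multi-level classification heads
#'
#' Levels are ordered coarse to fine.  Level 1 is an independent linear head;
#' each finer level adds a learned linear transform of the previous level's
#' scores: `y_i = x W_i + b_i + T_{i-1} y_{i-1}` (with `T_0 = 0`).
#'
#' @param x_b Backbone representation (d_model vector).
#' @param heads List of `list(W, b)` per level, coarse to fine.
#' @param transforms List of matrices; `transforms[[i]]` is the
#'   `M_{i+1} x M_i` map injecting level-i scores into level i + 1.  Zero
#'   matrices reproduce independent heads exactly.
#' @return List of score vectors, one per level.
#' @export
multilevel_forward <- function(x_b, heads, transforms = NULL) {
  L <- length(heads)
  y <- vector("list", L)
  for (i in seq_len(L)) {
    y[[i]] <- classify_linear(x_b, heads[[i]])
    if (i > 1) {
      Tm <- transforms[[i - 1]]
      if (is.null(Tm)) Tm <- matrix(0, length(y[[i]]), length(y[[i - 1]]))
      if (ncol(Tm) != length(y[[i - 1]]) || nrow(Tm) != length(y[[i]]))
        stop("transform ", i - 1, " has incompatible dimensions",
             call. = FALSE)
      y[[i]] <- y[[i]] + as.vector(Tm %*% y[[i - 1]])
    }
  }
  y
}

#' Encoder hyperparameter configuration
#'
#' The evaluated hyperparameter grid of the underlying architecture:
#' `d_model` 64/128, 1-4 encoder blocks, `d_ff` 256/512, mean or cls
#' reduction, dropout 0.0/0.1.  The head count divides `d_model`
#' (`d_k = d_v = d_model / h`).
#'
#' @param d_model Embedding dimension.
#' @param n_blocks Number of encoder blocks.
#' @param d_ff Feed-forward hidden width.
#' @param h Attention heads (default 8).
#' @param reduction `"mean"`, `"cls"` or `"concat"`.
#' @param dropout Dropout rate (applied to attention output, MLP output and
#'   input encoding during training).
#' @param n_max Maximum token-stream length (also the fixed length required
#'   by concat reduction).
#' @param ln_eps Layer-norm epsilon.
#' @param reduced_precision Round forward activations to float32 (training
#'   speed/memory flag; gradients stay double).
#' @return An `encoder_config` object.
#' @export
encoder_config <- function(d_model = 64L, n_blocks = 1L, d_ff = 256L, h = 8L,
                           reduction = c("mean", "cls", "concat"),
                           dropout = 0, n_max = 256L, ln_eps = 1e-5,
                           reduced_precision = FALSE) {
  reduction <- match.arg(reduction)
  if (d_model %% h != 0) stop("d_model must be divisible by h", call. = FALSE)
  if (d_model %% 2 != 0) stop("d_model must be even", call. = FALSE)
  if (n_blocks < 1 || d_ff < 1 || dropout < 0 || dropout >= 1)
    stop("invalid encoder configuration", call. = FALSE)
  structure(list(d_model = as.integer(d_model), n_blocks = as.integer(n_blocks),
                 d_ff = as.integer(d_ff), h = as.integer(h),
                 reduction = reduction, dropout = dropout,
                 n_max = as.integer(n_max), ln_eps = ln_eps,
                 reduced_precision = reduced_precision),
            class = "encoder_config")
}

he_uniform <- function(nr, nc) {
  lim <- sqrt(6 / nr)
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize a read classification model
#'
#' Builds all trainable parameters for the encoder and classification heads.
#' Projections use uniform He-style initialization, embedding tables
#' Normal(0, d_model^-1/2), layer-norm gains 1 / biases 0, classifier heads
#' zero (so initial logits are uniform and the starting loss is log(m)),
#' and the inter-level transforms start at zero (independent heads).
#'
#' @param config An [encoder_config()].
#' @param scheme A [token_scheme()]; `reduction = "cls"` requires
#'   `scheme$with_cls`.
#' @param levels Named list of class labels per taxonomic level, ordered
#'   coarse to fine (e.g. `list(genus = ..., species = ...)`).
#' @param seed Integer seed for the initialization.
#' @return An object of class `readformer_model`.
#' @export
init_model <- function(config, scheme, levels, seed = 1L) {
  stopifnot(inherits(config, "encoder_config"),
            inherits(scheme, "token_scheme"))
  if (config$reduction == "cls" && !scheme$with_cls)
    stop("cls reduction requires a scheme with with_cls = TRUE",
         call. = FALSE)
  if (!is.list(levels) || is.null(names(levels)) || any(names(levels) == ""))
    stop("levels must be a named list of class label vectors", call. = FALSE)
  levels <- lapply(levels, as.character)
  d <- config$d_model
  with_seed(seed, {
    p <- list()
    if (scheme$scheme == "hash") {
      p$pool <- matrix(rnorm((scheme$b + 3) * d, 0, 1 / sqrt(d)),
                       scheme$b + 3, d)
      p$impw <- matrix(1 / scheme$q + rnorm((scheme$W + 3) * scheme$q,
                                            0, 0.01),
                       scheme$W + 3, scheme$q)
    } else {
      p$emb <- matrix(rnorm(scheme$table_size * d, 0, 1 / sqrt(d)),
                      scheme$table_size, d)
    }
    for (i in seq_len(config$n_blocks)) {
      p[[paste0("Wq", i)]] <- he_uniform(d, d)
      p[[paste0("Wk", i)]] <- he_uniform(d, d)
      p[[paste0("Wv", i)]] <- he_uniform(d, d)
      p[[paste0("Wo", i)]] <- he_uniform(d, d)
      p[[paste0("ln1g", i)]] <- matrix(1, 1, d)
      p[[paste0("ln1b", i)]] <- matrix(0, 1, d)
      p[[paste0("ln2g", i)]] <- matrix(1, 1, d)
      p[[paste0("ln2b", i)]] <- matrix(0, 1, d)
      p[[paste0("W1", i)]] <- he_uniform(d, config$d_ff)
      p[[paste0("bb1", i)]] <- matrix(0, 1, config$d_ff)
      p[[paste0("W2", i)]] <- he_uniform(config$d_ff, d)
      p[[paste0("bb2", i)]] <- matrix(0, 1, d)
    }
    if (config$reduction == "concat")
      p$Wred <- he_uniform(config$n_max * d, d)
    M <- vapply(levels, length, integer(1))
    for (l in seq_along(levels)) {
      # classifier heads start at zero: initial logits are exactly uniform
      # (loss ln(m)) and the first updates are driven by the labels alone
      p[[paste0("HW", l)]] <- matrix(0, d, M[l])
      p[[paste0("Hb", l)]] <- matrix(0, 1, M[l])
      if (l > 1) p[[paste0("T", l - 1)]] <- matrix(0, M[l], M[l - 1])
    }
    structure(list(config = config, scheme = scheme, levels = levels,
                   params = p, P = positional_encoding(config$n_max, d),
                   init_seed = as.integer(seed)),
              class = "readformer_model")
  })
}

#' @export
print.readformer_model <- function(x, ...) {
  cat("readformer model: d_model =", x$config$d_model, "|", x$config$n_blocks,
      "block(s) | h =", x$config$h, "| d_ff =", x$config$d_ff,
      "|", x$config$reduction, "reduction\n")
  cat("  scheme:", x$scheme$scheme,
      if (x$scheme$scheme != "char") paste0("(k = ", x$scheme$k, ")"), "\n")
  cat("  levels:", paste(sprintf("%s (%d)", names(x$levels),
                                 lengths(x$levels)), collapse = ", "), "\n")
  cat("  trainable parameters:", format(n_params(x), big.mark = ","), "\n")
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model A `readformer_model`.
#' @return Integer number of trainable scalars; exact, so head-count
#'   invariance can be asserted as integer equality.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# Config list handed to the C++ core.
core_cfg <- function(model) {
  list(h = model$config$h, n_blocks = model$config$n_blocks,
       d_model = model$config$d_model, d_ff = model$config$d_ff,
       reduction = model$config$reduction, ln_eps = model$config$ln_eps,
       reduced_precision = isTRUE(model$config$reduced_precision),
       emb_mode = if (model$scheme$scheme == "hash") "hash" else "table",
       levels = vapply(model$levels, length, integer(1)))
}

# Batched forward (and optionally backward) pass through the C++ core.
# batch: a padded_batch; labels: list per level of 1-based integer vectors.
model_pass <- function(model, batch, labels = list(), weights = list(),
                       want_grad = FALSE, dropmasks = list()) {
  n <- ncol(batch$ids)
  if (model$config$reduction == "concat" && n != model$config$n_max)
    stop("concat reduction requires fixed sequence length n_max = ",
         model$config$n_max, call. = FALSE)
  inputs <- list(mask = matrix(as.integer(batch$mask), nrow(batch$mask)))
  if (model$scheme$scheme == "hash") {
    inputs$imp <- batch$imp
    inputs$comp <- batch$comp
    storage.mode(inputs$imp) <- "integer"
    storage.mode(inputs$comp) <- "integer"
  } else {
    inputs$ids <- batch$ids
    storage.mode(inputs$ids) <- "integer"
  }
  cpp_model_pass(inputs, model$params, core_cfg(model),
                 model$P[seq_len(n), , drop = FALSE],
                 labels, weights, want_grad, dropmasks)
}

#' Save a model checkpoint
#'
#' Writes a directory holding a JSON config document (architecture, scheme,
#' taxonomy class lists, provenance) and a weights blob;
#' `load_model(save_model(m, d))` reproduces forward outputs bit-for-bit.
#'
#' @param model A `readformer_model` (or `readformer_fit`).
#' @param dir Checkpoint directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  if (inherits(model, "readformer_fit")) model <- model$model
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scheme_meta <- model$scheme
  scheme_meta$vocab <- NULL  # rebuilt combinatorially on load
  cfg <- list(package = "readformer",
              version = as.character(utils::packageVersion("readformer")),
              config = unclass(model$config),
              scheme = unclass(scheme_meta),
              levels = model$levels,
              init_seed = model$init_seed)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  saveRDS(model$params, file.path(dir, "weights.rds"))
  invisible(dir)
}

#' Load a model checkpoint
#'
#' @param dir Directory written by [save_model()].
#' @return A `readformer_model`.
#' @export
load_model <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  config <- do.call(encoder_config, cfg$config[names(cfg$config) %in%
    names(formals(encoder_config))])
  sc <- cfg$scheme
  scheme <- token_scheme(sc$scheme, k = sc$k, b = sc$b, q = sc$q, W = sc$W,
                         seed = sc$seed, n_max = sc$n_max,
                         with_cls = sc$with_cls)
  levels <- lapply(cfg$levels, as.character)
  params <- readRDS(file.path(dir, "weights.rds"))
  structure(list(config = config, scheme = scheme, levels = levels,
                 params = params,
                 P = positional_encoding(config$n_max, config$d_model),
                 init_seed = cfg$init_seed),
            class = "readformer_model")
}
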