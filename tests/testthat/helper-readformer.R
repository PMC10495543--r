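# Shared fixtures and independent oracles, built in code at test time.

# random DNA string
rand_dna <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# all k-mers over ACGT, lexicographic order
all_kmers <- function(k) {
  g <- do.call(expand.grid,
               rev(replicate(k, c("A", "C", "G", "T"), simplify = FALSE)))
  sort(apply(g[, k:1, drop = FALSE], 1, paste, collapse = ""))
}

# brute-force scaled dot-product attention: explicit per-element loops
attention_oracle <- function(Q, K, V, mask = NULL) {
  n <- nrow(Q); d_k <- ncol(Q); d_v <- ncol(V)
  out <- matrix(0, n, d_v)
  for (i in seq_len(n)) {
    s <- numeric(n)
    for (j in seq_len(n)) {
      acc <- 0
      for (t in seq_len(d_k)) acc <- acc + Q[i, t] * K[j, t]
      s[j] <- acc / sqrt(d_k)
      if (!is.null(mask) && !mask[j]) s[j] <- -Inf
    }
    w <- exp(s - max(s))
    w <- w / sum(w)
    for (v in seq_len(d_v))
      out[i, v] <- sum(w * V[, v])
  }
  out
}

# split fused projection matrices into the per-head parameter layout used by
# the reference R functions
split_heads <- function(params, i, h, d) {
  dk <- d / h
  list(heads = lapply(seq_len(h), function(j) {
    cl <- ((j - 1) * dk + 1):(j * dk)
    list(Wq = params[[paste0("Wq", i)]][, cl],
         Wk = params[[paste0("Wk", i)]][, cl],
         Wv = params[[paste0("Wv", i)]][, cl])
  }), Wo = params[[paste0("Wo", i)]])
}

# reference forward pass composed from the exported R operations; must match
# the C++ fast path
ref_forward <- function(model, stream, mask = NULL) {
  p <- model$params
  cfg <- model$config
  ids <- if (inherits(stream, "token_stream")) stream$ids else stream
  n <- length(ids)
  if (is.null(mask)) mask <- rep(TRUE, n)
  S <- p$emb[ids + 1, , drop = FALSE]
  E <- input_encoding(S, positional_encoding(n, cfg$d_model))
  for (i in seq_len(cfg$n_blocks)) {
    pars <- list(att = split_heads(p, i, cfg$h, cfg$d_model),
                 ln1 = list(g = p[[paste0("ln1g", i)]][1, ],
                            b = p[[paste0("ln1b", i)]][1, ]),
                 ln2 = list(g = p[[paste0("ln2g", i)]][1, ],
                            b = p[[paste0("ln2b", i)]][1, ]),
                 mlp = list(W1 = p[[paste0("W1", i)]],
                            b1 = p[[paste0("bb1", i)]][1, ],
                            W2 = p[[paste0("W2", i)]],
                            b2 = p[[paste0("bb2", i)]][1, ]))
    E <- encoder_block(E, pars, mask)
  }
  x <- reduce_sequence(E, cfg$reduction, mask, W_red = p$Wred)
  L <- length(model$levels)
  heads <- lapply(seq_len(L), function(l)
    list(W = p[[paste0("HW", l)]], b = p[[paste0("Hb", l)]][1, ]))
  transforms <- if (L > 1) lapply(seq_len(L - 1), function(l)
    p[[paste0("T", l)]]) else NULL
  multilevel_forward(x, heads, transforms)
}

# small model for fast tests
tiny_model <- function(scheme = token_scheme("vocab", k = 3, seed = 1),
                       levels = list(species = c("s1", "s2", "s3")),
                       d_model = 8L, n_blocks = 1L, d_ff = 16L, h = 2L,
                       reduction = "mean", n_max = 32L, seed = 7L, ...) {
  cfg <- encoder_config(d_model = d_model, n_blocks = n_blocks, d_ff = d_ff,
                        h = h, reduction = reduction, n_max = n_max, ...)
  init_model(cfg, scheme, levels, seed = seed)
}

# two-genus / four-species toy taxonomy + labelled reads for training tests
toy_read_set <- function(n_per_class = 60, read_len = 60, seed = 99,
                         err_rate = 0) {
  tax <- simulate_taxonomy(2, 2, 2000, d_between = 0.3, d_within = 0.08,
                           seed = seed)
  reads <- generate_balanced_set(tax, f = 1, read_len = read_len,
                                 paired = FALSE, err_rate = err_rate,
                                 seed = seed + 1)
  list(tax = tax, reads = reads)
}
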