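# Encoder operations against closed forms and brute-force oracles, parameter
# bookkeeping, and the C++ fast path against the composed R reference.

test_that("positional encoding matches its closed form", {
  P <- positional_encoding(50, 8)
  expect_true(all(P >= -1 & P <= 1))
  # f_0 = 1: first component is sin(p), second cos(p)
  expect_equal(P[, 1], sin(1:50))
  expect_equal(P[, 2], cos(1:50))
  expect_equal(P[1, 1], sin(1), tolerance = 1e-12)
  # frequencies decrease geometrically => wavelengths strictly increase
  f <- 10000^(-2 * (0:3) / 8)
  expect_equal(P[2, 2 * (0:3) + 1], sin(2 * f))
  expect_true(all(diff(2 * pi / f) > 0))
  expect_error(positional_encoding(10, 7), "even")
})

test_that("input encoding scales embeddings then adds positions", {
  P <- positional_encoding(4, 6)
  S0 <- matrix(0, 4, 6)
  expect_equal(input_encoding(S0, P), P)
  S <- matrix(rnorm(24), 4, 6)
  E <- input_encoding(S, P)
  expect_equal(E - P, S * sqrt(6))
  expect_error(input_encoding(S[, 1:4], P), "mismatch")
})

test_that("attention reduces to convex combinations of values", {
  withr::with_seed(1, {
    V <- matrix(rnorm(4), 1, 4)
    Q <- matrix(rnorm(3), 1, 3)
    expect_equal(attention(Q, Q, V), V)  # n = 1: softmax of a scalar is 1

    # constant values: output equals that constant row regardless of Q, K
    Q <- matrix(rnorm(15), 5, 3)
    K <- matrix(rnorm(15), 5, 3)
    Vc <- matrix(rep(c(1, -2, 0.5), each = 5), 5, 3)
    out <- attention(Q, K, Vc)
    expect_equal(out, Vc, tolerance = 1e-12)
  })
  expect_error(attention(matrix(1), matrix(1), matrix(1),
                         mask = FALSE), "masked")
})

test_that("attention equals the brute-force per-element oracle", {
  withr::with_seed(2, {
    for (i in 1:100) {
      n <- sample(2:8, 1); dk <- sample(2:16, 1); dv <- sample(2:16, 1)
      Q <- matrix(rnorm(n * dk), n); K <- matrix(rnorm(n * dk), n)
      V <- matrix(rnorm(n * dv), n)
      mask <- if (i %% 3 == 0) {
        m <- runif(n) > 0.3
        if (!any(m)) m[1] <- TRUE
        m
      } else NULL
      expect_equal(attention(Q, K, V, mask), attention_oracle(Q, K, V, mask),
                   tolerance = 1e-6)
    }
  })
})

test_that("multi-head attention collapses to a single head with identity output", {
  withr::with_seed(3, {
    E <- matrix(rnorm(5 * 4), 5, 4)
    Wq <- matrix(rnorm(16), 4); Wk <- matrix(rnorm(16), 4)
    Wv <- matrix(rnorm(16), 4)
    params <- list(heads = list(list(Wq = Wq, Wk = Wk, Wv = Wv)),
                   Wo = diag(4))
    expect_equal(multi_head(E, params),
                 attention(E %*% Wq, E %*% Wk, E %*% Wv))
  })
})

test_that("trainable parameter count is invariant in the number of heads", {
  sc <- token_scheme("vocab", k = 3, seed = 1)
  counts <- vapply(c(1L, 2L, 4L, 8L), function(h)
    n_params(tiny_model(sc, d_model = 64L, d_ff = 256L, h = h)), numeric(1))
  expect_identical(counts, rep(counts[1], 4))
})

test_that("multi-head attention is permutation-equivariant", {
  withr::with_seed(4, {
    d <- 8; n <- 6; h <- 2
    E <- matrix(rnorm(n * d), n, d)
    params <- list(heads = lapply(1:h, function(j)
      list(Wq = matrix(rnorm(d * d / h), d),
           Wk = matrix(rnorm(d * d / h), d),
           Wv = matrix(rnorm(d * d / h), d))),
      Wo = matrix(rnorm(d * d), d))
    perm <- sample(n)
    expect_equal(multi_head(E[perm, ], params), multi_head(E, params)[perm, ],
                 tolerance = 1e-10)
  })
})

test_that("encoder blocks preserve shape and layer norm standardizes rows", {
  withr::with_seed(5, {
    X <- matrix(rnorm(20, sd = 4), 4, 5)
    N <- layer_norm(X)
    expect_equal(rowMeans(N), rep(0, 4), tolerance = 1e-8)
    expect_equal(apply(N, 1, function(r) mean(r^2)), rep(1, 4),
                 tolerance = 1e-3)  # eps-deflated unit variance

    m <- tiny_model(d_model = 8L, n_blocks = 4L)  # 4 blocks accepted
    ts <- encode_read(c(r = rand_dna(20)), m$scheme)
    out <- readformer:::model_pass(m, pad_batch(list(ts)))
    expect_equal(dim(out$scores[[1]]), c(1, 3))
  })
})

test_that("sequence reduction honours masks and modes", {
  withr::with_seed(6, {
    O <- matrix(rnorm(24), 6, 4)
    same <- matrix(rep(O[1, ], each = 6), 6, 4)
    expect_equal(reduce_sequence(same, "mean"), O[1, ])
    expect_equal(reduce_sequence(O, "cls"), O[1, ])

    mask <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE)
    base <- reduce_sequence(O, "mean", mask)
    O2 <- O
    O2[!mask, ] <- 999  # perturb masked rows: mean unchanged
    expect_equal(reduce_sequence(O2, "mean", mask), base)

    W_red <- matrix(rnorm(24 * 4), 24, 4)
    expect_equal(reduce_sequence(O, "concat", W_red = W_red),
                 as.vector(c(t(O)) %*% W_red))
    expect_error(reduce_sequence(O[1:3, ], "concat", W_red = W_red), "fixed")
  })
})

test_that("linear classification and multi-level heads follow their definitions", {
  withr::with_seed(7, {
    x <- rnorm(6)
    expect_equal(classify_linear(x, list(W = matrix(0, 6, 4), b = rep(2, 4))),
                 rep(2, 4))
    h1 <- list(W = matrix(rnorm(18), 6, 3), b = rnorm(3))
    h2 <- list(W = matrix(rnorm(24), 6, 4), b = rnorm(4))
    T1 <- matrix(rnorm(12), 4, 3)

    # zero transforms reproduce independent heads exactly
    y0 <- multilevel_forward(x, list(h1, h2), list(matrix(0, 4, 3)))
    expect_identical(y0[[1]], classify_linear(x, h1))
    expect_identical(y0[[2]], classify_linear(x, h2))

    # one level is plain classification
    expect_identical(multilevel_forward(x, list(h1))[[1]],
                     classify_linear(x, h1))

    # a non-zero transform propagates coarse scores into the fine level
    y <- multilevel_forward(x, list(h1, h2), list(T1))
    expect_equal(y[[2]], classify_linear(x, h2) + as.vector(T1 %*% y[[1]]))
    expect_false(isTRUE(all.equal(y[[2]], y0[[2]])))
    expect_error(multilevel_forward(x, list(h1, h2),
                                    list(matrix(0, 2, 2))), "incompatible")
  })
})

test_that("the C++ fast path matches the composed R reference", {
  withr::with_seed(8, {
    grids <- list(
      list(scheme = token_scheme("vocab", k = 3, seed = 1), red = "mean",
           nb = 2L, h = 2L),
      list(scheme = token_scheme("char", seed = 2, with_cls = TRUE),
           red = "cls", nb = 1L, h = 4L),
      list(scheme = token_scheme("lsh", k = 5, b = 128, seed = 3),
           red = "mean", nb = 3L, h = 1L))
    for (g in grids) {
      m <- tiny_model(g$scheme, levels = list(genus = c("a", "b"),
                                              species = c("x", "y", "z")),
                      d_model = 8L, n_blocks = g$nb, h = g$h,
                      reduction = g$red, seed = 11L)
      ts <- encode_read(c(r = rand_dna(17)), g$scheme)
      cpp <- readformer:::model_pass(m, pad_batch(list(ts)))$scores
      ref <- ref_forward(m, ts)
      for (l in 1:2)
        expect_equal(as.vector(cpp[[l]]), ref[[l]], tolerance = 1e-10)
    }
  })
})

test_that("padded positions do not leak into unmasked outputs", {
  withr::with_seed(9, {
    sc <- token_scheme("vocab", k = 3, seed = 1)
    m <- tiny_model(sc)
    ts <- encode_read(c(r = rand_dna(15)), sc)
    alone <- readformer:::model_pass(m, pad_batch(list(ts)))$scores[[1]]
    longer <- encode_read(c(r = rand_dna(30)), sc)
    both <- readformer:::model_pass(m, pad_batch(list(ts, longer)))$scores[[1]]
    expect_lt(max(abs(alone[1, ] - both[1, ])), 1e-6)
  })
})

test_that("forward passes are deterministic and survive checkpoint round-trips", {
  sc <- token_scheme("hash", k = 4, b = 64, q = 3, seed = 2)
  m <- tiny_model(sc, levels = list(species = c("x", "y")))
  reads <- vapply(1:5, function(i) rand_dna(12, seed = i), character(1))
  s1 <- predict_scores(m, reads)
  s2 <- predict_scores(m, reads)
  expect_identical(s1, s2)

  dir <- withr::local_tempdir()
  save_model(m, dir)
  m2 <- load_model(dir)
  expect_identical(predict_scores(m2, reads), s1)
})

test_that("invalid configurations are rejected at build time", {
  expect_error(encoder_config(d_model = 30, h = 4), "divisible")
  sc <- token_scheme("vocab", k = 3, seed = 1, with_cls = FALSE)
  expect_error(init_model(encoder_config(d_model = 8, h = 2,
                                         reduction = "cls"),
                          sc, list(species = c("a", "b"))), "with_cls")
})
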