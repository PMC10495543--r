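# Loss functions, class weights, and the Adam training loop with early
# stopping, determinism and the sparse-gradient contract.

test_that("class weights are mean-1 normalized inverse counts", {
  expect_equal(class_weights(c(10, 10, 10)), rep(1, 3))
  expect_equal(class_weights(c(100, 50)), c(2 / 3, 4 / 3))
  expect_equal(class_weights(c(100, 50)), class_weights(c(200, 100)))
  expect_error(class_weights(c(5, 0)), "zero count")
  withr::with_seed(1, {
    cnt <- sample(1:1000, 20)
    w <- class_weights(cnt)
    expect_equal(mean(w), 1)
    expect_true(all(w > 0))
    # weighted count mass identity under mean-1 normalization
    expect_equal(sum(w * cnt), length(cnt) * length(cnt) / sum(1 / cnt))
  })
})

test_that("cross-entropy matches closed forms and a naive implementation", {
  expect_equal(ce_loss(rep(0.7, 5), 3), log(5))
  expect_lt(ce_loss(c(100, 0, 0), 1), 1e-10)
  withr::with_seed(2, {
    for (i in 1:50) {
      s <- rnorm(sample(2:10, 1), sd = 3)
      y <- sample(length(s), 1)
      naive <- -log(exp(s[y]) / sum(exp(s)))
      expect_equal(ce_loss(s, y), naive, tolerance = 1e-8)
    }
  })
})

test_that("multi-level loss is the weighted sum of per-level losses", {
  withr::with_seed(3, {
    s1 <- rnorm(3); s2 <- rnorm(5)
    expect_equal(multilevel_loss(list(s1), 2), ce_loss(s1, 2))
    expect_equal(multilevel_loss(list(s1, s2), c(1, 4)),
                 ce_loss(s1, 1) + ce_loss(s2, 4))
    w <- list(c(2, 1, 1), rep(1, 5))
    expect_equal(multilevel_loss(list(s1, s2), c(1, 4), w),
                 2 * ce_loss(s1, 1) + ce_loss(s2, 4))
    expect_error(multilevel_loss(list(s1), c(1, 2)), "mismatch")
  })
})

test_that("loss at initialization is near log(m) and one step reduces it", {
  sc <- token_scheme("vocab", k = 3, seed = 1)
  m <- tiny_model(sc, levels = list(species = paste0("s", 1:6)))
  reads <- tibble::tibble(id = paste0("r", 1:16),
                          sequence = vapply(1:16, function(i)
                            rand_dna(20, seed = i), character(1)),
                          species_id = rep(paste0("s", 1:4), 4))
  batch <- readformer:::tokenize_batch(reads, sc)
  labels <- readformer:::encode_labels(reads, m$levels)
  out <- readformer:::model_pass(m, batch, labels, want_grad = TRUE)
  expect_lt(abs(out$loss - log(6)) / log(6), 0.10)

  st0 <- lapply(m$params, function(x) array(0, dim = dim(x)))
  upd <- readformer:::cpp_adam_step(m$params, out$grads, st0, st0, 1L,
                                    1e-3, 0.9, 0.999, 1e-8, NULL)
  m2 <- m
  m2$params <- upd$params
  out2 <- readformer:::model_pass(m2, batch, labels)
  expect_lt(out2$loss, out$loss)
})

test_that("training is deterministic and the fit tracks its best checkpoint", {
  set <- toy_read_set()
  run <- function() {
    m <- tiny_model(token_scheme("vocab", k = 4, seed = 2),
                    levels = list(species = sort(unique(set$reads$species_id))),
                    n_max = 64L)
    suppressMessages(train_model(m, set$reads, set$reads,
      train_config(learning_rate = 3e-3, batch_size = 16L, max_steps = 30L,
                   patience = 25L, val_interval = 10L, seed = 5,
                   shuffle_buffer = 64L)))
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  expect_equal(f1$best_val_loss, min(f1$history$val_loss))
  # best loss column is the running minimum: non-increasing over history
  expect_true(all(diff(cummin(f1$history$val_loss)) <= 0))
})

test_that("early stopping fires when validation stops improving", {
  set <- toy_read_set()
  # validation labels deliberately scrambled: fitting the training data
  # cannot keep improving a mislabelled validation set
  bad_val <- set$reads
  bad_val$species_id <- withr::with_seed(6, sample(bad_val$species_id))
  m <- tiny_model(token_scheme("vocab", k = 4, seed = 2),
                  levels = list(species = sort(unique(set$reads$species_id))),
                  n_max = 64L)
  fit <- suppressMessages(
    train_model(m, set$reads, bad_val,
      train_config(learning_rate = 5e-3, batch_size = 16L,
                   max_steps = 400L, patience = 30L, val_interval = 10L,
                   seed = 7, shuffle_buffer = 64L)))
  expect_lt(fit$steps, 400L)
})

test_that("sparse embedding updates stay close to dense updates", {
  set <- toy_read_set()
  lv <- list(species = sort(unique(set$reads$species_id)))
  run <- function(sparse) {
    m <- tiny_model(token_scheme("vocab", k = 3, seed = 2), levels = lv,
                    n_max = 64L)
    suppressMessages(train_model(m, set$reads, set$reads,
      train_config(learning_rate = 3e-3, batch_size = 16L, max_steps = 60L,
                   patience = 50L, val_interval = 20L, seed = 8,
                   shuffle_buffer = 64L, sparse_embedding = sparse)))
  }
  dense <- run(FALSE)
  sparse <- run(TRUE)
  expect_lt(abs(sparse$best_val_loss - dense$best_val_loss) /
              dense$best_val_loss, 0.05)
})

test_that("reduced-precision training stays close to full precision", {
  set <- toy_read_set()
  lv <- list(species = sort(unique(set$reads$species_id)))
  run <- function(rp) {
    cfg <- encoder_config(d_model = 8L, n_blocks = 1L, d_ff = 16L, h = 2L,
                          n_max = 64L, reduced_precision = rp)
    m <- init_model(cfg, token_scheme("vocab", k = 3, seed = 2), lv,
                    seed = 7L)
    suppressMessages(train_model(m, set$reads, set$reads,
      train_config(learning_rate = 3e-3, batch_size = 16L, max_steps = 60L,
                   patience = 50L, val_interval = 20L, seed = 9,
                   shuffle_buffer = 64L)))
  }
  full <- run(FALSE)
  half <- run(TRUE)
  expect_lt(abs(half$best_val_loss - full$best_val_loss) /
              full$best_val_loss, 0.05)
})

test_that("the encoder learns order information a bag-of-tokens model cannot", {
  # two classes with identical base composition that differ only in the
  # order of two fixed motifs: any classifier on token counts alone is at
  # chance, while the positional encoding lets the encoder separate them
  withr::with_seed(10, {
    X <- rand_dna(20)
    Y <- rand_dna(20)
    mk <- function(cls, n) {
      core <- if (cls == "AB") paste0(X, Y) else paste0(Y, X)
      tibble::tibble(id = paste0(cls, seq_len(n)), sequence = core,
                     species_id = cls)
    }
    reads <- dplyr::bind_rows(mk("AB", 40), mk("BA", 40))
    reads <- reads[sample(nrow(reads)), ]
  })
  # identical character composition: bag-of-characters carries no signal
  count_chars <- function(s) table(strsplit(s, "")[[1]])
  expect_identical(count_chars(reads$sequence[reads$species_id == "AB"][1]),
                   count_chars(reads$sequence[reads$species_id == "BA"][1]))

  sc <- token_scheme("char", seed = 3)
  m <- tiny_model(sc, levels = list(species = c("AB", "BA")), d_model = 16L,
                  n_max = 48L)
  fit <- suppressMessages(train_model(m, reads, reads,
    train_config(learning_rate = 3e-3, batch_size = 16L, max_steps = 120L,
                 patience = 100L, val_interval = 40L, seed = 11,
                 shuffle_buffer = 80L)))
  acc <- utils::tail(fit$history$val_recall_species, 1)
  expect_gte(acc, 0.99)
})

test_that("degenerate training inputs raise errors", {
  m <- tiny_model()
  empty <- tibble::tibble(id = character(0), sequence = character(0),
                          species_id = character(0))
  expect_error(train_model(m, empty, empty, train_config(max_steps = 10,
                                                         patience = 5)),
               "empty")
  expect_error(train_config(patience = 100, max_steps = 50), "patience")
})
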