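# Training: class weights, cross-entropy losses, and the Adam training loop
# with streaming batches, validation tracking and early stopping.

#' Normalized inverse-count class weights
#'
#' `w_j = (1 / count_j) * C / sum_l(1 / count_l)` for C classes, i.e.
#' weights proportional to inverse class counts, normalized to mean 1 so the
#' weighted loss keeps the scale of the unweighted one.
#'
#' @param counts Positive integer vector of per-class training read counts
#'   (optionally named).
#' @return Numeric weight vector (mean exactly 1).
#' @export
class_weights <- function(counts) {
  if (any(counts <= 0))
    stop("all classes must appear in the training data (zero count found)",
         call. = FALSE)
  inv <- 1 / counts
  w <- inv * length(counts) / sum(inv)
  names(w) <- names(counts)
  w
}

#' Cross-entropy loss of unnormalized scores
#'
#' `-log softmax(scores)[label]`, computed with the log-sum-exp trick.
#'
#' @param scores Numeric vector of unnormalized class scores.
#' @param label 1-based index of the true class.
#' @return Scalar loss.
#' @export
ce_loss <- function(scores, label) {
  m <- max(scores)
  lse <- m + log(sum(exp(scores - m)))
  lse - scores[label]
}

#' Class-weighted multi-level cross-entropy
#'
#' `sum_i w_{i, y_i} * CE_i(scores_i, y_i)` over taxonomic levels; with all
#' weights 1 this is the plain sum of per-level losses.
#'
#' @param scores List of score vectors, one per level (coarse to fine).
#' @param labels Integer vector of 1-based true class indices per level.
#' @param weights Optional list of per-class weight vectors per level.
#' @return Scalar loss.
#' @export
multilevel_loss <- function(scores, labels, weights = NULL) {
  if (length(scores) != length(labels))
    stop("level count mismatch between scores and labels", call. = FALSE)
  tot <- 0
  for (i in seq_along(scores)) {
    w <- if (is.null(weights)) 1 else weights[[i]][labels[i]]
    tot <- tot + w * ce_loss(scores[[i]], labels[i])
  }
  tot
}

#' Training configuration
#'
#' Reference defaults follow the training protocol of the underlying method
#' (Adam, learning rate 0.01, batch 2048, early stopping after 50,000
#' non-improving steps); desk-scale runs use smaller values.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Reads per optimization step.
#' @param max_steps Maximum optimization steps.
#' @param patience Stop when the validation loss has not improved for this
#'   many steps (must be < `max_steps`).
#' @param val_interval Steps between validation evaluations.
#' @param seed Seed driving shuffling, dropout and any other randomness.
#' @param shuffle_buffer Buffer size for the streaming batch shuffle.
#' @param sparse_embedding Update only embedding rows touched by the batch
#'   (SparseAdam semantics).
#' @param use_class_weights Apply inverse-count class weights.  Single-level
#'   training defaults to unweighted loss (balance is established at the
#'   dataset level by coverage-balanced read generation); multi-level
#'   training always weights, since one read set cannot be balanced at every
#'   level simultaneously.
#' @param val_max_reads Cap on validation reads used per evaluation.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 0.01, batch_size = 2048L,
                         max_steps = 300000L, patience = 50000L,
                         val_interval = 1000L, seed = 1L,
                         shuffle_buffer = 10000L, sparse_embedding = FALSE,
                         use_class_weights = NULL, val_max_reads = 4096L) {
  if (patience >= max_steps)
    stop("patience must be smaller than max_steps", call. = FALSE)
  if (learning_rate <= 0 || batch_size < 1 || val_interval < 1)
    stop("invalid training configuration", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_steps = as.integer(max_steps),
                 patience = as.integer(patience),
                 val_interval = as.integer(val_interval),
                 seed = as.integer(seed),
                 shuffle_buffer = as.integer(shuffle_buffer),
                 sparse_embedding = isTRUE(sparse_embedding),
                 use_class_weights = use_class_weights,
                 val_max_reads = as.integer(val_max_reads)),
            class = "train_config")
}

# Map label columns of a read tibble to 1-based indices per level.
encode_labels <- function(data, levels) {
  lapply(names(levels), function(lv) {
    col <- paste0(lv, "_id")
    if (!col %in% names(data))
      stop("missing label column '", col, "'", call. = FALSE)
    idx <- match(data[[col]], levels[[lv]])
    if (anyNA(idx))
      stop("labels outside the model's class list at level '", lv, "'",
           call. = FALSE)
    as.integer(idx)
  })
}

# Tokenize a batch tibble into a padded_batch (uniform read length fast path).
tokenize_batch <- function(data, scheme, with_cls = scheme$with_cls) {
  enc <- encode_batch(data$sequence, scheme, with_cls, ids = data$id)
  if (scheme$scheme == "hash") {
    streams <- lapply(seq_along(enc), function(i)
      structure(list(ids = enc[[i]]$imp, components = enc[[i]]$comp),
                class = "token_stream"))
    pad_batch(streams)
  } else {
    pad_batch(enc)
  }
}

make_dropmasks <- function(model, B, n) {
  p <- model$config$dropout
  if (p <= 0) return(list())
  d <- model$config$d_model
  keep <- function() matrix((runif(B * n * d) >= p) / (1 - p), B * n, d)
  dm <- list(inp = keep())
  for (i in seq_len(model$config$n_blocks)) {
    dm[[paste0("att", i)]] <- keep()
    dm[[paste0("mlp", i)]] <- keep()
  }
  dm
}

# Validation pass: loss plus per-level accuracy (threshold-0 classification,
# where read-level precision and recall coincide).
validate_model <- function(model, val_batches, weights) {
  tot_loss <- 0
  n <- 0
  L <- length(model$levels)
  correct <- numeric(L)
  for (vb in val_batches) {
    out <- model_pass(model, vb$batch, vb$labels, weights, want_grad = FALSE)
    B <- nrow(vb$batch$ids)
    tot_loss <- tot_loss + out$loss * B
    n <- n + B
    for (l in seq_len(L)) {
      pred <- max.col(out$scores[[l]], ties.method = "first")
      correct[l] <- correct[l] + sum(pred == vb$labels[[l]])
    }
  }
  list(loss = tot_loss / n, accuracy = correct / n)
}

#' Train a read classification model
#'
#' Streams shuffled batches over the training reads, optimizes the
#' cross-entropy (class-weighted for multi-level models) with Adam, tracks
#' the validation loss every `val_interval` steps, and stops early when the
#' validation loss has not improved for `patience` steps.  The returned fit
#' carries the parameters of the best validation checkpoint, not the last.
#'
#' @param model A [init_model()] model.
#' @param train,val Tibbles of labelled reads: columns `id`, `sequence`, and
#'   `<level>_id` for every model level (e.g. `genus_id`, `species_id`).
#' @param config A [train_config()].
#' @return An object of class `readformer_fit`: fields `model` (best
#'   checkpoint), `history` (tibble of step, train/validation loss and
#'   per-level validation accuracy), `best_step`, `best_val_loss`.
#' @export
train_model <- function(model, train, val, config = train_config()) {
  stopifnot(inherits(model, "readformer_model"),
            inherits(config, "train_config"))
  if (nrow(train) == 0 || nrow(val) == 0)
    stop("empty training or validation stream", call. = FALSE)
  L <- length(model$levels)

  # class weights (Eq.-style normalized inverse counts)
  use_w <- config$use_class_weights %||% (L > 1)
  weights <- list()
  if (use_w) {
    labs <- encode_labels(train, model$levels)
    weights <- lapply(seq_len(L), function(l) {
      cnt <- tabulate(labs[[l]], nbins = length(model$levels[[l]]))
      unname(class_weights(cnt))
    })
  }

  # pre-tokenized validation batches
  val_use <- head(val, config$val_max_reads)
  val_batches <- lapply(split(seq_len(nrow(val_use)),
                              ceiling(seq_len(nrow(val_use)) / 512)),
                        function(ix) {
                          d <- val_use[ix, ]
                          list(batch = tokenize_batch(d, model$scheme),
                               labels = encode_labels(d, model$levels))
                        })

  # Adam state
  m_state <- lapply(model$params, function(x) array(0, dim = dim(x)))
  v_state <- lapply(model$params, function(x) array(0, dim = dim(x)))
  sparse_names <- intersect(c("emb", "pool", "impw"), names(model$params))

  step <- 0L
  epoch <- 0L
  best_loss <- Inf
  best_step <- 0L
  best_params <- model$params
  hist <- list()
  batches <- NULL
  t0 <- Sys.time()

  repeat {
    if (is.null(batches)) {
      epoch <- epoch + 1L
      batches <- stream_batches(as_read_stream(train, 4096L),
                                config$batch_size,
                                shuffle_buffer = min(config$shuffle_buffer,
                                                     nrow(train)),
                                seed = derive_seed(config$seed,
                                                   paste0("epoch", epoch)))
    }
    data <- batches()
    if (is.null(data)) { batches <- NULL; next }
    step <- step + 1L

    batch <- tokenize_batch(data, model$scheme)
    labels <- encode_labels(data, model$levels)
    dm <- if (model$config$dropout > 0) {
      with_seed(derive_seed(config$seed, paste0("drop", step)),
                make_dropmasks(model, nrow(batch$ids), ncol(batch$ids)))
    } else list()

    out <- model_pass(model, batch, labels, weights, want_grad = TRUE,
                      dropmasks = dm)
    if (!is.finite(out$loss))
      stop("non-finite training loss at step ", step, " (first read id '",
           data$id[1], "'): try a lower learning rate", call. = FALSE)

    sparse <- NULL
    if (config$sparse_embedding && length(sparse_names) > 0)
      sparse <- out$touched[sparse_names]
    upd <- cpp_adam_step(model$params, out$grads, m_state, v_state, step,
                         config$learning_rate, 0.9, 0.999, 1e-8, sparse)
    model$params <- upd$params
    m_state <- upd$m
    v_state <- upd$v

    if (step %% config$val_interval == 0 || step >= config$max_steps) {
      vv <- validate_model(model, val_batches, weights)
      row <- tibble::tibble(step = step, epoch = epoch,
                            train_loss = out$loss, val_loss = vv$loss)
      for (l in seq_len(L)) {
        row[[paste0("val_precision_", names(model$levels)[l])]] <- vv$accuracy[l]
        row[[paste0("val_recall_", names(model$levels)[l])]] <- vv$accuracy[l]
      }
      hist[[length(hist) + 1L]] <- row
      rf_log("INFO", "step ", step, " train_loss ", signif(out$loss, 4),
             " val_loss ", signif(vv$loss, 4), " val_acc ",
             paste(signif(vv$accuracy, 4), collapse = "/"))
      if (vv$loss < best_loss) {
        best_loss <- vv$loss
        best_step <- step
        best_params <- model$params
      }
    }
    if (step >= config$max_steps) break
    if (step - best_step > config$patience && best_step > 0) {
      rf_log("INFO", "early stopping at step ", step,
             " (no improvement since step ", best_step, ")")
      break
    }
  }

  model$params <- best_params
  structure(list(model = model,
                 history = dplyr::bind_rows(hist),
                 best_step = best_step, best_val_loss = best_loss,
                 steps = step,
                 wall_time = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                 train_config = config),
            class = "readformer_fit")
}

#' @export
print.readformer_fit <- function(x, ...) {
  cat("readformer fit:", x$steps, "steps, best validation loss",
      signif(x$best_val_loss, 5), "at step", x$best_step, "\n")
  invisible(x)
}
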