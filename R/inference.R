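# Inference: read classification (single or paired-end), confidence
# thresholding, and per-sample abundance profiles.

softmax_rows <- function(S) {
  mx <- apply(S, 1, max)
  E <- exp(S - mx)
  E / rowSums(E)
}

#' Raw classification scores for a set of reads
#'
#' @param model A `readformer_model` or `readformer_fit`.
#' @param sequences Character vector of read sequences.
#' @param batch_size Reads per forward batch.
#' @return A list with one unnormalized score matrix
#'   (`length(sequences) x M_level`) per taxonomic level.
#' @export
predict_scores <- function(model, sequences, batch_size = 256L) {
  if (inherits(model, "readformer_fit")) model <- model$model
  L <- length(model$levels)
  out <- lapply(seq_len(L), function(l)
    matrix(NA_real_, length(sequences), length(model$levels[[l]])))
  for (ix in split(seq_along(sequences),
                   ceiling(seq_along(sequences) / batch_size))) {
    batch <- tokenize_batch(tibble::tibble(id = as.character(ix),
                                           sequence = sequences[ix]),
                            model$scheme)
    sc <- model_pass(model, batch)$scores
    for (l in seq_len(L)) out[[l]][ix, ] <- sc[[l]]
  }
  names(out) <- names(model$levels)
  out
}

#' Classify a read pair
#'
#' The model scores each mate separately; the two score vectors are averaged
#' component-wise *before* the softmax (averaging probabilities instead can
#' change the ranking).
#'
#' @param model A `readformer_model` or `readformer_fit`.
#' @param r1,r2 Character vectors of mate-1 / mate-2 sequences.
#' @return A list with one probability matrix per level (rows sum to 1).
#' @export
predict_paired <- function(model, r1, r2) {
  if (inherits(model, "readformer_fit")) model <- model$model
  stopifnot(length(r1) == length(r2))
  s1 <- predict_scores(model, r1)
  s2 <- predict_scores(model, r2)
  out <- lapply(seq_along(s1), function(l) softmax_rows((s1[[l]] + s2[[l]]) / 2))
  names(out) <- names(s1)
  out
}

#' Classify reads with a confidence threshold
#'
#' Single-end reads are scored individually; when a `mate` column is present,
#' mates are grouped into fragments by their shared id (trailing `/1` / `/2`
#' stripped), scores are averaged component-wise before the softmax, and one
#' prediction per fragment is emitted.  A read (or fragment) is called at the
#' argmax class when the top softmax probability reaches `threshold`, else
#' reported as `"unclassified"`; multi-level models threshold each level
#' independently.  Mates shorter than the scheme's k are skipped with a
#' warning; a fragment with no usable mate is unclassified.
#'
#' @param model A `readformer_model` or `readformer_fit`.
#' @param reads Tibble with `id`, `sequence` and optionally `mate`.
#' @param threshold Confidence threshold in `[0, 1)` (default 0.5).
#' @param batch_size Reads per forward batch.
#' @return A tibble of class `read_predictions`: `read_id`, `level`,
#'   `class_id`, `confidence`.
#' @export
classify_reads <- function(model, reads, threshold = 0.5, batch_size = 256L) {
  if (inherits(model, "readformer_fit")) model <- model$model
  if (threshold < 0 || threshold >= 1)
    stop("threshold must be in [0, 1)", call. = FALSE)
  scheme <- model$scheme
  min_len <- if (scheme$scheme == "char") 1L else scheme$k
  paired <- "mate" %in% names(reads) && !all(is.na(reads$mate))

  usable <- nchar(reads$sequence) >= min_len
  if (any(!usable))
    rf_log("WARN", sum(!usable), " reads shorter than k = ", min_len,
           " skipped")

  key <- if (paired) pair_key(reads$id) else reads$id
  frag_ids <- unique(key)
  L <- length(model$levels)

  # score usable reads, then average within fragments (pre-softmax)
  scores <- vector("list", L)
  su <- predict_scores(model, reads$sequence[usable], batch_size)
  for (l in seq_len(L)) {
    M <- length(model$levels[[l]])
    acc <- matrix(0, length(frag_ids), M)
    cnt <- numeric(length(frag_ids))
    fi <- match(key[usable], frag_ids)
    for (j in seq_along(fi)) {
      acc[fi[j], ] <- acc[fi[j], ] + su[[l]][j, ]
      cnt[fi[j]] <- cnt[fi[j]] + 1
    }
    ok <- cnt > 0
    acc[ok, ] <- acc[ok, , drop = FALSE] / cnt[ok]
    scores[[l]] <- list(s = acc, ok = ok)
  }

  out <- lapply(seq_len(L), function(l) {
    s <- scores[[l]]$s
    ok <- scores[[l]]$ok
    cls <- rep("unclassified", length(frag_ids))
    conf <- rep(NA_real_, length(frag_ids))
    if (any(ok)) {
      p <- softmax_rows(s[ok, , drop = FALSE])
      top <- max.col(p, ties.method = "first")
      conf[ok] <- p[cbind(seq_len(nrow(p)), top)]
      called <- conf[ok] >= threshold
      cls[ok][called] <- model$levels[[l]][top[called]]
    }
    tibble::tibble(read_id = frag_ids, level = names(model$levels)[l],
                   class_id = cls, confidence = conf)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("read_predictions", class(out))
  out
}

#' Abundance profile from read predictions
#'
#' Per-class read fractions over the classified reads at each level;
#' unclassified reads are excluded from the normalization but reported in the
#' attributes.
#'
#' @param predictions A `read_predictions` tibble (see [classify_reads()]).
#' @param classes Optional named list (level -> class ids) forcing the class
#'   universe, so absent classes appear with fraction 0.
#' @return A tibble of class `abundance_profile`: `level`, `class_id`,
#'   `read_count`, `fraction`, with attributes `total_reads` and a per-level
#'   `classified` count.  With no classified reads at a level, fractions are
#'   all 0 and the level is flagged in attribute `empty_levels`.
#' @export
abundance_profile <- function(predictions, classes = NULL) {
  lvls <- unique(predictions$level)
  total <- length(unique(predictions$read_id))
  rows <- list()
  classified <- setNames(numeric(length(lvls)), lvls)
  empty <- character(0)
  for (lv in lvls) {
    p <- predictions[predictions$level == lv, ]
    cl <- p$class_id[p$class_id != "unclassified"]
    classified[lv] <- length(cl)
    universe <- if (!is.null(classes)) classes[[lv]] else sort(unique(cl))
    cnt <- table(factor(cl, levels = universe))
    frac <- if (length(cl) > 0) as.numeric(cnt) / length(cl)
            else rep(0, length(universe))
    if (length(cl) == 0) empty <- c(empty, lv)
    rows[[lv]] <- tibble::tibble(level = lv, class_id = universe,
                                 read_count = as.integer(cnt),
                                 fraction = frac)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "total_reads") <- total
  attr(out, "classified") <- classified
  attr(out, "empty_levels") <- empty
  if (length(empty) > 0)
    rf_log("WARN", "no classified reads at level(s): ",
           paste(empty, collapse = ", "))
  class(out) <- c("abundance_profile", class(out))
  out
}
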