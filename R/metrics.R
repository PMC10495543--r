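# Evaluation: read-level precision/recall with per-class breakdowns, and the
# L2 distance between abundance profiles.

# Truth in wide manifest form (read_id, genus_id, species_id, ...) -> long.
truth_long <- function(truth, levels) {
  cols <- paste0(levels, "_id")
  missing <- setdiff(cols, names(truth))
  if (length(missing) > 0)
    stop("truth manifest lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- lapply(seq_along(levels), function(i)
    tibble::tibble(read_id = pair_key(truth[["read_id"]] %||% truth[["id"]]),
                   level = levels[i], truth_id = truth[[cols[i]]]))
  dplyr::distinct(dplyr::bind_rows(out))
}

#' Read-level precision and recall
#'
#' Precision = correctly classified / classified; recall = correctly
#' classified / total reads.  Unclassified reads therefore count only in the
#' recall denominator, which makes recall <= precision whenever anything is
#' classified.  Precision with zero classified reads is reported as `NA`.
#' Per-class metrics apply the same counting restricted to each truth class
#' (one-vs-rest).
#'
#' @param predictions A `read_predictions` tibble (see [classify_reads()]).
#' @param truth Ground-truth manifest: tibble with `read_id` (or `id`) and
#'   one `<level>_id` column per predicted level; mate suffixes (`/1`, `/2`)
#'   are stripped, so paired predictions match per-fragment truth.
#' @return An object of class `metrics_report`: list with `overall` (tibble:
#'   level, n_reads, n_classified, n_correct, precision, recall) and
#'   `per_class` (the same per truth class).
#' @export
precision_recall <- function(predictions, truth) {
  lvls <- unique(predictions$level)
  tl <- truth_long(truth, lvls)
  unknown <- setdiff(unique(predictions$read_id), unique(tl$read_id))
  if (length(unknown) > 0)
    stop("prediction for unknown read id '", unknown[1], "'", call. = FALSE)

  j <- dplyr::left_join(tl, predictions, by = c("read_id", "level"))
  j$class_id[is.na(j$class_id)] <- "unclassified"
  j$classified <- j$class_id != "unclassified"
  j$correct <- j$classified & j$class_id == j$truth_id

  overall <- j |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(n_reads = dplyr::n(),
                     n_classified = sum(.data$classified),
                     n_correct = sum(.data$correct), .groups = "drop") |>
    dplyr::mutate(
      precision = ifelse(.data$n_classified > 0,
                         .data$n_correct / .data$n_classified, NA_real_),
      recall = .data$n_correct / .data$n_reads)

  per_truth <- j |>
    dplyr::group_by(.data$level, class_id = .data$truth_id) |>
    dplyr::summarise(n_reads = dplyr::n(),
                     n_correct = sum(.data$correct), .groups = "drop")
  per_called <- j |>
    dplyr::filter(.data$classified) |>
    dplyr::group_by(.data$level, class_id = .data$class_id) |>
    dplyr::summarise(n_classified = dplyr::n(), .groups = "drop")
  per_class <- dplyr::full_join(per_truth, per_called,
                                by = c("level", "class_id")) |>
    dplyr::mutate(n_reads = dplyr::coalesce(.data$n_reads, 0L),
                  n_correct = dplyr::coalesce(.data$n_correct, 0L),
                  n_classified = dplyr::coalesce(.data$n_classified, 0L),
                  precision = ifelse(.data$n_classified > 0,
                                     .data$n_correct / .data$n_classified,
                                     NA_real_),
                  recall = ifelse(.data$n_reads > 0,
                                  .data$n_correct / .data$n_reads, NA_real_))

  structure(list(overall = overall, per_class = per_class),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Read-level classification metrics\n")
  print(x$overall)
  invisible(x)
}

profile_vector <- function(x, level = NULL) {
  if (inherits(x, "community_profile")) {
    return(setNames(x$count / sum(x$count), x$class_id))
  }
  if (inherits(x, "abundance_profile") || is.data.frame(x)) {
    if (!is.null(level) && "level" %in% names(x)) x <- x[x$level == level, ]
    if ("level" %in% names(x) && length(unique(x$level)) > 1)
      stop("profile spans several levels; pass `level = `", call. = FALSE)
    val <- if ("fraction" %in% names(x)) x$fraction
           else x$count / sum(x$count)
    setNames(val, x$class_id)
  } else {
    if (is.null(names(x))) stop("plain profiles must be named", call. = FALSE)
    x
  }
}

#' L2 distance between abundance profiles
#'
#' `sqrt(sum((a_i - b_i)^2))` over the union of the two class universes
#' (classes absent from one profile contribute 0).
#'
#' @param profile_a,profile_b Abundance profiles ([abundance_profile()] /
#'   [sample_lognormal_community()] tibbles or named fraction vectors).
#' @param level For multi-level profiles, which level to compare.
#' @return Non-negative scalar distance.
#' @export
l2_distance <- function(profile_a, profile_b, level = NULL) {
  a <- profile_vector(profile_a, level)
  b <- profile_vector(profile_b, level)
  a <- a[names(a) != "unclassified"]
  b <- b[names(b) != "unclassified"]
  classes <- union(names(a), names(b))
  av <- setNames(rep(0, length(classes)), classes)
  bv <- av
  av[names(a)] <- a
  bv[names(b)] <- b
  sqrt(sum((av - bv)^2))
}
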