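# Binary relevance, under-sampling, and partitioning ----------------------

#' Turn a multi-label corpus into one class's binary task
#'
#' Binary relevance: a record is positive for `target_class` iff that class
#' appears in its label set, so a multi-label record is positive for each of
#' its classes.
#'
#' @param records List of [ecg_record()]s.
#' @param target_class Class name (must be in `vocabulary`).
#' @param vocabulary Permitted class names.
#' @return A `binary_task`: `target_class`, `record_ids`, `labels` (0/1),
#'   `ratio` (majority:minority, `Inf` if a class is empty), `seed` (NA
#'   until balanced).
#' @export
binarize <- function(records, target_class, vocabulary = ecg_classes()) {
  if (!target_class %in% vocabulary)
    stop_ecgfb("ecgfb_validation_error",
               "class '%s' is not in the vocabulary", target_class)
  ids <- vapply(records, function(r) r$record_id, character(1))
  y <- vapply(records, function(r) as.integer(target_class %in% r$labels),
              integer(1))
  new_binary_task(target_class, ids, y, seed = NA_integer_)
}

new_binary_task <- function(target_class, ids, y, seed) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  ratio <- if (min(n0, n1) == 0) Inf else max(n0, n1) / min(n0, n1)
  structure(list(target_class = target_class, record_ids = ids,
                 labels = as.integer(y), ratio = ratio, seed = seed),
            class = "binary_task")
}

#' @export
print.binary_task <- function(x, ...) {
  cat(sprintf("<binary_task %s: %d records (%d pos / %d neg), ratio %.2f>\n",
              x$target_class, length(x$labels), sum(x$labels == 1),
              sum(x$labels == 0), x$ratio))
  invisible(x)
}

#' Random under-sampling to a majority:minority ratio
#'
#' Keeps every minority-class record; draws `floor(ratio * minority)`
#' majority records uniformly without replacement (all of them if fewer are
#' available). The default 2:1 ratio curbs the bias a heavily imbalanced
#' binary task would induce. Output order is shuffled deterministically by
#' `seed`.
#'
#' @param task A `binary_task` with at least one record of each class.
#' @param ratio Target majority:minority ratio (default 2).
#' @param seed Integer seed; same seed, same selection.
#' @return The balanced `binary_task`.
#' @export
undersample <- function(task, ratio = 2.0, seed = 1L) {
  y <- task$labels
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop_ecgfb("ecgfb_balance_error",
               "class %s task has an empty %s class; cannot balance",
               task$target_class, if (n1 == 0) "positive" else "negative")
  minority <- if (n1 <= n0) 1L else 0L
  min_idx <- which(y == minority)
  maj_idx <- which(y != minority)
  n_keep <- min(length(maj_idx), floor(ratio * length(min_idx)))
  keep <- with_seed(seed, {
    kept_maj <- if (n_keep < length(maj_idx))
      sample(maj_idx, n_keep) else maj_idx
    sample(c(min_idx, kept_maj))  # deterministic shuffle
  })
  new_binary_task(task$target_class, task$record_ids[keep], y[keep],
                  seed = as.integer(seed))
}

#' Train/validation/test split specification
#'
#' @param fractions Numeric length-3 (train, validation, test), positive,
#'   summing to 1. Default `c(0.64, 0.16, 0.20)`.
#' @param k Folds for cross-validation (default 5).
#' @param seed Integer seed.
#' @param stratified Preserve the class ratio in each partition (default
#'   `TRUE`).
#' @return A `split_spec` object.
#' @export
split_spec <- function(fractions = c(0.64, 0.16, 0.20), k = 5, seed = 1L,
                       stratified = TRUE) {
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop_ecgfb("ecgfb_parameter_error",
               "fractions must be 3 positive numbers summing to 1")
  if (k < 2) stop_ecgfb("ecgfb_parameter_error", "k must be >= 2")
  structure(list(fractions = fractions, k = as.integer(k),
                 seed = as.integer(seed), stratified = isTRUE(stratified)),
            class = "split_spec")
}

# Largest-remainder apportionment of n into parts proportional to fractions.
largest_remainder <- function(n, fractions) {
  ideal <- n * fractions
  sizes <- floor(ideal)
  short <- n - sum(sizes)
  if (short > 0) {
    order_rem <- order(ideal - sizes, decreasing = TRUE)
    sizes[order_rem[seq_len(short)]] <- sizes[order_rem[seq_len(short)]] + 1
  }
  as.integer(sizes)
}

#' Partition a balanced task into train/validation/test index sets
#'
#' Partition sizes follow largest-remainder rounding of the fractions
#' (total preserved). Under stratification each class is apportioned
#' separately, then single records are re-assigned (never breaking the
#' within-1 stratification bound) until the global sizes match.
#'
#' @param task A balanced `binary_task`.
#' @param spec A [split_spec()].
#' @return List with integer index vectors `train`, `validation`, `test`
#'   (disjoint, covering all records).
#' @export
split_task <- function(task, spec = split_spec()) {
  n <- length(task$labels)
  target <- largest_remainder(n, spec$fractions)
  if (any(target == 0))
    stop_ecgfb("ecgfb_split_error",
               "a partition would be empty (n = %d, fractions %s)",
               n, paste(spec$fractions, collapse = "/"))
  parts <- list(train = integer(), validation = integer(), test = integer())
  with_seed(spec$seed, {
    if (spec$stratified) {
      for (cls in unique(task$labels)) {
        idx <- sample(which(task$labels == cls))
        sz <- largest_remainder(length(idx), spec$fractions)
        cuts <- cumsum(c(0, sz))
        for (j in 1:3)
          parts[[j]] <- c(parts[[j]],
                          idx[seq_len(sz[j]) + cuts[j]])
      }
      # Per-class apportionment can drift from the global largest-remainder
      # sizes by a record or two; move single records between partitions,
      # picking the class that is most over-represented in the donor and
      # most under-represented in the receiver, so the per-class within-1
      # bound survives.
      repeat {
        sizes <- lengths(parts)
        over <- which(sizes > target)[1]
        under <- which(sizes < target)[1]
        if (is.na(over) || is.na(under)) break
        classes <- unique(task$labels)
        slack <- vapply(classes, function(cls) {
          n_cls <- sum(task$labels == cls)
          in_over <- sum(task$labels[parts[[over]]] == cls)
          in_under <- sum(task$labels[parts[[under]]] == cls)
          (in_over - n_cls * spec$fractions[over]) +
            (n_cls * spec$fractions[under] - in_under)
        }, numeric(1))
        cls <- classes[which.max(slack)]
        cand <- parts[[over]][task$labels[parts[[over]]] == cls]
        mv <- cand[length(cand)]
        parts[[over]] <- setdiff(parts[[over]], mv)
        parts[[under]] <- c(parts[[under]], mv)
      }
    } else {
      idx <- sample(n)
      cuts <- cumsum(c(0, target))
      for (j in 1:3) parts[[j]] <- idx[seq_len(target[j]) + cuts[j]]
    }
  })
  lapply(parts, sort)
}

#' k-fold cross-validation index pairs
#'
#' Stratified (per `spec$stratified`) disjoint folds whose sizes differ by
#' at most one; every record appears in exactly one validation fold.
#'
#' @param task A balanced `binary_task`.
#' @param spec A [split_spec()]; `spec$k` folds are produced.
#' @return List of `k` lists, each with `train` and `validation` index
#'   vectors.
#' @export
kfold <- function(task, spec = split_spec()) {
  n <- length(task$labels)
  k <- spec$k
  if (k > n)
    stop_ecgfb("ecgfb_parameter_error", "k = %d exceeds record count %d",
               k, n)
  if (spec$stratified && k > min(table(task$labels)))
    stop_ecgfb("ecgfb_parameter_error",
               "k = %d exceeds the minority class count %d",
               k, min(table(task$labels)))
  fold_of <- integer(n)
  with_seed(spec$seed, {
    if (spec$stratified) {
      # One global round-robin counter threaded through the classes keeps
      # fold sizes within 1 both globally and per class.
      counter <- 0L
      for (cls in unique(task$labels)) {
        idx <- sample(which(task$labels == cls))
        fold_of[idx] <- (counter + seq_along(idx) - 1L) %% k + 1L
        counter <- counter + length(idx)
      }
    } else {
      fold_of <- sample(rep_len(seq_len(k), n))
    }
  })
  lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), validation = which(fold_of == f)))
}
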