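# Evaluation measures -----------------------------------------------------

#' Confusion counts for one binary class
#'
#' @param calls 0/1 predictions.
#' @param truth 0/1 ground truth of equal length.
#' @return A `confusion_counts` list with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(calls, truth) {
  if (length(calls) != length(truth) || length(calls) < 1)
    stop_ecgfb("ecgfb_parameter_error",
               "calls (%d) and truth (%d) must have equal length >= 1",
               length(calls), length(truth))
  calls <- as.integer(calls); truth <- as.integer(truth)
  structure(list(TP = sum(calls == 1 & truth == 1),
                 FP = sum(calls == 1 & truth == 0),
                 FN = sum(calls == 0 & truth == 1),
                 TN = sum(calls == 0 & truth == 0)),
            class = "confusion_counts")
}

#' Precision, recall and F1 from confusion counts
#'
#' precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = their harmonic mean.
#' Degenerate 0/0 ratios (no predicted positives, or no true positives) are
#' defined as 0 and flagged in `degenerate`, which keeps macro averages over
#' rare classes well-defined.
#'
#' @param counts A [confusion()] result.
#' @return List with `precision`, `recall`, `f1` in \[0, 1\] and a logical
#'   `degenerate` flag.
#' @export
prf1 <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  degenerate <- (tp + fp == 0) || (tp + fn == 0)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  degenerate <- degenerate || (precision + recall == 0)
  list(precision = precision, recall = recall, f1 = f1,
       degenerate = degenerate)
}

#' ROC curve and area under it
#'
#' Sweeps the decision threshold over the unique scores (plus the
#' always-negative endpoint), producing one (false-positive-rate,
#' true-positive-rate) point per threshold; the curve starts at (0,0) and
#' ends at (1,1), and the trapezoidal area equals the
#' probability-of-correct-ranking statistic with tied scores counted half.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param truth 0/1 ground truth; both classes must be present.
#' @return List with `roc` (data.frame `fpr`, `tpr`, ordered) and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.integer(truth)
  if (length(scores) != length(truth))
    stop_ecgfb("ecgfb_parameter_error", "scores and truth length mismatch")
  n_pos <- sum(truth == 1); n_neg <- sum(truth == 0)
  if (n_pos == 0 || n_neg == 0)
    stop_ecgfb("ecgfb_undefined_auc_error",
               "AUC is undefined when truth has a single class")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  # group tied scores: each unique score is one threshold
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last_of_grp <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last_of_grp] / n_pos)
  fpr <- c(0, fp[last_of_grp] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Two-sided paired Wilcoxon signed-rank test
#'
#' Tests whether paired measurements (e.g. per-class F1 scores of two
#' preprocessing strategies) differ systematically. Zero differences are
#' dropped; |differences| are mid-ranked. For n <= `exact_max` pairs the
#' exact null distribution of the rank sum is computed by dynamic
#' programming over the (doubled, hence integer) ranks — exact even under
#' ties; above that a normal approximation with tie correction and
#' continuity correction is used. The two-sided p-value is twice the
#' smaller tail, capped at 1.
#'
#' @param f1_a,f1_b Paired numeric vectors of equal length >= 5.
#' @param exact_max Largest n for which the exact distribution is used
#'   (default 25).
#' @return List with `p_value`, `statistic` (W+, the positive-rank sum),
#'   `n` (non-zero pairs), `method`.
#' @export
paired_wilcoxon <- function(f1_a, f1_b, exact_max = 25) {
  if (length(f1_a) != length(f1_b) || length(f1_a) < 5)
    stop_ecgfb("ecgfb_parameter_error",
               "need paired vectors of equal length >= 5")
  d <- f1_a - f1_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    stop_ecgfb("ecgfb_degenerate_input_error",
               "all paired differences are zero; the test is degenerate")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    # distribution of W+ over all 2^n sign assignments, via convolution on
    # 2*ranks (mid-ranks are multiples of 1/2, so doubling gives integers)
    r2 <- as.integer(round(2 * r))
    counts <- c(1, rep(0, sum(r2)))  # counts[s+1] = #assignments with sum s
    for (ri in r2) {
      shifted <- c(rep(0, ri), counts[seq_len(length(counts) - ri)])
      counts <- counts + shifted
    }
    total <- 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(counts[seq_len(w2 + 1)]) / total
    p_ge <- sum(counts[(w2 + 1):length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(p_value = p, statistic = w, n = n, method = method)
}

#' Evaluation report across classes
#'
#' Collects per-class precision/recall/F1 plus ROC/AUC and unweighted
#' (macro) averages; micro averages (pooled counts) are included alongside.
#'
#' @param per_class Named list; each element a list with 0/1 `truth`, 0/1
#'   `calls`, numeric `scores`.
#' @return An `eval_report` with `classes` (per-class metrics), `macro_f1`,
#'   `macro_auc`, `micro_f1`.
#' @export
eval_report <- function(per_class) {
  classes <- lapply(per_class, function(x) {
    cc <- confusion(x$calls, x$truth)
    m <- prf1(cc)
    ra <- if (length(unique(x$truth)) == 2) roc_auc(x$scores, x$truth)
          else list(roc = NULL, auc = NA_real_)
    c(list(counts = cc), m, list(auc = ra$auc, roc = ra$roc))
  })
  f1s <- vapply(classes, function(x) x$f1, numeric(1))
  aucs <- vapply(classes, function(x) x$auc, numeric(1))
  pooled <- Reduce(function(a, b) Map(`+`, a, b),
                   lapply(classes, function(x) unclass(x$counts)))
  micro <- prf1(structure(pooled, class = "confusion_counts"))
  structure(list(classes = classes, macro_f1 = mean(f1s),
                 macro_auc = mean(aucs, na.rm = TRUE),
                 micro_f1 = micro$f1),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  for (cls in names(x$classes)) {
    m <- x$classes[[cls]]
    cat(sprintf("  %-7s precision %.3f  recall %.3f  F1 %.3f  AUC %s\n",
                cls, m$precision, m$recall, m$f1,
                ifelse(is.na(m$auc), "NA", sprintf("%.3f", m$auc))))
  }
  cat(sprintf("  macro F1 %.3f  macro AUC %.3f  micro F1 %.3f\n",
              x$macro_f1, x$macro_auc, x$micro_f1))
  invisible(x)
}
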