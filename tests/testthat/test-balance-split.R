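make_task <- function(n_pos, n_neg, cls = "AF") {
  ids <- sprintf("R%04d", seq_len(n_pos + n_neg))
  y <- c(rep(1L, n_pos), rep(0L, n_neg))
  ecgfb:::new_binary_task(cls, ids, y, NA_integer_)
}

test_that("binarize marks multi-label records positive for each class", {
  mk <- function(id, labels) {
    r <- random_record(100, 2, seed = 1, id = id)
    r$labels <- labels
    r
  }
  recs <- list(mk("a", "AF"), mk("b", c("AF", "RBBB")), mk("c", "Normal"))
  task <- binarize(recs, "AF")
  expect_identical(task$labels, c(1L, 1L, 0L))
  expect_identical(binarize(recs, "RBBB")$labels, c(0L, 1L, 0L))
  expect_error(binarize(recs, "FLUTTER"), class = "ecgfb_validation_error")
  # empty classes are tolerated at binarize time but refuse to balance
  expect_error(undersample(binarize(recs, "STE"), 2, 1),
               class = "ecgfb_balance_error")
  all_pos <- binarize(recs[1:2], "AF")
  expect_error(undersample(all_pos, 2, 1), class = "ecgfb_balance_error")
})

test_that("under-sampling reaches the 2:1 ratio and keeps every minority record", {
  task <- undersample(make_task(100, 1000), ratio = 2, seed = 42)
  expect_identical(sum(task$labels == 1), 100L)
  expect_identical(sum(task$labels == 0), 200L)
  expect_identical(task$ratio, 2)
  # minority records all kept
  expect_true(all(sprintf("R%04d", 1:100) %in% task$record_ids))
  expect_false(any(duplicated(task$record_ids)))
  # capped when the majority is scarce
  capped <- undersample(make_task(100, 150), ratio = 2, seed = 1)
  expect_identical(sum(capped$labels == 0), 150L)
  expect_identical(capped$ratio, 1.5)
  # determinism
  expect_identical(undersample(make_task(50, 500), 2, 7),
                   undersample(make_task(50, 500), 2, 7))
  expect_false(identical(undersample(make_task(50, 500), 2, 7)$record_ids,
                         undersample(make_task(50, 500), 2, 8)$record_ids))
})

test_that("achieved ratio never exceeds requested plus rounding slack", {
  for (seed in 1:10) {
    n_pos <- ecgfb:::with_seed(seed, sample(20:80, 1))
    n_neg <- ecgfb:::with_seed(seed + 100, sample(100:400, 1))
    task <- undersample(make_task(n_pos, n_neg), ratio = 2, seed = seed)
    expect_lte(task$ratio, 2 + 1 / n_pos)
  }
})

test_that("split sizes follow largest-remainder rounding", {
  task <- undersample(make_task(100, 200), 2, 1)
  parts <- split_task(task, split_spec(seed = 3))
  expect_identical(lengths(parts), c(train = 192L, validation = 48L,
                                     test = 60L))
  expect_identical(sort(unname(unlist(parts))), 1:300)
  # 10 records: sizes sum to 10, each partition non-empty
  small <- make_task(4, 6)
  p10 <- split_task(small, split_spec(seed = 1))
  expect_identical(sum(lengths(p10)), 10L)
  expect_true(all(lengths(p10) >= 1))
  # largest remainder of (6.4, 1.6, 2.0): floors (6,1,2), leftover to val
  expect_identical(lengths(p10), c(train = 6L, validation = 2L, test = 2L))
})

test_that("stratified splits keep the class ratio within one record", {
  task <- undersample(make_task(100, 200), 2, 1)
  for (seed in 1:50) {
    parts <- split_task(task, split_spec(seed = seed))
    for (nm in names(parts)) {
      pos <- sum(task$labels[parts[[nm]]] == 1)
      ideal <- length(parts[[nm]]) / 3
      expect_lte(abs(pos - ideal), 1)
    }
    expect_identical(sort(unname(unlist(parts))), seq_along(task$labels))
  }
  expect_error(split_task(make_task(1, 1), split_spec()),
               class = "ecgfb_split_error")
})

test_that("k-fold partitions are disjoint, exhaustive and near-equal", {
  task <- undersample(make_task(40, 80), 2, 1)
  folds <- kfold(task, split_spec(k = 5, seed = 2))
  expect_length(folds, 5)
  val_all <- unlist(lapply(folds, `[[`, "validation"))
  expect_identical(sort(val_all), seq_along(task$labels))
  expect_false(any(duplicated(val_all)))
  expect_true(all(vapply(folds, function(f)
    length(intersect(f$train, f$validation)) == 0, logical(1))))
  sizes <- vapply(folds, function(f) length(f$validation), integer(1))
  expect_identical(sizes, rep(24L, 5))
  # 103 records -> fold sizes 21,21,21,20,20 in some order
  t103 <- make_task(35, 68)
  s103 <- vapply(kfold(t103, split_spec(k = 5, seed = 9)),
                 function(f) length(f$validation), integer(1))
  expect_identical(sort(s103, decreasing = TRUE), c(21L, 21L, 21L, 20L, 20L))
  expect_error(kfold(make_task(3, 6), split_spec(k = 4, seed = 1)),
               class = "ecgfb_parameter_error")
})

test_that("splits and folds are bit-identical under a repeated seed", {
  task <- undersample(make_task(60, 120), 2, 5)
  expect_identical(split_task(task, split_spec(seed = 11)),
                   split_task(task, split_spec(seed = 11)))
  expect_identical(kfold(task, split_spec(k = 5, seed = 11)),
                   kfold(task, split_spec(k = 5, seed = 11)))
})
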