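test_that("RSM window scores aggregate node errors as specified", {
  p <- rae_params(34, seed = 1)
  toks <- sample(34, 6, replace = TRUE)
  tree <- build_greedy_tree(toks, p, registry = REG)
  expect_equal(score_rsm_window(tree, "avg_parents"), mean(tree$errors))
  expect_equal(score_rsm_window(tree, "root"),
               tree$errors[length(tree$errors)])
  # independently recompute each node error from the stored vectors
  manual <- vapply(seq_len(nrow(tree$structure)), function(j) {
    reconstruction_error(tree$recon[, j],
                         raetrace:::tree_forward(tree$leaves, tree$structure,
                                                 p)$X[, j])
  }, 0)
  expect_equal(score_rsm_window(tree, "avg_parents"), mean(manual))
  # two-leaf tree: both modes coincide
  two <- build_greedy_tree(toks[1:2], p, registry = REG)
  expect_equal(score_rsm_window(two, "avg_parents"),
               score_rsm_window(two, "root"))
  # degenerate single-leaf tree scores 0 with a flag
  one <- build_greedy_tree(toks[1], p, registry = REG)
  s <- score_rsm_window(one)
  expect_equal(as.numeric(s), 0)
  expect_true(attr(s, "degenerate"))
})

test_that("perfect reconstruction scores 0 in both modes", {
  n <- 4
  # identity-like zero model on zero leaves reconstructs exactly
  z <- structure(list(W1 = matrix(0, n, 2 * n), b1 = rep(0, n),
                      W2 = matrix(0, 2 * n, n), b2 = rep(0, 2 * n), n = n),
                 class = "rae_params")
  tree <- build_linear_tree(matrix(0, n, 3), z)
  expect_equal(score_rsm_window(tree, "avg_parents"), 0)
  expect_equal(score_rsm_window(tree, "root"), 0)
  expect_equal(score_bos_chunk(matrix(0, 5, n), z), 0)
})

test_that("BOS chunk scoring builds a w-row linear tree", {
  p <- rae_params(34, seed = 3)
  rows <- matrix(rbinom(25 * 34, 1, 0.1), 25, 34)
  tree <- build_linear_tree(rows, p, rows_are_rows = TRUE)
  expect_equal(length(tree$errors), 24)
  expect_equal(score_bos_chunk(rows, p), mean(tree$errors))
  expect_equal(score_bos_chunk(rows, p), score_bos_chunk(rows, p))
  expect_error(score_bos_chunk(rows[1, , drop = FALSE], p), "at least 2")
})

test_that("bos_chunk_matrices groups per day and drops short tails", {
  log <- generate_days(tiny_model(), 2, seed = 31)
  ch <- segment_windows(log, 1, REG)
  cb <- bos_chunk_matrices(ch, 25, REG)
  expect_true(all(vapply(cb$rows, nrow, 0L) == 25))
  days <- as.Date(ch$start, tz = "UTC")
  expected <- sum(vapply(unique(days), function(d) sum(days == d) %/% 25L, 0L))
  expect_equal(length(cb$rows), expected)
  # chunks never straddle a day boundary
  expect_true(all(as.Date(cb$start, tz = "UTC") ==
                    as.Date(cb$end - 1, tz = "UTC")))
})

test_that("thresholding is monotone and matches direct comparison", {
  scores <- c(0.5, 0.1, 0.9, 0.3, 0.7)
  expect_equal(threshold_scores(scores, 0.4), scores > 0.4)
  expect_equal(sum(threshold_scores(scores, Inf)), 0)
  expect_equal(sum(threshold_scores(scores, 0)), 5)
  flags <- vapply(sort(scores), function(t) sum(threshold_scores(scores, t)), 0L)
  expect_true(all(diff(flags) <= 0))
})

test_that("mean-confidence thresholds follow the per-class mean", {
  conf <- list(a = c(0.8, 0.6), b = 0.9)
  m <- mean_confidence_threshold(conf)
  expect_equal(unname(m), c(0.7, 0.9))
  expect_equal(mean_confidence_threshold(list(a = c(0.6, 0.8)))[["a"]],
               mean_confidence_threshold(list(a = c(0.8, 0.6)))[["a"]])
  expect_error(mean_confidence_threshold(list(a = numeric())), "empty")
  flags <- flag_low_confidence(c(0.65, 0.75, 0.85), c("a", "a", "b"), m)
  expect_equal(unname(flags), c(TRUE, FALSE, TRUE))
  # a fraction < 1 relaxes the flagging
  expect_equal(unname(flag_low_confidence(0.65, "a", m, fraction = 0.9)), FALSE)
})
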