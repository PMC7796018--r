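test_that("encode/decode match closed forms and a hand-rolled oracle", {
  n <- 3
  p <- rae_params(n, seed = 1)
  z <- list(W1 = matrix(0, n, 2 * n), b1 = rep(0, n),
            W2 = matrix(0, 2 * n, n), b2 = rep(0, 2 * n), n = n)
  class(z) <- "rae_params"
  expect_equal(encode_pair(rep(1, n), rep(-1, n), z), rep(0, n))
  z$b1 <- rep(0.5, n)
  expect_equal(encode_pair(rep(1, n), rep(2, n), z), rep(tanh(0.5), n))
  dec <- decode_pair(rep(0.3, n), z)
  expect_equal(dec$c1, rep(0, n))
  expect_equal(dec$c2, rep(0, n))
  # elementwise recomputation oracle
  set.seed(7)
  c1 <- rnorm(n); c2 <- rnorm(n)
  manual <- tanh(p$W1 %*% c(c1, c2) + p$b1)
  expect_equal(encode_pair(c1, c2, p), as.numeric(manual), tolerance = 1e-12)
  r <- p$W2 %*% manual + p$b2
  dd <- decode_pair(as.numeric(manual), p)
  expect_equal(c(dd$c1, dd$c2), as.numeric(r), tolerance = 1e-12)
  expect_length(dd$c1, n)
  expect_error(encode_pair(rep(1, 2), rep(1, n), p), "expected length")
})

test_that("reconstruction error is the symmetric MSE", {
  expect_equal(reconstruction_error(c(1, 2), c(1, 2)), 0)
  expect_equal(reconstruction_error(c(1, 0, 0, 0), c(0, 0, 0, 0)), 0.25)
  x <- rnorm(5); y <- rnorm(5)
  expect_equal(reconstruction_error(x, y), reconstruction_error(y, x))
  expect_error(reconstruction_error(1:2, 1:3), "mismatch")
})

test_that("softmax, cross-entropy and the combined loss satisfy their identities", {
  p <- rae_params(4, K = 3, seed = 2)
  p$Wlabel <- matrix(0, 3, 4)
  expect_equal(softmax_label(rnorm(4), p), rep(1 / 3, 3))
  p1 <- rae_params(4, K = 1, seed = 2)
  expect_equal(softmax_label(rnorm(4), p1), 1)
  # exp-normalise oracle
  p3 <- rae_params(4, K = 3, seed = 3)
  v <- rnorm(4)
  s <- as.numeric(p3$Wlabel %*% v)
  expect_equal(softmax_label(v, p3), exp(s) / sum(exp(s)), tolerance = 1e-12)
  expect_lte(supervised_error(c(0, 1, 0), c(0, 1, 0)), 1e-10)
  expect_equal(supervised_error(rep(0.25, 4), c(0, 0, 1, 0)), log(4))
  expect_gt(supervised_error(c(0.2, 0.8), c(1, 0)),
            supervised_error(c(0.4, 0.6), c(1, 0)))
  expect_equal(combined_error(0.2, 0.4, 0.5), 0.3)
  expect_equal(combined_error(0.2, 9, 1), 0.2)
  expect_equal(combined_error(9, 0.4, 0), 0.4)
  expect_error(combined_error(1, 1, 1.5), "alpha")
  expect_error(softmax_label(rnorm(4), rae_params(4, seed = 1)), "Wlabel")
})

test_that("linear trees cascade right-to-left as in the traditional RAE", {
  n <- 34
  p <- rae_params(n, seed = 4)
  rows <- t(rsm_sequence(sample(34, 4), REG)$onehot)
  tree <- build_linear_tree(rows, p)
  # 4 leaves: merge (x3,x4) -> y1(id 5), (x2,y1) -> y2(id 6), (x1,y2) -> y3
  expect_equal(tree$structure, rbind(c(3L, 4L), c(2L, 5L), c(1L, 6L)))
  expect_equal(tree$k - 1, length(tree$errors))
  expect_true(all(tree$errors >= 0))
  two <- build_linear_tree(rows[, 1:2], p)
  expect_equal(nrow(two$structure), 1)
  expect_equal(nrow(build_linear_tree(
    matrix(rnorm(34 * 25), 34, 25), p)$structure), 24)
  expect_error(build_linear_tree(rows[, 1, drop = FALSE], p), "at least 2")
})

test_that("greedy merges always take the minimal-error adjacent pair", {
  set.seed(99)
  for (rep in 1:30) {
    k <- sample(2:8, 1)
    toks <- sample(34, k, replace = TRUE)
    p <- rae_params(34, seed = rep, init = 0.2)
    tree <- build_greedy_tree(toks, p, registry = REG)
    expect_equal(tree$structure, greedy_oracle_structure(toks, p, REG))
    expect_equal(nrow(tree$structure), k - 1)
  }
  p <- rae_params(34, seed = 1)
  expect_error(build_greedy_tree(integer(), p, registry = REG), "empty")
})

test_that("root features are fixed-length and deterministic", {
  p <- rae_params(34, seed = 5)
  toks <- sensor_index(REG, c("M7", "M3", "M7", "M3", "M5", "M4"))
  t1 <- build_greedy_tree(toks, p, registry = REG)
  t2 <- build_greedy_tree(toks, p, registry = REG)
  expect_length(root_feature(t1), 34)
  expect_identical(root_feature(t1), root_feature(t2))
  single <- build_greedy_tree(3L, p, registry = REG)
  expect_equal(root_feature(single), as.numeric(bos_vector(3L, REG)))
  expect_equal(single$k, 1)
})

test_that("analytic gradients agree with central differences", {
  n <- 5
  set.seed(31)
  leaves <- t(rsm_sequence(sample(n, 4, replace = TRUE),
                           sensor_registry(sprintf("M%03d", 1:n)))$onehot)
  for (case in list(list(alpha = 1, K = NULL), list(alpha = 0.2, K = 3),
                    list(alpha = 0, K = 3))) {
    p <- rae_params(n, K = case$K, seed = 17, init = 0.3)
    target <- if (case$alpha < 1) 2 else NULL
    for (st in list(raetrace:::linear_structure(4),
                    raetrace:::greedy_structure(leaves, p))) {
      ga <- raetrace:::tree_gradient(p, leaves, st, case$alpha, target)
      gn <- numerical_gradient(function(pp) tree_loss(pp, leaves, st,
                                                      case$alpha, target),
                               p, names(ga))
      expect_lt(max_rel_err(ga, gn, names(ga)), 1e-4)
    }
  }
  # tanh decoder option
  p <- rae_params(n, seed = 3, init = 0.3)
  st <- raetrace:::linear_structure(4)
  ga <- raetrace:::tree_gradient(p, leaves, st, 1, NULL, decode = "tanh")
  gn <- numerical_gradient(function(pp) tree_loss(pp, leaves, st, 1, NULL,
                                                  decode = "tanh"),
                           p, names(ga))
  expect_lt(max_rel_err(ga, gn, names(ga)), 1e-4)
})

test_that("alpha = 1 reduces the semi-supervised objective to the unsupervised one", {
  n <- 5
  p <- rae_params(n, K = 3, seed = 8, init = 0.2)
  leaves <- matrix(rnorm(n * 3), n, 3)
  st <- raetrace:::linear_structure(3)
  expect_equal(tree_loss(p, leaves, st, alpha = 1, target = 2),
               tree_loss(p, leaves, st, alpha = 1))
  fw <- raetrace:::tree_forward(leaves, st, p)
  expect_equal(tree_loss(p, leaves, st, alpha = 1), mean(fw$errors))
})

test_that("training reduces the corpus loss and is seed-deterministic", {
  set.seed(123)
  corpus <- lapply(1:60, function(i) {
    t(rsm_sequence(sample(c(1, 2, 5), sample(2:5, 1), replace = TRUE),
                   REG)$onehot)
  })
  cfg0 <- training_config(epochs = 0, seed = 2)
  init <- rae_train(corpus, cfg0, n = 34)
  expect_identical(init$W1, rae_params(34, seed = 2, init = cfg0$init)$W1)
  cfg <- training_config(epochs = 3, seed = 2)
  fit <- rae_train(corpus, cfg, n = 34)
  h <- attr(fit, "history")
  expect_lt(h[length(h)], h[1])
  fit2 <- rae_train(corpus, cfg, n = 34)
  expect_identical(fit$W1, fit2$W1)
  # semi-supervised needs labels
  expect_error(rae_train(corpus, training_config(mode = "semisupervised")),
               "labels")
})

test_that("checkpoints round-trip through JSON", {
  p <- rae_params(6, K = 2, seed = 9)
  attr(p, "label_levels") <- c("a", "b")
  f <- withr::local_tempfile(fileext = ".json")
  save_params(p, f)
  q <- load_params(f)
  expect_equal(q$W1, p$W1)
  expect_equal(q$b2, p$b2)
  expect_equal(q$Wlabel, p$Wlabel)
  expect_equal(attr(q, "label_levels"), c("a", "b"))
})
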