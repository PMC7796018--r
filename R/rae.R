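#' Recursive auto-encoder parameters
#'
#' The same encoder/decoder pair is applied at every node of a binary merge
#' tree. For children `c1, c2` of dimension n the parent is
#' `p = tanh(W1 [c1; c2] + b1)` and the children are reconstructed as
#' `[c1'; c2'] = g(W2 p + b2)` with `g` the identity by default (a tanh
#' decoder is available via the `decode` training option). The parent has
#' the same dimension n as each child, so a variable-length sequence always
#' compresses to a fixed 1 x n root feature. In semi-supervised mode a
#' softmax readout `d = softmax(Wlabel p)` is attached to every parent.
#'
#' @param n feature dimension (= registry size for one-hot RSM rows and BOS
#'   vectors).
#' @param K number of activity labels for the semi-supervised softmax, or
#'   `NULL` for a purely unsupervised model.
#' @param seed integer seed for the uniform(-init, init) initialisation.
#' @param init half-width of the uniform initialisation.
#' @return An object of class `rae_params`: list with `W1` (n x 2n), `b1`
#'   (n), `W2` (2n x n), `b2` (2n) and optionally `Wlabel` (K x n).
#' @export
rae_params <- function(n, K = NULL, seed = 1L, init = 0.05) {
  set.seed(as.integer(seed))
  u <- function(nr, nc) matrix(stats::runif(nr * nc, -init, init), nr, nc)
  p <- list(W1 = u(n, 2 * n), b1 = as.numeric(u(n, 1)),
            W2 = u(2 * n, n), b2 = as.numeric(u(2 * n, 1)))
  if (!is.null(K)) p$Wlabel <- u(K, n)
  p$n <- n
  structure(p, class = "rae_params")
}

check_vec <- function(x, n, what) {
  x <- as.numeric(x)
  if (length(x) != n) stop(what, ": expected length ", n, ", got ", length(x))
  x
}

#' Encode a child pair into a parent vector
#'
#' `p = tanh(W1 [c1; c2] + b1)`; entries lie in (-1, 1).
#'
#' @param c1,c2 child vectors of dimension n.
#' @param params an `rae_params`.
#' @return numeric parent vector of dimension n.
#' @export
encode_pair <- function(c1, c2, params) {
  n <- params$n
  x <- c(check_vec(c1, n, "c1"), check_vec(c2, n, "c2"))
  as.numeric(tanh(params$W1 %*% x + params$b1))
}

#' Decode a parent vector back into its two children
#'
#' `[c1'; c2'] = g(W2 p + b2)` split into halves; `g` is the identity
#' (default) or `tanh`.
#'
#' @param p parent vector of dimension n.
#' @param params an `rae_params`.
#' @param decode decoder activation, `"identity"` or `"tanh"`.
#' @return list with numeric vectors `c1` and `c2` of dimension n.
#' @export
decode_pair <- function(p, params, decode = c("identity", "tanh")) {
  decode <- match.arg(decode)
  n <- params$n
  p <- check_vec(p, n, "p")
  r <- as.numeric(params$W2 %*% p + params$b2)
  if (decode == "tanh") r <- tanh(r)
  list(c1 = r[1:n], c2 = r[(n + 1):(2 * n)])
}

#' Mean-squared reconstruction error
#'
#' `E = (1/N) sum_i (x'_i - x_i)^2` over the N entries of the vectors.
#'
#' @param x,xp original and reconstructed vectors of equal dimension.
#' @return non-negative scalar.
#' @export
reconstruction_error <- function(x, xp) {
  if (length(x) != length(xp)) stop("dimension mismatch: ", length(x),
                                    " vs ", length(xp))
  mean((as.numeric(xp) - as.numeric(x))^2)
}

#' Softmax label distribution at a parent
#'
#' `d = softmax(Wlabel p)`: non-negative entries summing to 1.
#'
#' @param p parent vector.
#' @param params `rae_params` with a `Wlabel` component.
#' @return numeric probability vector of length K.
#' @export
softmax_label <- function(p, params) {
  if (is.null(params$Wlabel)) stop("params carry no Wlabel (unsupervised model)")
  s <- as.numeric(params$Wlabel %*% check_vec(p, params$n, "p"))
  e <- exp(s - max(s))
  e / sum(e)
}

#' Cross-entropy between a predicted distribution and a target
#'
#' `E = -sum_k t_k log d_k`, with probabilities clamped at `eps` so a
#' zero-probability target index yields a large finite loss.
#'
#' @param d predicted distribution.
#' @param t target distribution (typically one-hot).
#' @param eps clamp for `log`.
#' @return non-negative scalar.
#' @export
supervised_error <- function(d, t, eps = 1e-12) {
  if (length(d) != length(t)) stop("dimension mismatch")
  -sum(t * log(pmax(d, eps)))
}

#' Convex combination of unsupervised and supervised error
#'
#' `E = alpha * E_unsup + (1 - alpha) * E_sup`; `alpha = 1` recovers the
#' purely unsupervised loss, `alpha = 0` the pure cross-entropy.
#'
#' @param eu unsupervised (reconstruction) error.
#' @param es supervised (cross-entropy) error.
#' @param alpha weight in \[0, 1\].
#' @return scalar.
#' @export
combined_error <- function(eu, es, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  alpha * eu + (1 - alpha) * es
}

# ---------------------------------------------------------------------------
# Trees. Leaves are columns of an n x k matrix; node ids are 1..k for leaves
# and k+1 .. 2k-1 for internal nodes in creation order, so a node's parent is
# always created after it and reverse creation order is a valid backprop
# order. `structure` is an (k-1) x 2 matrix of (left, right) child ids.
# ---------------------------------------------------------------------------

linear_structure <- function(k) {
  if (k < 2) stop("a linear tree needs at least 2 rows")
  s <- matrix(0L, k - 1, 2)
  s[1, ] <- c(k - 1L, k)                     # rightmost pair first
  if (k > 2) for (j in 2:(k - 1)) s[j, ] <- c(k - j, k + j - 1L)
  s
}

# Forward pass over a fixed structure. Returns parent matrix P (n x (k-1)),
# reconstruction matrix R (2n x (k-1)), inputs X (2n x (k-1)) and per-node
# errors.
tree_forward <- function(leaves, structure, params, decode = "identity") {
  n <- params$n
  k <- ncol(leaves)
  m <- nrow(structure)
  vecs <- cbind(leaves, matrix(0, n, m))
  X <- matrix(0, 2 * n, m)
  P <- matrix(0, n, m)
  R <- matrix(0, 2 * n, m)
  err <- numeric(m)
  for (j in seq_len(m)) {
    x <- c(vecs[, structure[j, 1]], vecs[, structure[j, 2]])
    p <- tanh(params$W1 %*% x + params$b1)
    r <- params$W2 %*% p + params$b2
    if (decode == "tanh") r <- tanh(r)
    X[, j] <- x
    P[, j] <- p
    R[, j] <- r
    err[j] <- mean((r - x)^2)
    vecs[, k + j] <- p
  }
  list(P = P, R = R, X = X, errors = err)
}

new_rae_tree <- function(leaves, structure, fw, tokens = NULL, spans = NULL,
                         label = NA_character_) {
  k <- ncol(leaves)
  if (is.null(spans)) {
    spans <- matrix(0L, max(k - 1, 0), 2)
    if (k >= 2) {
      lo <- c(seq_len(k), integer(k - 1))
      hi <- lo
      for (j in seq_len(k - 1)) {
        lo[k + j] <- lo[structure[j, 1]]
        hi[k + j] <- hi[structure[j, 2]]
        spans[j, ] <- c(lo[k + j], hi[k + j])
      }
    }
  }
  structure(list(leaves = leaves, structure = structure, P = fw$P,
                 recon = fw$R, errors = fw$errors, spans = spans,
                 tokens = tokens, label = label, k = k,
                 root = if (k == 1) 1L else 2L * k - 1L),
            class = "rae_tree")
}

#' Build the traditional linear (right-to-left cascade) RAE tree
#'
#' The rightmost pair of rows is merged first; each parent is then merged
#' with the next row to its left, so k rows yield k - 1 internal nodes with
#' the cascade shape of the traditional recursive auto-encoder.
#'
#' @param rows an n x k matrix of leaf columns (or k x n with
#'   `rows_are_rows = TRUE`).
#' @param params an `rae_params`.
#' @param decode decoder activation.
#' @param rows_are_rows interpret `rows` as one leaf per matrix row.
#' @param label optional activity label carried by the tree.
#' @return An object of class `rae_tree` with per-node parent vectors,
#'   reconstructions and errors.
#' @export
build_linear_tree <- function(rows, params, decode = "identity",
                              rows_are_rows = FALSE, label = NA_character_) {
  leaves <- if (rows_are_rows) t(rows) else as.matrix(rows)
  if (nrow(leaves) != params$n) stop("leaf dimension ", nrow(leaves),
                                     " != params n = ", params$n)
  k <- ncol(leaves)
  if (k < 2) stop("a linear tree needs at least 2 rows (got ", k, ")")
  s <- linear_structure(k)
  new_rae_tree(leaves, s, tree_forward(leaves, s, params, decode),
               label = label)
}

#' Build a greedy RAE tree over an activation sequence
#'
#' At each level the reconstruction error of every adjacent pair is
#' evaluated and the pair with the smallest error is merged (leftmost pair
#' on ties); the merge repeats until a single parent remains. A single-token
#' sequence yields a degenerate tree whose root is the leaf itself.
#'
#' @param tokens an `rsm_sequence`, an integer token vector, or an n x k
#'   matrix of leaf columns.
#' @param params an `rae_params`.
#' @param decode decoder activation.
#' @param registry registry used when `tokens` are indices.
#' @param label optional activity label carried by the tree.
#' @return An `rae_tree`; each internal node's leaf span is contiguous and
#'   recorded in `spans` for pattern mining.
#' @export
build_greedy_tree <- function(tokens, params, decode = "identity",
                              registry = default_registry(),
                              label = NA_character_) {
  if (inherits(tokens, "rsm_sequence")) {
    leaves <- t(tokens$onehot)
    toks <- tokens$tokens
  } else if (is.matrix(tokens)) {
    leaves <- tokens
    toks <- NULL
  } else {
    toks <- as.integer(tokens)
    leaves <- t(rsm_sequence(toks, registry)$onehot)
  }
  if (ncol(leaves) == 0) stop("empty sequence: a greedy tree needs >= 1 token")
  if (nrow(leaves) != params$n) stop("leaf dimension ", nrow(leaves),
                                     " != params n = ", params$n)
  k <- ncol(leaves)
  st <- greedy_structure(leaves, params, decode)
  fw <- tree_forward(leaves, st, params, decode)
  new_rae_tree(leaves, st, fw, tokens = toks, label = label)
}

# Greedy structure selection under the current parameters: vectorised
# evaluation of all adjacent pairs at each level.
greedy_structure <- function(leaves, params, decode = "identity") {
  n <- params$n
  k <- ncol(leaves)
  if (k == 1) return(matrix(0L, 0, 2))
  ids <- seq_len(k)
  V <- leaves
  s <- matrix(0L, k - 1, 2)
  for (j in seq_len(k - 1)) {
    m <- ncol(V)
    X <- rbind(V[, -m, drop = FALSE], V[, -1, drop = FALSE])  # 2n x (m-1)
    P <- tanh(params$W1 %*% X + params$b1)
    R <- params$W2 %*% P + params$b2
    if (decode == "tanh") R <- tanh(R)
    errs <- colMeans((R - X)^2)
    i <- which.min(errs)                      # leftmost minimal pair
    s[j, ] <- c(ids[i], ids[i + 1])
    V[, i] <- P[, i]
    V <- V[, -(i + 1), drop = FALSE]
    ids[i] <- k + j
    ids <- ids[-(i + 1)]
  }
  s
}

#' Fixed-length root feature of a tree
#'
#' The root parent vector (1 x n) summarises the whole variable-length
#' sequence and can feed any fixed-input classifier. A degenerate
#' single-leaf tree returns the leaf itself.
#'
#' @param tree an `rae_tree`.
#' @return numeric vector of length n.
#' @export
root_feature <- function(tree) {
  if (tree$k == 1) return(as.numeric(tree$leaves[, 1]))
  as.numeric(tree$P[, tree$k - 1])
}

# ---------------------------------------------------------------------------
# Loss and gradients (backpropagation through structure).
# Tree loss = mean over internal nodes of
#   alpha * e_j + (1 - alpha) * xent(softmax(Wlabel p_j), t)
# with alpha = 1 / no label term in unsupervised mode.
# ---------------------------------------------------------------------------

#' Loss of one tree under fixed structure
#'
#' @param params an `rae_params`.
#' @param leaves n x k leaf matrix.
#' @param structure (k-1) x 2 child-id matrix (see [build_greedy_tree()]).
#' @param alpha reconstruction weight in \[0, 1\]; 1 = unsupervised.
#' @param target integer class index (1..K) when `alpha < 1`.
#' @param decode decoder activation.
#' @return scalar loss (mean over internal nodes).
#' @export
tree_loss <- function(params, leaves, structure, alpha = 1, target = NULL,
                      decode = "identity") {
  fw <- tree_forward(leaves, structure, params, decode)
  m <- length(fw$errors)
  if (m == 0) return(0)
  l <- alpha * fw$errors
  if (alpha < 1) {
    if (is.null(target)) stop("semi-supervised loss needs a target label")
    for (j in seq_len(m)) {
      d <- softmax_label(fw$P[, j], params)
      l[j] <- l[j] + (1 - alpha) * (-log(max(d[target], 1e-12)))
    }
  }
  mean(l)
}

# Analytic gradient of tree_loss w.r.t. all parameters; same contract.
tree_gradient <- function(params, leaves, structure, alpha = 1,
                          target = NULL, decode = "identity") {
  n <- params$n
  k <- ncol(leaves)
  m <- nrow(structure)
  fw <- tree_forward(leaves, structure, params, decode)
  g <- list(W1 = matrix(0, n, 2 * n), b1 = numeric(n),
            W2 = matrix(0, 2 * n, n), b2 = numeric(2 * n))
  semisup <- alpha < 1
  if (semisup) {
    if (is.null(params$Wlabel)) stop("semi-supervised gradient needs Wlabel")
    g$Wlabel <- matrix(0, nrow(params$Wlabel), n)
    tvec <- numeric(nrow(params$Wlabel))
    tvec[target] <- 1
  }
  acc <- matrix(0, n, m)                      # dL/dp accumulated from parents
  loss <- 0
  for (j in rev(seq_len(m))) {
    x <- fw$X[, j]; p <- fw$P[, j]; r <- fw$R[, j]
    wr <- (alpha / m) * (2 / (2 * n))
    drr <- wr * (r - x)                       # dL/dr (post-activation)
    dr <- if (decode == "tanh") drr * (1 - r^2) else drr
    gp <- acc[, j] + as.numeric(crossprod(params$W2, dr))
    if (semisup) {
      d <- softmax_label(p, params)
      dd <- ((1 - alpha) / m) * (d - tvec)
      gp <- gp + as.numeric(crossprod(params$Wlabel, dd))
      g$Wlabel <- g$Wlabel + tcrossprod(dd, p)
    }
    g$W2 <- g$W2 + tcrossprod(dr, p)
    g$b2 <- g$b2 + dr
    dz <- gp * (1 - p^2)
    g$W1 <- g$W1 + tcrossprod(dz, x)
    g$b1 <- g$b1 + dz
    # gradient w.r.t. the child vectors: through the encoder input and
    # through their role as reconstruction targets
    gx <- as.numeric(crossprod(params$W1, dz)) - drr
    for (side in 1:2) {
      child <- structure[j, side]
      if (child > k) {
        acc[, child - k] <- acc[, child - k] +
          gx[((side - 1) * n + 1):(side * n)]
      }
    }
  }
  g
}

#' Training configuration
#'
#' @param mode `"unsupervised"` or `"semisupervised"`.
#' @param tree `"greedy"` or `"linear"` tree construction.
#' @param alpha reconstruction weight of the combined loss (default 0.2 in
#'   semi-supervised mode; forced to 1 when unsupervised).
#' @param epochs passes over the corpus.
#' @param lr Adam learning rate.
#' @param batch mini-batch size (trees per update).
#' @param seed integer seed (initialisation + shuffling).
#' @param decode decoder activation.
#' @param init initialisation half-width.
#' @return list of class `training_config`.
#' @export
training_config <- function(mode = c("unsupervised", "semisupervised"),
                            tree = c("greedy", "linear"), alpha = 0.2,
                            epochs = 5, lr = 0.01, batch = 20, seed = 1L,
                            decode = "identity", init = 0.05) {
  mode <- match.arg(mode)
  tree <- match.arg(tree)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (mode == "unsupervised") alpha <- 1
  structure(list(mode = mode, tree = tree, alpha = alpha, epochs = epochs,
                 lr = lr, batch = batch, seed = as.integer(seed),
                 decode = decode, init = init), class = "training_config")
}

#' Train a recursive auto-encoder by backpropagation through structure
#'
#' Minimises the mean per-tree loss over the corpus with mini-batch Adam.
#' Greedy tree structures depend on the parameters and are rebuilt at the
#' start of every epoch; linear structures are fixed. Inputs with fewer than
#' two leaves are skipped (a single leaf has no internal node to train on).
#' In semi-supervised mode the window's activity label is applied as the
#' target at every parent of its tree; unlabelled inputs are skipped.
#'
#' @param inputs list of n x k leaf matrices (use [rsm_leaf_matrices()] or
#'   [bos_chunk_matrices()] to build them from window tables).
#' @param config a [training_config()].
#' @param labels factor/character vector of activity labels per input
#'   (required in semi-supervised mode).
#' @param n feature dimension (inferred from the first input by default).
#' @return An `rae_params` with attributes `history` (epoch mean losses,
#'   element 1 = loss at initialisation) and `label_levels`.
#' @export
rae_train <- function(inputs, config = training_config(), labels = NULL,
                      n = NULL) {
  if (length(inputs) == 0) stop("empty training corpus")
  if (is.null(n)) n <- nrow(inputs[[1]])
  semisup <- config$mode == "semisupervised"
  if (semisup && is.null(labels)) stop("semi-supervised training needs labels")
  keep <- vapply(inputs, ncol, 0L) >= 2
  if (semisup) keep <- keep & !is.na(labels)
  inputs <- inputs[keep]
  if (length(inputs) == 0) stop("no trainable inputs (>= 2 leaves each)")
  lev <- NULL
  targets <- NULL
  if (semisup) {
    labels <- labels[keep]
    lev <- sort(unique(as.character(labels)))
    targets <- match(as.character(labels), lev)
  }
  params <- rae_params(n, K = if (semisup) length(lev) else NULL,
                       seed = config$seed, init = config$init)
  alpha <- config$alpha
  pnames <- intersect(c("W1", "b1", "W2", "b2", "Wlabel"), names(params))
  adam_m <- lapply(params[pnames], function(x) x * 0)
  adam_v <- lapply(params[pnames], function(x) x * 0)
  adam_t <- 0
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  structures <- function() {
    lapply(inputs, function(L) {
      if (config$tree == "linear") linear_structure(ncol(L))
      else greedy_structure(L, params, config$decode)
    })
  }
  mean_loss <- function(sts) {
    mean(vapply(seq_along(inputs), function(i) {
      tree_loss(params, inputs[[i]], sts[[i]], alpha,
                target = targets[i], decode = config$decode)
    }, 0))
  }
  history <- mean_loss(structures())
  if (config$epochs > 0) {
    for (ep in seq_len(config$epochs)) {
      sts <- structures()                    # rebuilt under current params
      ord <- sample(length(inputs))
      ep_loss <- 0
      for (b in split(ord, ceiling(seq_along(ord) / config$batch))) {
        acc <- lapply(params[pnames], function(x) x * 0)
        for (i in b) {
          gi <- tree_gradient(params, inputs[[i]], sts[[i]], alpha,
                              target = targets[i], decode = config$decode)
          for (nm in pnames) acc[[nm]] <- acc[[nm]] + gi[[nm]]
          ep_loss <- ep_loss + tree_loss(params, inputs[[i]], sts[[i]],
                                         alpha, targets[i], config$decode)
        }
        adam_t <- adam_t + 1
        for (nm in pnames) {
          gr <- acc[[nm]] / length(b)
          adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * gr
          adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * gr^2
          mhat <- adam_m[[nm]] / (1 - beta1^adam_t)
          vhat <- adam_v[[nm]] / (1 - beta2^adam_t)
          params[[nm]] <- params[[nm]] - config$lr * mhat / (sqrt(vhat) + adam_eps)
        }
      }
      history <- c(history, ep_loss / length(inputs))
    }
  }
  attr(params, "history") <- history
  attr(params, "label_levels") <- lev
  attr(params, "config") <- config
  params
}

#' Leaf matrices for RSM windows
#'
#' @param chunks a `window_chunks` table.
#' @param registry the `sensor_registry`.
#' @param min_tokens drop windows with fewer tokens (default 1 keeps all
#'   non-empty windows).
#' @return list with `inputs` (n x k matrices), `labels`, `index` (rows of
#'   `chunks` retained).
#' @export
rsm_leaf_matrices <- function(chunks, registry = default_registry(),
                              min_tokens = 1) {
  keep <- which(chunks$n_tokens >= min_tokens)
  inputs <- lapply(keep, function(i) {
    t(rsm_sequence(chunks$tokens[[i]], registry)$onehot)
  })
  list(inputs = inputs, labels = chunks$label[keep], index = keep)
}

#' Save / load parameter checkpoints
#'
#' Checkpoints are portable JSON: shapes and values of every weight array
#' plus the training configuration and label levels.
#'
#' @param params an `rae_params`.
#' @param path file path.
#' @return `load_params` returns an `rae_params`; `save_params` returns
#'   `invisible(path)`.
#' @export
save_params <- function(params, path) {
  obj <- list(n = params$n,
              W1 = params$W1, b1 = params$b1, W2 = params$W2, b2 = params$b2,
              Wlabel = params$Wlabel,
              label_levels = attr(params, "label_levels"),
              config = unclass(attr(params, "config")))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_params
#' @export
load_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- list(W1 = as.matrix(obj$W1), b1 = as.numeric(obj$b1),
            W2 = as.matrix(obj$W2), b2 = as.numeric(obj$b2), n = obj$n)
  if (!is.null(obj$Wlabel)) p$Wlabel <- as.matrix(obj$Wlabel)
  p <- structure(p, class = "rae_params")
  attr(p, "label_levels") <- obj$label_levels
  p
}
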