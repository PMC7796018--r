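#' Collect the lowest-error nodes across a tree collection
#'
#' Sensor activations that frequently follow each other are reconstructed
#' well by a trained RAE, so the internal nodes with the least reconstruction
#' error mark recurring sub-activities. All internal nodes of all trees are
#' pooled globally, sorted ascending by error, and the first `k` kept.
#'
#' With discrete one-hot leaves, nodes over identical token pairs have
#' *identical* error, so a global top-k under ties collapses onto copies of
#' the one most-frequent pattern and starves every other activity class.
#' The default therefore keeps the k least-error nodes *per activity class*
#' (matching per-class pattern tables); `per_class = FALSE` gives the global
#' selection.
#'
#' @param trees list of `rae_tree`s (each may carry an activity `label` and
#'   its token sequence).
#' @param k number of nodes to keep (default 500); all nodes if fewer exist.
#' @param per_class select k nodes within each activity class (default)
#'   rather than globally.
#' @return data frame sorted ascending by `error`: `activity`, `error`,
#'   `n_leaves`, and `tokens` (list column of the node's left-to-right leaf
#'   token indices).
#' @export
extract_top_nodes <- function(trees, k = 500, per_class = TRUE) {
  per_tree <- lapply(trees, function(tr) {
    m <- if (tr$k >= 2) tr$k - 1L else 0L
    if (m == 0) return(NULL)
    toks <- lapply(seq_len(m), function(j) {
      if (is.null(tr$tokens)) integer() else
        tr$tokens[tr$spans[j, 1]:tr$spans[j, 2]]
    })
    d <- data.frame(activity = rep(tr$label, m), error = tr$errors,
                    n_leaves = tr$spans[, 2] - tr$spans[, 1] + 1L,
                    stringsAsFactors = FALSE)
    d$tokens <- toks
    d
  })
  nodes <- do.call(rbind, per_tree)
  if (is.null(nodes)) {
    nodes <- data.frame(activity = character(), error = numeric(),
                        n_leaves = integer(), stringsAsFactors = FALSE)
    nodes$tokens <- list()
    return(nodes)
  }
  nodes <- nodes[order(nodes$error, method = "radix"), , drop = FALSE]
  if (per_class) {
    keep <- unlist(lapply(split(seq_len(nrow(nodes)), nodes$activity),
                          utils::head, k), use.names = FALSE)
    nodes <- nodes[sort(keep), , drop = FALSE]
  } else {
    nodes <- utils::head(nodes, k)
  }
  rownames(nodes) <- NULL
  nodes
}

#' N-gram sub-activity patterns from selected tree nodes
#'
#' Every selected node whose subtree spans exactly `n` leaves contributes
#' its left-to-right leaf sensor tuple as one n-gram occurrence. Occurrences
#' are counted per activity class and ranked by frequency (ties broken
#' lexicographically by sensor ids) — the recurring low-error merges are
#' exactly the counted objects.
#'
#' @param top_nodes output of [extract_top_nodes()].
#' @param n n-gram order, 2 or 3.
#' @param registry the `sensor_registry` naming the tokens.
#' @return data frame `activity`, `ngram` (comma-separated sensor ids), `n`,
#'   `count`, ranked within each activity.
#' @export
ngram_patterns <- function(top_nodes, n, registry = default_registry()) {
  if (!n %in% c(2, 3)) stop("n must be 2 or 3")
  sel <- top_nodes[top_nodes$n_leaves == n, , drop = FALSE]
  if (nrow(sel) == 0) {
    return(data.frame(activity = character(), ngram = character(),
                      n = integer(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  gram <- vapply(sel$tokens, function(tok) {
    paste(unclass(registry)[tok], collapse = ",")
  }, "")
  counts <- stats::aggregate(list(count = gram),
                             by = list(activity = sel$activity, ngram = gram),
                             FUN = length)
  counts <- counts[order(counts$activity, -counts$count, counts$ngram,
                         method = "radix"), , drop = FALSE]
  counts$n <- as.integer(n)
  rownames(counts) <- NULL
  counts[, c("activity", "ngram", "n", "count")]
}

#' Build labelled greedy trees for every window of a table
#'
#' @param chunks a `window_chunks` table (labels attached).
#' @param params trained `rae_params`.
#' @param registry the `sensor_registry`.
#' @param decode decoder activation.
#' @param min_tokens skip windows with fewer activations (default 2: a
#'   single token has no merge node).
#' @return list of `rae_tree`s carrying window labels.
#' @export
window_trees <- function(chunks, params, registry = default_registry(),
                         decode = "identity", min_tokens = 2) {
  keep <- which(chunks$n_tokens >= min_tokens)
  lapply(keep, function(i) {
    build_greedy_tree(chunks$tokens[[i]], params, decode, registry,
                      label = chunks$label[i])
  })
}
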