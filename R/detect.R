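#' Score an RSM tree by reconstruction error
#'
#' A tree built under parameters trained on normal behaviour reconstructs
#' familiar merges well; poorly reconstructed nodes signal abnormality. Two
#' aggregations are supported: the mean error over all parents
#' (`avg_parents`) and the error of the last (root) parent (`root`). A
#' degenerate single-leaf tree cannot be reconstructed at all and scores 0
#' (flagged via the `"degenerate"` attribute).
#'
#' @param tree an `rae_tree`.
#' @param mode `"avg_parents"` or `"root"`.
#' @return non-negative scalar score.
#' @export
score_rsm_window <- function(tree, mode = c("avg_parents", "root")) {
  mode <- match.arg(mode)
  if (tree$k < 2) return(structure(0, degenerate = TRUE))
  if (mode == "avg_parents") mean(tree$errors)
  else tree$errors[length(tree$errors)]
}

#' Score a chunk of consecutive BOS rows with a linear RAE
#'
#' The w one-minute BOS vectors of a chunk are cascaded right-to-left into a
#' linear tree and the w - 1 parent errors are averaged, so an abnormality
#' in any minute of the chunk raises the chunk score.
#'
#' @param rows w x N matrix of consecutive one-minute BOS vectors (w >= 2).
#' @param params trained `rae_params`.
#' @param decode decoder activation.
#' @return non-negative scalar score.
#' @export
score_bos_chunk <- function(rows, params, decode = "identity") {
  rows <- as.matrix(rows)
  if (nrow(rows) < 2) stop("a BOS chunk needs at least 2 rows")
  tree <- build_linear_tree(rows, params, decode, rows_are_rows = TRUE)
  mean(tree$errors)
}

#' Score every window of a table with greedy RSM trees
#'
#' @param chunks a `window_chunks` table.
#' @param params trained `rae_params`.
#' @param mode score aggregation (see [score_rsm_window()]).
#' @param registry the `sensor_registry`.
#' @param decode decoder activation.
#' @return numeric vector of scores, one per window; windows with < 2
#'   activations score 0 (treated as normal).
#' @export
score_windows_rsm <- function(chunks, params, mode = "avg_parents",
                              registry = default_registry(),
                              decode = "identity") {
  vapply(seq_len(nrow(chunks)), function(i) {
    tok <- chunks$tokens[[i]]
    if (length(tok) < 2) return(0)
    as.numeric(score_rsm_window(
      build_greedy_tree(tok, params, decode, registry), mode))
  }, 0)
}

#' Group windows into consecutive BOS chunks of w rows
#'
#' Windows are grouped per calendar day (chunks never straddle days) into
#' consecutive groups of `w`; a trailing group shorter than `w` is dropped.
#'
#' @param chunks a `window_chunks` table.
#' @param w rows per chunk (default 25 one-minute slices).
#' @param registry the `sensor_registry`.
#' @return list with `rows` (list of w x N matrices), `start`/`end`
#'   (POSIXct per chunk), `window_index` (list of member window rows).
#' @export
bos_chunk_matrices <- function(chunks, w = 25, registry = default_registry()) {
  B <- bos_matrix(chunks, registry)
  day <- as.Date(chunks$start, tz = "UTC")
  rows <- list(); starts <- c(); ends <- c(); members <- list()
  for (d in unique(day)) {
    idx <- which(day == d)
    ng <- length(idx) %/% w
    for (g in seq_len(ng)) {
      sel <- idx[((g - 1) * w + 1):(g * w)]
      rows[[length(rows) + 1]] <- B[sel, , drop = FALSE]
      starts <- c(starts, chunks$start[sel[1]])
      ends <- c(ends, chunks$end[sel[w]])
      members[[length(members) + 1]] <- sel
    }
  }
  list(rows = rows,
       start = as.POSIXct(starts, tz = "UTC", origin = "1970-01-01"),
       end = as.POSIXct(ends, tz = "UTC", origin = "1970-01-01"),
       window_index = members)
}

#' Flag scored windows by a score threshold
#'
#' @param scores numeric scores.
#' @param threshold flag abnormal iff score > threshold.
#' @return logical vector of predicted-abnormal flags.
#' @export
threshold_scores <- function(scores, threshold) {
  as.numeric(scores) > threshold
}

#' Per-class mean training confidences (classifier-wrapper thresholding)
#'
#' Supervised baselines flag a test instance as abnormal when its
#' classification confidence falls below (a fraction of) the mean training
#' confidence of its recognised class: `m_j = (1/N) sum_t p_t`.
#'
#' @param train_confidences named list, one numeric vector of training
#'   confidences per class (each non-empty).
#' @return named numeric vector of per-class means.
#' @export
mean_confidence_threshold <- function(train_confidences) {
  if (any(lengths(train_confidences) == 0)) {
    stop("empty confidence list for class(es): ",
         paste(names(train_confidences)[lengths(train_confidences) == 0],
               collapse = ", "))
  }
  vapply(train_confidences, mean, 0)
}

#' Flag test instances whose confidence undercuts the class mean
#'
#' @param confidence numeric vector of test confidences.
#' @param class character/factor vector of recognised classes.
#' @param means per-class mean confidences ([mean_confidence_threshold()]).
#' @param fraction scale applied to the class mean (sweeping it traces the
#'   ROC curve).
#' @return logical vector: abnormal iff `confidence < fraction * means[class]`.
#' @export
flag_low_confidence <- function(confidence, class, means, fraction = 1) {
  confidence < fraction * means[as.character(class)]
}
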