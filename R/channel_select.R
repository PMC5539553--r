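# Fisher's-criterion scoring of per-channel features and selection of
# best / worst channel configurations.

#' Labelled feature table
#'
#' @param values `trials x q` numeric matrix, one column per channel
#'   feature.
#' @param labels Class label per trial (exactly two classes, each with at
#'   least two trials).
#' @param channel_names Optional column labels (defaults to `V1..Vq`).
#' @return A `labelled_feature_table`.
#' @export
feature_table <- function(values, labels, channel_names = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || ncol(values) < 1)
    stop("'values' must be a numeric trials x q matrix")
  labels <- as.vector(labels)
  if (length(labels) != nrow(values))
    stop("one label per trial required")
  cls <- sort(unique(labels))
  if (length(cls) != 2) stop("exactly two classes required")
  if (any(table(labels) < 2))
    stop("each class needs at least 2 trials (within-class variance undefined otherwise)")
  if (is.null(channel_names))
    channel_names <- colnames(values)
  if (is.null(channel_names))
    channel_names <- paste0("V", seq_len(ncol(values)))
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  structure(list(values = values, labels = labels,
                 channel_names = channel_names, classes = cls),
            class = "labelled_feature_table")
}

#' Diagonals of the within- and between-class scatter matrices
#'
#' For classes `i = 1..c` with prior `P_i = n_i / sum(n_j)`:
#' `S_w(f) = sum_i P_i * (1/n_i) sum_j (x_ijf - m_if)^2` and
#' `S_b(f) = sum_i P_i * (m_if - m_f)^2`, where `m_i` is the class mean and
#' `m` the grand (prior-weighted) mean. Population (1/n) variances are used.
#'
#' @param table A [feature_table()].
#' @return List with numeric vectors `sw_diag` and `sb_diag` (length `q`).
#' @examples
#' tab <- feature_table(matrix(c(0, 2, 4, 6)), c(1, 1, 2, 2))
#' scatter_diagonals(tab)   # S_w = 1, S_b = 4
#' @export
scatter_diagonals <- function(table) {
  if (!inherits(table, "labelled_feature_table"))
    stop("'table' must come from feature_table()")
  x <- table$values
  lab <- table$labels
  n <- nrow(x)
  sw <- numeric(ncol(x))
  sb <- numeric(ncol(x))
  m_all <- colMeans(x)
  for (cl in table$classes) {
    xi <- x[lab == cl, , drop = FALSE]
    ni <- nrow(xi)
    Pi <- ni / n
    mi <- colMeans(xi)
    sw <- sw + Pi * colMeans(sweep(xi, 2, mi)^2)
    sb <- sb + Pi * (mi - m_all)^2
  }
  list(sw_diag = sw, sb_diag = sb)
}

#' Fisher scores and channel ranking
#'
#' `F(f) = S_b(f) / S_w(f)` per feature, with a small floor on `S_w` so
#' that zero within-class variance yields a large finite score instead of
#' an infinity. Ranking is by descending score with ties broken by
#' ascending column index.
#'
#' @param sw_diag,sb_diag Scatter diagonals from [scatter_diagonals()], or
#'   pass a [feature_table()] as `sw_diag` to compute both internally.
#' @param guard Floor on `S_w` (default 1e-12).
#' @param channel_names Optional labels for reporting.
#' @return A `fisher_ranking` with `scores`, `order` (permutation of
#'   `1..q`, best first), `sw_diag`, `sb_diag`, `guarded` (which columns
#'   hit the floor) and `channel_names`.
#' @export
fisher_scores <- function(sw_diag, sb_diag = NULL, guard = 1e-12,
                          channel_names = NULL) {
  if (inherits(sw_diag, "labelled_feature_table")) {
    tab <- sw_diag
    sd_ <- scatter_diagonals(tab)
    sw_diag <- sd_$sw_diag
    sb_diag <- sd_$sb_diag
    if (is.null(channel_names)) channel_names <- tab$channel_names
  }
  if (length(sw_diag) != length(sb_diag))
    stop("scatter diagonals must have the same length")
  stop_if_not_scalar_pos(guard, "guard")
  guarded <- sw_diag < guard
  scores <- sb_diag / pmax(sw_diag, guard)
  q <- length(scores)
  if (is.null(channel_names)) channel_names <- paste0("V", seq_len(q))
  structure(list(scores = scores,
                 order = order(-scores, seq_len(q)),
                 sw_diag = sw_diag, sb_diag = sb_diag, guarded = guarded,
                 channel_names = channel_names),
            class = "fisher_ranking")
}

#' @export
print.fisher_ranking <- function(x, ...) {
  k <- min(5L, length(x$scores))
  top <- x$order[seq_len(k)]
  cat(sprintf("Fisher ranking of %d channels; top %d: %s\n",
              length(x$scores), k,
              paste(sprintf("%s (%.4f)", x$channel_names[top],
                            x$scores[top]), collapse = ", ")))
  invisible(x)
}

#' Select best or worst channels from a Fisher ranking
#'
#' @param ranking A [fisher_scores()] ranking.
#' @param d Number of channels to select, `1 <= d <= q`.
#' @param mode `"top"` (highest scores first) or `"worst"` (lowest scores
#'   first).
#' @return Integer vector of channel indices, ordered by score (descending
#'   for `"top"`, ascending for `"worst"`), with channel names attached.
#' @export
select_channels <- function(ranking, d, mode = c("top", "worst")) {
  mode <- match.arg(mode)
  if (!inherits(ranking, "fisher_ranking"))
    stop("'ranking' must come from fisher_scores()")
  q <- length(ranking$scores)
  if (!is_count(d, 1) || d > q)
    stop(sprintf("invalid d: need 1 <= d <= %d", q))
  idx <- if (mode == "top") ranking$order[seq_len(d)]
         else rev(ranking$order)[seq_len(d)]
  names(idx) <- ranking$channel_names[idx]
  idx
}

#' Write a Fisher ranking as a delimited table
#'
#' Columns: channel, score, rank (1 = highest score).
#'
#' @param ranking A [fisher_scores()] ranking.
#' @param path Output file (tab-separated).
#' @return The table, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  rk <- integer(length(ranking$scores))
  rk[ranking$order] <- seq_along(ranking$order)
  tab <- data.frame(channel = ranking$channel_names,
                    score = ranking$scores, rank = rk)
  data.table::fwrite(tab, path, sep = "\t")
  invisible(tab)
}
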