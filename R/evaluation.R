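# Classifiers (K-NN, LDA), leave-one-out cross-validation, grid search,
# and the end-to-end pipeline evaluator over channel configurations.

#' Classifier specification
#'
#' @param kind `"knn"` or `"lda"`.
#' @param K Neighbor count for K-NN (default 1; odd values avoid vote
#'   ties).
#' @param shrinkage LDA pooled-covariance regularizer in `[0, 1]`
#'   (default 0; a small value is applied automatically if the pooled
#'   covariance is singular).
#' @param standardize Z-score features with training-fold statistics before
#'   classification (default `TRUE`; distance scales differ across feature
#'   types). Disable for raw-feature runs.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("knn", "lda"), K = 1, shrinkage = 0,
                            standardize = TRUE) {
  kind <- match.arg(kind)
  if (!is_count(K, 1)) stop("'K' must be a positive integer")
  if (!(is.numeric(shrinkage) && shrinkage >= 0 && shrinkage <= 1))
    stop("'shrinkage' must be in [0, 1]")
  structure(list(kind = kind, K = as.integer(K), shrinkage = shrinkage,
                 standardize = isTRUE(standardize)),
            class = "classifier_spec")
}

#' K-nearest-neighbor prediction for one query
#'
#' Majority label among the `K` Euclidean-nearest training points. Vote
#' ties are broken by the smaller mean distance to the query; a remaining
#' tie goes to the lower class (sorted order of the labels).
#'
#' @param train_x Training feature matrix (trials x features).
#' @param train_y Training labels.
#' @param query Feature vector (or matrix of queries, one per row).
#' @param K Neighbor count, `K <= nrow(train_x)`.
#' @return Predicted label(s).
#' @export
knn_predict <- function(train_x, train_y, query, K = 1) {
  train_x <- as.matrix(train_x)
  if (nrow(train_x) == 0) stop("empty training set")
  if (!is_count(K, 1) || K > nrow(train_x))
    stop("'K' must be a positive integer not exceeding the training size")
  qs <- if (is.matrix(query)) query
        else if (ncol(train_x) == 1) matrix(as.numeric(query), ncol = 1)
        else matrix(as.numeric(query), nrow = 1)
  if (ncol(qs) != ncol(train_x))
    stop("query dimension does not match the training features")
  classes <- sort(unique(train_y))
  out <- vapply(seq_len(nrow(qs)), function(i) {
    d <- sqrt(colSums((t(train_x) - as.numeric(qs[i, ]))^2))
    nb <- order(d, seq_along(d))[seq_len(K)]
    votes <- table(factor(train_y[nb], levels = classes))
    winners <- names(votes)[votes == max(votes)]
    if (length(winners) > 1) {
      md <- vapply(winners, function(cl)
        mean(d[nb][train_y[nb] == cl]), numeric(1))
      winners <- winners[md == min(md)]
    }
    winners[1]                     # lower class index on a residual tie
  }, character(1))
  if (is.numeric(train_y)) out <- as.numeric(out)
  if (length(out) == 1) out[[1]] else out
}

#' Linear discriminant analysis: fit on training data, predict queries
#'
#' Two-class LDA with pooled within-class covariance and equal priors
#' (classes are balanced by design in this protocol). A singular pooled
#' covariance with zero shrinkage triggers an automatic diagonal shrinkage
#' fallback, reported via the `shrinkage_used` attribute.
#'
#' @param train_x Training feature matrix (>= 2 trials per class).
#' @param train_y Training labels (two classes).
#' @param query Feature vector or matrix of queries.
#' @param shrinkage Covariance regularizer in `[0, 1]`.
#' @return Predicted label(s).
#' @export
lda_fit_predict <- function(train_x, train_y, query, shrinkage = 0) {
  train_x <- as.matrix(train_x)
  classes <- sort(unique(train_y))
  if (length(classes) != 2) stop("two-class LDA requires two classes")
  if (any(table(train_y) < 2)) stop("need at least 2 trials per class")
  x1 <- train_x[train_y == classes[1], , drop = FALSE]
  x2 <- train_x[train_y == classes[2], , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  n <- nrow(train_x)
  Sp <- (crossprod(sweep(x1, 2, m1)) + crossprod(sweep(x2, 2, m2))) / (n - 2)
  reg <- function(S, g) {
    scale <- mean(diag(S))
    if (scale <= 0) scale <- 1   # zero within-class scatter
    (1 - g) * S + g * scale * diag(nrow(S))
  }
  used <- shrinkage
  if (shrinkage > 0) Sp <- reg(Sp, shrinkage)
  w <- tryCatch(solve(Sp, m1 - m2), error = function(e) NULL)
  if (is.null(w) || rcond(Sp) < 1e-12) {
    used <- max(shrinkage, 1e-3)
    w <- solve(reg(Sp, used), m1 - m2)
  }
  qs <- if (is.matrix(query)) query
        else if (ncol(train_x) == 1) matrix(as.numeric(query), ncol = 1)
        else matrix(as.numeric(query), nrow = 1)
  score <- qs %*% w - sum((m1 + m2) / 2 * w)   # equal priors
  out <- ifelse(as.numeric(score) > 0, classes[1], classes[2])
  attr(out, "shrinkage_used") <- used
  if (length(out) == 1) {
    a <- attr(out, "shrinkage_used")
    out <- out[[1]]
    attr(out, "shrinkage_used") <- a
  }
  out
}

predict_with_spec <- function(spec, train_x, train_y, query) {
  if (spec$kind == "knn")
    knn_predict(train_x, train_y, query, K = spec$K)
  else
    lda_fit_predict(train_x, train_y, query, shrinkage = spec$shrinkage)
}

#' Leave-one-out cross-validation over a feature table
#'
#' One fold per trial: the held-out trial is predicted from all remaining
#' ones. Standardization (when the spec requests it) and, in nested mode,
#' Fisher channel selection are re-fit on each training fold so that no
#' information from the test trial enters the model.
#'
#' @param values Feature matrix (trials x features).
#' @param labels Class labels (two classes, >= 2 trials per class; at least
#'   3 trials overall).
#' @param spec A [classifier_spec()].
#' @param select_d Nested Fisher selection: keep the top `select_d`
#'   channels per fold (`NULL` = no selection).
#' @param select_mode `"top"` or `"worst"` for the nested selection.
#' @param channel_of Integer vector mapping each feature column to a
#'   channel (defaults to one column per channel). Channel scores for
#'   multi-column channels are the mean Fisher score of their columns.
#' @param channel_names Optional channel labels.
#' @return A `cv_report` with `accuracy`, `n_folds`, `per_fold`
#'   (data.frame with `truth` and `pred`), and the spec.
#' @export
loo_cv <- function(values, labels, spec = classifier_spec(),
                   select_d = NULL, select_mode = "top",
                   channel_of = NULL, channel_names = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (n < 3) stop("fewer than 3 trials: leave-one-out not meaningful")
  if (length(labels) != n) stop("one label per trial required")
  if (is.null(channel_of)) channel_of <- seq_len(ncol(values))
  preds <- vector(mode = typeof(labels), length = n)
  for (i in seq_len(n)) {
    tr_x <- values[-i, , drop = FALSE]
    tr_y <- labels[-i]
    te_x <- values[i, , drop = FALSE]
    if (!is.null(select_d)) {
      tab <- feature_table(tr_x, tr_y)
      fr <- fisher_scores(tab)
      ch_scores <- tapply(fr$scores, channel_of, mean)
      ord <- order(-ch_scores, as.integer(names(ch_scores)))
      keep_ch <- as.integer(names(ch_scores))[
        if (select_mode == "top") ord[seq_len(select_d)]
        else rev(ord)[seq_len(select_d)]]
      cols <- which(channel_of %in% keep_ch)
      tr_x <- tr_x[, cols, drop = FALSE]
      te_x <- te_x[, cols, drop = FALSE]
    }
    if (spec$standardize) {
      mu <- colMeans(tr_x)
      sg <- apply(tr_x, 2, stats::sd)
      sg[sg == 0] <- 1
      tr_x <- sweep(sweep(tr_x, 2, mu), 2, sg, "/")
      te_x <- sweep(sweep(te_x, 2, mu), 2, sg, "/")
    }
    preds[i] <- predict_with_spec(spec, tr_x, tr_y, te_x)
  }
  new_cv_report(labels, preds, spec)
}

new_cv_report <- function(truth, pred, spec, task = NA_character_,
                          feature_method = NA_character_,
                          channel_config = NA_character_,
                          chosen_params = list()) {
  structure(list(accuracy = mean(pred == truth), n_folds = length(truth),
                 per_fold = data.frame(truth = truth, pred = pred),
                 spec = spec, task = task, feature_method = feature_method,
                 channel_config = channel_config,
                 chosen_params = chosen_params),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("LOO-CV: accuracy %.2f%% over %d folds (%s%s%s)\n",
              100 * x$accuracy, x$n_folds, x$spec$kind,
              if (!is.na(x$feature_method))
                paste0(", ", x$feature_method) else "",
              if (!is.na(x$channel_config))
                paste0(", channels: ", x$channel_config) else ""))
  invisible(x)
}

#' Grid search over a parameter set
#'
#' Evaluates `objective(candidate)` (typically a LOO-CV accuracy) for every
#' candidate and returns the argmax; ties go to the smaller candidate
#' value. The full accuracy table is retained for reporting.
#'
#' @param candidates Numeric vector of parameter values (non-empty).
#' @param objective Function mapping one candidate to a scalar accuracy.
#' @return List with `best`, `best_value` and `table` (data.frame of
#'   candidate and accuracy).
#' @export
grid_search <- function(candidates, objective) {
  if (length(candidates) == 0) stop("empty candidate grid")
  ord <- order(candidates)
  cand <- candidates[ord]
  acc <- vapply(cand, function(p) objective(p), numeric(1))
  best <- cand[which.max(acc)]    # first max: smaller value wins ties
  list(best = best, best_value = max(acc),
       table = data.frame(candidate = cand, accuracy = acc))
}

# Per-trial, per-channel feature matrix for the unsupervised methods.
# Columns are grouped channel by channel; 'channel_of' maps columns to
# channels (AR contributes 'order' columns per channel).
session_features <- function(session, feature_method, tau = 50,
                             epsilon = 0.001, M_max = 50, kmax = 100,
                             band = band_def(8, 12), order = 4) {
  stopifnot(inherits(session, "epoch_set"))
  nt <- dim(session$data)[1]
  nc <- dim(session$data)[2]
  fs <- session$fs
  per_trial <- function(e) {
    switch(feature_method,
      gpfd = apply(e, 1, function(ch)
        gpfd(ch, tau = tau, epsilon = epsilon, M_max = M_max)$fd),
      hfd = apply(e, 1, function(ch) hfd(ch, kmax = kmax)$fd),
      bp = band_power(e, band, fs),
      ar = ar_features(e, order),
      stop("unsupported feature method: ", feature_method))
  }
  vals <- t(vapply(seq_len(nt),
                   function(i) per_trial(session$data[i, , , drop = TRUE]),
                   numeric(if (feature_method == "ar") nc * order else nc)))
  channel_of <- if (feature_method == "ar") rep(seq_len(nc), each = order)
                else seq_len(nc)
  list(values = vals, channel_of = channel_of)
}

csp_loo <- function(session, band, p, spec, channels = NULL) {
  dat <- session$data
  if (!is.null(channels)) dat <- dat[, channels, , drop = FALSE]
  nc <- dim(dat)[2]
  if (nc < 2)
    stop("at least two channels are required for CSP")
  n <- dim(dat)[1]
  labels <- session$labels
  classes <- sort(unique(labels))
  # filter once, covariances once; CSP per fold is then just an eigenproblem
  filt <- lapply(seq_len(n), function(i)
    butter_bandpass(dat[i, , , drop = TRUE], band$low, band$high,
                    session$fs))
  covs <- lapply(filt, trial_cov)
  preds <- vector(mode = typeof(labels), length = n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ia <- tr[labels[tr] == classes[1]]
    ib <- tr[labels[tr] == classes[2]]
    CA <- Reduce(`+`, covs[ia]) / length(ia)
    CB <- Reduce(`+`, covs[ib]) / length(ib)
    Cc <- CA + CB
    ec <- eigen(Cc, symmetric = TRUE)
    if (min(ec$values) < 1e-10 * max(ec$values)) {
      Cc <- (1 - 1e-6) * Cc + 1e-6 * mean(diag(Cc)) * diag(nc)
      ec <- eigen(Cc, symmetric = TRUE)
    }
    P <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)
    S <- P %*% CA %*% t(P)
    W <- t(eigen((S + t(S)) / 2, symmetric = TRUE)$vectors) %*% P
    sel <- c(seq_len(p), (nc - p + 1):nc)
    featf <- function(j) {
      z <- W %*% filt[[j]]
      v <- apply(z[sel, , drop = FALSE], 1, stats::var)
      log(v / sum(v))
    }
    tr_x <- t(vapply(tr, featf, numeric(2 * p)))
    te_x <- matrix(featf(i), nrow = 1)
    if (spec$standardize) {
      mu <- colMeans(tr_x); sg <- apply(tr_x, 2, stats::sd); sg[sg == 0] <- 1
      tr_x <- sweep(sweep(tr_x, 2, mu), 2, sg, "/")
      te_x <- sweep(sweep(te_x, 2, mu), 2, sg, "/")
    }
    preds[i] <- predict_with_spec(spec, tr_x, labels[tr], te_x)
  }
  new_cv_report(labels, preds, spec)
}

#' Evaluate a full feature / channel-selection / classifier pipeline
#'
#' Extracts per-channel features from a two-class epoch set, applies the
#' channel policy, and reports the leave-one-out cross-validated accuracy.
#' By default channel selection is nested inside the cross-validation
#' (re-ranked on every training fold, which is the statistically sound
#' placement); `paper_faithful = TRUE` instead scores channels once on all
#' trials before the CV, the common but optimistic variant, kept for
#' comparability.
#'
#' CSP is supervised, so its spatial filters (and features) are always
#' re-fit per fold; its channel policy, when not `"all"`, uses Fisher
#' scores of log band power in the CSP band to pick channels and requires
#' at least two of them.
#'
#' @param session An [epoch_set()] with exactly two classes.
#' @param feature_method One of `"gpfd"`, `"hfd"`, `"bp"`, `"ar"`, `"csp"`.
#' @param channel_policy `"all"`, or `list(mode = "top"|"worst", d = n)`.
#' @param spec A [classifier_spec()].
#' @param paper_faithful Score channels once on all trials (see above).
#' @param tau,epsilon,M_max GPFD parameters.
#' @param kmax HFD parameter.
#' @param band Band for `"bp"` (power band) and `"csp"` (filter band).
#' @param order AR model order.
#' @param p CSP filter pairs.
#' @return A `cv_report`.
#' @export
pipeline_evaluate <- function(session, feature_method = c("gpfd", "hfd",
                                                          "bp", "ar",
                                                          "csp"),
                              channel_policy = "all",
                              spec = classifier_spec(),
                              paper_faithful = FALSE,
                              tau = 50, epsilon = 0.001, M_max = 50,
                              kmax = 100, band = NULL, order = 4, p = 1) {
  feature_method <- match.arg(feature_method)
  stopifnot(inherits(session, "epoch_set"))
  if (length(unique(session$labels)) != 2)
    stop("pipeline_evaluate needs a two-class session")
  if (is.null(band))
    band <- if (feature_method == "csp") band_def(13, 30, "beta")
            else band_def(8, 12)
  policy_mode <- if (identical(channel_policy, "all")) "all"
                 else channel_policy$mode
  policy_d <- if (policy_mode == "all") NA_integer_ else channel_policy$d
  config <- if (policy_mode == "all") "all"
            else sprintf("%s%d", policy_mode, policy_d)

  if (feature_method == "csp") {
    if (policy_mode != "all" && policy_d < 2)
      stop("at least two channels are required for CSP")
    channels <- NULL
    if (policy_mode != "all") {
      bp_feats <- session_features(session, "bp", band = band)
      bp_tab <- feature_table(log(pmax(bp_feats$values, 1e-300)),
                              session$labels,
                              channel_names = session$channel_names)
      channels <- as.integer(select_channels(fisher_scores(bp_tab),
                                             policy_d, policy_mode))
    }
    rep_ <- csp_loo(session, band, p, spec, channels)
  } else {
    feats <- session_features(session, feature_method, tau = tau,
                              epsilon = epsilon, M_max = M_max, kmax = kmax,
                              band = band, order = order)
    if (policy_mode == "all") {
      rep_ <- loo_cv(feats$values, session$labels, spec)
    } else if (paper_faithful) {
      tab <- feature_table(feats$values, session$labels)
      fr <- fisher_scores(tab)
      ch_scores <- tapply(fr$scores, feats$channel_of, mean)
      ord <- order(-ch_scores, as.integer(names(ch_scores)))
      keep_ch <- as.integer(names(ch_scores))[
        if (policy_mode == "top") ord[seq_len(policy_d)]
        else rev(ord)[seq_len(policy_d)]]
      cols <- which(feats$channel_of %in% keep_ch)
      rep_ <- loo_cv(feats$values[, cols, drop = FALSE], session$labels,
                     spec)
    } else {
      rep_ <- loo_cv(feats$values, session$labels, spec,
                     select_d = policy_d, select_mode = policy_mode,
                     channel_of = feats$channel_of)
    }
  }
  rep_$task <- session$task
  rep_$feature_method <- feature_method
  rep_$channel_config <- config
  rep_$chosen_params <- list(tau = tau, epsilon = epsilon, M_max = M_max,
                             kmax = kmax, band = band$name, order = order,
                             p = p, paper_faithful = paper_faithful)
  rep_
}

#' Write a CV report as a delimited table
#'
#' @param report A `cv_report`.
#' @param path Output file (tab-separated); per-fold predictions with a
#'   header line of summary fields as comments.
#' @return The per-fold table, invisibly.
#' @export
write_cv_report <- function(report, path) {
  hdr <- sprintf(
    "# task=%s method=%s channels=%s classifier=%s accuracy=%.6f n_folds=%d",
    report$task, report$feature_method, report$channel_config,
    report$spec$kind, report$accuracy, report$n_folds)
  writeLines(hdr, path)
  data.table::fwrite(report$per_fold, path, sep = "\t", append = TRUE,
                     col.names = TRUE)
  invisible(report$per_fold)
}
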