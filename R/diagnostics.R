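#' Area under the ROC curve via the rank (Mann-Whitney) formula
#'
#' `AUC = (sum of positive ranks - n1 (n1 + 1) / 2) / (n1 n0)`, identical to
#' the Mann-Whitney U statistic normalized by `n1 n0` (ties handled by
#' midranks).
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param labels 0/1 or logical positive indicator.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) stop("AUC requires both classes present")
  r <- rank(scores)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUC for sweep detection
#'
#' Follows the published convention: selection classes (hard, soft) are
#' positive, linked and neutral classes negative. For model output the
#' sweep score is `P(hard) + P(soft)`; per-type curves use one-vs-rest with
#' the same negative set.
#'
#' @param scores per-case sweep scores (finite).
#' @param labels logical/0-1 positive-class indicator.
#' @return list `fpr`, `tpr` (threshold-sorted), `auc`.
#' @export
sweep_roc <- function(scores, labels) {
  stopifnot(all(is.finite(scores)))
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) stop("ROC requires both classes present")
  o <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[o] == 1L); fp <- cumsum(labels[o] == 0L)
  list(fpr = c(0, fp / sum(labels == 0L)), tpr = c(0, tp / sum(labels == 1L)),
       auc = auc_rank(scores, labels))
}

#' Sweep score and per-type ROC from 5-class probabilities
#'
#' @param probs 5 x N probability matrix with rows in [sweep_classes()]
#'   order.
#' @param truth factor/character true labels.
#' @return list `overall` (hard+soft vs rest), `hard`, `soft` (one-vs-rest
#'   against linked+neutral negatives, sweep cases of the other type
#'   excluded), each a [sweep_roc()] result.
#' @export
model_sweep_roc <- function(probs, truth) {
  truth <- as.character(truth)
  score <- probs["hard", ] + probs["soft", ]
  pos <- truth %in% c("hard", "soft")
  overall <- sweep_roc(score, pos)
  per_type <- function(type) {
    keep <- truth %in% c(type, "linked_hard", "linked_soft", "neutral")
    sweep_roc(probs[type, keep], truth[keep] == type)
  }
  list(overall = overall, hard = per_type("hard"), soft = per_type("soft"))
}

#' Extreme-statistic sweep score over the central region
#'
#' The comparison convention for classical single-statistic scans: the score
#' of a fragment is the extreme absolute value of one statistic row over the
#' positional intervals whose centers fall in `[0.45 L, 0.55 L]`.
#'
#' @param feature_grid `(nstat, m)` feature matrix (raw scale).
#' @param stat_name row name (registry key) to score.
#' @param names registry names for the rows.
#' @param central central fraction bounds (default `c(0.45, 0.55)`).
#' @return scalar score.
#' @export
extreme_stat_score <- function(feature_grid, stat_name, names,
                               central = c(0.45, 0.55)) {
  m <- ncol(feature_grid)
  centers <- (seq_len(m) - 0.5) / m
  j <- which(centers >= central[1] & centers <= central[2])
  max(abs(feature_grid[match(stat_name, names), j]))
}

#' Per-statistic two-sample mismatch tests
#'
#' For each feature, a two-sample Kolmogorov-Smirnov test and a
#' Mann-Whitney U test of source vs target values, with
#' Benjamini-Hochberg-adjusted q-values alongside the raw p-values.
#' Statistics constant on both sides are flagged and skipped.
#'
#' @param source_feats,target_feats case-by-feature matrices with matching
#'   columns (>= 20 rows each recommended).
#' @return data.frame: `stat`, `ks_d`, `ks_p`, `mwu_u`, `mwu_p`, `ks_q`,
#'   `mwu_q`, `skipped`.
#' @export
per_stat_mismatch <- function(source_feats, target_feats) {
  stopifnot(ncol(source_feats) == ncol(target_feats))
  nm <- colnames(source_feats)
  if (is.null(nm)) nm <- paste0("stat", seq_len(ncol(source_feats)))
  rows <- lapply(seq_len(ncol(source_feats)), function(j) {
    a <- source_feats[, j]; b <- target_feats[, j]
    if (stats::sd(c(a, b)) == 0)
      return(data.frame(stat = nm[j], ks_d = NA, ks_p = NA, mwu_u = NA,
                        mwu_p = NA, skipped = TRUE))
    ks <- suppressWarnings(stats::ks.test(a, b))
    mw <- suppressWarnings(stats::wilcox.test(a, b))
    data.frame(stat = nm[j], ks_d = unname(ks$statistic), ks_p = ks$p.value,
               mwu_u = unname(mw$statistic), mwu_p = mw$p.value,
               skipped = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ks_q <- stats::p.adjust(out$ks_p, "BH")
  out$mwu_q <- stats::p.adjust(out$mwu_p, "BH")
  out
}

#' Joint PCA of source and target features
#'
#' Components fitted on the pooled, centered feature matrix; inputs are
#' expected on a common scale already (max-min standardized feature
#' summaries), so no per-feature variance scaling is applied and a
#' domain shift on one feature surfaces as a leading component.
#'
#' @param source_feats,target_feats case-by-feature matrices.
#' @param n_components number of components (default 2).
#' @return list `scores` (pooled projections), `domain` (factor), `explained`
#'   (variance fractions, decreasing), `rotation`.
#' @export
joint_pca <- function(source_feats, target_feats, n_components = 2L) {
  pooled <- rbind(source_feats, target_feats)
  if (nrow(pooled) < n_components) stop("fewer samples than components")
  keep <- apply(pooled, 2, stats::sd) > 0
  pc <- stats::prcomp(pooled[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  k <- seq_len(min(n_components, ncol(pc$x)))
  list(scores = pc$x[, k, drop = FALSE],
       domain = factor(rep(c("source", "target"),
                           c(nrow(source_feats), nrow(target_feats)))),
       explained = (pc$sdev^2 / sum(pc$sdev^2))[k],
       rotation = pc$rotation[, k, drop = FALSE])
}

#' Cross-validated domain-classifier AUC
#'
#' An RBF-kernel support-vector machine is trained to tell source from
#' target cases; the k-fold cross-validated AUC of its decision values
#' measures domain mismatch (0.5 = indistinguishable). With
#' `shuffle_control`, the procedure is repeated on permuted domain labels as
#' a negative control.
#'
#' @param source_feats,target_feats case-by-feature matrices.
#' @param folds cross-validation folds (default 5).
#' @param seed fold-assignment / shuffle seed.
#' @param shuffle_control number of label-shuffle control repetitions
#'   (default 0).
#' @return list `auc`, `control_aucs`.
#' @export
domain_classifier_auc <- function(source_feats, target_feats, folds = 5L,
                                  seed = 1L, shuffle_control = 0L) {
  x <- rbind(source_feats, target_feats)
  y <- rep(c(0L, 1L), c(nrow(source_feats), nrow(target_feats)))
  cv_auc <- function(x, y, seed) {
    set.seed(seed)
    n <- length(y)
    fold <- sample(rep_len(seq_len(folds), n))
    # per-fold AUCs are averaged: decision values from different fold
    # models live on different scales and must not be rank-pooled
    aucs <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) {
        return(cv_auc(x, y, seed + 1L))   # degenerate fold: refold
      }
      fit <- e1071::svm(x[tr, , drop = FALSE], factor(y[tr], levels = c(0, 1)),
                        kernel = "radial", scale = FALSE)
      dv <- attr(stats::predict(fit, x[!tr, , drop = FALSE],
                                decision.values = TRUE), "decision.values")
      # orient decision values toward the target (label 1) class
      sc <- if (colnames(dv)[1] == "0/1") -dv[, 1] else dv[, 1]
      aucs[f] <- auc_rank(sc, y[!tr])
    }
    mean(aucs)
  }
  auc <- cv_auc(x, y, seed)
  controls <- if (shuffle_control > 0) {
    vapply(seq_len(shuffle_control), function(i) {
      set.seed(seed + 1000L + i)
      cv_auc(x, sample(y), seed + 2000L + i)
    }, numeric(1))
  } else numeric(0)
  list(auc = auc, control_aucs = controls)
}

#' 5-class confusion matrix
#'
#' Columns are true labels, rows predicted labels (the published heatmap
#' orientation); `rates` column-normalizes to fractions of each true class.
#'
#' @param predictions,truths factors/characters over [sweep_classes()].
#' @return list `counts` (5 x 5), `rates`, `per_class_accuracy`.
#' @export
confusion_5class <- function(predictions, truths) {
  cls <- sweep_classes()
  predictions <- as.character(predictions); truths <- as.character(truths)
  if (!all(predictions %in% cls) || !all(truths %in% cls))
    stop("unknown class label")
  counts <- table(factor(predictions, cls), factor(truths, cls))
  totals <- colSums(counts)
  rates <- sweep(counts, 2, pmax(totals, 1), "/")
  list(counts = unclass(counts), rates = unclass(rates),
       per_class_accuracy = diag(rates))
}

#' Domain-score histogram and alignment mass
#'
#' The fraction of target-domain discriminator scores below 0.5 summarizes
#' alignment: well-aligned target data looks source-like to the
#' discriminator, concentrating scores to the left of 0.5.
#'
#' @param domain_scores discriminator outputs in `[0, 1]`.
#' @param breaks histogram breaks (default 20 equal bins).
#' @return list `hist` (counts), `mids`, `mass_below_half`.
#' @export
domain_score_histogram <- function(domain_scores, breaks = seq(0, 1, 0.05)) {
  h <- graphics::hist(domain_scores, breaks = breaks, plot = FALSE)
  list(hist = h$counts, mids = h$mids,
       mass_below_half = mean(domain_scores < 0.5))
}
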