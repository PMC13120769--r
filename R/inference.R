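#' Spearman rank correlation between a pairwise metric and the true overlap
#'
#' Correlates the off-diagonal upper-triangle entries (i < j) of a pairwise
#' measure with the corresponding entries of the ground-truth
#' resource-utilization overlap, using Spearman's rank correlation with the
#' standard large-sample p-value.
#'
#' @param metric A `metric_matrix` (or plain symmetric matrix).
#' @param overlap Ground-truth overlap matrix of the same dimension.
#' @return A list with `rho` and `p_value`.
#' @export
spearman_vs_overlap <- function(metric, overlap) {
  m <- as.matrix(metric); o <- as.matrix(overlap)
  if (!all(dim(m) == dim(o)))
    stop_ecoguilds("metric and overlap dimensions differ",
                   class = "ecoguilds_data_error")
  x <- upper_pairs(m); y <- upper_pairs(o)
  if (length(x) < 3)
    stop_ecoguilds("need at least 3 species pairs",
                   class = "ecoguilds_data_error")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Threshold a pairwise metric into an undirected link adjacency
#'
#' A link is placed between every pair whose metric value is strictly greater
#' than the threshold; the diagonal is excluded.
#'
#' @param metric A `metric_matrix` or symmetric matrix.
#' @param threshold Threshold value.
#' @return A binary N x N adjacency matrix with zero diagonal.
#' @export
threshold_links <- function(metric, threshold) {
  m <- as.matrix(metric)
  adj <- (m > threshold) * 1L
  diag(adj) <- 0L
  adj
}

#' Single-linkage guild partition from a link adjacency
#'
#' In `"full"` mode species are grouped by the transitive closure of the links
#' (connected components): if i-j and j-k are linked, all three share a guild.
#' In `"one_iteration"` mode the closure is run for a single round only, so
#' two species count as same-guild if they are linked directly or share a
#' common direct neighbor; this relation is not transitive and is returned as
#' a pair relation rather than labels.
#'
#' @param links Binary adjacency matrix (from [threshold_links()]).
#' @param mode `"full"` or `"one_iteration"`.
#' @return An object of class `guild_partition`: list with `labels` (full mode
#'   only, else `NULL`), `pair_same` (logical N x N pair relation), `mode`,
#'   and `n_clusters` (full mode).
#' @export
single_linkage_partition <- function(links, mode = c("full", "one_iteration")) {
  mode <- match.arg(mode)
  A <- as.matrix(links)
  n <- nrow(A)
  if (mode == "full") {
    g <- igraph::graph_from_adjacency_matrix(A != 0, mode = "undirected")
    labels <- igraph::components(g)$membership
    pair_same <- outer(labels, labels, "==")
    diag(pair_same) <- TRUE
    structure(list(labels = as.integer(labels), pair_same = pair_same,
                   mode = mode, n_clusters = length(unique(labels))),
              class = "guild_partition")
  } else {
    direct <- A != 0
    shared <- (direct %*% direct) > 0   # common direct neighbor
    pair_same <- direct | shared
    diag(pair_same) <- TRUE
    structure(list(labels = NULL, pair_same = pair_same, mode = mode,
                   n_clusters = NA_integer_),
              class = "guild_partition")
  }
}

#' @export
print.guild_partition <- function(x, ...) {
  cat("<guild_partition> mode =", x$mode,
      if (!is.na(x$n_clusters)) paste0(", ", x$n_clusters, " clusters"), "\n")
  invisible(x)
}

# Threshold sweep shared by the ROC tasks: evenly spaced thresholds spanning
# the off-diagonal metric range, plus +/-Inf endpoints.
threshold_sweep <- function(metric, n_thresholds = 200) {
  vals <- upper_pairs(as.matrix(metric))
  c(-Inf, seq(min(vals), max(vals), length.out = n_thresholds), Inf)
}

roc_from_points <- function(fpr, tpr, thresholds, task) {
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]; thresholds <- thresholds[ord]
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(thresholds = thresholds, fpr = fpr, tpr = tpr,
                 auc = auc, task = task),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result>", x$task, "detection, AUC =", round(x$auc, 4), "over",
      length(x$thresholds), "thresholds\n")
  invisible(x)
}

#' @describeIn link_roc Tidy an ROC result to a tibble of sweep points.
#' @param x A `roc_result`.
#' @param ... Unused.
#' @export
tidy.roc_result <- function(x, ...) {
  tibble::tibble(task = x$task, threshold = x$thresholds,
                 fpr = x$fpr, tpr = x$tpr)
}

#' @describeIn link_roc One-row summary (task, AUC, sweep size).
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(task = x$task, auc = x$auc,
                 n_thresholds = length(x$thresholds))
}

#' ROC for link detection against the true resource overlap
#'
#' Ground truth: a species pair interacts if its off-diagonal overlap entry is
#' strictly positive (tolerance 1e-12). The metric is swept over evenly spaced
#' thresholds spanning its off-diagonal range (plus infinite endpoints), each
#' pair with metric above threshold is predicted as linked, and TPR/FPR are
#' accumulated into an ROC with trapezoidal AUC.
#'
#' @param metric A `metric_matrix` or symmetric matrix of pair scores.
#' @param overlap Ground-truth overlap matrix (same dimension).
#' @param n_thresholds Number of interior thresholds in the sweep.
#' @return A `roc_result` (thresholds, fpr, tpr, auc, task = "link").
#' @export
link_roc <- function(metric, overlap, n_thresholds = 200) {
  scores <- upper_pairs(as.matrix(metric))
  truth <- upper_pairs(as.matrix(overlap)) > 1e-12
  if (all(truth) || !any(truth))
    warning("degenerate ground truth: all pairs ",
            if (all(truth)) "linked" else "unlinked")
  ths <- threshold_sweep(metric, n_thresholds)
  tpr <- vapply(ths, function(th) mean(scores[truth] > th), numeric(1))
  fpr <- if (any(!truth))
    vapply(ths, function(th) mean(scores[!truth] > th), numeric(1))
  else rep(0, length(ths))
  roc_from_points(fpr, tpr, ths, "link")
}

#' ROC for guild detection via single-linkage clustering
#'
#' For each threshold in the sweep the metric is thresholded into links, the
#' links are closed into a partition by single-linkage clustering (full
#' transitive closure, or one merging iteration), and every species pair is
#' classified as same- versus different-cluster. Comparing against the true
#' guild labels over the sweep yields the ROC and its trapezoidal AUC.
#'
#' @param metric A `metric_matrix` or symmetric matrix.
#' @param true_labels Integer vector of ground-truth guild ids.
#' @param mode Clustering mode, see [single_linkage_partition()].
#' @param n_thresholds Number of interior thresholds in the sweep.
#' @return A `roc_result` with task `"guild"`.
#' @export
guild_roc <- function(metric, true_labels, mode = c("full", "one_iteration"),
                      n_thresholds = 200) {
  mode <- match.arg(mode)
  m <- as.matrix(metric)
  n <- nrow(m)
  stopifnot(length(true_labels) == n)
  truth <- upper_pairs(outer(true_labels, true_labels, "=="))
  if (all(truth) || !any(truth))
    warning("degenerate ground truth: a single guild")
  ths <- threshold_sweep(metric, n_thresholds)
  pred <- guild_pair_predictions(m, ths, mode)
  tpr <- colMeans(pred[truth, , drop = FALSE])
  fpr <- if (any(!truth)) colMeans(pred[!truth, , drop = FALSE])
         else rep(0, length(ths))
  roc_from_points(fpr, tpr, ths, "guild")
}

# Same-cluster predictions for every unordered pair (rows) at every threshold
# (columns). The partition only changes when the threshold crosses a metric
# value, so one partition per equivalence class is computed and looked up.
guild_pair_predictions <- function(m, ths, mode = "full") {
  vals <- sort(unique(upper_pairs(m)))
  class_of <- findInterval(ths, vals)            # 0 .. length(vals)
  reps <- c(vals[1] - 1, vals)                   # representative thresholds
  by_class <- lapply(unique(class_of), function(k) {
    part <- single_linkage_partition(threshold_links(m, reps[k + 1]), mode)
    upper_pairs(part$pair_same)
  })
  names(by_class) <- as.character(unique(class_of))
  pred <- vapply(as.character(class_of), function(k) by_class[[k]],
                 logical(choose(nrow(m), 2)))
  dimnames(pred) <- NULL
  pred
}

#' ROC for guild detection pooled over realizations
#'
#' Pools the same-cluster predictions of several independent realizations into
#' one ROC: a common threshold sweep spans the pooled score range, each
#' realization's metric is clustered per threshold, and TPR/FPR are computed
#' over the pooled species pairs. This is the pooling convention for ensembles
#' of communities; [guild_roc()] scores a single realization (averaging those
#' AUCs is the alternative convention).
#'
#' @param metrics List of `metric_matrix` objects, one per realization.
#' @param label_list List of ground-truth guild-label vectors, matching
#'   `metrics`.
#' @param mode Clustering mode, see [single_linkage_partition()].
#' @param n_thresholds Number of interior thresholds in the sweep.
#' @return A `roc_result` with task `"guild"`.
#' @export
pooled_guild_roc <- function(metrics, label_list, mode = c("full", "one_iteration"),
                             n_thresholds = 200) {
  mode <- match.arg(mode)
  stopifnot(length(metrics) == length(label_list), length(metrics) >= 1)
  ms <- lapply(metrics, as.matrix)
  all_vals <- unlist(lapply(ms, upper_pairs))
  ths <- c(-Inf, seq(min(all_vals), max(all_vals), length.out = n_thresholds),
           Inf)
  truth <- unlist(lapply(seq_along(ms), function(r) {
    lab <- label_list[[r]]
    stopifnot(length(lab) == nrow(ms[[r]]))
    upper_pairs(outer(lab, lab, "=="))
  }))
  if (all(truth) || !any(truth))
    warning("degenerate ground truth: a single guild")
  pred <- do.call(rbind, lapply(ms, guild_pair_predictions, ths = ths,
                                mode = mode))
  tpr <- colMeans(pred[truth, , drop = FALSE])
  fpr <- if (any(!truth)) colMeans(pred[!truth, , drop = FALSE])
         else rep(0, length(ths))
  roc_from_points(fpr, tpr, ths, "guild")
}

#' Per-guild local detectability
#'
#' For one guild: the true positive rate is the fraction of its
#' `N_k (N_k - 1)/2` within-guild pairs that carry a detected link (or
#' same-cluster relation), and the false positive rate is the fraction of
#' pairs joining a guild member to an outside species that are falsely
#' linked.
#'
#' @param links Binary adjacency (from [threshold_links()]) or a
#'   `guild_partition` (its pair relation is used).
#' @param true_labels Ground-truth guild ids.
#' @param guild_id Guild to score (must have at least 2 members).
#' @return A list with `tpr` and `fpr`.
#' @export
local_detectability <- function(links, true_labels, guild_id) {
  rel <- if (inherits(links, "guild_partition")) links$pair_same
         else as.matrix(links) != 0
  members <- which(true_labels == guild_id)
  if (length(members) < 2)
    stop_ecoguilds("guild ", guild_id, " has fewer than 2 members",
                   class = "ecoguilds_data_error")
  outside <- which(true_labels != guild_id)
  within <- rel[members, members, drop = FALSE]
  tpr <- mean(within[upper.tri(within)])
  fpr <- if (length(outside)) mean(rel[members, outside, drop = FALSE]) else 0
  list(tpr = tpr, fpr = fpr)
}
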