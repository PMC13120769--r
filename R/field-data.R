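#' Build an abundance table from a replicated long-format table
#'
#' Takes per-day replicate measurements (e.g. three samples per OTU per day)
#' and averages replicates within each day, returning a taxa-by-day matrix
#' wrapped with metadata. Every taxon must be observed on every day: the
#' spectral pipeline requires consecutive, evenly spaced time points and does
#' not impute missing days.
#'
#' @param table A data frame (or TSV/CSV path) with columns `taxon`, `day`,
#'   `abundance`, and optionally `replicate`.
#' @param is_relative Whether values are relative abundances.
#' @return An object of class `abundance_table`: list with `values` (taxa x
#'   day matrix), `taxa`, `days`, `is_relative`.
#' @export
load_and_average <- function(table, is_relative = TRUE) {
  if (is.character(table)) {
    sep <- if (grepl("\\.csv$", table)) "," else "\t"
    table <- read.delim(table, sep = sep, check.names = FALSE)
  }
  table <- tibble::as_tibble(table)
  need <- c("taxon", "day", "abundance")
  if (!all(need %in% names(table)))
    stop_ecoguilds("table needs columns: ", paste(need, collapse = ", "),
                   class = "ecoguilds_data_error")
  avg <- table |>
    dplyr::group_by(.data$taxon, .data$day) |>
    dplyr::summarise(abundance = mean(.data$abundance), .groups = "drop")
  days <- sort(unique(avg$day))
  taxa <- sort(unique(avg$taxon))
  missing <- avg |>
    tidyr::complete(taxon = taxa, day = days) |>
    dplyr::filter(is.na(.data$abundance))
  if (nrow(missing) > 0)
    stop_ecoguilds("missing day/taxon combinations (the method does not ",
                   "handle missing time points): ",
                   paste(head(paste(missing$taxon, missing$day, sep = "@"), 10),
                         collapse = ", "),
                   class = "ecoguilds_data_error")
  wide <- tidyr::pivot_wider(avg, names_from = "day",
                             values_from = "abundance")
  values <- as.matrix(wide[, -1])
  rownames(values) <- wide$taxon
  values <- values[, order(as.numeric(colnames(values)))]
  d <- diff(as.numeric(colnames(values)))
  if (length(d) && any(abs(d - d[1]) > 1e-9))
    stop_ecoguilds("days are not equally spaced: gaps at ",
                   paste(head(colnames(values)[-1][abs(d - d[1]) > 1e-9], 5),
                         collapse = ", "),
                   class = "ecoguilds_data_error")
  structure(list(values = values, taxa = rownames(values),
                 days = as.numeric(colnames(values)),
                 is_relative = is_relative),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("<abundance_table>", nrow(x$values), "taxa x", ncol(x$values), "days",
      if (x$is_relative) "(relative)" else "(absolute)", "\n")
  invisible(x)
}

#' Keep only taxa present at every time point
#'
#' Retains taxa with strictly positive abundance on every day; zeros cannot be
#' log-transformed and the method was developed for series without them.
#'
#' @param table An `abundance_table`.
#' @return A filtered `abundance_table`.
#' @export
filter_always_present <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  keep <- apply(table$values > 0, 1, all)
  if (!any(keep))
    stop_ecoguilds("no taxon is present at every time point",
                   class = "ecoguilds_data_error")
  table$values <- table$values[keep, , drop = FALSE]
  table$taxa <- rownames(table$values)
  table
}

#' Jukes-Cantor distances from pre-aligned sequences
#'
#' Computes the pairwise proportion `p` of differing sites over comparable
#' (non-gap, unambiguous) positions of a fixed alignment and maps it to the
#' Jukes-Cantor distance `d = -(3/4) ln(1 - (4/3) p)` (via `ape::dist.dna`,
#' pairwise deletion). Pairs with `p >= 3/4` have no defined distance and
#' raise an error naming the offending pairs.
#'
#' @param alignment A path to an aligned FASTA file, a `DNAbin` matrix, or a
#'   named character vector of equal-length aligned sequences.
#' @return A symmetric `dist`-free matrix of distances with taxa dimnames.
#' @export
jukes_cantor <- function(alignment) {
  if (is.character(alignment) && length(alignment) == 1 && file.exists(alignment)) {
    alignment <- ape::read.FASTA(alignment)
  }
  if (is.character(alignment)) {
    lens <- nchar(alignment)
    if (length(unique(lens)) != 1)
      stop_ecoguilds("aligned sequences must have equal length",
                     class = "ecoguilds_data_error")
    alignment <- ape::as.DNAbin(t(sapply(strsplit(tolower(alignment), ""),
                                         identity)))
  }
  if (is.list(alignment)) alignment <- ape::as.matrix.DNAbin(alignment)
  d <- as.matrix(ape::dist.dna(alignment, model = "JC69",
                               pairwise.deletion = TRUE))
  bad <- which(!is.finite(d) & upper.tri(d), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_ecoguilds("Jukes-Cantor distance undefined (p >= 3/4 or no ",
                   "comparable sites) for pairs: ",
                   paste(apply(head(bad, 5), 1, function(r)
                     paste(rownames(d)[r[1]], rownames(d)[r[2]], sep = "-")),
                     collapse = ", "),
                   class = "ecoguilds_data_error")
  d
}

# Assign upper-triangle pairs to equal-width distance bins over the observed
# range; returns list(bin per pair, edges).
assign_distance_bins <- function(dist, n_bins) {
  dvals <- upper_pairs(as.matrix(dist))
  edges <- seq(min(dvals), max(dvals), length.out = n_bins + 1)
  bin <- findInterval(dvals, edges, rightmost.closed = TRUE)
  bin[bin > n_bins] <- n_bins
  list(bin = bin, edges = edges)
}

#' Bin a pairwise metric by phylogenetic distance
#'
#' Pairs (i < j) are assigned to `n_bins` equal-width bins of the observed
#' distance range; the mean and standard deviation of the metric are reported
#' per bin. Empty bins are kept with `NA` summaries.
#'
#' @param metric A `metric_matrix` or symmetric matrix over the same taxa as
#'   `dist`.
#' @param dist Symmetric distance matrix.
#' @param n_bins Number of equal-width bins (default 8).
#' @return An object of class `binned_association`: tibble of per-bin
#'   summaries (`bin`, `lower`, `upper`, `midpoint`, `n_pairs`, `mean`, `sd`)
#'   with the bin edges as an attribute.
#' @export
bin_metric_by_distance <- function(metric, dist, n_bins = 8) {
  m <- as.matrix(metric); d <- as.matrix(dist)
  if (!all(dim(m) == dim(d)))
    stop_ecoguilds("metric and distance matrices must match",
                   class = "ecoguilds_data_error")
  ab <- assign_distance_bins(d, n_bins)
  mvals <- upper_pairs(m)
  out <- tibble::tibble(bin = seq_len(n_bins),
                        lower = ab$edges[-length(ab$edges)],
                        upper = ab$edges[-1]) |>
    dplyr::mutate(midpoint = (.data$lower + .data$upper) / 2)
  stats_by <- lapply(seq_len(n_bins), function(b) {
    v <- mvals[ab$bin == b]
    c(n = length(v),
      mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) > 1) sd(v) else NA_real_)
  })
  out$n_pairs <- vapply(stats_by, `[[`, numeric(1), "n")
  out$mean <- vapply(stats_by, `[[`, numeric(1), "mean")
  out$sd <- vapply(stats_by, `[[`, numeric(1), "sd")
  structure(out, edges = ab$edges, metric = attr(metric, "metric"),
            class = c("binned_association", class(out)))
}

#' Index-shuffle null model for the distance-binned metric
#'
#' Destroys any association between the pairwise metric and the distances by
#' jointly permuting the rows and columns of the metric matrix (preserving the
#' multiset of metric values exactly), recomputing the per-bin means for each
#' shuffle, and reporting the upper-tail p-value for the first (smallest
#' distance) bin: the proportion of shuffles whose first-bin mean is strictly
#' larger than the observed one.
#'
#' @inheritParams bin_metric_by_distance
#' @param n_shuffles Number of random permutations (the reference analysis
#'   uses 1e5).
#' @param seed Seed for the permutations.
#' @param add_one If TRUE use the (b+1)/(n+1) corrected estimator; the default
#'   is the raw proportion.
#' @return A `binned_association` tibble with added columns `null_mean` and
#'   `null_sd` per bin, plus attributes `first_bin_p`, `first_bin_null`
#'   (vector of shuffled first-bin means) and `observed_first_bin`.
#' @export
index_shuffle_null <- function(metric, dist, n_bins = 8, n_shuffles = 1000,
                               seed = NULL, add_one = FALSE) {
  m <- as.matrix(metric); d <- as.matrix(dist)
  n <- nrow(m)
  obs <- bin_metric_by_distance(metric, dist, n_bins)
  ab <- assign_distance_bins(d, n_bins)
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  null_means <- with_seed(
    if (is.null(seed)) NULL else derive_seed(seed, "index-shuffle"), {
      vapply(seq_len(n_shuffles), function(s) {
        perm <- sample.int(n)
        vals <- m[cbind(perm[pairs[, 1]], perm[pairs[, 2]])]
        vapply(seq_len(n_bins), function(b) {
          v <- vals[ab$bin == b]
          if (length(v)) mean(v) else NA_real_
        }, numeric(1))
      }, numeric(n_bins))
    })
  null_means <- matrix(null_means, nrow = n_bins)   # n_bins x n_shuffles
  first_null <- null_means[1, ]
  b <- sum(first_null > obs$mean[1], na.rm = TRUE)
  p <- if (add_one) (b + 1) / (n_shuffles + 1) else b / n_shuffles
  obs$null_mean <- rowMeans(null_means, na.rm = TRUE)
  obs$null_sd <- apply(null_means, 1, sd, na.rm = TRUE)
  attr(obs, "first_bin_p") <- p
  attr(obs, "first_bin_null") <- first_null
  attr(obs, "observed_first_bin") <- obs$mean[1]
  attr(obs, "n_shuffles") <- n_shuffles
  obs
}

#' Find the threshold yielding a target number of clusters
#'
#' Binary-searches the sorted unique off-diagonal metric values for a
#' threshold whose full single-linkage partition has exactly `k_target`
#' clusters (including singletons); the cluster count is non-increasing as the
#' threshold decreases. If ties make the exact count unreachable, the nearest
#' achievable partition is returned with a warning.
#'
#' @param metric A `metric_matrix` or symmetric matrix.
#' @param k_target Desired number of clusters, `1 <= k_target <= N`.
#' @return A `guild_partition` (full mode) with an added `threshold` element.
#' @export
cluster_to_k <- function(metric, k_target) {
  m <- as.matrix(metric)
  n <- nrow(m)
  if (k_target < 1 || k_target > n)
    stop_ecoguilds("k_target must lie in [1, N]", class = "ecoguilds_data_error")
  vals <- sort(unique(upper_pairs(m)))
  count_at <- function(th)
    single_linkage_partition(threshold_links(m, th))$n_clusters
  # candidate thresholds: just below each unique value, plus above the max
  cands <- c(vals - .Machine$double.eps^0.5 * pmax(1, abs(vals)), max(vals) + 1)
  lo <- 1L; hi <- length(cands)
  while (lo < hi) {          # counts are non-decreasing along cands
    mid <- (lo + hi) %/% 2L
    if (count_at(cands[mid]) < k_target) lo <- mid + 1L else hi <- mid
  }
  th <- cands[lo]
  part <- single_linkage_partition(threshold_links(m, th))
  if (part$n_clusters != k_target)
    warning("exact cluster count ", k_target, " unreachable due to ties; ",
            "returning nearest achievable (", part$n_clusters, ")")
  part$threshold <- th
  part
}
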