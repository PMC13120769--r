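# Small synthetic field data set shared across blocks: 8 taxa, 120 days,
# 3 replicates, two "ecotypes" whose sequences and dynamics both cluster.
# Each ecotype tracks its own broadband AR(1) environmental signal.
make_field_fixture <- function() {
  set.seed(101)
  taxa <- paste0("otu", 1:8)
  days <- 1:120
  group <- rep(1:2, each = 4)
  shared <- rbind(as.numeric(arima.sim(list(ar = 0.8), 120)),
                  as.numeric(arima.sim(list(ar = 0.8), 120)))
  values <- exp(shared[group, ] + 0.4 * matrix(rnorm(8 * 120), 8)) + 0.01
  long <- do.call(rbind, lapply(1:3, function(rep) {
    data.frame(taxon = rep(taxa, times = 120),
               day = rep(days, each = 8),
               replicate = rep,
               abundance = as.vector(values) * exp(rnorm(960, 0, 0.05)))
  }))
  base <- paste(rep(c("a", "c", "g", "t"), 25), collapse = "")
  mutate_at <- function(s, pos, to) {
    v <- strsplit(s, "")[[1]]; v[pos] <- to; paste(v, collapse = "")
  }
  seqs <- vapply(1:8, function(i) {
    s <- base
    if (group[i] == 2) s <- mutate_at(s, 1:20, "t")   # deep split
    mutate_at(s, 90 + i, "g")                          # shallow within-group
  }, character(1))
  names(seqs) <- taxa
  list(long = long, seqs = seqs, group = group, taxa = taxa)
}

test_that("load_and_average averages replicates into a taxa-by-day matrix", {
  fx <- make_field_fixture()
  tab <- load_and_average(fx$long)
  expect_s3_class(tab, "abundance_table")
  expect_equal(dim(tab$values), c(8, 120))
  expect_equal(tab$days, 1:120)
  # replicate averaging oracle for one cell
  sub <- subset(fx$long, taxon == "otu3" & day == 7)
  expect_equal(tab$values["otu3", "7"], mean(sub$abundance))
  # a TSV path round-trips to the same table
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(fx$long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(load_and_average(path)$values, tab$values)
})

test_that("load_and_average rejects missing combos and uneven spacing", {
  fx <- make_field_fixture()
  # a taxon-day combination missing from every replicate
  holey <- subset(fx$long, !(taxon == "otu1" & day == 1))
  expect_error(load_and_average(holey), class = "ecoguilds_data_error")
  expect_error(load_and_average(fx$long[, -1]),
               class = "ecoguilds_data_error")
  gappy <- subset(fx$long, day != 5)
  expect_error(load_and_average(gappy), class = "ecoguilds_data_error")
})

test_that("filter_always_present drops taxa with zeros", {
  fx <- make_field_fixture()
  tab <- load_and_average(fx$long)
  tab$values["otu2", 10] <- 0
  kept <- filter_always_present(tab)
  expect_identical(kept$taxa, setdiff(fx$taxa, "otu2"))
  tab$values[] <- 0
  expect_error(filter_always_present(tab), class = "ecoguilds_data_error")
})

test_that("Jukes-Cantor distance matches the closed form", {
  # 100 aligned sites, 24 differences: p = 0.24
  a <- paste(rep("a", 100), collapse = "")
  b <- paste(c(rep("c", 24), rep("a", 76)), collapse = "")
  d <- jukes_cantor(c(x = a, y = b))
  expect_equal(d["x", "y"], -3 / 4 * log(1 - 4 * 0.24 / 3))
  expect_equal(unname(diag(d)), c(0, 0))
  # p = 0.3 oracle value
  b2 <- paste(c(rep("c", 30), rep("a", 70)), collapse = "")
  expect_equal(jukes_cantor(c(x = a, y = b2))["x", "y"],
               -0.75 * log(1 - 0.4), tolerance = 1e-12)
  # saturated pairs (p >= 3/4) are an error, not NaN
  bad <- paste(c(rep("c", 80), rep("a", 20)), collapse = "")
  expect_error(jukes_cantor(c(x = a, y = bad)), class = "ecoguilds_data_error")
  expect_error(jukes_cantor(c(x = a, y = substr(a, 1, 50))),
               class = "ecoguilds_data_error")
})

test_that("jukes_cantor reads FASTA files and uses pairwise deletion", {
  fx <- make_field_fixture()
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(fx$seqs), function(nm)
    c(paste0(">", nm), fx$seqs[[nm]]))), path)
  d <- jukes_cantor(path)
  expect_identical(rownames(d), fx$taxa)
  # within-group pairs are closer than cross-group pairs
  same <- outer(fx$group, fx$group, "==") & upper.tri(d)
  cross <- outer(fx$group, fx$group, "!=") & upper.tri(d)
  expect_lt(max(d[same]), min(d[cross]))
  # gap positions are excluded pairwise: distance unchanged by trailing gaps
  gapped <- fx$seqs
  gapped[1] <- paste0(substr(gapped[1], 1, 95), "-----")
  d2 <- jukes_cantor(gapped)
  expect_lt(abs(d2[1, 2] - d[1, 2]), 0.01)
})

test_that("bin_metric_by_distance reproduces a hand-binned oracle", {
  set.seed(3)
  n <- 10
  m <- matrix(rnorm(n * n), n); m <- (m + t(m)) / 2; diag(m) <- 1
  d <- as.matrix(dist(matrix(runif(n * 2), n)))
  b <- bin_metric_by_distance(m, d, n_bins = 4)
  expect_s3_class(b, "binned_association")
  expect_equal(nrow(b), 4)
  expect_equal(sum(b$n_pairs), choose(n, 2))
  edges <- attr(b, "edges")
  dv <- d[upper.tri(d)]; mv <- m[upper.tri(m)]
  for (k in 1:4) {
    inb <- dv >= edges[k] & (if (k == 4) dv <= edges[5] else dv < edges[k + 1])
    expect_equal(b$n_pairs[k], sum(inb))
    if (sum(inb)) expect_equal(b$mean[k], mean(mv[inb]))
  }
  expect_equal(b$midpoint, (b$lower + b$upper) / 2)
  expect_error(bin_metric_by_distance(m, d[1:5, 1:5]),
               class = "ecoguilds_data_error")
})

test_that("index shuffle preserves the value multiset and calibrates", {
  set.seed(4)
  n <- 9
  m <- matrix(rnorm(n * n), n); m <- (m + t(m)) / 2
  d <- as.matrix(dist(matrix(runif(n * 2), n)))
  # a single bin contains all pairs: every shuffle reproduces the same mean
  b1 <- index_shuffle_null(m, d, n_bins = 1, n_shuffles = 50, seed = 1)
  expect_equal(unique(attr(b1, "first_bin_null")),
               attr(b1, "observed_first_bin"))
  expect_equal(attr(b1, "first_bin_p"), 0)   # never strictly larger
  # under a null metric the p-value is approximately uniform:
  # estimate the p-value distribution over independent data sets
  ps <- vapply(1:40, function(i) {
    mm <- matrix(rnorm(n * n), n); mm <- (mm + t(mm)) / 2
    attr(index_shuffle_null(mm, d, n_bins = 3, n_shuffles = 200, seed = i),
         "first_bin_p")
  }, numeric(1))
  expect_gt(mean(ps), 0.3); expect_lt(mean(ps), 0.7)
  expect_gt(sum(ps < 0.25), 2)
  expect_gt(sum(ps > 0.75), 2)
})

test_that("shuffle estimator agrees with exhaustive permutation at N = 5", {
  set.seed(6)
  n <- 5
  m <- matrix(rnorm(n * n), n); m <- (m + t(m)) / 2
  d <- as.matrix(dist(matrix(runif(n * 2), n)))
  ab <- ecoguilds:::assign_distance_bins(d, 2)
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  obs <- bin_metric_by_distance(m, d, 2)$mean[1]
  perms <- perms_of(n)
  exact_means <- apply(perms, 1, function(p) {
    vals <- m[cbind(p[pairs[, 1]], p[pairs[, 2]])]
    mean(vals[ab$bin == 1])
  })
  p_exact <- mean(exact_means > obs)
  est <- attr(index_shuffle_null(m, d, 2, n_shuffles = 4000, seed = 2),
              "first_bin_p")
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(est - p_exact), 4 * se + 1e-9)
  # add_one correction shifts by ~1/n
  est1 <- attr(index_shuffle_null(m, d, 2, n_shuffles = 100, seed = 2,
                                  add_one = TRUE), "first_bin_p")
  expect_gt(est1, 0)
})

test_that("cluster_to_k reaches every achievable cluster count", {
  run <- cached_ou_run()
  m <- pairwise_metrics(log_zscore(sample_series(run$trajectory, 1)),
                        1)$total_coherence
  for (k in 1:6) {
    part <- cluster_to_k(m, k)
    expect_equal(part$n_clusters, k)
    # the returned threshold really produces that partition
    redo <- single_linkage_partition(threshold_links(m, part$threshold))
    expect_identical(canon(redo$labels), canon(part$labels))
  }
  expect_error(cluster_to_k(m, 0), class = "ecoguilds_data_error")
  expect_error(cluster_to_k(m, 7), class = "ecoguilds_data_error")
  # ties: an all-equal metric can only give 1 or N clusters
  tied <- matrix(1, 4, 4); diag(tied) <- 0
  expect_warning(p <- cluster_to_k(tied, 2), "unreachable")
  expect_true(p$n_clusters %in% c(1L, 4L))
})

test_that("the full field pipeline recovers the planted ecotype split", {
  fx <- make_field_fixture()
  outdir <- withr::local_tempdir()
  abpath <- withr::local_tempfile(fileext = ".tsv")
  write.table(fx$long, abpath, sep = "\t", quote = FALSE, row.names = FALSE)
  fapath <- withr::local_tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(fx$seqs), function(nm)
    c(paste0(">", nm), fx$seqs[[nm]]))), fapath)
  res <- suppressMessages(
    cmd_field(abpath, fapath, outdir, n_shuffles = 500, k_clusters = 2,
              seed = 3))
  expect_named(res$binned, c("C0", "absC0", "total_cpsd", "total_coherence"))
  # planted structure: dynamics cluster with phylogeny -> small first-bin p
  expect_lt(attr(res$binned$total_coherence, "first_bin_p"), 0.1)
  # and the 2-cluster partition matches the planted groups
  expect_identical(canon(res$partitions$total_coherence$labels),
                   canon(fx$group))
  for (f in c("binned_C0.tsv", "null_summary.json",
              "partition_total_coherence.tsv", "edges_total_cpsd.tsv"))
    expect_true(file.exists(file.path(outdir, f)))
})
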