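test_that("guild_config validates its inputs", {
  cfg <- default_config(q = 0.4)
  expect_s3_class(cfg, "guild_config")
  expect_equal(cfg$p_in, 0.9)
  expect_equal(cfg$p_out, 0.1)

  expect_error(guild_config(guild_bias = 0.7), class = "ecoguilds_config_error")
  expect_error(guild_config(guild_bias = -0.1), class = "ecoguilds_config_error")
  expect_error(guild_config(p_in = 0.2, p_out = 0.6),
               class = "ecoguilds_config_error")
  expect_no_error(guild_config(guild_bias = 0))
  expect_error(guild_config(p_in = 0.5, p_out = NULL),
               class = "ecoguilds_config_error")
  expect_error(guild_config(n_species = 4, n_resources = 30, n_guilds = 5,
                            guild_bias = 0.1), class = "ecoguilds_config_error")
  expect_error(guild_config(n_species = 6, n_resources = 5, guild_bias = 0.1),
               class = "ecoguilds_config_error")
  expect_error(guild_config(guild_bias = 0.1, uptake_rate = 0),
               class = "ecoguilds_config_error")
})

test_that("finite-size scaling matches the closed form and the N = 6 anchor", {
  for (q in c(0, 0.25, 0.5)) {
    at6 <- finite_size_rates(6, q)
    expect_equal(at6$p_in, 0.5 + q)
    expect_equal(at6$p_out, 0.5 - q)
    at24 <- finite_size_rates(24, q)
    expect_equal(at24$p_in, (0.5 + q) / 2)
    expect_equal(at24$p_out, (0.5 - q) / 4)
    at96 <- finite_size_rates(96, q)
    expect_equal(at96$p_in, (0.5 + q) / 4)
    expect_equal(at96$p_out, (0.5 - q) / 16)
  }
  expect_error(finite_size_rates(5, 0.2), class = "ecoguilds_config_error")
})

test_that("heterogeneous sizes follow the geometric rounding rules", {
  # independent re-implementation of the round-up-then-correct rule
  oracle <- function(total, k, q, min_size) {
    w <- q^(0:(k - 1))
    parts <- pmax(ceiling(total * w / sum(w)), min_size)
    while (sum(parts) > total) {
      ord <- order(parts)
      donor <- ord[which(parts[ord] > min_size)[1]]
      parts[donor] <- parts[donor] - 1
    }
    while (sum(parts) < total) parts[which.max(parts)] <- parts[which.max(parts)] + 1
    as.integer(parts)
  }
  grid <- expand.grid(N = c(8, 24, 96), k = c(2, 4), q = c(1, 0.5, 0.3))
  for (r in seq_len(nrow(grid))) {
    N <- grid$N[r]; k <- grid$k[r]; q <- grid$q[r]
    M <- 5 * N
    hs <- heterogeneous_sizes(N, M, k, q_N = q, q_M = q)
    expect_equal(sum(hs$guild_sizes), N)
    expect_equal(sum(hs$resource_counts), M - N)
    expect_true(all(hs$guild_sizes >= 2))
    expect_true(all(hs$resource_counts >= 1))
    expect_identical(hs$guild_sizes, oracle(N, k, q, 2L))
    expect_identical(hs$resource_counts, oracle(M - N, k, q, 1L))
  }
  # homogeneous case: equal split
  expect_identical(heterogeneous_sizes(24, 120, 4)$guild_sizes, rep(6L, 4))
  expect_identical(heterogeneous_sizes(24, 120, 4)$resource_counts, rep(24L, 4))
  expect_error(heterogeneous_sizes(6, 30, 4), class = "ecoguilds_config_error")
})

test_that("sampled networks have the documented structure", {
  net <- sample_network(default_config(q = 0.4, seed = 11))
  N <- 6; M <- 30
  expect_equal(dim(net$adjacency), c(N, M))
  expect_true(all(net$adjacency %in% 0:1))
  # private resources: identity block consumed by exactly one species
  priv <- net$adjacency[, net$private_resource_index]
  expect_identical(unname(priv), diag(1L, N))
  expect_identical(net$resource_guilds[net$private_resource_index], rep(0L, N))
  # gain = r * adjacency * yields, overlap = G G^T
  expect_equal(unname(net$gain),
               unname(0.1 * net$adjacency * net$yields))
  expect_equal(unname(net$overlap), unname(net$gain %*% t(net$gain)))
  expect_true(all(net$yields >= 0))
  expect_true(isSymmetric(net$overlap))
  expect_identical(net$guild_labels, rep(1:2, each = 3))
})

test_that("network sampling is reproducible and seed-stream independent", {
  a <- sample_network(default_config(seed = 42))
  b <- sample_network(default_config(seed = 42))
  expect_identical(a$adjacency, b$adjacency)
  expect_identical(a$yields, b$yields)
  c <- sample_network(default_config(seed = 43))
  expect_false(identical(a$adjacency, c$adjacency))
  # sampling a network never disturbs the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(sample_network(default_config(seed = 42)))
  after <- rnorm(3)
  expect_identical(before, after)
})

test_that("q = 0.5 gives disjoint guilds: cross-guild overlap is exactly zero", {
  for (seed in 1:5) {
    net <- sample_network(default_config(q = 0.5, seed = seed))
    cross <- outer(net$guild_labels, net$guild_labels, "!=")
    expect_identical(unname(net$overlap[cross]),
                     rep(0, sum(cross)))
  }
})

test_that("block Bernoulli frequencies match p_in / p_out", {
  # 40 networks -> binomial counts; compare against 4 sigma
  n_net <- 40
  cfg <- function(s) guild_config(n_species = 24, n_resources = 120,
                                  n_guilds = 4, guild_bias = 0.3, seed = s)
  hits_in <- hits_out <- trials_in <- trials_out <- 0
  for (s in seq_len(n_net)) {
    net <- sample_network(cfg(s))
    shared <- seq_len(120 - 24)
    same <- outer(net$guild_labels, net$resource_guilds[shared], "==")
    a <- net$adjacency[, shared]
    hits_in <- hits_in + sum(a[same]);  trials_in <- trials_in + sum(same)
    hits_out <- hits_out + sum(a[!same]); trials_out <- trials_out + sum(!same)
  }
  se_in <- sqrt(0.8 * 0.2 / trials_in)
  se_out <- sqrt(0.2 * 0.8 / trials_out)
  expect_lt(abs(hits_in / trials_in - 0.8), 4 * se_in)
  expect_lt(abs(hits_out / trials_out - 0.2), 4 * se_out)
})

test_that("yields are Gaussian(1, 1/6) conditioned on non-negativity", {
  nets <- lapply(1:20, function(s) sample_network(default_config(seed = s)))
  y <- unlist(lapply(nets, function(n) as.vector(n$yields)))
  # at mean/sd = 6 the truncation is negligible: mean within 4 SE of 1
  expect_lt(abs(mean(y) - 1), 4 * (1 / 6) / sqrt(length(y)))
  expect_lt(abs(sd(y) - 1 / 6), 0.02)
  expect_true(all(y >= 0))
})

test_that("analytic no-link probability and degree match Monte Carlo", {
  p_in <- 0.6; p_out <- 0.2; k <- 2; N <- 6; M_shared <- 24
  n_net <- 400
  cfg <- guild_config(n_species = N, n_resources = M_shared + N, n_guilds = k,
                      p_in = p_in, p_out = p_out)
  same0 <- diff0 <- 0; n_same <- n_diff <- 0; degs <- numeric(0)
  set.seed(314)
  for (s in seq_len(n_net)) {
    net <- sample_network(cfg)
    ov <- net$overlap; diag(ov) <- 0
    linked <- ov > 1e-12
    same <- outer(net$guild_labels, net$guild_labels, "==")
    ut <- upper.tri(ov)
    same0 <- same0 + sum(!linked[ut & same]); n_same <- n_same + sum(ut & same)
    diff0 <- diff0 + sum(!linked[ut & !same]); n_diff <- n_diff + sum(ut & !same)
    degs <- c(degs, rowSums(linked))
  }
  p0s_hat <- same0 / n_same
  p0d_hat <- diff0 / n_diff
  p0s <- expected_no_link_prob(p_in, p_out, M_shared, k, TRUE)
  p0d <- expected_no_link_prob(p_in, p_out, M_shared, k, FALSE)
  expect_lt(abs(p0s_hat - p0s), 3 * sqrt(p0s * (1 - p0s) / n_same) + 1e-12)
  expect_lt(abs(p0d_hat - p0d), 3 * sqrt(p0d * (1 - p0d) / n_diff) + 1e-12)
  d_exp <- expected_degree(p_in, p_out, N, M_shared, k)
  expect_lt(abs(mean(degs) - d_exp), 3 * sd(degs) / sqrt(length(degs)))
})

test_that("network round-trips through TSV + JSON exactly", {
  dir <- withr::local_tempdir()
  net <- sample_network(default_config(q = 0.4, seed = 5))
  write_resource_network(net, dir)
  back <- read_resource_network(dir)
  expect_equal(unname(back$adjacency), unname(net$adjacency),
               ignore_attr = TRUE)
  expect_equal(back$gain, net$gain)
  expect_equal(back$overlap, net$overlap)
  expect_identical(back$guild_labels, net$guild_labels)
  expect_identical(back$private_resource_index, net$private_resource_index)
  expect_equal(back$config$p_in, net$config$p_in)
})

test_that("tidy.resource_network gives one row per unordered pair", {
  net <- sample_network(default_config(seed = 2))
  td <- tidy(net)
  expect_equal(nrow(td), choose(6, 2))
  expect_named(td, c("i", "j", "taxon_i", "taxon_j", "overlap", "same_guild"))
  expect_equal(td$overlap[td$i == 1 & td$j == 2], net$overlap[1, 2])
  expect_equal(sum(td$same_guild), 2 * choose(3, 2))
})
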