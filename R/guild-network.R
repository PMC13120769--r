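#' Configuration of a guild-structured consumer-resource network
#'
#' Defines the ensemble from which species-by-resource networks are drawn.
#' Species are partitioned into `n_guilds` groups and shared resources into
#' matching blocks; a species consumes each resource of its own block with
#' probability `p_in` and each resource of another block with probability
#' `p_out`. With two guilds the single bias parameter `guild_bias` (q) sets
#' `p_in = 0.5 + q` and `p_out = 0.5 - q`: q = 0.5 gives disjoint guilds and
#' q = 0 no guild structure at all. Each species additionally receives one
#' private resource consumed by no other species, which prevents extinction;
#' hence `n_resources >= n_species` shared-plus-private resources in total.
#'
#' @param n_species Number of species N.
#' @param n_resources Total number of resources M, including the N private
#'   resources (so M - N are shared).
#' @param n_guilds Number of guilds k.
#' @param guild_bias Guild-structure bias q in `[0, 0.5]`. When supplied,
#'   `p_in` and `p_out` are set to `0.5 + q` and `0.5 - q`.
#' @param p_in,p_out Bernoulli probabilities for preferred / non-preferred
#'   resource blocks. Ignored when `guild_bias` is given.
#' @param uptake_rate Uptake rate r applied to every nonzero adjacency entry.
#' @param yield_mean,yield_sd Mean and sd of the Gaussian yield distribution
#'   (redrawn until non-negative).
#' @param q_N,q_M Geometric ratios for heterogeneous guild sizes and per-guild
#'   shared-resource counts (1 = homogeneous). See [heterogeneous_sizes()].
#' @param seed Integer root seed; adjacency and yields use independent derived
#'   streams so adding other random components never changes the network.
#' @return An object of class `guild_config`.
#' @seealso [sample_network()], [finite_size_rates()]
#' @export
#' @examples
#' guild_config(n_species = 6, n_resources = 30, n_guilds = 2, guild_bias = 0.4)
guild_config <- function(n_species = 6, n_resources = 30, n_guilds = 2,
                         guild_bias = NULL, p_in = NULL, p_out = NULL,
                         uptake_rate = 0.1, yield_mean = 1, yield_sd = 1 / 6,
                         q_N = 1, q_M = 1, seed = NULL) {
  if (!is_count(n_species) || !is_count(n_resources) || !is_count(n_guilds))
    stop_ecoguilds("n_species, n_resources and n_guilds must be positive integers",
                   class = "ecoguilds_config_error")
  if (!is.null(guild_bias)) {
    if (guild_bias < 0 || guild_bias > 0.5)
      stop_ecoguilds("guild_bias must lie in [0, 0.5], got ", guild_bias,
                     class = "ecoguilds_config_error")
    p_in <- 0.5 + guild_bias
    p_out <- 0.5 - guild_bias
  }
  if (is.null(p_in) || is.null(p_out))
    stop_ecoguilds("supply either guild_bias or both p_in and p_out",
                   class = "ecoguilds_config_error")
  if (p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1 || p_out > p_in)
    stop_ecoguilds("need 0 <= p_out <= p_in <= 1 (got p_in=", p_in,
                   ", p_out=", p_out, ")", class = "ecoguilds_config_error")
  if (n_guilds > n_species)
    stop_ecoguilds("n_guilds cannot exceed n_species",
                   class = "ecoguilds_config_error")
  if (n_resources < n_species)
    stop_ecoguilds("n_resources must be >= n_species (one private resource each)",
                   class = "ecoguilds_config_error")
  if (uptake_rate <= 0 || yield_mean <= 0 || yield_sd < 0)
    stop_ecoguilds("uptake_rate and yield_mean must be positive, yield_sd >= 0",
                   class = "ecoguilds_config_error")
  if (q_N <= 0 || q_M <= 0)
    stop_ecoguilds("q_N and q_M must be positive",
                   class = "ecoguilds_config_error")
  structure(
    list(n_species = as.integer(n_species), n_resources = as.integer(n_resources),
         n_guilds = as.integer(n_guilds), guild_bias = guild_bias,
         p_in = p_in, p_out = p_out, uptake_rate = uptake_rate,
         yield_mean = yield_mean, yield_sd = yield_sd,
         q_N = q_N, q_M = q_M, seed = seed),
    class = "guild_config")
}

#' @export
print.guild_config <- function(x, ...) {
  cat("<guild_config> N =", x$n_species, " M =", x$n_resources,
      " k =", x$n_guilds, "\n  p_in =", signif(x$p_in, 4),
      " p_out =", signif(x$p_out, 4),
      if (!is.null(x$guild_bias)) paste0(" (q = ", x$guild_bias, ")"), "\n")
  invisible(x)
}

#' Finite-size scaling of the block connection probabilities
#'
#' When the community is grown with M proportional to N and k proportional to
#' N, the block probabilities must shrink so that the expected degree of each
#' species in the resource-overlap graph stays bounded:
#' `p_in = (1/2 + q) (N/6)^(-1/2)` and `p_out = (1/2 - q) (N/6)^(-1)`.
#' At N = 6 this reduces to the two-guild parameterization `0.5 +/- q`.
#'
#' @param n_species Number of species N (>= 6).
#' @param guild_bias Guild-structure bias q in `[0, 0.5]`.
#' @return A list with elements `p_in` and `p_out`.
#' @export
#' @examples
#' finite_size_rates(24, 0.4)
finite_size_rates <- function(n_species, guild_bias) {
  if (n_species < 6)
    stop_ecoguilds("finite-size scaling is defined for N >= 6",
                   class = "ecoguilds_config_error")
  if (guild_bias < 0 || guild_bias > 0.5)
    stop_ecoguilds("guild_bias must lie in [0, 0.5]",
                   class = "ecoguilds_config_error")
  p_in <- (0.5 + guild_bias) * (n_species / 6)^(-1 / 2)
  p_out <- (0.5 - guild_bias) * (n_species / 6)^(-1)
  if (p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1)
    stop_ecoguilds("scaled probabilities fall outside [0, 1]",
                   class = "ecoguilds_config_error")
  list(p_in = p_in, p_out = p_out)
}

#' Geometrically heterogeneous guild sizes and resource counts
#'
#' Splits N species into k guilds with sizes forming a geometric series
#' `N_j = q_N^(j-1) N_1` (rounded up) summing exactly to N, and splits the
#' M - N shared resources into per-guild counts `M_j = q_M^(j-1) M_1` summing
#' to M - N. Rounding corrections: a deficit is added to the largest guild; an
#' excess is removed from the smallest guild unless that would push it below
#' two members, in which case it is removed from the second smallest. Minimum
#' guild size is 2.
#'
#' @param n_species,n_resources,n_guilds Community dimensions (M counts private
#'   resources, so M - N shared resources are split).
#' @param q_N,q_M Geometric ratios; 1 gives equal splits.
#' @return A list with integer vectors `guild_sizes` (length k, sums to N) and
#'   `resource_counts` (length k, sums to M - N).
#' @export
#' @examples
#' heterogeneous_sizes(24, 120, 4, q_N = 0.5, q_M = 0.5)
heterogeneous_sizes <- function(n_species, n_resources, n_guilds,
                                q_N = 1, q_M = 1) {
  if (n_species < 2 * n_guilds)
    stop_ecoguilds("infeasible: need at least 2 species per guild (N >= 2k)",
                   class = "ecoguilds_config_error")
  m_shared <- n_resources - n_species
  if (m_shared < n_guilds)
    stop_ecoguilds("need at least one shared resource per guild",
                   class = "ecoguilds_config_error")
  sizes <- geometric_partition(n_species, n_guilds, q_N, min_size = 2L)
  counts <- geometric_partition(m_shared, n_guilds, q_M, min_size = 1L)
  list(guild_sizes = sizes, resource_counts = counts)
}

# Round-up geometric partition of `total` into `k` parts with ratio `q`,
# corrected to sum exactly to `total` with every part >= min_size.
geometric_partition <- function(total, k, q, min_size = 2L) {
  w <- q^(seq_len(k) - 1)
  parts <- as.integer(ceiling(total * w / sum(w)))
  parts <- pmax(parts, min_size)
  while (sum(parts) != total) {
    if (sum(parts) < total) {
      largest <- which.max(parts)
      parts[largest] <- parts[largest] + 1L
    } else {
      ord <- order(parts)   # remove from smallest part still above the minimum
      donor <- ord[which(parts[ord] > min_size)[1]]
      if (is.na(donor))
        stop_ecoguilds("cannot satisfy minimum part size ", min_size,
                       " while partitioning ", total, " into ", k, " parts",
                       class = "ecoguilds_config_error")
      parts[donor] <- parts[donor] - 1L
    }
  }
  parts
}

#' Sample a guild-structured consumer-resource network
#'
#' Draws the binary species-by-resource adjacency `g` blockwise
#' (Bernoulli `p_in` within a species' own resource block, `p_out` elsewhere),
#' assigns each species one private resource, draws Gaussian yields (redrawn
#' until non-negative), and assembles the gain matrix `G = r g * yields` and
#' the ground-truth resource-utilization overlap `G %*% t(G)`.
#'
#' @param config A [guild_config()].
#' @return An object of class `resource_network` with components `adjacency`,
#'   `uptake`, `yields`, `gain`, `overlap`, `guild_labels`,
#'   `resource_guilds` (0 marks private resources),
#'   `private_resource_index`, and `config`.
#' @export
#' @examples
#' net <- sample_network(guild_config(guild_bias = 0.4, seed = 1))
#' net$overlap[1:3, 1:3]
sample_network <- function(config) {
  stopifnot(inherits(config, "guild_config"))
  N <- config$n_species; M <- config$n_resources; k <- config$n_guilds
  sz <- heterogeneous_sizes(N, M, k, config$q_N, config$q_M)
  m_shared <- M - N
  guild_labels <- rep(seq_len(k), times = sz$guild_sizes)
  resource_guilds <- c(rep(seq_len(k), times = sz$resource_counts), rep(0L, N))

  adjacency <- with_seed(
    if (is.null(config$seed)) NULL else derive_seed(config$seed, "adjacency"), {
      p <- ifelse(outer(guild_labels, resource_guilds[seq_len(m_shared)], "=="),
                  config$p_in, config$p_out)
      shared <- matrix(as.integer(runif(N * m_shared) < p), N, m_shared)
      cbind(shared, diag(1L, N))
    })
  private_resource_index <- m_shared + seq_len(N)

  yields <- with_seed(
    if (is.null(config$seed)) NULL else derive_seed(config$seed, "yields"), {
      y <- matrix(rnorm(N * M, config$yield_mean, config$yield_sd), N, M)
      while (any(neg <- y < 0))   # redraw until all non-negative
        y[neg] <- rnorm(sum(neg), config$yield_mean, config$yield_sd)
      y
    })

  uptake <- config$uptake_rate * adjacency
  gain <- uptake * yields
  overlap <- gain %*% t(gain)
  species <- paste0("sp", seq_len(N))
  resources <- paste0("res", seq_len(M))
  dimnames(adjacency) <- dimnames(uptake) <- dimnames(gain) <-
    dimnames(yields) <- list(species, resources)
  dimnames(overlap) <- list(species, species)

  structure(
    list(adjacency = adjacency, uptake = uptake, yields = yields,
         gain = gain, overlap = overlap,
         guild_labels = guild_labels, resource_guilds = resource_guilds,
         private_resource_index = private_resource_index, config = config),
    class = "resource_network")
}

#' @export
print.resource_network <- function(x, ...) {
  cat("<resource_network>", nrow(x$gain), "species x", ncol(x$gain),
      "resources,", x$config$n_guilds, "guilds\n")
  cat("  guild sizes:", paste(tabulate(x$guild_labels), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy the pairwise ground-truth overlap of a network
#'
#' @param x A `resource_network`.
#' @param ... Unused.
#' @return A tibble with one row per unordered species pair: indices, ids,
#'   overlap value, and whether the pair shares a guild.
#' @export
tidy.resource_network <- function(x, ...) {
  n <- nrow(x$overlap)
  out <- pair_index(n, rownames(x$overlap))
  out$overlap <- x$overlap[upper.tri(x$overlap)]
  out$same_guild <- x$guild_labels[out$i] == x$guild_labels[out$j]
  out
}

#' Analytic probability that two species share no resource
#'
#' Closed-form ensemble probability that the off-diagonal overlap entry for a
#' species pair is exactly zero, i.e. that the pair consumes no common shared
#' resource. For a same-guild pair this is
#' `(1 - p_in^2)^(M/k) (1 - p_out^2)^(M (1 - 1/k))`; for a different-guild pair
#' `(1 - p_in p_out)^(2 M/k) (1 - p_out^2)^(M (1 - 2/k))`, where M counts the
#' shared resources only (private resources cannot create overlap between
#' distinct species).
#'
#' @param p_in,p_out Block connection probabilities.
#' @param n_resources Number of *shared* resources entering the blocks.
#' @param n_guilds Number of guilds k.
#' @param same_guild Logical: does the pair share a guild?
#' @return A probability.
#' @export
expected_no_link_prob <- function(p_in, p_out, n_resources, n_guilds,
                                  same_guild) {
  M <- n_resources; k <- n_guilds
  if (same_guild) {
    (1 - p_in^2)^(M / k) * (1 - p_out^2)^(M * (1 - 1 / k))
  } else {
    (1 - p_in * p_out)^(2 * M / k) * (1 - p_out^2)^(M * (1 - 2 / k))
  }
}

#' Expected degree in the resource-overlap graph
#'
#' Expected number of species sharing at least one resource with a focal
#' species, combining the same-guild and different-guild no-link
#' probabilities:
#' `d = [1 - P0_same] (N/k - 1) + [1 - P0_diff] N (1 - 1/k)`.
#'
#' @inheritParams expected_no_link_prob
#' @param n_species Number of species N.
#' @return Expected degree (a real number).
#' @export
expected_degree <- function(p_in, p_out, n_species, n_resources, n_guilds) {
  N <- n_species; k <- n_guilds
  p0_same <- expected_no_link_prob(p_in, p_out, n_resources, k, TRUE)
  p0_diff <- expected_no_link_prob(p_in, p_out, n_resources, k, FALSE)
  (1 - p0_same) * (N / k - 1) + (1 - p0_diff) * N * (1 - 1 / k)
}

#' Write / read a resource network as TSV matrices plus a JSON sidecar
#'
#' Exports `adjacency`, `gain` and `overlap` as tab-separated matrices with
#' species/resource headers, and a JSON sidecar holding the configuration and
#' guild labels.
#'
#' @param network A `resource_network`.
#' @param dir Directory to write into (created if missing).
#' @param prefix File-name prefix.
#' @return `write_resource_network()` returns the sidecar path invisibly;
#'   `read_resource_network()` returns a `resource_network`.
#' @export
write_resource_network <- function(network, dir, prefix = "network") {
  stopifnot(inherits(network, "resource_network"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (what in c("adjacency", "gain", "overlap", "yields")) {
    write.table(network[[what]],
                file.path(dir, paste0(prefix, "_", what, ".tsv")),
                sep = "\t", quote = FALSE, col.names = NA)
  }
  sidecar <- file.path(dir, paste0(prefix, "_config.json"))
  cfg <- unclass(network$config)
  jsonlite::write_json(
    list(config = cfg, guild_labels = network$guild_labels,
         resource_guilds = network$resource_guilds,
         private_resource_index = network$private_resource_index),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(sidecar)
}

#' @rdname write_resource_network
#' @export
read_resource_network <- function(dir, prefix = "network") {
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, "_config.json")),
                              simplifyVector = TRUE)
  cfg <- meta$config
  config <- guild_config(cfg$n_species, cfg$n_resources, cfg$n_guilds,
                         guild_bias = cfg$guild_bias,
                         p_in = cfg$p_in, p_out = cfg$p_out,
                         uptake_rate = cfg$uptake_rate,
                         yield_mean = cfg$yield_mean, yield_sd = cfg$yield_sd,
                         q_N = cfg$q_N, q_M = cfg$q_M, seed = cfg$seed)
  read_mat <- function(what)
    as.matrix(read.delim(file.path(dir, paste0(prefix, "_", what, ".tsv")),
                         row.names = 1, check.names = FALSE))
  adjacency <- read_mat("adjacency")
  yields <- read_mat("yields")
  uptake <- config$uptake_rate * adjacency
  structure(
    list(adjacency = adjacency, uptake = uptake, yields = yields,
         gain = read_mat("gain"), overlap = read_mat("overlap"),
         guild_labels = as.integer(meta$guild_labels),
         resource_guilds = as.integer(meta$resource_guilds),
         private_resource_index = as.integer(meta$private_resource_index),
         config = config),
    class = "resource_network")
}
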