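# Shared fixtures; everything is generated in code with fixed seeds.

default_config <- function(q = 0.4, seed = 1, ...)
  guild_config(n_species = 6, n_resources = 30, n_guilds = 2,
               guild_bias = q, seed = seed, ...)

# A short but analysis-grade OU-driven simulation, cached per test run.
cached_ou_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      net <- sample_network(default_config(q = 0.4, seed = 7))
      drv <- drive_spec("ou", 30, frequency = 1, seed = 7)
      traj <- simulate_ecrm(net, drv, sim_params(t_final = 4000), seed = 7)
      cache <<- list(network = net, drive = drv, trajectory = traj)
    }
    cache
  }
})

# Independent brute-force connected components (breadth-first search),
# used as the oracle for single-linkage clustering.
bf_components <- function(adj) {
  n <- nrow(adj)
  labels <- rep(NA_integer_, n)
  cl <- 0L
  for (s in seq_len(n)) {
    if (!is.na(labels[s])) next
    cl <- cl + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(labels[v])) next
      labels[v] <- cl
      queue <- c(queue, which(adj[v, ] != 0 & is.na(labels)))
    }
  }
  labels
}

# Canonical form of a partition label vector (relabel by first appearance).
canon <- function(labels) as.integer(factor(labels, levels = unique(labels)))

# All n! permutations of 1..n as rows (small n only).
perms_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}
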