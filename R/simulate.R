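#' Specify the external resource-supply drive
#'
#' The resource supply `K_a(t)` fluctuates around a base level either
#' sinusoidally, `K_a(t) = K0_a + A_a sin(w_a t - phi_a)`, or as an
#' Ornstein-Uhlenbeck (OU) process `K_a(t) = K0_a + Q_a(t)` with
#' `dQ_a/dt = -w_a Q_a + A_a w_a eta_a(t)` and independent unit white noise per
#' resource, giving stationary variance `A_a^2 w_a / 2`. Frequencies can be
#' fixed or sampled log-uniformly over `omega_range` to emulate an environment
#' mixing many timescales.
#'
#' @param kind `"sinusoidal"`, `"ou"`, or `"constant"`.
#' @param n_resources Number of resources M.
#' @param base_supply Base supply K0 (recycled to length M).
#' @param amplitude Drive amplitude A (recycled). Default `0.5 * base_supply`.
#' @param frequency Angular frequency w (recycled); ignored when `omega_range`
#'   is given.
#' @param phase Phases in `[0, 2pi)` (sinusoidal only); sampled uniformly when
#'   `NULL`.
#' @param omega_range Optional length-2 range; frequencies are sampled
#'   log-uniformly over it (one per resource).
#' @param seed Seed used for sampling frequencies/phases here, and for the OU
#'   innovations during integration.
#' @return An object of class `drive_spec` with resolved per-resource vectors.
#' @export
#' @examples
#' drive_spec("ou", n_resources = 30, frequency = 1, seed = 1)
#' drive_spec("sinusoidal", 30, omega_range = c(0.03, 3), seed = 1)
drive_spec <- function(kind = c("sinusoidal", "ou", "constant"), n_resources,
                       base_supply = 1, amplitude = 0.5 * base_supply,
                       frequency = 1, phase = NULL, omega_range = NULL,
                       seed = NULL) {
  kind <- match.arg(kind)
  M <- as.integer(n_resources)
  K0 <- rep_len(base_supply, M)
  A <- if (kind == "constant") rep(0, M) else rep_len(amplitude, M)
  if (any(K0 < 0) || any(A < 0))
    stop_ecoguilds("base_supply and amplitude must be non-negative",
                   class = "ecoguilds_config_error")
  sub <- if (is.null(seed)) NULL else derive_seed(seed, "drive-spec")
  omega <- with_seed(sub, {
    if (!is.null(omega_range)) {
      stopifnot(length(omega_range) == 2, all(omega_range > 0))
      exp(runif(M, log(omega_range[1]), log(omega_range[2])))
    } else rep_len(frequency, M)
  })
  phi <- if (kind == "sinusoidal") {
    if (is.null(phase)) {
      with_seed(if (is.null(seed)) NULL else derive_seed(seed, "drive-phase"),
                runif(M, 0, 2 * pi))
    } else rep_len(phase, M)
  } else rep(0, M)
  if (any(omega <= 0))
    stop_ecoguilds("frequencies must be positive",
                   class = "ecoguilds_config_error")
  structure(list(kind = kind, n_resources = M, base_supply = K0,
                 amplitude = A, frequency = omega, phase = phi, seed = seed),
            class = "drive_spec")
}

#' Evaluate a sinusoidal drive on a time grid
#'
#' @param spec A `drive_spec` with `kind = "sinusoidal"` (or `"constant"`).
#' @param times Numeric vector of times.
#' @return An M x length(times) matrix of supply values.
#' @export
make_sinusoidal_drive <- function(spec, times) {
  stopifnot(inherits(spec, "drive_spec"))
  if (spec$kind == "ou")
    stop_ecoguilds("spec has kind 'ou'; use make_ou_drive()",
                   class = "ecoguilds_config_error")
  K <- outer(seq_len(spec$n_resources), times, function(a, t)
    spec$base_supply[a] + spec$amplitude[a] *
      sin(spec$frequency[a] * t - spec$phase[a]))
  K
}

#' Realize an Ornstein-Uhlenbeck drive on a uniform grid
#'
#' Uses the exact discretization of the OU process: per step of size `dt`, the
#' deviation from base supply decays by `exp(-w dt)` and receives a Gaussian
#' innovation of variance `(A^2 w / 2)(1 - exp(-2 w dt))`; the initial state is
#' drawn from the stationary distribution. Streams are independent across
#' resources.
#'
#' @param spec A `drive_spec` with `kind = "ou"`.
#' @param dt Grid spacing.
#' @param t_final Final time; the grid is `seq(0, t_final, by = dt)`.
#' @return An M x T matrix of supply values.
#' @export
make_ou_drive <- function(spec, dt, t_final) {
  stopifnot(inherits(spec, "drive_spec"), spec$kind == "ou", dt > 0)
  n <- floor(t_final / dt) + 1L
  M <- spec$n_resources
  with_seed(if (is.null(spec$seed)) NULL else derive_seed(spec$seed, "ou-path"), {
    K <- matrix(0, M, n)
    for (a in seq_len(M)) {
      w <- spec$frequency[a]
      var_stat <- spec$amplitude[a]^2 * w / 2
      decay <- exp(-w * dt)
      sd_step <- sqrt(var_stat * (1 - decay^2))
      q <- numeric(n)
      q[1] <- rnorm(1, 0, sqrt(var_stat))
      innov <- rnorm(n - 1, 0, sd_step)
      for (t in seq_len(n - 1)) q[t + 1] <- decay * q[t] + innov[t]
      K[a, ] <- spec$base_supply[a] + q
    }
    K
  })
}

#' Simulation parameters for the consumer-resource integrator
#'
#' @param death_rate_species Species death rate d_x (default 0.3; turnover
#'   timescale 1/d_x).
#' @param depletion_rate_resource Resource depletion rate d_R (default 0.5).
#' @param t_final Duration of the analyzed trajectory t_f (after burn-in).
#' @param integrator_step Fixed RK4 step (default 0.01).
#' @param burn_in Transient discarded before t = 0 (default `10 / death_rate`).
#' @param sampling_interval Default abundance sampling interval for analysis.
#' @param record_interval Spacing of the stored trajectory grid; must be a
#'   multiple of `integrator_step` and divide the sampling intervals used.
#' @param x0 Initial abundances (recycled; default 1).
#' @param R0 Initial resource concentrations; default `base_supply / d_R`, the
#'   species-free supply balance.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(death_rate_species = 0.3, depletion_rate_resource = 0.5,
                       t_final = 20000, integrator_step = 0.01,
                       burn_in = 10 / death_rate_species,
                       sampling_interval = 1, record_interval = 0.25,
                       x0 = 1, R0 = NULL) {
  stopifnot(death_rate_species > 0, depletion_rate_resource > 0, t_final > 0,
            integrator_step > 0, burn_in >= 0,
            sampling_interval >= integrator_step)
  ratio <- record_interval / integrator_step
  if (abs(ratio - round(ratio)) > 1e-8)
    stop_ecoguilds("record_interval must be a multiple of integrator_step",
                   class = "ecoguilds_config_error")
  structure(list(death_rate_species = death_rate_species,
                 depletion_rate_resource = depletion_rate_resource,
                 t_final = t_final, integrator_step = integrator_step,
                 burn_in = burn_in, sampling_interval = sampling_interval,
                 record_interval = record_interval, x0 = x0, R0 = R0),
            class = "sim_params")
}

#' Integrate the environment-mediated consumer-resource model
#'
#' Solves `dx_i/dt = x_i (sum_a G_ia R_a - d_x)` and
#' `dR_a/dt = K_a(t) - (d_R + sum_i r_ia x_i) R_a` with fixed-step RK4,
#' species in log space (strict positivity by construction). The burn-in
#' transient is discarded and the trajectory is stored on a uniform record
#' grid. Under OU supply, rare small negative supply excursions can pull a
#' resource slightly below zero; these are left to the dynamics (never
#' clipped) and counted in `n_negative_resource_steps`; the run aborts with a
#' diagnostic if a resource diverges.
#'
#' @param network A [sample_network()] result (or any list with `gain` and
#'   `uptake` matrices).
#' @param drive A [drive_spec()].
#' @param params A [sim_params()].
#' @param seed Optional seed for the OU innovations; defaults to the drive's
#'   seed stream.
#' @return An object of class `ecrm_trajectory` with `times` (starting at 0
#'   after burn-in), `abundances` (N x T), `resources` (M x T),
#'   `drive_realization` (M x T), and bookkeeping fields.
#' @export
#' @examples
#' net <- sample_network(guild_config(guild_bias = 0.4, seed = 1))
#' drv <- drive_spec("ou", net$config$n_resources, frequency = 1, seed = 1)
#' traj <- simulate_ecrm(net, drv, sim_params(t_final = 50), seed = 1)
simulate_ecrm <- function(network, drive, params = sim_params(), seed = NULL) {
  stopifnot(inherits(drive, "drive_spec"), inherits(params, "sim_params"))
  gain <- network$gain; uptake <- network$uptake
  N <- nrow(gain); M <- ncol(gain)
  if (drive$n_resources != M)
    stop_ecoguilds("drive has ", drive$n_resources, " resources, network ", M,
                   class = "ecoguilds_config_error")
  dt <- params$integrator_step
  n_steps <- round((params$burn_in + params$t_final) / dt)
  record_every <- round(params$record_interval / dt)
  record_from <- round(params$burn_in / dt)
  x0 <- rep_len(params$x0, N)
  R0 <- if (is.null(params$R0))
    drive$base_supply / params$depletion_rate_resource
  else rep_len(params$R0, M)
  if (any(x0 <= 0) || any(R0 <= 0))
    stop_ecoguilds("initial abundances and resources must be positive",
                   class = "ecoguilds_config_error")
  drive_kind <- match(drive$kind, c("constant", "sinusoidal", "ou")) - 1L

  ou_seed <- if (!is.null(seed)) derive_seed(seed, "ou-innovations")
             else if (!is.null(drive$seed)) derive_seed(drive$seed, "ou-innovations")
             else NULL
  res <- with_seed(ou_seed,
    ecrm_integrate_cpp(gain, uptake,
                       params$death_rate_species,
                       params$depletion_rate_resource,
                       x0, R0, dt, n_steps, record_every, record_from,
                       drive_kind, drive$base_supply, drive$amplitude,
                       drive$frequency, drive$phase))
  # time is measured from the first retained sample (the burn-in need not be
  # a multiple of the record grid)
  times <- res$times - res$times[1]
  rownames(res$abundances) <- rownames(gain)
  structure(list(times = times, abundances = res$abundances,
                 resources = res$resources, drive_realization = res$drive,
                 n_negative_resource_steps = res$n_negative_resource_steps,
                 record_interval = params$record_interval,
                 params = params, drive = drive),
            class = "ecrm_trajectory")
}

#' @export
print.ecrm_trajectory <- function(x, ...) {
  cat("<ecrm_trajectory>", nrow(x$abundances), "species,",
      nrow(x$resources), "resources,", length(x$times),
      "samples on [", min(x$times), ",", max(x$times), "] at dt =",
      x$record_interval, "\n")
  invisible(x)
}

#' Tidy a trajectory into long form
#'
#' @param x An `ecrm_trajectory`.
#' @param what `"abundances"`, `"resources"`, or `"drive"`.
#' @param ... Unused.
#' @return A tibble with columns `series`, `time`, `value`.
#' @export
tidy.ecrm_trajectory <- function(x, what = c("abundances", "resources", "drive"),
                                 ...) {
  what <- match.arg(what)
  m <- switch(what, abundances = x$abundances, resources = x$resources,
              drive = x$drive_realization)
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0(substr(what, 1, 3), seq_len(nrow(m)))
  tibble::tibble(series = rep(ids, times = ncol(m)),
                 time = rep(x$times, each = nrow(m)),
                 value = as.vector(m))
}

#' Subsample an abundance trajectory at a coarser interval
#'
#' @param traj An `ecrm_trajectory` (or a list with `times`, `abundances`, and
#'   `record_interval`).
#' @param sampling_interval Desired interval; must be an integer multiple of
#'   the stored record grid.
#' @return An N x T' abundance matrix with sampled times as column names.
#' @export
sample_series <- function(traj, sampling_interval) {
  grid <- traj$record_interval
  ratio <- sampling_interval / grid
  if (abs(ratio - round(ratio)) > 1e-8)
    stop_ecoguilds("sampling_interval (", sampling_interval,
                   ") must be an integer multiple of the record grid (",
                   grid, ")", class = "ecoguilds_data_error")
  idx <- seq(1, length(traj$times), by = round(ratio))
  out <- traj$abundances[, idx, drop = FALSE]
  colnames(out) <- traj$times[idx]
  out
}

#' Log-transform and z-score abundance series
#'
#' Per species: take the natural log, subtract the mean over time, and divide
#' by the standard deviation over time (population normalization, so that the
#' equal-time self-correlation `(1/T) sum_t s_i(t)^2` equals 1 exactly).
#'
#' @param abundances Strictly positive N x T matrix (absolute or relative
#'   abundances).
#' @return An object of class `zscore_series`: list with `scores` (N x T),
#'   `source_means`, `source_sds`.
#' @export
log_zscore <- function(abundances) {
  if (inherits(abundances, "ecrm_trajectory")) abundances <- abundances$abundances
  abundances <- as.matrix(abundances)
  if (any(abundances <= 0))
    stop_ecoguilds("abundances must be strictly positive for log z-scoring; ",
                   "filter zeros upstream", class = "ecoguilds_data_error")
  s <- log(abundances)
  mu <- rowMeans(s)
  s <- s - mu
  sds <- sqrt(rowMeans(s^2))
  if (any(sds == 0))
    stop_ecoguilds("constant series cannot be z-scored (zero variance in rows: ",
                   paste(which(sds == 0), collapse = ", "), ")",
                   class = "ecoguilds_data_error")
  structure(list(scores = s / sds, source_means = mu, source_sds = sds),
            class = "zscore_series")
}
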