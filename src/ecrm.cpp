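#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Environment-mediated consumer-resource dynamics:
//   dx_i/dt = x_i (sum_a G_ia R_a - d_x)        [multiplicative growth]
//   dR_a/dt = K_a(t) - (d_R + sum_i r_ia x_i) R_a
// Species are integrated in log space (positivity by construction); resources
// on their natural scale.  Fixed-step classical RK4; the supply K_a(t) is
// evaluated analytically at RK4 substeps for sinusoidal drives and held
// constant over a step for OU drives (exact OU discretization per step,
// using R's RNG so set.seed() in R controls the realization).

static inline void ecrm_rhs(int N, int M,
                            const double* G, const double* U,
                            double dx_rate, double dR_rate,
                            const double* logx, const double* R,
                            const double* K,
                            double* dlogx, double* dR,
                            double* xbuf) {
  for (int i = 0; i < N; ++i) xbuf[i] = std::exp(logx[i]);
  // column-major N x M matrices
  for (int i = 0; i < N; ++i) {
    double g = 0.0;
    for (int a = 0; a < M; ++a) g += G[i + a * N] * R[a];
    dlogx[i] = g - dx_rate;
  }
  for (int a = 0; a < M; ++a) {
    double cons = 0.0;
    for (int i = 0; i < N; ++i) cons += U[i + a * N] * xbuf[i];
    dR[a] = K[a] - (dR_rate + cons) * R[a];
  }
}

// drive_kind: 0 constant, 1 sinusoidal, 2 OU
// [[Rcpp::export]]
List ecrm_integrate_cpp(NumericMatrix gain, NumericMatrix uptake,
                        double death_rate, double depletion_rate,
                        NumericVector x0, NumericVector R0,
                        double step, int n_steps,
                        int record_every, int record_from,
                        int drive_kind,
                        NumericVector K0, NumericVector A,
                        NumericVector omega, NumericVector phase) {
  const int N = gain.nrow(), M = gain.ncol();
  if (uptake.nrow() != N || uptake.ncol() != M)
    stop("gain and uptake dimensions disagree");

  std::vector<double> logx(N), R(M), K(M), Q(M, 0.0);
  for (int i = 0; i < N; ++i) logx[i] = std::log(x0[i]);
  for (int a = 0; a < M; ++a) R[a] = R0[a];

  // OU: stationary initial condition and per-step exact update factors
  std::vector<double> ou_decay(M), ou_sd(M);
  if (drive_kind == 2) {
    for (int a = 0; a < M; ++a) {
      double var_stat = A[a] * A[a] * omega[a] / 2.0;
      ou_decay[a] = std::exp(-omega[a] * step);
      ou_sd[a] = std::sqrt(var_stat * (1.0 - ou_decay[a] * ou_decay[a]));
      Q[a] = std::sqrt(var_stat) * R::norm_rand();
    }
  }

  const int n_rec = (n_steps - record_from) / record_every + 1;
  NumericVector times(n_rec);
  NumericMatrix x_out(N, n_rec), R_out(M, n_rec), K_out(M, n_rec);

  std::vector<double> k1x(N), k2x(N), k3x(N), k4x(N);
  std::vector<double> k1R(M), k2R(M), k3R(M), k4R(M);
  std::vector<double> tx(N), tR(M), xbuf(N);
  std::vector<double> Kmid(M), Kend(M);

  const double* Gp = REAL(gain);
  const double* Up = REAL(uptake);

  double neg_floor = 0.0;
  for (int a = 0; a < M; ++a) neg_floor += K0[a];
  neg_floor = -10.0 * (neg_floor / M) / depletion_rate;  // pathological level

  int rec = 0;
  long n_negative_R = 0;

  auto eval_drive = [&](double t, double* out) {
    if (drive_kind == 1) {
      for (int a = 0; a < M; ++a)
        out[a] = K0[a] + A[a] * std::sin(omega[a] * t - phase[a]);
    } else if (drive_kind == 2) {
      for (int a = 0; a < M; ++a) out[a] = K0[a] + Q[a];
    } else {
      for (int a = 0; a < M; ++a) out[a] = K0[a];
    }
  };

  for (int s = 0; s <= n_steps; ++s) {
    double t = s * step;
    eval_drive(t, K.data());

    if (s >= record_from && (s - record_from) % record_every == 0) {
      times[rec] = t;
      for (int i = 0; i < N; ++i) x_out(i, rec) = std::exp(logx[i]);
      for (int a = 0; a < M; ++a) { R_out(a, rec) = R[a]; K_out(a, rec) = K[a]; }
      ++rec;
    }
    if (s == n_steps) break;

    // supply at substeps: analytic for sinusoid, frozen for constant/OU
    if (drive_kind == 1) {
      eval_drive(t + step / 2.0, Kmid.data());
      eval_drive(t + step, Kend.data());
    } else {
      std::copy(K.begin(), K.end(), Kmid.begin());
      std::copy(K.begin(), K.end(), Kend.begin());
    }

    ecrm_rhs(N, M, Gp, Up, death_rate, depletion_rate,
             logx.data(), R.data(), K.data(), k1x.data(), k1R.data(), xbuf.data());
    for (int i = 0; i < N; ++i) tx[i] = logx[i] + 0.5 * step * k1x[i];
    for (int a = 0; a < M; ++a) tR[a] = R[a] + 0.5 * step * k1R[a];
    ecrm_rhs(N, M, Gp, Up, death_rate, depletion_rate,
             tx.data(), tR.data(), Kmid.data(), k2x.data(), k2R.data(), xbuf.data());
    for (int i = 0; i < N; ++i) tx[i] = logx[i] + 0.5 * step * k2x[i];
    for (int a = 0; a < M; ++a) tR[a] = R[a] + 0.5 * step * k2R[a];
    ecrm_rhs(N, M, Gp, Up, death_rate, depletion_rate,
             tx.data(), tR.data(), Kmid.data(), k3x.data(), k3R.data(), xbuf.data());
    for (int i = 0; i < N; ++i) tx[i] = logx[i] + step * k3x[i];
    for (int a = 0; a < M; ++a) tR[a] = R[a] + step * k3R[a];
    ecrm_rhs(N, M, Gp, Up, death_rate, depletion_rate,
             tx.data(), tR.data(), Kend.data(), k4x.data(), k4R.data(), xbuf.data());

    for (int i = 0; i < N; ++i)
      logx[i] += step / 6.0 * (k1x[i] + 2.0 * k2x[i] + 2.0 * k3x[i] + k4x[i]);
    for (int a = 0; a < M; ++a) {
      R[a] += step / 6.0 * (k1R[a] + 2.0 * k2R[a] + 2.0 * k3R[a] + k4R[a]);
      if (R[a] < 0.0) {
        ++n_negative_R;
        if (R[a] < neg_floor)
          stop("resource %d fell to %g at t=%g: dynamics diverged", a + 1, R[a], t);
      }
    }
    for (int i = 0; i < N; ++i)
      if (!std::isfinite(logx[i]))
        stop("species %d became non-finite at t=%g", i + 1, t);

    if (drive_kind == 2) {
      for (int a = 0; a < M; ++a)
        Q[a] = ou_decay[a] * Q[a] + ou_sd[a] * R::norm_rand();
    }
  }

  return List::create(_["times"] = times, _["abundances"] = x_out,
                      _["resources"] = R_out, _["drive"] = K_out,
                      _["n_negative_resource_steps"] = (double)n_negative_R);
}
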