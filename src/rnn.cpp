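#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Euler-Maruyama integration of a rank-R rate network
//   tau dx/dt = -x + (1/N) M (Nm^T phi(x)) + Win u(t) + eta(t),  phi = tanh
// with x(0) = 0 (or x0) and eta white noise of s.d. sigma (the discrete
// update adds sigma * sqrt(dt/tau) * N(0,1)).
// u: T x n_in input trace; M, Nm: N x R; Win: N x n_in; wout: N.
// Returns states X ((T+1) x N, including the initial state) and readout
// o(t) = sum_i wout_i phi(x_i), length T+1. Uses R's RNG (set.seed-driven).
// [[Rcpp::export]]
List rnn_forward_cpp(NumericMatrix M, NumericMatrix Nm, NumericMatrix Win,
                     NumericVector wout, NumericMatrix u,
                     double dt, double tau, double sigma,
                     Nullable<NumericVector> x0 = R_NilValue) {
  const int N = M.nrow(), R = M.ncol(), T = u.nrow(), n_in = u.ncol();
  if (Nm.nrow() != N || Nm.ncol() != R) stop("Nm shape mismatch");
  if (Win.nrow() != N || Win.ncol() != n_in) stop("Win shape mismatch");
  const double a = dt / tau, snoise = sigma * std::sqrt(dt / tau);

  NumericMatrix X(T + 1, N);
  NumericVector o(T + 1);
  std::vector<double> x(N, 0.0), phi(N), drive(N);
  if (x0.isNotNull()) {
    NumericVector xv(x0);
    if (xv.size() != N) stop("x0 length mismatch");
    for (int i = 0; i < N; ++i) x[i] = xv[i];
  }
  for (int t = 0; t <= T; ++t) {
    double ot = 0.0;
    for (int i = 0; i < N; ++i) {
      phi[i] = std::tanh(x[i]);
      X(t, i) = x[i];
      ot += wout[i] * phi[i];
    }
    o[t] = ot;
    if (t == T) break;
    for (int i = 0; i < N; ++i) drive[i] = 0.0;
    for (int r = 0; r < R; ++r) {
      double s = 0.0;
      const double *nr = &Nm(0, r), *mr = &M(0, r);
      for (int i = 0; i < N; ++i) s += nr[i] * phi[i];
      s /= N;
      for (int i = 0; i < N; ++i) drive[i] += mr[i] * s;
    }
    for (int j = 0; j < n_in; ++j) {
      const double uj = u(t, j);
      if (uj != 0.0) {
        const double *wj = &Win(0, j);
        for (int i = 0; i < N; ++i) drive[i] += wj[i] * uj;
      }
    }
    if (sigma > 0.0)
      for (int i = 0; i < N; ++i)
        x[i] = (1.0 - a) * x[i] + a * drive[i] + snoise * R::norm_rand();
    else
      for (int i = 0; i < N; ++i)
        x[i] = (1.0 - a) * x[i] + a * drive[i];
  }
  return List::create(_["X"] = X, _["o"] = o);
}

// Decision loss mean_{t >= dec_start} |o(t) - target| and its gradient
// w.r.t. M, Nm, Win, wout by backpropagation through time of the
// recurrence above (the noise realisation is drawn on the forward pass
// and held fixed going backward: the pathwise gradient). With
// dec_start = T (0-based step index) this reduces to the final-time loss
// |o(T) - target|.
// [[Rcpp::export]]
List rnn_loss_grad_cpp(NumericMatrix M, NumericMatrix Nm, NumericMatrix Win,
                       NumericVector wout, NumericMatrix u, double target,
                       double dt, double tau, double sigma,
                       int dec_start = -1) {
  const int N = M.nrow(), R = M.ncol(), T = u.nrow(), n_in = u.ncol();
  const double a = dt / tau, snoise = sigma * std::sqrt(dt / tau);

  // forward, storing phi_t contiguously per step
  std::vector<double> Phi((size_t)(T + 1) * N);
  std::vector<double> x(N, 0.0), drive(N);
  std::vector<double> kap((size_t)T * R);   // kappa_r(t), reused backward
  for (int t = 0; t <= T; ++t) {
    double *ph = &Phi[(size_t)t * N];
    for (int i = 0; i < N; ++i) ph[i] = std::tanh(x[i]);
    if (t == T) break;
    for (int i = 0; i < N; ++i) drive[i] = 0.0;
    for (int r = 0; r < R; ++r) {
      double s = 0.0;
      const double *nr = &Nm(0, r), *mr = &M(0, r);
      for (int i = 0; i < N; ++i) s += nr[i] * ph[i];
      s /= N;
      kap[(size_t)t * R + r] = s;
      for (int i = 0; i < N; ++i) drive[i] += mr[i] * s;
    }
    for (int j = 0; j < n_in; ++j) {
      const double uj = u(t, j);
      if (uj != 0.0) {
        const double *wj = &Win(0, j);
        for (int i = 0; i < N; ++i) drive[i] += wj[i] * uj;
      }
    }
    if (sigma > 0.0)
      for (int i = 0; i < N; ++i)
        x[i] = (1.0 - a) * x[i] + a * drive[i] + snoise * R::norm_rand();
    else
      for (int i = 0; i < N; ++i)
        x[i] = (1.0 - a) * x[i] + a * drive[i];
  }
  if (dec_start < 0 || dec_start > T) dec_start = T;
  const int n_dec = T - dec_start + 1;
  // per-step readouts over the decision window
  double loss = 0.0, oT = 0.0;
  std::vector<double> sgn(T + 1, 0.0);
  for (int t = dec_start; t <= T; ++t) {
    const double *ph = &Phi[(size_t)t * N];
    double ot = 0.0;
    for (int i = 0; i < N; ++i) ot += wout[i] * ph[i];
    if (t == T) oT = ot;
    loss += std::fabs(ot - target) / n_dec;
    sgn[t] = ((ot > target) ? 1.0 : ((ot < target) ? -1.0 : 0.0)) / n_dec;
  }

  NumericMatrix gM(N, R), gNm(N, R), gWin(N, n_in);
  NumericVector gwout(N);
  // dL/dx_t; readout seeds are injected at every decision step
  std::vector<double> g(N);
  const double *phT = &Phi[(size_t)T * N];
  for (int i = 0; i < N; ++i) {
    gwout[i] = sgn[T] * phT[i];
    g[i] = sgn[T] * wout[i] * (1.0 - phT[i] * phT[i]);
  }
  std::vector<double> mg(R);
  for (int t = T - 1; t >= 0; --t) {
    const double *ph = &Phi[(size_t)t * N];
    for (int r = 0; r < R; ++r) {
      double sm = 0.0;
      const double *mr = &M(0, r);
      for (int i = 0; i < N; ++i) sm += mr[i] * g[i];
      mg[r] = sm;
    }
    for (int r = 0; r < R; ++r) {
      const double cm = a * kap[(size_t)t * R + r], cn = a * mg[r] / N;
      double *gm = &gM(0, r), *gn = &gNm(0, r);
      for (int i = 0; i < N; ++i) {
        gm[i] += cm * g[i];
        gn[i] += cn * ph[i];
      }
    }
    for (int j = 0; j < n_in; ++j) {
      const double cu = a * u(t, j);
      if (cu != 0.0) {
        double *gw = &gWin(0, j);
        for (int i = 0; i < N; ++i) gw[i] += cu * g[i];
      }
    }
    // g_t = (1-a) g_{t+1} + phi'_t .* (a/N) Nm (M^T g_{t+1}), plus the
    // readout seed when t is inside the decision window
    const double st = sgn[t];
    for (int i = 0; i < N; ++i) {
      double rec = 0.0;
      for (int r = 0; r < R; ++r) rec += Nm(i, r) * mg[r];
      const double dphi = 1.0 - ph[i] * ph[i];
      g[i] = (1.0 - a) * g[i] + dphi * (a / N) * rec;
      if (st != 0.0) {
        g[i] += st * wout[i] * dphi;
        gwout[i] += st * ph[i];
      }
    }
  }
  return List::create(_["loss"] = loss, _["o_T"] = oT,
                      _["gM"] = gM, _["gNm"] = gNm,
                      _["gWin"] = gWin, _["gwout"] = gwout);
}

// Final readout o(T) only, for fast accuracy evaluation.
// [[Rcpp::export]]
double rnn_final_output_cpp(NumericMatrix M, NumericMatrix Nm,
                            NumericMatrix Win, NumericVector wout,
                            NumericMatrix u, double dt, double tau,
                            double sigma) {
  const int N = M.nrow(), R = M.ncol(), T = u.nrow(), n_in = u.ncol();
  const double a = dt / tau, snoise = sigma * std::sqrt(dt / tau);
  std::vector<double> x(N, 0.0), phi(N), drive(N);
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < N; ++i) phi[i] = std::tanh(x[i]);
    for (int i = 0; i < N; ++i) drive[i] = 0.0;
    for (int r = 0; r < R; ++r) {
      double s = 0.0;
      const double *nr = &Nm(0, r), *mr = &M(0, r);
      for (int i = 0; i < N; ++i) s += nr[i] * phi[i];
      s /= N;
      for (int i = 0; i < N; ++i) drive[i] += mr[i] * s;
    }
    for (int j = 0; j < n_in; ++j) {
      const double uj = u(t, j);
      if (uj != 0.0) {
        const double *wj = &Win(0, j);
        for (int i = 0; i < N; ++i) drive[i] += wj[i] * uj;
      }
    }
    if (sigma > 0.0)
      for (int i = 0; i < N; ++i)
        x[i] = (1.0 - a) * x[i] + a * drive[i] + snoise * R::norm_rand();
    else
      for (int i = 0; i < N; ++i)
        x[i] = (1.0 - a) * x[i] + a * drive[i];
  }
  double oT = 0.0;
  for (int i = 0; i < N; ++i) oT += wout[i] * std::tanh(x[i]);
  return oT;
}
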