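// Pseudo-spectral RK4 core for the two-species nonlocal vegetation model.
// Mirrors the R reference right-hand side exactly (same discrete operators:
// Fourier-space kernels, fixed-width approximation of the biomass-dependent
// root kernel, spectral Laplacian); lives here only for speed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

struct Model {
  double P, E1, E2, K1, K2, M1, M2, N, Lam1, Lam2, Gam1, Gam2,
         R1, R2, Th1, Th2, DW, Ws1, Ws2;
  int J;
  vec mass;      // kernel masses at the J width nodes
  double dBnode; // node spacing in B
  cube Kroot;    // nx x ny x J transfer functions
  mat Ks1, Ks2;  // sucker/dispersal transfer functions
  mat lap;       // -k^2
};

static Model parse_model(const List& pre) {
  Model md;
  List p = pre["params"];
  md.P = p["P"];   md.E1 = p["E1"];  md.E2 = p["E2"];
  md.K1 = p["K1"]; md.K2 = p["K2"];  md.M1 = p["M1"]; md.M2 = p["M2"];
  md.N = p["N"];   md.Lam1 = p["Lam1"]; md.Lam2 = p["Lam2"];
  md.Gam1 = p["Gam1"]; md.Gam2 = p["Gam2"];
  md.R1 = p["R1"]; md.R2 = p["R2"];
  md.Th1 = p["Th1"]; md.Th2 = p["Th2"]; md.DW = p["DW"];
  md.Ws1 = p["Wstar1"]; md.Ws2 = p["Wstar2"];
  md.J = Rcpp::as<int>(pre["J"]);
  md.mass = Rcpp::as<vec>(pre["mass"]);
  md.dBnode = Rcpp::as<double>(pre["dB_node"]);
  md.Kroot = Rcpp::as<cube>(pre["Kroot"]);
  md.Ks1 = Rcpp::as<mat>(pre["Ks1"]);
  md.Ks2 = Rcpp::as<mat>(pre["Ks2"]);
  md.lap = Rcpp::as<mat>(pre["lap"]);
  return md;
}

// forward / inverse transforms; 1D fields (single column) use the vector
// FFT — fft2 on an n x 1 matrix degenerates to n length-1 transforms and
// is an order of magnitude slower
static inline cx_mat fwd(const mat& f) {
  if (f.n_cols == 1) {
    cx_vec v = fft(conv_to<cx_vec>::from(f.col(0)));
    return cx_mat(v);
  }
  return fft2(conv_to<cx_mat>::from(f));
}

static inline mat conv_real(const cx_mat& fhat, const mat& khat) {
  if (fhat.n_cols == 1) {
    cx_vec v = ifft(cx_vec(fhat.col(0) % conv_to<cx_vec>::from(khat.col(0))));
    return mat(real(v));
  }
  return real(ifft2(fhat % conv_to<cx_mat>::from(khat)));
}

// interpolation weights of the kernel approximation at one biomass value:
// two bracketing nodes, rescaled for an exact total mass (1 + E1*B)^2
// t is deliberately not clamped at the extreme segments (linear
// extrapolation keeps B -> w(B) kink-free at B = 0; matches kernel_weights)
static inline void weights_at(const Model& md, double B,
                              int& j0, double& w0, double& w1) {
  double u = B / md.dBnode;
  j0 = (int)std::floor(u);
  if (j0 < 0) j0 = 0;
  if (j0 > md.J - 2) j0 = md.J - 2;
  double t = u - j0;
  double tot = (1 + md.E1 * B) * (1 + md.E1 * B);
  double denom = (1 - t) * md.mass(j0) + t * md.mass(j0 + 1);
  double resc = denom > 0.1 ? tot / denom : 0.0;
  w0 = resc * (1 - t);
  w1 = resc * t;
}

static void rhs(const mat& B1, const mat& B2, const mat& W, const Model& md,
                mat& dB1, mat& dB2, mat& dW) {
  const uword nx = B1.n_rows, ny = B1.n_cols, n = nx * ny;
  cx_mat What = fwd(W);
  cx_mat B1hat = fwd(B1);
  cx_mat B2hat = fwd(B2);

  // per-point two-node weights
  std::vector<int> j0(n);
  vec w0(n), w1(n);
  for (uword e = 0; e < n; ++e) {
    int jj; double a, b;
    weights_at(md, B1(e), jj, a, b);
    j0[e] = jj; w0(e) = a; w1(e) = b;
  }

  mat Gb1(nx, ny, fill::zeros), Gw1(nx, ny, fill::zeros);
  for (int j = 0; j < md.J; ++j) {
    mat wj(nx, ny, fill::zeros);
    bool any = false;
    for (uword e = 0; e < n; ++e) {
      if (j0[e] == j)          { wj(e) += w0(e); any = true; }
      if (j0[e] == j - 1)      { wj(e) += w1(e); any = true; }
    }
    if (!any) continue;
    Gb1 += wj % conv_real(What, md.Kroot.slice(j));
    cx_mat srchat = fwd(wj % B1);
    Gw1 += conv_real(srchat, md.Kroot.slice(j));
  }
  Gb1 *= md.Lam1;
  Gw1 *= md.Gam1;

  mat fac2 = square(1 + md.E2 * B2);
  mat Gb2 = md.Lam2 * (W % fac2);
  mat Gw2 = md.Gam2 * (B2 % fac2);

  mat D1 = md.Th1 * (W / (W + md.Ws1)) % conv_real(B1hat, md.Ks1);
  mat D2 = md.Th2 * (W / (W + md.Ws2)) % conv_real(B2hat, md.Ks2);

  dB1 = Gb1 % B1 % (1 - B1 / md.K1) - md.M1 * B1 + D1;
  dB2 = Gb2 % B2 % (1 - B2 / md.K2) - md.M2 * B2 + D2;
  mat L = md.N * (1 - (md.R1 / md.K1) * B1 - (md.R2 / md.K2) * B2);
  dW = md.P - L % W - W % (Gw1 + Gw2) + md.DW * conv_real(What, md.lap);
}

// [[Rcpp::export]]
List core_rhs(const arma::mat& B1, const arma::mat& B2, const arma::mat& W,
              const List& pre) {
  Model md = parse_model(pre);
  mat dB1, dB2, dW;
  rhs(B1, B2, W, md, dB1, dB2, dW);
  return List::create(Named("dB1") = dB1, Named("dB2") = dB2,
                      Named("dW") = dW);
}

// One classical RK4 step; returns clipped mass (field units * cells)
static double rk4_step(mat& B1, mat& B2, mat& W, const Model& md, double dt,
                       bool clip, double& minval) {
  mat k1a, k1b, k1c, k2a, k2b, k2c, k3a, k3b, k3c, k4a, k4b, k4c;
  rhs(B1, B2, W, md, k1a, k1b, k1c);
  rhs(B1 + 0.5 * dt * k1a, B2 + 0.5 * dt * k1b, W + 0.5 * dt * k1c,
      md, k2a, k2b, k2c);
  rhs(B1 + 0.5 * dt * k2a, B2 + 0.5 * dt * k2b, W + 0.5 * dt * k2c,
      md, k3a, k3b, k3c);
  rhs(B1 + dt * k3a, B2 + dt * k3b, W + dt * k3c, md, k4a, k4b, k4c);
  B1 += (dt / 6.0) * (k1a + 2 * k2a + 2 * k3a + k4a);
  B2 += (dt / 6.0) * (k1b + 2 * k2b + 2 * k3b + k4b);
  W  += (dt / 6.0) * (k1c + 2 * k2c + 2 * k3c + k4c);
  double mn = std::min(B1.min(), std::min(B2.min(), W.min()));
  if (mn < minval) minval = mn;
  double clipped = 0.0;
  if (clip && mn < 0) {
    for (uword e = 0; e < B1.n_elem; ++e) {
      if (B1(e) < 0) { clipped -= B1(e); B1(e) = 0; }
      if (B2(e) < 0) { clipped -= B2(e); B2(e) = 0; }
      if (W(e) < 0)  { clipped -= W(e);  W(e) = 0; }
    }
  }
  return clipped;
}

// [[Rcpp::export]]
List core_step(const arma::mat& B1, const arma::mat& B2, const arma::mat& W,
               const List& pre, double dt, bool clip = true) {
  Model md = parse_model(pre);
  mat b1 = B1, b2 = B2, w = W;
  double minval = 0.0;
  double clipped = rk4_step(b1, b2, w, md, dt, clip, minval);
  return List::create(Named("B1") = b1, Named("B2") = b2, Named("W") = w,
                      Named("clipped") = clipped, Named("minval") = minval);
}

// Advance nsteps (or until steady); steady when the mean absolute per-step
// change summed over the three fields drops below steady_tol.
// [[Rcpp::export]]
List core_integrate(const arma::mat& B1, const arma::mat& B2,
                    const arma::mat& W, const List& pre, double dt,
                    int nsteps, double steady_tol, bool clip = true) {
  Model md = parse_model(pre);
  mat b1 = B1, b2 = B2, w = W;
  double clipped = 0.0, minval = 0.0;
  bool steady = false, blowup = false;
  int steps = 0;
  mat p1, p2, pw;
  for (int s = 0; s < nsteps; ++s) {
    p1 = b1; p2 = b2; pw = w;
    clipped += rk4_step(b1, b2, w, md, dt, clip, minval);
    if (!b1.is_finite() || !b2.is_finite() || !w.is_finite()) {
      // report the last valid state
      b1 = p1; b2 = p2; w = pw;
      blowup = true;
      break;
    }
    ++steps;
    double change = accu(abs(b1 - p1)) + accu(abs(b2 - p2)) +
                    accu(abs(w - pw));
    if (change / b1.n_elem < steady_tol) { steady = true; break; }
  }
  return List::create(Named("B1") = b1, Named("B2") = b2, Named("W") = w,
                      Named("steps") = steps, Named("steady") = steady,
                      Named("blowup") = blowup, Named("clipped") = clipped,
                      Named("minval") = minval);
}
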