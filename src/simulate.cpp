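// Euler integrator and damped fixed-point solver for the microcircuit
// rate model. Conventions (fixed so runs are bit-reproducible):
// per step, synaptic currents are computed from the current rates, then
// calcium events, then the activation variables are updated, then rates
// are rectified. PC drive is I - theta, unrectified; interneuron drive
// carries no rheobase.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Net {
  arma::mat W_EE, W_EP, W_EnM, W_PE, W_PP, W_PS, W_PV, W_SE, W_SV, W_VE, W_VS;
  std::vector<arma::mat> W_DE, W_DM;
  arma::uvec idx_M, idx_nM;
  arma::vec x_E, x_P, x_S, x_V;
  arma::mat x_D;
  double tau_E, tau_I, theta, lambda_D, lambda_E, c_amp, theta_c;
  bool calcium_shared;
  int K;
};

static Net build_net(const List& W, const List& x, const List& pars,
                     const IntegerVector& idx_M, const IntegerVector& idx_nM) {
  Net n;
  n.W_EE = as<arma::mat>(W["EE"]);   n.W_EP = as<arma::mat>(W["EP"]);
  n.W_EnM = as<arma::mat>(W["EnM"]); n.W_PE = as<arma::mat>(W["PE"]);
  n.W_PP = as<arma::mat>(W["PP"]);   n.W_PS = as<arma::mat>(W["PS"]);
  n.W_PV = as<arma::mat>(W["PV"]);   n.W_SE = as<arma::mat>(W["SE"]);
  n.W_SV = as<arma::mat>(W["SV"]);   n.W_VE = as<arma::mat>(W["VE"]);
  n.W_VS = as<arma::mat>(W["VS"]);
  n.K = W.containsElementNamed("D2E") ? 2 : 1;
  for (int k = 1; k <= n.K; ++k) {
    std::string de = "D" + std::to_string(k) + "E";
    std::string dm = "D" + std::to_string(k) + "M";
    n.W_DE.push_back(as<arma::mat>(W[de]));
    n.W_DM.push_back(as<arma::mat>(W[dm]));
  }
  n.idx_M = as<arma::uvec>(idx_M) - 1;   // to 0-based
  n.idx_nM = as<arma::uvec>(idx_nM) - 1;
  n.x_E = as<arma::vec>(x["x_E"]); n.x_P = as<arma::vec>(x["x_P"]);
  n.x_S = as<arma::vec>(x["x_S"]); n.x_V = as<arma::vec>(x["x_V"]);
  n.x_D = as<arma::mat>(x["x_D"]);
  n.tau_E = as<double>(pars["tau_E"]); n.tau_I = as<double>(pars["tau_I"]);
  n.theta = as<double>(pars["theta"]);
  n.lambda_D = as<double>(pars["lambda_D"]);
  n.lambda_E = as<double>(pars["lambda_E"]);
  n.c_amp = as<double>(pars["c_amp"]); n.theta_c = as<double>(pars["theta_c"]);
  n.calcium_shared = as<bool>(pars["calcium_shared"]);
  return n;
}

struct Drive {
  arma::vec d_E, d_P, d_S, d_V, I_E_syn;
  arma::mat I_D_syn, calcium;
};

// steady-state map: drives implied by the current rates
static void compute_drive(const Net& n, const arma::vec& r_E,
                          const arma::vec& r_P, const arma::vec& r_S,
                          const arma::vec& r_V, Drive& d) {
  arma::vec r_M = r_S.elem(n.idx_M);
  arma::vec r_nM = r_S.elem(n.idx_nM);
  d.I_E_syn = n.x_E + n.W_EE * r_E - n.W_EP * r_P - n.W_EnM * r_nM;
  const int npc = r_E.n_elem;
  d.I_D_syn.set_size(npc, n.K);
  d.calcium.set_size(npc, n.K);
  for (int k = 0; k < n.K; ++k) {
    d.I_D_syn.col(k) = n.x_D.col(k) + n.W_DE[k] * r_E - n.W_DM[k] * r_M;
    // within-dendrite current deciding the calcium event (strict threshold)
    arma::vec I0 = n.lambda_E * d.I_E_syn + (1.0 - n.lambda_D) * d.I_D_syn.col(k);
    d.calcium.col(k) = n.c_amp * arma::conv_to<arma::vec>::from(I0 > n.theta_c);
  }
  if (n.calcium_shared && n.K > 1) {
    arma::vec any_c = arma::max(d.calcium, 1);
    for (int k = 0; k < n.K; ++k) d.calcium.col(k) = any_c;
  }
  arma::vec I = (1.0 - n.lambda_E) * d.I_E_syn;
  for (int k = 0; k < n.K; ++k) {
    I += n.lambda_D * arma::clamp(d.I_D_syn.col(k) + d.calcium.col(k),
                                  0.0, arma::datum::inf);
  }
  d.d_E = I - n.theta;
  d.d_P = n.x_P + n.W_PE * r_E - n.W_PP * r_P - n.W_PS * r_S - n.W_PV * r_V;
  d.d_S = n.x_S + n.W_SE * r_E - n.W_SV * r_V;
  d.d_V = n.x_V + n.W_VE * r_E - n.W_VS * r_S;
}

static List pack_state(const Net& n, const arma::vec& h_E, const arma::vec& h_P,
                       const arma::vec& h_S, const arma::vec& h_V,
                       bool converged, int steps, double resid) {
  arma::vec r_E = arma::clamp(h_E, 0.0, arma::datum::inf);
  arma::vec r_P = arma::clamp(h_P, 0.0, arma::datum::inf);
  arma::vec r_S = arma::clamp(h_S, 0.0, arma::datum::inf);
  arma::vec r_V = arma::clamp(h_V, 0.0, arma::datum::inf);
  Drive d;
  compute_drive(n, r_E, r_P, r_S, r_V, d);
  return List::create(
    _["h_E"] = h_E, _["h_P"] = h_P, _["h_S"] = h_S, _["h_V"] = h_V,
    _["r_E"] = r_E, _["r_P"] = r_P, _["r_S"] = r_S, _["r_V"] = r_V,
    _["I_E_syn"] = d.I_E_syn, _["I_D_syn"] = d.I_D_syn,
    _["calcium"] = d.calcium, _["A_dend"] = d.I_D_syn + d.calcium,
    _["converged"] = converged, _["steps"] = steps, _["resid"] = resid);
}

// [[Rcpp::export]]
List sim_euler_cpp(List W, List x, List h0, List pars,
                   IntegerVector idx_M, IntegerVector idx_nM,
                   double dt, int n_steps, double tol,
                   bool early_exit, int check_window) {
  Net n = build_net(W, x, pars, idx_M, idx_nM);
  arma::vec h_E = as<arma::vec>(h0["h_E"]), h_P = as<arma::vec>(h0["h_P"]);
  arma::vec h_S = as<arma::vec>(h0["h_S"]), h_V = as<arma::vec>(h0["h_V"]);
  arma::vec r_E = arma::clamp(h_E, 0.0, arma::datum::inf);
  arma::vec r_P = arma::clamp(h_P, 0.0, arma::datum::inf);
  arma::vec r_S = arma::clamp(h_S, 0.0, arma::datum::inf);
  arma::vec r_V = arma::clamp(h_V, 0.0, arma::datum::inf);
  Drive d;
  double aE = dt / n.tau_E, aI = dt / n.tau_I;
  double max_drate = R_PosInf;
  int quiet = 0, step = 0;
  bool converged = false;
  for (step = 0; step < n_steps; ++step) {
    compute_drive(n, r_E, r_P, r_S, r_V, d);
    h_E += aE * (d.d_E - h_E);
    h_P += aI * (d.d_P - h_P);
    h_S += aI * (d.d_S - h_S);
    h_V += aI * (d.d_V - h_V);
    if (!h_E.is_finite() || !h_P.is_finite() || !h_S.is_finite() ||
        !h_V.is_finite()) {
      stop("non-finite network state at step %d", step + 1);
    }
    arma::vec nr_E = arma::clamp(h_E, 0.0, arma::datum::inf);
    arma::vec nr_P = arma::clamp(h_P, 0.0, arma::datum::inf);
    arma::vec nr_S = arma::clamp(h_S, 0.0, arma::datum::inf);
    arma::vec nr_V = arma::clamp(h_V, 0.0, arma::datum::inf);
    double md = 0.0;
    md = std::max(md, arma::abs(nr_E - r_E).max());
    if (nr_P.n_elem) md = std::max(md, arma::abs(nr_P - r_P).max());
    if (nr_S.n_elem) md = std::max(md, arma::abs(nr_S - r_S).max());
    if (nr_V.n_elem) md = std::max(md, arma::abs(nr_V - r_V).max());
    max_drate = md / dt;
    r_E = nr_E; r_P = nr_P; r_S = nr_S; r_V = nr_V;
    if (max_drate < tol) {
      if (++quiet >= check_window) { converged = true; ++step; break; }
    } else {
      quiet = 0;
    }
    if (!early_exit) converged = (max_drate < tol);
  }
  if (!early_exit) converged = (max_drate < tol);
  return pack_state(n, h_E, h_P, h_S, h_V, converged, step, max_drate);
}

// Direct steady-state solver. The fixed point of the dynamics satisfies a
// piecewise-linear system: once the rectification pattern (which units have
// h > 0, which dendritic brackets are open, which branches have a calcium
// event) is fixed, the equations are linear. The solver iterates between
// solving the linear system for a given pattern and recomputing the pattern
// from the solution; it converges when the pattern reproduces itself, and
// the residual of the full nonlinear steady-state map is reported so the
// caller can verify (and fall back to Euler integration if needed).
// [[Rcpp::export]]
List solve_newton_cpp(List W, List x, List h0, List pars,
                      IntegerVector idx_M, IntegerVector idx_nM,
                      int max_iter, double tol) {
  Net n = build_net(W, x, pars, idx_M, idx_nM);
  arma::vec h_E = as<arma::vec>(h0["h_E"]), h_P = as<arma::vec>(h0["h_P"]);
  arma::vec h_S = as<arma::vec>(h0["h_S"]), h_V = as<arma::vec>(h0["h_V"]);
  const int nE = h_E.n_elem, nP = h_P.n_elem, nS = h_S.n_elem,
            nV = h_V.n_elem;
  const int N = nE + nP + nS + nV;
  const int oP = nE, oS = nE + nP, oV = nE + nP + nS;
  Drive d;

  auto rect = [](const arma::vec& v) {
    return arma::conv_to<arma::vec>::from(v > 0);
  };
  // initial pattern from the warm-start state
  arma::vec r_E = arma::clamp(h_E, 0.0, arma::datum::inf);
  arma::vec r_P = arma::clamp(h_P, 0.0, arma::datum::inf);
  arma::vec r_S = arma::clamp(h_S, 0.0, arma::datum::inf);
  arma::vec r_V = arma::clamp(h_V, 0.0, arma::datum::inf);
  compute_drive(n, r_E, r_P, r_S, r_V, d);
  arma::vec aE = rect(h_E), aP = rect(h_P), aS = rect(h_S), aV = rect(h_V);
  arma::mat bk(nE, n.K), ck(nE, n.K);
  for (int k = 0; k < n.K; ++k) {
    bk.col(k) = rect(d.I_D_syn.col(k) + d.calcium.col(k));
    ck.col(k) = rect(d.calcium.col(k));
  }

  auto mask_cols = [](const arma::mat& Wm, const arma::vec& a) {
    arma::mat out = Wm;
    arma::uvec off = arma::find(a == 0);
    if (off.n_elem) out.cols(off).zeros();
    return out;
  };

  bool converged = false;
  int it = 0;
  double resid = R_PosInf;
  arma::vec z(N);
  for (it = 0; it < max_iter; ++it) {
    arma::vec aM = aS.elem(n.idx_M), anM = aS.elem(n.idx_nM);
    arma::mat M(N, N, arma::fill::zeros);
    arma::vec b(N);
    double lE = n.lambda_E, lD = n.lambda_D;
    // PC soma rows
    arma::mat WEEa = mask_cols(n.W_EE, aE);
    arma::mat WEPa = mask_cols(n.W_EP, aP);
    arma::mat WEnMa = mask_cols(n.W_EnM, anM);
    M.submat(0, 0, nE - 1, nE - 1) = (1 - lE) * WEEa;
    if (nP) M.submat(0, oP, nE - 1, oP + nP - 1) = -(1 - lE) * WEPa;
    arma::mat ME_S(nE, nS, arma::fill::zeros);
    for (arma::uword j = 0; j < n.idx_nM.n_elem; ++j) {
      ME_S.col(n.idx_nM[j]) -= (1 - lE) * WEnMa.col(j);
    }
    arma::vec bE = (1 - lE) * n.x_E - n.theta;
    for (int k = 0; k < n.K; ++k) {
      arma::mat WDEa = mask_cols(n.W_DE[k], aE);
      arma::mat WDMa = mask_cols(n.W_DM[k], aM);
      WDEa.each_col() %= bk.col(k);
      WDMa.each_col() %= bk.col(k);
      M.submat(0, 0, nE - 1, nE - 1) += lD * WDEa;
      for (arma::uword j = 0; j < n.idx_M.n_elem; ++j) {
        ME_S.col(n.idx_M[j]) -= lD * WDMa.col(j);
      }
      bE += lD * bk.col(k) % (n.x_D.col(k) + n.c_amp * ck.col(k));
    }
    if (nS) M.submat(0, oS, nE - 1, oS + nS - 1) = ME_S;
    b.subvec(0, nE - 1) = bE;
    // interneuron rows
    if (nP) {
      M.submat(oP, 0, oP + nP - 1, nE - 1) = mask_cols(n.W_PE, aE);
      M.submat(oP, oP, oP + nP - 1, oP + nP - 1) = -mask_cols(n.W_PP, aP);
      if (nS) M.submat(oP, oS, oP + nP - 1, oS + nS - 1) = -mask_cols(n.W_PS, aS);
      if (nV) M.submat(oP, oV, oP + nP - 1, oV + nV - 1) = -mask_cols(n.W_PV, aV);
      b.subvec(oP, oP + nP - 1) = n.x_P;
    }
    if (nS) {
      M.submat(oS, 0, oS + nS - 1, nE - 1) = mask_cols(n.W_SE, aE);
      if (nV) M.submat(oS, oV, oS + nS - 1, oV + nV - 1) = -mask_cols(n.W_SV, aV);
      b.subvec(oS, oS + nS - 1) = n.x_S;
    }
    if (nV) {
      M.submat(oV, 0, oV + nV - 1, nE - 1) = mask_cols(n.W_VE, aE);
      if (nS) M.submat(oV, oS, oV + nV - 1, oS + nS - 1) = -mask_cols(n.W_VS, aS);
      b.subvec(oV, oV + nV - 1) = n.x_V;
    }
    arma::mat A = arma::eye(N, N) - M;
    bool ok = arma::solve(z, A, b, arma::solve_opts::no_approx);
    if (!ok || !z.is_finite()) break;
    h_E = z.subvec(0, nE - 1);
    if (nP) h_P = z.subvec(oP, oP + nP - 1);
    if (nS) h_S = z.subvec(oS, oS + nS - 1);
    if (nV) h_V = z.subvec(oV, oV + nV - 1);
    r_E = arma::clamp(h_E, 0.0, arma::datum::inf);
    r_P = arma::clamp(h_P, 0.0, arma::datum::inf);
    r_S = arma::clamp(h_S, 0.0, arma::datum::inf);
    r_V = arma::clamp(h_V, 0.0, arma::datum::inf);
    compute_drive(n, r_E, r_P, r_S, r_V, d);
    // residual of the steady-state map
    double md = arma::abs(d.d_E - h_E).max();
    if (nP) md = std::max(md, arma::abs(d.d_P - h_P).max());
    if (nS) md = std::max(md, arma::abs(d.d_S - h_S).max());
    if (nV) md = std::max(md, arma::abs(d.d_V - h_V).max());
    resid = md;
    // recompute pattern; converged when it reproduces itself
    arma::vec naE = rect(h_E), naP = rect(h_P), naS = rect(h_S),
              naV = rect(h_V);
    arma::mat nbk(nE, n.K), nck(nE, n.K);
    for (int k = 0; k < n.K; ++k) {
      nbk.col(k) = rect(d.I_D_syn.col(k) + d.calcium.col(k));
      nck.col(k) = rect(d.calcium.col(k));
    }
    bool same = arma::approx_equal(naE, aE, "absdiff", 0.5) &&
      arma::approx_equal(naP, aP, "absdiff", 0.5) &&
      arma::approx_equal(naS, aS, "absdiff", 0.5) &&
      arma::approx_equal(naV, aV, "absdiff", 0.5) &&
      arma::approx_equal(nbk, bk, "absdiff", 0.5) &&
      arma::approx_equal(nck, ck, "absdiff", 0.5);
    aE = naE; aP = naP; aS = naS; aV = naV; bk = nbk; ck = nck;
    if (same && md < tol) { converged = true; ++it; break; }
  }
  return pack_state(n, h_E, h_P, h_S, h_V, converged, it, resid);
}

// ---------------------------------------------------------------------------
// Compiled training loop. Per presentation: draw a noisy match phase, solve
// the steady state (pattern iteration with LU reuse and iterative
// refinement across presentations -- the rectification pattern and the
// weights drift slowly during training), apply all plastic updates from the
// frozen steady state, then do the same for a baseline phase. Noise is
// drawn from R's RNG so runs are reproducible from set.seed().

struct SteadySolver {
  arma::mat L, U, P;            // stale LU factors of A = I - M(pattern)
  arma::vec aE, aP, aS, aV;     // pattern the factors belong to
  arma::mat bk, ck;
  bool valid = false;

  static arma::vec rect01(const arma::vec& v) {
    return arma::conv_to<arma::vec>::from(v > 0);
  }

  void build(const Net& n, const arma::vec& aM, const arma::vec& anM,
             arma::mat& A, arma::vec& b) const {
    const int nE = n.x_E.n_elem, nP = n.x_P.n_elem, nS = n.x_S.n_elem,
              nV = n.x_V.n_elem;
    const int N = nE + nP + nS + nV;
    const int oP = nE, oS = nE + nP, oV = nE + nP + nS;
    double lE = n.lambda_E, lD = n.lambda_D;
    arma::mat M(N, N, arma::fill::zeros);
    b.set_size(N);
    auto mask_cols = [](const arma::mat& Wm, const arma::vec& a) {
      arma::mat out = Wm;
      arma::uvec off = arma::find(a == 0);
      if (off.n_elem) out.cols(off).zeros();
      return out;
    };
    M.submat(0, 0, nE - 1, nE - 1) = (1 - lE) * mask_cols(n.W_EE, aE);
    if (nP) M.submat(0, oP, nE - 1, oP + nP - 1) =
      -(1 - lE) * mask_cols(n.W_EP, aP);
    arma::mat ME_S(nE, nS, arma::fill::zeros);
    arma::mat WEnMa = mask_cols(n.W_EnM, anM);
    for (arma::uword j = 0; j < n.idx_nM.n_elem; ++j) {
      ME_S.col(n.idx_nM[j]) -= (1 - lE) * WEnMa.col(j);
    }
    arma::vec bE = (1 - lE) * n.x_E - n.theta;
    for (int k = 0; k < n.K; ++k) {
      arma::mat WDEa = mask_cols(n.W_DE[k], aE);
      arma::mat WDMa = mask_cols(n.W_DM[k], aM);
      WDEa.each_col() %= bk.col(k);
      WDMa.each_col() %= bk.col(k);
      M.submat(0, 0, nE - 1, nE - 1) += lD * WDEa;
      for (arma::uword j = 0; j < n.idx_M.n_elem; ++j) {
        ME_S.col(n.idx_M[j]) -= lD * WDMa.col(j);
      }
      bE += lD * bk.col(k) % (n.x_D.col(k) + n.c_amp * ck.col(k));
    }
    if (nS) M.submat(0, oS, nE - 1, oS + nS - 1) = ME_S;
    b.subvec(0, nE - 1) = bE;
    if (nP) {
      M.submat(oP, 0, oP + nP - 1, nE - 1) = mask_cols(n.W_PE, aE);
      M.submat(oP, oP, oP + nP - 1, oP + nP - 1) = -mask_cols(n.W_PP, aP);
      if (nS) M.submat(oP, oS, oP + nP - 1, oS + nS - 1) =
        -mask_cols(n.W_PS, aS);
      if (nV) M.submat(oP, oV, oP + nP - 1, oV + nV - 1) =
        -mask_cols(n.W_PV, aV);
      b.subvec(oP, oP + nP - 1) = n.x_P;
    }
    if (nS) {
      M.submat(oS, 0, oS + nS - 1, nE - 1) = mask_cols(n.W_SE, aE);
      if (nV) M.submat(oS, oV, oS + nS - 1, oV + nV - 1) =
        -mask_cols(n.W_SV, aV);
      b.subvec(oS, oS + nS - 1) = n.x_S;
    }
    if (nV) {
      M.submat(oV, 0, oV + nV - 1, nE - 1) = mask_cols(n.W_VE, aE);
      if (nS) M.submat(oV, oS, oV + nV - 1, oS + nS - 1) =
        -mask_cols(n.W_VS, aS);
      b.subvec(oV, oV + nV - 1) = n.x_V;
    }
    A = -M;
    A.diag() += 1.0;
  }

  bool same_pattern(const arma::vec& naE, const arma::vec& naP,
                    const arma::vec& naS, const arma::vec& naV,
                    const arma::mat& nbk, const arma::mat& nck) const {
    return valid &&
      arma::approx_equal(naE, aE, "absdiff", 0.5) &&
      arma::approx_equal(naP, aP, "absdiff", 0.5) &&
      arma::approx_equal(naS, aS, "absdiff", 0.5) &&
      arma::approx_equal(naV, aV, "absdiff", 0.5) &&
      arma::approx_equal(nbk, bk, "absdiff", 0.5) &&
      arma::approx_equal(nck, ck, "absdiff", 0.5);
  }

  // solve A z = b by iterative refinement on the stored factors; returns
  // false if the factors are too stale to converge
  bool refine(const arma::mat& A, const arma::vec& b, arma::vec& z) const {
    for (int it = 0; it < 12; ++it) {
      arma::vec r = b - A * z;
      double rn = arma::abs(r).max();
      if (rn < 1e-11) return true;
      arma::vec y = arma::solve(arma::trimatl(L), P * r);
      z += arma::solve(arma::trimatu(U), y);
    }
    return arma::abs(b - A * z).max() < 1e-11;
  }

  // full pattern-iteration solve; h holds the stacked warm start on entry
  // and the solution on exit. Returns the converged flag.
  bool solve(const Net& n, arma::vec& h_E, arma::vec& h_P, arma::vec& h_S,
             arma::vec& h_V, Drive& d, int max_iter, double tol) {
    const int nE = h_E.n_elem, nP = h_P.n_elem, nS = h_S.n_elem,
              nV = h_V.n_elem;
    const int oP = nE, oS = nE + nP, oV = nE + nP + nS;
    const int N = nE + nP + nS + nV;
    arma::vec r_E = arma::clamp(h_E, 0.0, arma::datum::inf);
    arma::vec r_P = arma::clamp(h_P, 0.0, arma::datum::inf);
    arma::vec r_S = arma::clamp(h_S, 0.0, arma::datum::inf);
    arma::vec r_V = arma::clamp(h_V, 0.0, arma::datum::inf);
    compute_drive(n, r_E, r_P, r_S, r_V, d);
    arma::vec naE = rect01(h_E), naP = rect01(h_P), naS = rect01(h_S),
              naV = rect01(h_V);
    arma::mat nbk(nE, n.K), nck(nE, n.K);
    for (int k = 0; k < n.K; ++k) {
      nbk.col(k) = rect01(d.I_D_syn.col(k) + d.calcium.col(k));
      nck.col(k) = rect01(d.calcium.col(k));
    }
    arma::vec z(N);
    z.subvec(0, nE - 1) = h_E;
    if (nP) z.subvec(oP, oP + nP - 1) = h_P;
    if (nS) z.subvec(oS, oS + nS - 1) = h_S;
    if (nV) z.subvec(oV, oV + nV - 1) = h_V;
    for (int it = 0; it < max_iter; ++it) {
      aE = naE; aP = naP; aS = naS; aV = naV; bk = nbk; ck = nck;
      arma::vec aM = aS.elem(n.idx_M), anM = aS.elem(n.idx_nM);
      arma::mat A; arma::vec b;
      build(n, aM, anM, A, b);
      // stale factors usually still precondition well: the weights and the
      // rectification pattern drift slowly between presentations
      bool solved = valid && refine(A, b, z);
      if (!solved) {
        if (!arma::lu(L, U, P, A)) return false;
        valid = true;
        if (!refine(A, b, z)) {
          if (!arma::solve(z, A, b, arma::solve_opts::no_approx)) return false;
        }
      }
      if (!z.is_finite()) return false;
      h_E = z.subvec(0, nE - 1);
      if (nP) h_P = z.subvec(oP, oP + nP - 1);
      if (nS) h_S = z.subvec(oS, oS + nS - 1);
      if (nV) h_V = z.subvec(oV, oV + nV - 1);
      r_E = arma::clamp(h_E, 0.0, arma::datum::inf);
      r_P = arma::clamp(h_P, 0.0, arma::datum::inf);
      r_S = arma::clamp(h_S, 0.0, arma::datum::inf);
      r_V = arma::clamp(h_V, 0.0, arma::datum::inf);
      compute_drive(n, r_E, r_P, r_S, r_V, d);
      double md = arma::abs(d.d_E - h_E).max();
      if (nP) md = std::max(md, arma::abs(d.d_P - h_P).max());
      if (nS) md = std::max(md, arma::abs(d.d_S - h_S).max());
      if (nV) md = std::max(md, arma::abs(d.d_V - h_V).max());
      naE = rect01(h_E); naP = rect01(h_P); naS = rect01(h_S);
      naV = rect01(h_V);
      for (int k = 0; k < n.K; ++k) {
        nbk.col(k) = rect01(d.I_D_syn.col(k) + d.calcium.col(k));
        nck.col(k) = rect01(d.calcium.col(k));
      }
      if (md < tol &&
          arma::approx_equal(naE, aE, "absdiff", 0.5) &&
          arma::approx_equal(naP, aP, "absdiff", 0.5) &&
          arma::approx_equal(naS, aS, "absdiff", 0.5) &&
          arma::approx_equal(naV, aV, "absdiff", 0.5) &&
          arma::approx_equal(nbk, bk, "absdiff", 0.5) &&
          arma::approx_equal(nck, ck, "absdiff", 0.5)) {
        return true;
      }
    }
    return false;
  }
};

// Euler settle used as a fallback when the pattern iteration cycles
static void euler_settle(const Net& n, arma::vec& h_E, arma::vec& h_P,
                         arma::vec& h_S, arma::vec& h_V, Drive& d,
                         double dt, double duration, double tol) {
  double aE = dt / n.tau_E, aI = dt / n.tau_I;
  int n_steps = (int)std::ceil(duration / dt);
  int window = (int)std::ceil(0.001 / dt), quiet = 0;
  arma::vec r_E = arma::clamp(h_E, 0.0, arma::datum::inf);
  arma::vec r_P = arma::clamp(h_P, 0.0, arma::datum::inf);
  arma::vec r_S = arma::clamp(h_S, 0.0, arma::datum::inf);
  arma::vec r_V = arma::clamp(h_V, 0.0, arma::datum::inf);
  for (int s = 0; s < n_steps; ++s) {
    compute_drive(n, r_E, r_P, r_S, r_V, d);
    h_E += aE * (d.d_E - h_E);
    h_P += aI * (d.d_P - h_P);
    h_S += aI * (d.d_S - h_S);
    h_V += aI * (d.d_V - h_V);
    arma::vec nr_E = arma::clamp(h_E, 0.0, arma::datum::inf);
    arma::vec nr_P = arma::clamp(h_P, 0.0, arma::datum::inf);
    arma::vec nr_S = arma::clamp(h_S, 0.0, arma::datum::inf);
    arma::vec nr_V = arma::clamp(h_V, 0.0, arma::datum::inf);
    double md = arma::abs(nr_E - r_E).max();
    if (nr_P.n_elem) md = std::max(md, arma::abs(nr_P - r_P).max());
    if (nr_S.n_elem) md = std::max(md, arma::abs(nr_S - r_S).max());
    if (nr_V.n_elem) md = std::max(md, arma::abs(nr_V - r_V).max());
    r_E = nr_E; r_P = nr_P; r_S = nr_S; r_V = nr_V;
    if (md / dt < tol) { if (++quiet >= window) break; } else quiet = 0;
  }
  compute_drive(n, r_E, r_P, r_S, r_V, d);
}

static inline arma::mat logistic_mat(const arma::mat& v) {
  return 1.0 / (1.0 + arma::exp(-v));
}

static inline arma::mat softplus_mat(const arma::mat& v) {
  return arma::clamp(v, 0.0, arma::datum::inf) +
    arma::log1p(arma::exp(-arma::abs(v)));
}

// [[Rcpp::export]]
List train_loop_cpp(List W, List vparams, List masks, List x_base,
                    List pars, List plast, IntegerVector idx_M,
                    IntegerVector idx_nM, NumericMatrix preferred_pc,
                    NumericMatrix preferred_som, List tuning,
                    NumericVector train_feature, NumericMatrix epsilon,
                    int n_pairs, double noise_sigma, bool update_baseline,
                    bool som_untuned, double early_frac, int early_window,
                    int record_every, int newton_iter, double newton_tol,
                    double dt, double steady_tol) {
  Net net = build_net(W, x_base, pars, idx_M, idx_nM);
  arma::mat pref_pc = as<arma::mat>(preferred_pc);
  arma::mat pref_som = as<arma::mat>(preferred_som);
  const double sig_pc = as<double>(tuning["sigma_pc"]);
  const double sig_som = as<double>(tuning["sigma_som"]);
  const double r_max = as<double>(tuning["r_max"]);
  const double amp_pv = as<double>(tuning["untuned_amp_pv"]);
  const double amp_vip = as<double>(tuning["untuned_amp_vip"]);
  const double eta_EP = as<double>(plast["eta_EP"]);
  const double eta_ES = as<double>(plast["eta_ES"]);
  const double eta_DS = as<double>(plast["eta_DS"]);
  const double eta_PS = as<double>(plast["eta_PS"]);
  const double eta_PV = as<double>(plast["eta_PV"]);
  const double rho = as<double>(plast["rho"]);
  const bool wspace = as<std::string>(plast["gradient"]) == "weight";
  const double w_floor = 1e-12;
  arma::mat eps = as<arma::mat>(epsilon);
  arma::mat v_EP = as<arma::mat>(vparams["EP"]);
  arma::mat v_EnM = as<arma::mat>(vparams["EnM"]);
  arma::mat v_PS = as<arma::mat>(vparams["PS"]);
  arma::mat v_PV = as<arma::mat>(vparams["PV"]);
  arma::mat m_EP = as<arma::mat>(masks["EP"]);
  arma::mat m_EnM = as<arma::mat>(masks["EnM"]);
  arma::mat m_PS = as<arma::mat>(masks["PS"]);
  arma::mat m_PV = as<arma::mat>(masks["PV"]);
  std::vector<arma::mat> v_DM(net.K), m_DM(net.K);
  for (int k = 0; k < net.K; ++k) {
    std::string nm = "D" + std::to_string(k + 1) + "M";
    v_DM[k] = as<arma::mat>(vparams[nm]);
    m_DM[k] = as<arma::mat>(masks[nm]);
  }
  const arma::vec xE0 = net.x_E, xP0 = net.x_P, xS0 = net.x_S, xV0 = net.x_V;
  const arma::mat xD0 = net.x_D;
  const int nE = xE0.n_elem;
  const int dims = pref_pc.n_cols;

  RNGScope rng;
  SteadySolver solver_match, solver_base;
  arma::vec hEm(nE, arma::fill::zeros), hPm(xP0.n_elem, arma::fill::zeros),
    hSm(xS0.n_elem, arma::fill::zeros), hVm(xV0.n_elem, arma::fill::zeros);
  arma::vec hEb = hEm, hPb = hPm, hSb = hSm, hVb = hVm;
  Drive d;
  std::vector<double> rec_pres, rec_match, rec_base, rec_dend;
  int quiet = 0, done = 0;
  bool stopped = false;

  auto tuned = [&](const arma::mat& pref, const arma::vec& s, double sig) {
    arma::vec out(pref.n_rows, arma::fill::zeros);
    for (arma::uword i = 0; i < pref.n_rows; ++i) {
      double q = 0;
      for (int dd = 0; dd < dims; ++dd) {
        double diff = s[dd] - pref(i, dd);
        q += diff * diff;
      }
      out[i] = r_max * std::exp(-q / (2.0 * sig * sig));
    }
    return out;
  };

  // weight-space: apply the error terms to the magnitudes, floored at
  // w_floor; softplus ("literal gradient") mode: update the pre-activations
  // with the logistic dw/dv factor
  auto bump_w = [&](arma::mat& Wm, const arma::mat& delta,
                    const arma::mat& m) {
    Wm = arma::clamp(Wm + delta, w_floor, arma::datum::inf) % m;
  };
  auto apply_updates = [&](const arma::vec& r_E, const arma::vec& r_P,
                           const arma::vec& r_S, const arma::vec& r_V,
                           const arma::mat& A_dend) {
    arma::vec err = r_E - rho;
    arma::vec r_M = r_S.elem(net.idx_M), r_nM = r_S.elem(net.idx_nM);
    arma::vec bp = net.W_EP.t() * err;
    if (wspace) {
      bump_w(net.W_EP, eta_EP * (err * r_P.t()) % m_EP, m_EP);
      bump_w(net.W_EnM, eta_ES * (err * r_nM.t()) % m_EnM, m_EnM);
      bump_w(net.W_PS, -eta_PS * (bp * r_S.t()) % m_PS, m_PS);
      bump_w(net.W_PV, -eta_PV * (bp * r_V.t()) % m_PV, m_PV);
      for (int k = 0; k < net.K; ++k) {
        arma::vec errD = net.lambda_D * err + (A_dend.col(k) - eps.col(k));
        bump_w(net.W_DM[k], eta_DS * (errD * r_M.t()) % m_DM[k], m_DM[k]);
      }
    } else {
      v_EP += eta_EP * (err * r_P.t()) % logistic_mat(v_EP) % m_EP;
      v_EnM += eta_ES * (err * r_nM.t()) % logistic_mat(v_EnM) % m_EnM;
      v_PS += -eta_PS * (bp * r_S.t()) % logistic_mat(v_PS) % m_PS;
      v_PV += -eta_PV * (bp * r_V.t()) % logistic_mat(v_PV) % m_PV;
      net.W_EP = softplus_mat(v_EP) % m_EP;
      net.W_EnM = softplus_mat(v_EnM) % m_EnM;
      net.W_PS = softplus_mat(v_PS) % m_PS;
      net.W_PV = softplus_mat(v_PV) % m_PV;
      for (int k = 0; k < net.K; ++k) {
        arma::vec errD = net.lambda_D * err + (A_dend.col(k) - eps.col(k));
        v_DM[k] += eta_DS * (errD * r_M.t()) % logistic_mat(v_DM[k]) % m_DM[k];
        net.W_DM[k] = softplus_mat(v_DM[k]) % m_DM[k];
      }
    }
  };

  for (int t = 0; t < n_pairs; ++t) {
    // ---- match phase (noisy features; P drawn before S as in phase_inputs)
    arma::vec Pf(dims), Sf(dims);
    for (int dd = 0; dd < dims; ++dd) {
      Pf[dd] = train_feature[dd] +
        (noise_sigma > 0 ? R::rnorm(0.0, noise_sigma) : 0.0);
    }
    for (int dd = 0; dd < dims; ++dd) {
      Sf[dd] = train_feature[dd] +
        (noise_sigma > 0 ? R::rnorm(0.0, noise_sigma) : 0.0);
    }
    net.x_E = xE0 + tuned(pref_pc, Sf, sig_pc);
    if (som_untuned) net.x_S = xS0 + amp_pv;
    else net.x_S = xS0 + tuned(pref_som, Sf, sig_som);
    net.x_P = xP0 + amp_pv;
    net.x_V = xV0 + amp_vip;
    net.x_D = xD0;
    for (int k = 0; k < net.K; ++k) {
      for (int i = 0; i < nE; ++i) {
        double diff = Pf[k] - pref_pc(i, k);
        net.x_D(i, k) += r_max * std::exp(-diff * diff / (2.0 * sig_pc * sig_pc));
      }
    }
    if (!solver_match.solve(net, hEm, hPm, hSm, hVm, d, newton_iter,
                            newton_tol)) {
      euler_settle(net, hEm, hPm, hSm, hVm, d, dt, 2.0, steady_tol);
      solver_match.valid = false;
    }
    arma::vec r_E = arma::clamp(hEm, 0.0, arma::datum::inf);
    arma::vec r_P = arma::clamp(hPm, 0.0, arma::datum::inf);
    arma::vec r_S = arma::clamp(hSm, 0.0, arma::datum::inf);
    arma::vec r_V = arma::clamp(hVm, 0.0, arma::datum::inf);
    double err_match = arma::mean(arma::abs(r_E - rho));
    double dend_dev = arma::mean(arma::vectorise(
      arma::abs((d.I_D_syn + d.calcium) - eps)));
    apply_updates(r_E, r_P, r_S, r_V, d.I_D_syn + d.calcium);

    // ---- baseline phase (background only)
    net.x_E = xE0; net.x_S = xS0; net.x_P = xP0; net.x_V = xV0; net.x_D = xD0;
    if (!solver_base.solve(net, hEb, hPb, hSb, hVb, d, newton_iter,
                           newton_tol)) {
      euler_settle(net, hEb, hPb, hSb, hVb, d, dt, 2.0, steady_tol);
      solver_base.valid = false;
    }
    r_E = arma::clamp(hEb, 0.0, arma::datum::inf);
    double err_base = arma::mean(arma::abs(r_E - rho));
    if (update_baseline) {
      r_P = arma::clamp(hPb, 0.0, arma::datum::inf);
      r_S = arma::clamp(hSb, 0.0, arma::datum::inf);
      r_V = arma::clamp(hVb, 0.0, arma::datum::inf);
      apply_updates(r_E, r_P, r_S, r_V, d.I_D_syn + d.calcium);
    }
    done = t + 1;
    if (done == 1 || done % record_every == 0) {
      rec_pres.push_back(done);
      rec_match.push_back(err_match);
      rec_base.push_back(err_base);
      rec_dend.push_back(dend_dev);
    }
    if (early_frac > 0 && err_match < early_frac * rho &&
        err_base < early_frac * rho) {
      if (++quiet >= early_window) { stopped = true; break; }
    } else {
      quiet = 0;
    }
  }

  if (wspace) {
    // keep w = softplus(v) on the mask after every update
    auto refresh_v = [&](arma::mat& v, const arma::mat& Wm,
                         const arma::mat& m) {
      arma::mat wsafe = arma::clamp(Wm, w_floor, arma::datum::inf);
      v = (wsafe + arma::log1p(-arma::exp(-wsafe))) % m;
    };
    refresh_v(v_EP, net.W_EP, m_EP);
    refresh_v(v_EnM, net.W_EnM, m_EnM);
    refresh_v(v_PS, net.W_PS, m_PS);
    refresh_v(v_PV, net.W_PV, m_PV);
    for (int k = 0; k < net.K; ++k) refresh_v(v_DM[k], net.W_DM[k], m_DM[k]);
  }
  List Wout = clone(W);
  Wout["EP"] = net.W_EP; Wout["EnM"] = net.W_EnM;
  Wout["PS"] = net.W_PS; Wout["PV"] = net.W_PV;
  List vout;
  vout["EP"] = v_EP; vout["EnM"] = v_EnM; vout["PS"] = v_PS; vout["PV"] = v_PV;
  for (int k = 0; k < net.K; ++k) {
    std::string nm = "D" + std::to_string(k + 1) + "M";
    Wout[nm] = net.W_DM[k];
    vout[nm] = v_DM[k];
  }
  return List::create(
    _["W"] = Wout, _["v"] = vout, _["presentations"] = done,
    _["early_stopped"] = stopped,
    _["history"] = DataFrame::create(
      _["presentation"] = rec_pres, _["err_match"] = rec_match,
      _["err_base"] = rec_base, _["dend_dev"] = rec_dend));
}
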