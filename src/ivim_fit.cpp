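// Bounded Levenberg-Marquardt fitting of the bi-exponential IVIM model
//   s(b) = S0 * (f * exp(-b * D*) + (1 - f) * exp(-b * D))
// Internal parameterization theta = (S0, f, D, delta) with D* = D + delta,
// which enforces D <= D* structurally; box bounds are applied by projection
// after each trial step and only SSR-decreasing steps are accepted, so the
// SSR trajectory is monotone from the supplied initialization.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

struct Bounds {
  double s0_lo, s0_hi, f_lo, f_hi, d_lo, d_hi, dstar_lo, dstar_hi;
};

static void project(vec &th, const Bounds &bd) {
  th(0) = clampd(th(0), bd.s0_lo, bd.s0_hi);
  th(1) = clampd(th(1), bd.f_lo, bd.f_hi);
  th(2) = clampd(th(2), bd.d_lo, bd.d_hi);
  double delta_lo = std::max(0.0, bd.dstar_lo - th(2));
  double delta_hi = std::max(delta_lo, bd.dstar_hi - th(2));
  th(3) = clampd(th(3), delta_lo, delta_hi);
}

static vec model(const vec &th, const vec &b) {
  return th(0) * (th(1) * exp(-b * (th(2) + th(3))) +
                  (1.0 - th(1)) * exp(-b * th(2)));
}

// Jacobian of the model signal w.r.t. theta (nb x 4)
static mat jacobian(const vec &th, const vec &b) {
  vec e1 = exp(-b * (th(2) + th(3)));   // perfusion compartment
  vec e0 = exp(-b * th(2));             // diffusion compartment
  mat J(b.n_elem, 4);
  J.col(0) = th(1) * e1 + (1.0 - th(1)) * e0;
  J.col(1) = th(0) * (e1 - e0);
  J.col(2) = -th(0) * (b % (th(1) * e1 + (1.0 - th(1)) * e0));
  J.col(3) = -th(0) * th(1) * (b % e1);
  return J;
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_fit_ivim(const arma::mat &curves, const arma::vec &b,
                                 const arma::mat &init,
                                 const arma::vec &s0_hi_per_curve,
                                 double f_lo, double f_hi,
                                 double d_lo, double d_hi,
                                 double dstar_lo, double dstar_hi,
                                 int max_iter, double cost_tol) {
  const uword n = curves.n_rows;
  Rcpp::NumericMatrix out(n, 7);  // s0, f, d, dstar, ssr, iters, status

  for (uword c = 0; c < n; ++c) {
    vec y = curves.row(c).t();
    if (!y.is_finite() || max(y) <= 0.0) {      // degenerate voxel
      out(c, 0) = NA_REAL; out(c, 1) = NA_REAL; out(c, 2) = NA_REAL;
      out(c, 3) = NA_REAL; out(c, 4) = NA_REAL; out(c, 5) = 0; out(c, 6) = 2;
      continue;
    }

    Bounds bd;
    bd.s0_hi = s0_hi_per_curve(c);
    bd.s0_lo = 1e-8 * bd.s0_hi;
    bd.f_lo = f_lo; bd.f_hi = f_hi;
    bd.d_lo = d_lo; bd.d_hi = d_hi;
    bd.dstar_lo = dstar_lo; bd.dstar_hi = dstar_hi;

    vec th(4);
    th(0) = init(c, 0); th(1) = init(c, 1); th(2) = init(c, 2);
    th(3) = init(c, 3) - init(c, 2);        // delta = D* - D
    project(th, bd);

    vec r = y - model(th, b);
    double ssr = dot(r, r);
    double lambda = 1e-3;
    int iter = 0, status = 1;               // assume max-iter until convergence

    for (iter = 1; iter <= max_iter; ++iter) {
      mat J = -jacobian(th, b);             // d r / d theta
      vec g = J.t() * r;
      mat H = J.t() * J;
      double dmax = H.diag().max();
      if (!std::isfinite(dmax) || dmax <= 0.0) { status = 0; break; }
      vec dref = H.diag();
      dref.transform([&](double v) { return std::max(v, 1e-12 * dmax); });

      bool accepted = false;
      double ssr_new = ssr;
      vec th_new = th;
      for (int inner = 0; inner < 60; ++inner) {
        mat A = H;
        A.diag() += lambda * dref;
        vec p;
        bool ok = solve(p, A, -g, solve_opts::no_approx);
        if (ok) {
          th_new = th + p;
          project(th_new, bd);
          vec r_new = y - model(th_new, b);
          ssr_new = dot(r_new, r_new);
          if (std::isfinite(ssr_new) && ssr_new <= ssr) {
            accepted = true;
            r = r_new;
            break;
          }
        }
        lambda *= 5.0;
        if (lambda > 1e14) break;
      }

      if (!accepted) { status = 0; break; } // no descent direction left: done
      double drop = ssr - ssr_new;
      th = th_new;
      ssr = ssr_new;
      lambda = std::max(lambda / 3.0, 1e-12);
      if (drop <= cost_tol * (ssr + 1e-300)) { status = 0; break; }
    }
    if (iter > max_iter) iter = max_iter;

    out(c, 0) = th(0); out(c, 1) = th(1); out(c, 2) = th(2);
    out(c, 3) = th(2) + th(3);
    out(c, 4) = ssr; out(c, 5) = iter; out(c, 6) = status;
  }
  return out;
}
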