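// Hierarchical equations of motion for a Frenkel exciton system with
// site-local Drude-Lorentz baths expanded in exponential (Matsubara) series.
//
// State layout: one auxiliary density operator (ADO) per hierarchy
// multi-index, stored as an N x N complex slice of a cube (density
// hierarchy) or an N-vector column (optical-coherence hierarchy used for
// linear spectra). All frequencies are angular (rad/ps), time in ps.
//
// Site-projector structure is exploited throughout: for Q = |s><s|,
// Q*rho touches one row, rho*Q one column, and the double commutator
// [Q,[Q,rho]] is assembled from that row/column pair.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cx_mat;
using arma::cx_cube;
using arma::cx_vec;

namespace {

struct Hier {
  int n_ado, n_modes, N;
  arma::imat nmat;          // n_ado x n_modes multi-indices
  arma::imat up, down;      // neighbour ADO indices (0-based, -1 if absent)
  arma::ivec site;          // site of each mode (0-based)
  cx_vec c;                 // expansion coefficients (rad^2/ps^2)
  arma::vec nu;             // decay rates (rad/ps)
  arma::vec kappa;          // per-site terminator prefactor (rad/ps)
  arma::vec gamma_n;        // per-ADO damping sum(n_m nu_m)
  bool scaled;
};

Hier make_hier(const cx_mat& H, const IntegerMatrix& nmat,
               const IntegerMatrix& up, const IntegerMatrix& down,
               const IntegerVector& site, const ComplexVector& c,
               const NumericVector& nu, const NumericVector& kappa,
               bool scaled) {
  Hier h;
  h.N = H.n_rows;
  h.n_ado = nmat.nrow();
  h.n_modes = nmat.ncol();
  h.nmat = as<arma::imat>(nmat);
  h.up = as<arma::imat>(up);
  h.down = as<arma::imat>(down);
  h.site = as<arma::ivec>(site);
  h.c = as<cx_vec>(c);
  h.nu = as<arma::vec>(nu);
  h.kappa = as<arma::vec>(kappa);
  h.scaled = scaled;
  h.gamma_n.set_size(h.n_ado);
  for (int a = 0; a < h.n_ado; ++a) {
    double g = 0;
    for (int m = 0; m < h.n_modes; ++m) g += h.nmat(a, m) * h.nu(m);
    h.gamma_n(a) = g;
  }
  return h;
}

// density-hierarchy right-hand side
void rhs_density(const Hier& h, const cx_mat& H, const cx_cube& st, cx_cube& d) {
  const std::complex<double> I(0.0, 1.0);
  const int N = h.N;
  for (int a = 0; a < h.n_ado; ++a) {
    const cx_mat& r = st.slice(a);
    cx_mat& o = d.slice(a);
    o = -I * (H * r - r * H) - h.gamma_n(a) * r;
    // terminator: - sum_s kappa_s [Q_s,[Q_s, r]]
    for (int s = 0; s < (int)h.kappa.n_elem; ++s) {
      double k = h.kappa(s);
      if (k == 0) continue;
      for (int j = 0; j < N; ++j) {
        if (j == s) continue;
        o(s, j) -= k * r(s, j);
        o(j, s) -= k * r(j, s);
      }
    }
    for (int m = 0; m < h.n_modes; ++m) {
      int s = h.site(m);
      int iu = h.up(a, m);
      if (iu >= 0) {
        // -i fac [Q_s, rho_up]
        double fac = h.scaled ? std::sqrt((h.nmat(a, m) + 1.0) * std::abs(h.c(m))) : 1.0;
        const cx_mat& ru = st.slice(iu);
        for (int j = 0; j < N; ++j) {
          o(s, j) -= I * fac * ru(s, j);
          o(j, s) += I * fac * ru(j, s);
        }
      }
      int idn = h.down(a, m);
      if (idn >= 0) {
        // -i fac (c Q rho_dn - conj(c) rho_dn Q)
        double nm = h.nmat(a, m);
        double fac = h.scaled ? std::sqrt(nm / std::abs(h.c(m))) : nm;
        std::complex<double> cc = h.c(m);
        const cx_mat& rd = st.slice(idn);
        for (int j = 0; j < N; ++j) {
          o(s, j) -= I * fac * cc * rd(s, j);
          o(j, s) += I * fac * std::conj(cc) * rd(j, s);
        }
      }
    }
  }
}

// optical-coherence hierarchy (columns |i><0| for absorption, side = 0;
// rows <i| of |0><i| blocks for emission, side = 1)
void rhs_coh(const Hier& h, const cx_mat& H, const cx_mat& st, cx_mat& d, int side) {
  const std::complex<double> I(0.0, 1.0);
  if (side == 0) {
    d = -I * (H * st);
  } else {
    d = I * (st.st() * H).st();  // +i w H for each row vector (stored as column)
  }
  for (int a = 0; a < h.n_ado; ++a) {
    d.col(a) -= h.gamma_n(a) * st.col(a);
    for (int s = 0; s < (int)h.kappa.n_elem; ++s)
      d(s, a) -= h.kappa(s) * st(s, a);
    for (int m = 0; m < h.n_modes; ++m) {
      int s = h.site(m);
      int iu = h.up(a, m);
      if (iu >= 0) {
        double fac = h.scaled ? std::sqrt((h.nmat(a, m) + 1.0) * std::abs(h.c(m))) : 1.0;
        if (side == 0) d(s, a) -= I * fac * st(s, iu);
        else           d(s, a) += I * fac * st(s, iu);
      }
      int idn = h.down(a, m);
      if (idn >= 0) {
        double nm = h.nmat(a, m);
        double fac = h.scaled ? std::sqrt(nm / std::abs(h.c(m))) : nm;
        if (side == 0) d(s, a) -= I * fac * h.c(m) * st(s, idn);
        else           d(s, a) += I * fac * std::conj(h.c(m)) * st(s, idn);
      }
    }
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_heom_propagate(ComplexMatrix H_, IntegerMatrix nmat, IntegerMatrix up,
                        IntegerMatrix down, IntegerVector site, ComplexVector c,
                        NumericVector nu, NumericVector kappa, bool scaled,
                        ComplexMatrix rho0_, double dt, int nsteps, int stride,
                        IntegerVector pop_sites, bool return_state,
                        Nullable<ComplexVector> state0 = R_NilValue) {
  cx_mat H = as<cx_mat>(H_);
  Hier h = make_hier(H, nmat, up, down, site, c, nu, kappa, scaled);
  int N = h.N;
  cx_cube st(N, N, h.n_ado, arma::fill::zeros);
  if (state0.isNotNull()) {
    ComplexVector s0(state0);
    std::copy(reinterpret_cast<const std::complex<double>*>(&s0[0]),
              reinterpret_cast<const std::complex<double>*>(&s0[0]) + N * N * h.n_ado,
              st.begin());
  } else {
    st.slice(0) = as<cx_mat>(rho0_);
  }
  cx_cube k1(N, N, h.n_ado), k2(N, N, h.n_ado), k3(N, N, h.n_ado),
      k4(N, N, h.n_ado), tmp(N, N, h.n_ado);
  int nrec = nsteps / stride + 1;
  NumericVector times(nrec), pA(nrec), trace(nrec);
  arma::uvec psites = as<arma::uvec>(pop_sites);
  int rec = 0;
  for (int step = 0; step <= nsteps; ++step) {
    if (step % stride == 0) {
      times[rec] = step * dt;
      double pa = 0, tr = 0;
      for (int i = 0; i < N; ++i) {
        double pii = st.slice(0)(i, i).real();
        tr += pii;
      }
      for (arma::uword q = 0; q < psites.n_elem; ++q)
        pa += st.slice(0)(psites(q), psites(q)).real();
      pA[rec] = pa; trace[rec] = tr;
      ++rec;
    }
    if (step == nsteps) break;
    rhs_density(h, H, st, k1);
    tmp = st + 0.5 * dt * k1;
    rhs_density(h, H, tmp, k2);
    tmp = st + 0.5 * dt * k2;
    rhs_density(h, H, tmp, k3);
    tmp = st + dt * k3;
    rhs_density(h, H, tmp, k4);
    st += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
  }
  List out = List::create(_["time"] = times, _["P_A"] = pA, _["trace"] = trace);
  if (return_state) {
    ComplexVector flat(N * N * h.n_ado);
    std::copy(st.begin(), st.end(), reinterpret_cast<std::complex<double>*>(flat.begin()));
    flat.attr("dim") = IntegerVector::create(N, N, h.n_ado);
    out["state"] = flat;
  }
  return out;
}

// [[Rcpp::export]]
ComplexVector cpp_heom_rhs(ComplexMatrix H_, IntegerMatrix nmat, IntegerMatrix up,
                           IntegerMatrix down, IntegerVector site, ComplexVector c,
                           NumericVector nu, NumericVector kappa, bool scaled,
                           ComplexVector state_) {
  cx_mat H = as<cx_mat>(H_);
  Hier h = make_hier(H, nmat, up, down, site, c, nu, kappa, scaled);
  int N = h.N;
  cx_cube st(N, N, h.n_ado), d(N, N, h.n_ado);
  std::copy(reinterpret_cast<const std::complex<double>*>(&state_[0]),
            reinterpret_cast<const std::complex<double>*>(&state_[0]) + N * N * h.n_ado,
            st.begin());
  rhs_density(h, H, st, d);
  ComplexVector out(N * N * h.n_ado);
  std::copy(d.begin(), d.end(), reinterpret_cast<std::complex<double>*>(out.begin()));
  out.attr("dim") = IntegerVector::create(N, N, h.n_ado);
  return out;
}

// [[Rcpp::export]]
ComplexVector cpp_heom_propagate_coherence(ComplexMatrix H_, IntegerMatrix nmat,
                                           IntegerMatrix up, IntegerMatrix down,
                                           IntegerVector site, ComplexVector c,
                                           NumericVector nu, NumericVector kappa,
                                           bool scaled, ComplexMatrix coh0_,
                                           ComplexVector dvec_, double dt,
                                           int nsteps, int side) {
  cx_mat H = as<cx_mat>(H_);
  Hier h = make_hier(H, nmat, up, down, site, c, nu, kappa, scaled);
  int N = h.N;
  cx_mat st = as<cx_mat>(coh0_);          // N x n_ado
  cx_vec dv = as<cx_vec>(dvec_);
  cx_mat k1(N, h.n_ado), k2(N, h.n_ado), k3(N, h.n_ado), k4(N, h.n_ado),
      tmp(N, h.n_ado);
  ComplexVector signal(nsteps + 1);
  for (int step = 0; step <= nsteps; ++step) {
    std::complex<double> s = arma::cdot(arma::conj(dv), st.col(0)); // sum d_i x_i
    signal[step] = Rcomplex{s.real(), s.imag()};
    if (step == nsteps) break;
    rhs_coh(h, H, st, k1, side);
    tmp = st + 0.5 * dt * k1;
    rhs_coh(h, H, tmp, k2, side);
    tmp = st + 0.5 * dt * k2;
    rhs_coh(h, H, tmp, k3, side);
    tmp = st + dt * k3;
    rhs_coh(h, H, tmp, k4, side);
    st += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
  }
  return signal;
}
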