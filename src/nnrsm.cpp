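// Nearest-neighbour regularised Stokeslet core: kernel evaluation and
// aggregation of the two-level (coarse traction / fine quadrature) matrix.
// Prefactor convention: kernels carry no -1/(8*pi); that factor is applied
// by the assembly on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Regularised Stokeslet (Cortez blob):
//   S_ij = [(r^2 + 2 eps^2) delta_ij + r_i r_j] / (r^2 + eps^2)^(3/2)
// S is a 3x3 block stored column-major.
static inline void kern_stokeslet(const double* x, const double* y,
                                  double eps2, double* S) {
  const double r0 = x[0] - y[0], r1 = x[1] - y[1], r2 = x[2] - y[2];
  const double rr = r0 * r0 + r1 * r1 + r2 * r2;
  const double d  = rr + eps2;
  const double ir3 = 1.0 / (d * std::sqrt(d));
  const double dg = (rr + 2.0 * eps2) * ir3;
  S[0] = dg + r0 * r0 * ir3;
  S[4] = dg + r1 * r1 * ir3;
  S[8] = dg + r2 * r2 * ir3;
  S[1] = S[3] = r0 * r1 * ir3;
  S[2] = S[6] = r0 * r2 * ir3;
  S[5] = S[7] = r1 * r2 * ir3;
}

// Regularised Blakelet: image system for a point force above the no-slip
// plane z = wall. Blake's (1971) construction with each inverse power of the
// image distance regularised, 1/R^n -> (R^2+eps^2)^(-n/2):
//   B_ij = S^eps_ij(r) - S^eps_ij(R) + 2h Delta_jk [ h PD_ik - SD_ik ]
// with r = x - y, R = x - y*, y* the mirror image, h the source height,
// Delta = diag(1,1,-1), PD the potential dipole and SD the Stokeslet doublet.
// On the plane z = wall the cancellation is per power of 1/R, so the wall
// velocity vanishes to rounding for every eps.
static inline void kern_blakelet(const double* x, const double* y,
                                 double eps2, double wall, double* B) {
  double S[9], SI[9];
  kern_stokeslet(x, y, eps2, S);
  const double h = y[2] - wall;
  const double ys[3] = { y[0], y[1], 2.0 * wall - y[2] };
  kern_stokeslet(x, ys, eps2, SI);
  const double R[3] = { x[0] - ys[0], x[1] - ys[1], x[2] - ys[2] };
  const double RR = R[0] * R[0] + R[1] * R[1] + R[2] * R[2];
  const double d  = RR + eps2;
  const double sq = std::sqrt(d);
  const double Re3 = 1.0 / (d * sq);
  const double Re5 = Re3 / d;
  for (int j = 0; j < 3; ++j) {
    const double sgn = (j == 2) ? -1.0 : 1.0;  // Delta_jj
    for (int i = 0; i < 3; ++i) {
      const double pd = ((i == j) ? Re3 : 0.0) - 3.0 * R[i] * R[j] * Re5;
      double sd = -3.0 * R[i] * R[2] * R[j] * Re5;
      if (i == 2) sd -= R[j] * Re3;
      if (i == j) sd += R[2] * Re3;
      if (j == 2) sd += R[i] * Re3;
      B[3 * j + i] = S[3 * j + i] - SI[3 * j + i] +
        sgn * 2.0 * h * (h * pd - sd);
    }
  }
}

// Single kernel evaluation (kind 0 = regularised Stokeslet, 1 = regularised
// Blakelet with plane z = wall). Exposed for the R-level kernel functions.
// [[Rcpp::export]]
NumericMatrix cpp_kernel(NumericVector x, NumericVector y, double eps,
                         int kind, double wall) {
  NumericMatrix out(3, 3);
  double S[9];
  if (kind == 0) kern_stokeslet(x.begin(), y.begin(), eps * eps, S);
  else kern_blakelet(x.begin(), y.begin(), eps * eps, wall, S);
  std::copy(S, S + 9, out.begin());
  return out;
}

// Aggregated two-level matrix: for collocation points x[m] and fine
// quadrature nodes x[q] with nearest coarse traction node nn[q] and fine
// area weight fw[q],
//   K[3m+i, 3n+j] = sum_{q : nn[q]=n} S_ij(x[m], x[q]) fw[q]
// plus the aggregated area A~[n] = sum_q nu[q,n] fw[q] and first moment
// M~[n] = sum_q nu[q,n] fw[q] x[q] used by the force/torque balance rows.
// [[Rcpp::export]]
List cpp_assemble_nn(const arma::mat& colloc, const arma::mat& fine,
                     const arma::ivec& nn, const arma::vec& fw,
                     double eps, int kind, double wall) {
  const int N = colloc.n_rows, Q = fine.n_rows;
  const int M = colloc.n_rows;
  arma::vec area(N, arma::fill::zeros);
  arma::mat moment(N, 3, arma::fill::zeros);
  const arma::mat Ft = fine.t();
  const double eps2 = eps * eps;
  // structure-of-arrays accumulation planes: contiguous in m for each
  // coarse column n, so the inner loop vectorises; interleaved into the
  // 3M x 3N block matrix once at the end
  arma::mat P11(M, N, arma::fill::zeros), P12(M, N, arma::fill::zeros),
            P13(M, N, arma::fill::zeros), P22(M, N, arma::fill::zeros),
            P23(M, N, arma::fill::zeros), P33(M, N, arma::fill::zeros);
  const arma::vec cx = colloc.col(0), cy = colloc.col(1),
                  cz = colloc.col(2);
  const double* cxp = cx.memptr();
  const double* cyp = cy.memptr();
  const double* czp = cz.memptr();
  if (kind == 0) {
    for (int q = 0; q < Q; ++q) {
      const int n = nn[q] - 1;
      const double w = fw[q];
      const double* y = Ft.colptr(q);
      area[n] += w;
      moment(n, 0) += w * y[0];
      moment(n, 1) += w * y[1];
      moment(n, 2) += w * y[2];
      const double y0 = y[0], y1 = y[1], y2 = y[2];
      double* p11 = P11.colptr(n); double* p12 = P12.colptr(n);
      double* p13 = P13.colptr(n); double* p22 = P22.colptr(n);
      double* p23 = P23.colptr(n); double* p33 = P33.colptr(n);
      for (int m = 0; m < M; ++m) {
        const double r0 = cxp[m] - y0, r1 = cyp[m] - y1, r2 = czp[m] - y2;
        const double rr = r0 * r0 + r1 * r1 + r2 * r2;
        const double d = rr + eps2;
        const double ir3 = w / (d * std::sqrt(d));
        const double dg = (rr + 2.0 * eps2) * ir3;
        p11[m] += dg + r0 * r0 * ir3;
        p22[m] += dg + r1 * r1 * ir3;
        p33[m] += dg + r2 * r2 * ir3;
        p12[m] += r0 * r1 * ir3;
        p13[m] += r0 * r2 * ir3;
        p23[m] += r1 * r2 * ir3;
      }
    }
  } else {
    // Blakelet: not symmetric in (i, j); fall back to the generic path
    arma::mat P21(M, N, arma::fill::zeros), P31(M, N, arma::fill::zeros),
              P32(M, N, arma::fill::zeros);
    const arma::mat Ct = colloc.t();
    double S[9];
    for (int q = 0; q < Q; ++q) {
      const int n = nn[q] - 1;
      const double w = fw[q];
      const double* y = Ft.colptr(q);
      area[n] += w;
      moment(n, 0) += w * y[0];
      moment(n, 1) += w * y[1];
      moment(n, 2) += w * y[2];
      for (int m = 0; m < M; ++m) {
        kern_blakelet(Ct.colptr(m), y, eps2, wall, S);
        P11(m, n) += w * S[0]; P21(m, n) += w * S[1]; P31(m, n) += w * S[2];
        P12(m, n) += w * S[3]; P22(m, n) += w * S[4]; P32(m, n) += w * S[5];
        P13(m, n) += w * S[6]; P23(m, n) += w * S[7]; P33(m, n) += w * S[8];
      }
    }
    arma::mat K(3 * M, 3 * N);
    for (int n = 0; n < N; ++n) for (int m = 0; m < M; ++m) {
      K(3 * m, 3 * n) = P11(m, n);
      K(3 * m + 1, 3 * n) = P21(m, n);
      K(3 * m + 2, 3 * n) = P31(m, n);
      K(3 * m, 3 * n + 1) = P12(m, n);
      K(3 * m + 1, 3 * n + 1) = P22(m, n);
      K(3 * m + 2, 3 * n + 1) = P32(m, n);
      K(3 * m, 3 * n + 2) = P13(m, n);
      K(3 * m + 1, 3 * n + 2) = P23(m, n);
      K(3 * m + 2, 3 * n + 2) = P33(m, n);
    }
    return List::create(_["K"] = K, _["area"] = area, _["moment"] = moment);
  }
  arma::mat K(3 * M, 3 * N);
  for (int n = 0; n < N; ++n) {
    const double* p11 = P11.colptr(n); const double* p12 = P12.colptr(n);
    const double* p13 = P13.colptr(n); const double* p22 = P22.colptr(n);
    const double* p23 = P23.colptr(n); const double* p33 = P33.colptr(n);
    double* K0 = K.colptr(3 * n);
    double* K1 = K.colptr(3 * n + 1);
    double* K2 = K.colptr(3 * n + 2);
    for (int m = 0; m < M; ++m) {
      K0[3 * m] = p11[m]; K0[3 * m + 1] = p12[m]; K0[3 * m + 2] = p13[m];
      K1[3 * m] = p12[m]; K1[3 * m + 1] = p22[m]; K1[3 * m + 2] = p23[m];
      K2[3 * m] = p13[m]; K2[3 * m + 1] = p23[m]; K2[3 * m + 2] = p33[m];
    }
  }
  return List::create(_["K"] = K, _["area"] = area, _["moment"] = moment);
}

// Brute-force nearest neighbour: index (1-based) of the coarse point closest
// to each fine point; ties broken by lowest coarse index.
// [[Rcpp::export]]
IntegerVector cpp_nearest(const arma::mat& fine, const arma::mat& coarse) {
  const int Q = fine.n_rows, N = coarse.n_rows;
  IntegerVector out(Q);
  const arma::mat Ft = fine.t(), Ct = coarse.t();
  for (int q = 0; q < Q; ++q) {
    const double* f = Ft.colptr(q);
    double best = std::numeric_limits<double>::infinity();
    int arg = 0;
    for (int n = 0; n < N; ++n) {
      const double* c = Ct.colptr(n);
      const double d0 = f[0] - c[0], d1 = f[1] - c[1], d2 = f[2] - c[2];
      const double d = d0 * d0 + d1 * d1 + d2 * d2;
      if (d < best) { best = d; arg = n; }
    }
    out[q] = arg + 1;
  }
  return out;
}
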