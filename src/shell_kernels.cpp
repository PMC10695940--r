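// Flat triangular shell element kernels: constant-strain membrane (CST)
// superposed with discrete-Kirchhoff bending (DKT, Batoz-type) and a small
// fictitious drilling stiffness.  Local bending DOFs per node are
// (w, theta_x, theta_y) with theta_x = dw/dy and theta_y = -dw/dx
// (right-hand rotations about the local in-plane axes).
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::mat;
using arma::vec;

namespace {

// DKT shape-function derivative arrays (Batoz, Bathe & Ho 1980).
// p,q,t,r are the side quantities for sides 4:(23), 5:(31), 6:(12).
void dkt_hderiv(double xi, double eta,
                const double* p, const double* q, const double* t, const double* r,
                vec& hx_xi, vec& hy_xi, vec& hx_eta, vec& hy_eta) {
  const double p4 = p[0], p5 = p[1], p6 = p[2];
  const double q4 = q[0], q5 = q[1], q6 = q[2];
  const double t4 = t[0], t5 = t[1], t6 = t[2];
  const double r4 = r[0], r5 = r[1], r6 = r[2];

  hx_xi.set_size(9); hy_xi.set_size(9); hx_eta.set_size(9); hy_eta.set_size(9);

  hx_xi(0) = p6 * (1.0 - 2.0 * xi) + (p5 - p6) * eta;
  hx_xi(1) = q6 * (1.0 - 2.0 * xi) - (q5 + q6) * eta;
  hx_xi(2) = -4.0 + 6.0 * (xi + eta) + r6 * (1.0 - 2.0 * xi) - eta * (r5 + r6);
  hx_xi(3) = -p6 * (1.0 - 2.0 * xi) + eta * (p4 + p6);
  hx_xi(4) = q6 * (1.0 - 2.0 * xi) - eta * (q6 - q4);
  hx_xi(5) = -2.0 + 6.0 * xi + r6 * (1.0 - 2.0 * xi) + eta * (r4 - r6);
  hx_xi(6) = -eta * (p5 + p4);
  hx_xi(7) = eta * (q4 - q5);
  hx_xi(8) = -eta * (r5 - r4);

  hy_xi(0) = t6 * (1.0 - 2.0 * xi) + eta * (t5 - t6);
  hy_xi(1) = 1.0 + r6 * (1.0 - 2.0 * xi) - eta * (r5 + r6);
  hy_xi(2) = -q6 * (1.0 - 2.0 * xi) + eta * (q5 + q6);
  hy_xi(3) = -t6 * (1.0 - 2.0 * xi) + eta * (t4 + t6);
  hy_xi(4) = -1.0 + r6 * (1.0 - 2.0 * xi) + eta * (r4 - r6);
  hy_xi(5) = -q6 * (1.0 - 2.0 * xi) - eta * (q4 - q6);
  hy_xi(6) = -eta * (t4 + t5);
  hy_xi(7) = eta * (r4 - r5);
  hy_xi(8) = -eta * (q4 - q5);

  hx_eta(0) = -p5 * (1.0 - 2.0 * eta) - xi * (p6 - p5);
  hx_eta(1) = q5 * (1.0 - 2.0 * eta) - xi * (q5 + q6);
  hx_eta(2) = -4.0 + 6.0 * (xi + eta) + r5 * (1.0 - 2.0 * eta) - xi * (r5 + r6);
  hx_eta(3) = xi * (p4 + p6);
  hx_eta(4) = xi * (q4 - q6);
  hx_eta(5) = -xi * (r6 - r4);
  hx_eta(6) = p5 * (1.0 - 2.0 * eta) - xi * (p4 + p5);
  hx_eta(7) = q5 * (1.0 - 2.0 * eta) + xi * (q4 - q5);
  hx_eta(8) = -2.0 + 6.0 * eta + r5 * (1.0 - 2.0 * eta) + xi * (r4 - r5);

  hy_eta(0) = -t5 * (1.0 - 2.0 * eta) - xi * (t6 - t5);
  hy_eta(1) = 1.0 + r5 * (1.0 - 2.0 * eta) - xi * (r5 + r6);
  hy_eta(2) = -q5 * (1.0 - 2.0 * eta) + xi * (q5 + q6);
  hy_eta(3) = xi * (t4 + t6);
  hy_eta(4) = xi * (r4 - r6);
  hy_eta(5) = -xi * (q4 - q6);
  hy_eta(6) = t5 * (1.0 - 2.0 * eta) - xi * (t4 + t5);
  hy_eta(7) = -1.0 + r5 * (1.0 - 2.0 * eta) + xi * (r4 - r5);
  hy_eta(8) = -q5 * (1.0 - 2.0 * eta) - xi * (q4 - q5);
}

// 9x9 DKT bending stiffness in local coords (nodes have (w, thx, thy))
mat dkt_bending(double x1, double y1, double x2, double y2, double x3, double y3,
                double E, double nu, double th) {
  const double x23 = x2 - x3, y23 = y2 - y3;
  const double x31 = x3 - x1, y31 = y3 - y1;
  const double x12 = x1 - x2, y12 = y1 - y2;
  const double A2 = x31 * y12 - x12 * y31;  // 2*Area
  const double xs[3] = {x23, x31, x12};
  const double ys[3] = {y23, y31, y12};
  double p[3], q[3], t[3], r[3];
  for (int k = 0; k < 3; ++k) {
    double l2 = xs[k] * xs[k] + ys[k] * ys[k];
    p[k] = -6.0 * xs[k] / l2;
    q[k] = 3.0 * xs[k] * ys[k] / l2;
    t[k] = -6.0 * ys[k] / l2;
    r[k] = 3.0 * ys[k] * ys[k] / l2;
  }
  const double D0 = E * th * th * th / (12.0 * (1.0 - nu * nu));
  mat Db(3, 3, arma::fill::zeros);
  Db(0, 0) = Db(1, 1) = D0;
  Db(0, 1) = Db(1, 0) = nu * D0;
  Db(2, 2) = 0.5 * (1.0 - nu) * D0;

  const double gp[3][2] = {{0.5, 0.0}, {0.0, 0.5}, {0.5, 0.5}};
  mat K(9, 9, arma::fill::zeros);
  vec hx_xi, hy_xi, hx_eta, hy_eta;
  for (int g = 0; g < 3; ++g) {
    dkt_hderiv(gp[g][0], gp[g][1], p, q, t, r, hx_xi, hy_xi, hx_eta, hy_eta);
    mat B(3, 9);
    for (int j = 0; j < 9; ++j) {
      B(0, j) = (y31 * hx_xi(j) + y12 * hx_eta(j)) / A2;
      B(1, j) = (-x31 * hy_xi(j) - x12 * hy_eta(j)) / A2;
      B(2, j) = (-x31 * hx_xi(j) - x12 * hx_eta(j) + y31 * hy_xi(j) + y12 * hy_eta(j)) / A2;
    }
    K += (A2 / 2.0) * (1.0 / 3.0) * B.t() * Db * B;
  }
  return K;
}

// 6x6 CST membrane stiffness in local coords (nodes have (u, v))
mat cst_membrane(double x1, double y1, double x2, double y2, double x3, double y3,
                 double E, double nu, double th, mat* Bout = nullptr) {
  const double b1 = y2 - y3, b2 = y3 - y1, b3 = y1 - y2;
  const double c1 = x3 - x2, c2 = x1 - x3, c3 = x2 - x1;
  const double A2 = (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1);
  mat B(3, 6, arma::fill::zeros);
  B(0, 0) = b1; B(0, 2) = b2; B(0, 4) = b3;
  B(1, 1) = c1; B(1, 3) = c2; B(1, 5) = c3;
  B(2, 0) = c1; B(2, 1) = b1; B(2, 2) = c2; B(2, 3) = b2; B(2, 4) = c3; B(2, 5) = b3;
  B /= A2;
  mat Dm(3, 3, arma::fill::zeros);
  const double f = E / (1.0 - nu * nu);
  Dm(0, 0) = Dm(1, 1) = f;
  Dm(0, 1) = Dm(1, 0) = nu * f;
  Dm(2, 2) = 0.5 * (1.0 - nu) * f;
  if (Bout) *Bout = B;
  return th * (A2 / 2.0) * B.t() * Dm * B;
}

// local frame rows (e1, e2, e3) and local 2D coordinates of the triangle
void local_frame(const mat& P, mat& R, double* xl, double* yl) {
  vec d1 = P.row(1).t() - P.row(0).t();
  vec d2 = P.row(2).t() - P.row(0).t();
  vec e3 = arma::cross(d1, d2);
  double a2 = arma::norm(e3);
  if (a2 <= 0) stop("degenerate triangle in shell mesh");
  e3 /= a2;
  vec e1 = d1 / arma::norm(d1);
  vec e2 = arma::cross(e3, e1);
  R.set_size(3, 3);
  R.row(0) = e1.t(); R.row(1) = e2.t(); R.row(2) = e3.t();
  xl[0] = 0.0; yl[0] = 0.0;
  xl[1] = arma::dot(d1, e1); yl[1] = 0.0;
  xl[2] = arma::dot(d2, e1); yl[2] = arma::dot(d2, e2);
}

// Full 18x18 local stiffness, DOF order per node (u,v,w,thx,thy,thz)
mat shell_local(const mat& P, double E, double nu, double th, double drill) {
  mat R; double xl[3], yl[3];
  local_frame(P, R, xl, yl);
  mat Km = cst_membrane(xl[0], yl[0], xl[1], yl[1], xl[2], yl[2], E, nu, th);
  mat Kb = dkt_bending(xl[0], yl[0], xl[1], yl[1], xl[2], yl[2], E, nu, th);
  const double A = 0.5 * ((xl[1] - xl[0]) * (yl[2] - yl[0]) - (xl[2] - xl[0]) * (yl[1] - yl[0]));
  mat K(18, 18, arma::fill::zeros);
  const int mi[6] = {0, 1, 6, 7, 12, 13};           // u,v per node
  const int bi[9] = {2, 3, 4, 8, 9, 10, 14, 15, 16}; // w,thx,thy per node
  const int di[3] = {5, 11, 17};                     // thz per node
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b) K(mi[a], mi[b]) += Km(a, b);
  for (int a = 0; a < 9; ++a)
    for (int b = 0; b < 9; ++b) K(bi[a], bi[b]) += Kb(a, b);
  // fictitious drilling stiffness, zero-energy for uniform drilling rotation
  const double kd = drill * E * th * A;
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) K(di[a], di[b]) += kd * (a == b ? 1.0 : -0.5);
  // transform to global axes
  mat T(18, 18, arma::fill::zeros);
  for (int blk = 0; blk < 6; ++blk)
    T.submat(3 * blk, 3 * blk, 3 * blk + 2, 3 * blk + 2) = R;
  return T.t() * K * T;
}

} // namespace

// [[Rcpp::export(name = ".shell_triplets_cpp")]]
List shell_triplets_cpp(NumericMatrix nodes, IntegerMatrix tris,
                        double E, double nu, NumericVector thickness,
                        double drill) {
  const int nt = tris.nrow();
  if (thickness.size() != 1 && thickness.size() != nt)
    stop("thickness must be scalar or one value per element");
  mat N(nodes.begin(), nodes.nrow(), 3, false);
  std::vector<int> ti, tj;
  std::vector<double> tv;
  ti.reserve((size_t)nt * 324); tj.reserve((size_t)nt * 324); tv.reserve((size_t)nt * 324);
  mat P(3, 3);
  for (int e = 0; e < nt; ++e) {
    int v[3] = {tris(e, 0) - 1, tris(e, 1) - 1, tris(e, 2) - 1};
    for (int a = 0; a < 3; ++a) P.row(a) = N.row(v[a]);
    double th = thickness.size() == 1 ? thickness[0] : thickness[e];
    mat K = shell_local(P, E, nu, th, drill);
    for (int a = 0; a < 18; ++a) {
      int ga = 6 * v[a / 6] + (a % 6);
      for (int b = 0; b < 18; ++b) {
        int gb = 6 * v[b / 6] + (b % 6);
        double x = K(a, b);
        if (x != 0.0) { ti.push_back(ga + 1); tj.push_back(gb + 1); tv.push_back(x); }
      }
    }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj), _["x"] = wrap(tv));
}

// Per-element membrane stress recovered from a global 6-DOF/node displacement
// vector; the in-plane stress tensor is rotated to the global axes and
// returned as (sxx, syy, szz, sxy, sxz, syz).
// [[Rcpp::export(name = ".membrane_stress_cpp")]]
NumericMatrix membrane_stress_cpp(NumericMatrix nodes, IntegerMatrix tris,
                                  double E, double nu, NumericVector u) {
  const int nt = tris.nrow();
  mat N(nodes.begin(), nodes.nrow(), 3, false);
  NumericMatrix S(nt, 6);
  mat P(3, 3);
  for (int e = 0; e < nt; ++e) {
    int v[3] = {tris(e, 0) - 1, tris(e, 1) - 1, tris(e, 2) - 1};
    for (int a = 0; a < 3; ++a) P.row(a) = N.row(v[a]);
    mat R; double xl[3], yl[3];
    local_frame(P, R, xl, yl);
    mat B;
    cst_membrane(xl[0], yl[0], xl[1], yl[1], xl[2], yl[2], E, nu, 1.0, &B);
    vec um(6);
    for (int a = 0; a < 3; ++a) {
      vec ug(3);
      for (int k = 0; k < 3; ++k) ug(k) = u[6 * v[a] + k];
      vec ul = R * ug;
      um(2 * a) = ul(0); um(2 * a + 1) = ul(1);
    }
    mat Dm(3, 3, arma::fill::zeros);
    const double f = E / (1.0 - nu * nu);
    Dm(0, 0) = Dm(1, 1) = f; Dm(0, 1) = Dm(1, 0) = nu * f; Dm(2, 2) = 0.5 * (1.0 - nu) * f;
    vec s = Dm * (B * um);
    mat Sl(3, 3, arma::fill::zeros);
    Sl(0, 0) = s(0); Sl(1, 1) = s(1); Sl(0, 1) = Sl(1, 0) = s(2);
    mat Sg = R.t() * Sl * R;
    S(e, 0) = Sg(0, 0); S(e, 1) = Sg(1, 1); S(e, 2) = Sg(2, 2);
    S(e, 3) = Sg(0, 1); S(e, 4) = Sg(0, 2); S(e, 5) = Sg(1, 2);
  }
  return S;
}
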