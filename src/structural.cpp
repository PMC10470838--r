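// Point-cloud kernels: kNN mean-distance statistic (statistical outlier
// filter), moving-least-squares plane projection, and an incremental 3-D
// convex hull (volume + outward facet planes).

#include <RcppArmadillo.h>
#include <vector>
#include <algorithm>
#include <cmath>

// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Mean Euclidean distance from each point to its k nearest neighbours.
// Brute force O(n^2); fine at phenotyping-plot scales (<= ~10^5 points).
// [[Rcpp::export(name = ".knn_mean_dist")]]
NumericVector knn_mean_dist(const NumericMatrix& pts, int k) {
  const int n = pts.nrow();
  if (k < 1) stop("k must be >= 1");
  if (k >= n) stop("need more points than k");
  NumericVector out(n);
  std::vector<double> d2(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      const double dx = pts(i, 0) - pts(j, 0);
      const double dy = pts(i, 1) - pts(j, 1);
      const double dz = pts(i, 2) - pts(j, 2);
      d2[j] = dx * dx + dy * dy + dz * dz;
    }
    d2[i] = std::numeric_limits<double>::infinity();  // skip self
    std::nth_element(d2.begin(), d2.begin() + (k - 1), d2.end());
    double s = 0.0;
    for (int j = 0; j < k; ++j) s += std::sqrt(d2[j]);
    out[i] = s / k;
  }
  return out;
}

// Project each point onto the total-least-squares plane of its neighbours
// within `radius` (degree-1 MLS). Points with < 3 neighbours (self included)
// pass through unchanged.
// [[Rcpp::export(name = ".mls_project")]]
NumericMatrix mls_project(const NumericMatrix& pts, double radius) {
  const int n = pts.nrow();
  if (radius <= 0) stop("radius must be > 0");
  const double r2 = radius * radius;
  NumericMatrix out(n, 3);
  arma::mat P(pts.begin(), n, 3);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int j = 0; j < n; ++j) {
      const double dx = P(i, 0) - P(j, 0);
      const double dy = P(i, 1) - P(j, 1);
      const double dz = P(i, 2) - P(j, 2);
      if (dx * dx + dy * dy + dz * dz <= r2) nb.push_back(j);
    }
    if ((int)nb.size() < 3) {
      for (int c = 0; c < 3; ++c) out(i, c) = P(i, c);
      continue;
    }
    arma::rowvec mu(3, arma::fill::zeros);
    for (int j : nb) mu += P.row(j);
    mu /= (double)nb.size();
    arma::mat C(3, 3, arma::fill::zeros);
    for (int j : nb) {
      arma::rowvec d = P.row(j) - mu;
      C += d.t() * d;
    }
    arma::vec eigval;
    arma::mat eigvec;
    if (!arma::eig_sym(eigval, eigvec, C)) {
      for (int c = 0; c < 3; ++c) out(i, c) = P(i, c);
      continue;
    }
    arma::vec nrm = eigvec.col(0);  // smallest eigenvalue -> plane normal
    arma::rowvec d = P.row(i) - mu;
    const double t = arma::dot(d, nrm.t());
    for (int c = 0; c < 3; ++c) out(i, c) = P(i, c) - t * nrm(c);
  }
  return out;
}

// ---- incremental convex hull ----------------------------------------------

struct Face {
  int a, b, c;
  arma::vec n;   // outward, not normalised
  double off;    // n . x = off on the face plane
  bool alive;
};

static inline arma::vec face_normal(const arma::mat& P, int a, int b, int c) {
  arma::vec u = P.col(b) - P.col(a);
  arma::vec v = P.col(c) - P.col(a);
  return arma::cross(u, v);
}

static void add_face(std::vector<Face>& faces, const arma::mat& P,
                     int a, int b, int c, const arma::vec& interior) {
  Face f;
  f.a = a; f.b = b; f.c = c;
  f.n = face_normal(P, a, b, c);
  f.off = arma::dot(f.n, P.col(a));
  if (arma::dot(f.n, interior) - f.off > 0) {  // flip to point outward
    std::swap(f.b, f.c);
    f.n = -f.n;
    f.off = arma::dot(f.n, P.col(f.a));
  }
  f.alive = true;
  faces.push_back(f);
}

// Returns hull volume plus outward unit-normal facet planes (n . x <= d).
// [[Rcpp::export(name = ".convex_hull3d")]]
List convex_hull3d(const NumericMatrix& pts) {
  const int n = pts.nrow();
  if (n < 4) stop("degenerate hull: need at least 4 points");
  arma::mat P(3, n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) P(c, i) = pts(i, c);

  const double scale = arma::abs(P).max() + 1.0;
  const double eps = 1e-10 * scale;

  // initial simplex: extreme pair, then farthest from line, then from plane
  int i0 = 0, i1 = 0;
  double best = -1.0;
  for (int c = 0; c < 3; ++c) {
    arma::uword lo, hi;
    P.row(c).min(lo); P.row(c).max(hi);
    const double d = P(c, hi) - P(c, lo);
    if (d > best) { best = d; i0 = lo; i1 = hi; }
  }
  if (best <= eps) stop("degenerate hull: points are coincident");
  arma::vec dir = P.col(i1) - P.col(i0);
  int i2 = -1; best = -1.0;
  for (int i = 0; i < n; ++i) {
    arma::vec w = P.col(i) - P.col(i0);
    const double d = arma::norm(arma::cross(dir, w));
    if (d > best) { best = d; i2 = i; }
  }
  if (best <= eps * arma::norm(dir))
    stop("degenerate hull: points are collinear");
  arma::vec nrm0 = face_normal(P, i0, i1, i2);
  const double off0 = arma::dot(nrm0, P.col(i0));
  int i3 = -1; best = -1.0;
  for (int i = 0; i < n; ++i) {
    const double d = std::fabs(arma::dot(nrm0, P.col(i)) - off0);
    if (d > best) { best = d; i3 = i; }
  }
  if (best <= eps * arma::norm(nrm0))
    stop("degenerate hull: points are coplanar");

  arma::vec interior =
    (P.col(i0) + P.col(i1) + P.col(i2) + P.col(i3)) / 4.0;
  std::vector<Face> faces;
  add_face(faces, P, i0, i1, i2, interior);
  add_face(faces, P, i0, i1, i3, interior);
  add_face(faces, P, i0, i2, i3, interior);
  add_face(faces, P, i1, i2, i3, interior);

  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    // faces visible from point i
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      const double d = arma::dot(faces[f].n, P.col(i)) - faces[f].off;
      if (d > eps * arma::norm(faces[f].n)) vis.push_back((int)f);
    }
    if (vis.empty()) continue;
    // horizon = edges of visible faces appearing exactly once
    std::vector<std::pair<int, int>> edges;
    for (int f : vis) {
      const Face& fc = faces[f];
      edges.emplace_back(fc.a, fc.b);
      edges.emplace_back(fc.b, fc.c);
      edges.emplace_back(fc.c, fc.a);
      faces[f].alive = false;
    }
    for (const auto& e : edges) {
      bool paired = false;
      for (const auto& e2 : edges)
        if (e2.first == e.second && e2.second == e.first) {
          paired = true; break;
        }
      if (!paired) add_face(faces, P, e.first, e.second, i, interior);
    }
  }

  double vol = 0.0;
  int n_faces = 0;
  for (const Face& f : faces) {
    if (!f.alive) continue;
    ++n_faces;
    // signed tetra (interior, a, b, c); outward orientation => positive
    arma::vec a = P.col(f.a) - interior;
    arma::vec b = P.col(f.b) - interior;
    arma::vec c = P.col(f.c) - interior;
    vol += arma::dot(a, arma::cross(b, c)) / 6.0;
  }
  NumericMatrix normals(n_faces, 3);
  NumericVector offsets(n_faces);
  int r = 0;
  for (const Face& f : faces) {
    if (!f.alive) continue;
    const double len = arma::norm(f.n);
    for (int c = 0; c < 3; ++c) normals(r, c) = f.n(c) / len;
    offsets[r] = f.off / len;
    ++r;
  }
  return List::create(_["volume"] = vol,
                      _["normals"] = normals,
                      _["offsets"] = offsets);
}
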