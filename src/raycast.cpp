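#include <Rcpp.h>
using namespace Rcpp;

// Möller–Trumbore intersection of rays (origin at each pixel unit vector,
// direction toward the coordinate origin) against every mesh triangle.
// Returns, per ray, the nearest hit: face index (1-based, 0 = miss),
// distance t along the unit direction, and barycentric coordinates (u, v)
// of the hit point with respect to vertices 2 and 3 of the face.
// [[Rcpp::export]]
List raycast_mesh(NumericMatrix origins, NumericMatrix dirs,
                  NumericMatrix vertices, IntegerMatrix faces) {
  const int nray = origins.nrow();
  const int nf = faces.nrow();
  IntegerVector hit_face(nray);
  NumericVector hit_t(nray), hit_u(nray), hit_v(nray);

  std::vector<double> v0x(nf), v0y(nf), v0z(nf);
  std::vector<double> e1x(nf), e1y(nf), e1z(nf);
  std::vector<double> e2x(nf), e2y(nf), e2z(nf);
  for (int f = 0; f < nf; ++f) {
    const int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
    v0x[f] = vertices(a, 0); v0y[f] = vertices(a, 1); v0z[f] = vertices(a, 2);
    e1x[f] = vertices(b, 0) - v0x[f];
    e1y[f] = vertices(b, 1) - v0y[f];
    e1z[f] = vertices(b, 2) - v0z[f];
    e2x[f] = vertices(c, 0) - v0x[f];
    e2y[f] = vertices(c, 1) - v0y[f];
    e2z[f] = vertices(c, 2) - v0z[f];
  }

  const double eps = 1e-12;
  for (int r = 0; r < nray; ++r) {
    const double ox = origins(r, 0), oy = origins(r, 1), oz = origins(r, 2);
    const double dx = dirs(r, 0), dy = dirs(r, 1), dz = dirs(r, 2);
    double best_t = R_PosInf;
    int best_f = 0;
    double best_u = 0, best_v = 0;
    for (int f = 0; f < nf; ++f) {
      // p = d x e2
      const double px = dy * e2z[f] - dz * e2y[f];
      const double py = dz * e2x[f] - dx * e2z[f];
      const double pz = dx * e2y[f] - dy * e2x[f];
      const double det = e1x[f] * px + e1y[f] * py + e1z[f] * pz;
      if (det > -eps && det < eps) continue;
      const double inv = 1.0 / det;
      const double tx = ox - v0x[f], ty = oy - v0y[f], tz = oz - v0z[f];
      const double u = (tx * px + ty * py + tz * pz) * inv;
      if (u < -1e-9 || u > 1.0 + 1e-9) continue;
      // q = t x e1
      const double qx = ty * e1z[f] - tz * e1y[f];
      const double qy = tz * e1x[f] - tx * e1z[f];
      const double qz = tx * e1y[f] - ty * e1x[f];
      const double v = (dx * qx + dy * qy + dz * qz) * inv;
      if (v < -1e-9 || u + v > 1.0 + 1e-9) continue;
      const double t = (e2x[f] * qx + e2y[f] * qy + e2z[f] * qz) * inv;
      if (t > 1e-9 && t < best_t) {
        best_t = t; best_f = f + 1; best_u = u; best_v = v;
      }
    }
    hit_face[r] = best_f;
    hit_t[r] = best_f ? best_t : NA_REAL;
    hit_u[r] = best_f ? best_u : NA_REAL;
    hit_v[r] = best_f ? best_v : NA_REAL;
  }
  return List::create(_["face"] = hit_face, _["t"] = hit_t,
                      _["u"] = hit_u, _["v"] = hit_v);
}
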