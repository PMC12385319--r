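#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Wolf-style maximum Lyapunov exponent from a sequence of state points.
//
// The caller supplies one point per row (a delay embedding of a scalar
// signal, or directly the system's state trajectory); the fiducial
// trajectory's nearest neighbour (at least min_sep samples away in time) is
// tracked for `evolv` iterations, the log distance growth is accumulated,
// and the neighbour is then replaced by a nearby point that minimises the
// change in orientation relative to the fiducial point (standard Wolf
// replacement). Exactly coincident points (distance 0, e.g. on a periodic
// orbit stored in finite precision) contribute zero growth: two identical
// states separate at rate 0.
//
// Neighbour searches use a uniform grid over the first two embedding
// coordinates; the 2-D cell distance is a lower bound on the full m-D
// distance, so ring-expansion pruning remains exact for any m.

namespace {

struct EmbeddedSet {
  const double *x;  // np x m matrix, column-major
  int np, m;
  // grid over coordinates 0 and 1
  int ncell;
  double x0min, x1min, cwx, cwy;
  std::vector<int> cell_start;  // ncell*ncell + 1
  std::vector<int> cell_pts;    // point ids sorted by cell

  double coord(int i, int d) const { return x[i + (R_xlen_t)d * np]; }

  double dist2(int i, int j) const {
    double s = 0.0;
    for (int d = 0; d < m; ++d) {
      double diff = coord(i, d) - coord(j, d);
      s += diff * diff;
    }
    return s;
  }

  int cell_of(int i) const {
    int cx = (int)((coord(i, 0) - x0min) / cwx);
    int cy = (int)((coord(i, 1) - x1min) / cwy);
    if (cx < 0) cx = 0; if (cx >= ncell) cx = ncell - 1;
    if (cy < 0) cy = 0; if (cy >= ncell) cy = ncell - 1;
    return cx * ncell + cy;
  }

  void build() {
    ncell = (int)std::sqrt((double)np / 4.0);
    if (ncell < 1) ncell = 1;
    if (ncell > 1024) ncell = 1024;
    double x0max = coord(0, 0), x1max = coord(0, 1);
    x0min = x0max; x1min = x1max;
    for (int i = 0; i < np; ++i) {
      double a = coord(i, 0), b = coord(i, 1);
      if (a < x0min) x0min = a; if (a > x0max) x0max = a;
      if (b < x1min) x1min = b; if (b > x1max) x1max = b;
    }
    cwx = (x0max - x0min) / ncell; if (cwx <= 0) cwx = 1.0;
    cwy = (x1max - x1min) / ncell; if (cwy <= 0) cwy = 1.0;
    std::vector<int> count(ncell * ncell, 0);
    for (int i = 0; i < np; ++i) ++count[cell_of(i)];
    cell_start.assign(ncell * ncell + 1, 0);
    for (int c = 0; c < ncell * ncell; ++c)
      cell_start[c + 1] = cell_start[c] + count[c];
    cell_pts.assign(np, 0);
    std::vector<int> fill(cell_start.begin(), cell_start.end() - 1);
    for (int i = 0; i < np; ++i) cell_pts[fill[cell_of(i)]++] = i;
  }

  // visit points in cells at Chebyshev ring `ring` around the query cell
  template <typename F>
  void scan_ring(int qcx, int qcy, int ring, F &&visit) const {
    int xlo = qcx - ring, xhi = qcx + ring;
    int ylo = qcy - ring, yhi = qcy + ring;
    for (int cx = xlo; cx <= xhi; ++cx) {
      if (cx < 0 || cx >= ncell) continue;
      for (int cy = ylo; cy <= yhi; ++cy) {
        if (cy < 0 || cy >= ncell) continue;
        if (ring > 0 && cx != xlo && cx != xhi && cy != ylo && cy != yhi)
          continue; // interior of the ring, already visited
        int c = cx * ncell + cy;
        for (int k = cell_start[c]; k < cell_start[c + 1]; ++k)
          visit(cell_pts[k]);
      }
    }
  }

  // nearest admissible neighbour of i; returns -1 if none exists
  int nearest(int i, int min_sep, int jmax, double *dout) const {
    int qc = cell_of(i), qcx = qc / ncell, qcy = qc % ncell;
    double cw = std::min(cwx, cwy);
    int best = -1;
    double best2 = R_PosInf;
    int max_ring = 2 * ncell;
    for (int ring = 0; ring <= max_ring; ++ring) {
      if (ring >= 2) {
        double bound = (ring - 1) * cw;
        if (best >= 0 && bound * bound > best2) break;
      }
      scan_ring(qcx, qcy, ring, [&](int j) {
        if (j == i || std::abs(j - i) < min_sep || j > jmax) return;
        double d2 = dist2(i, j);
        if (d2 < best2) { best2 = d2; best = j; }
      });
    }
    if (dout) *dout = (best >= 0) ? std::sqrt(best2) : R_PosInf;
    return best;
  }

  // candidates of i within radius rmax (capped), for orientation-preserving
  // replacement
  void within(int i, int min_sep, int jmax, double rmax,
              std::vector<int> &out) const {
    out.clear();
    int qc = cell_of(i), qcx = qc / ncell, qcy = qc % ncell;
    double cw = std::min(cwx, cwy);
    double rmax2 = rmax * rmax;
    int max_ring = 2 * ncell;
    for (int ring = 0; ring <= max_ring; ++ring) {
      if (ring >= 2 && (ring - 1) * cw > rmax) break;
      scan_ring(qcx, qcy, ring, [&](int j) {
        if (j == i || std::abs(j - i) < min_sep || j > jmax) return;
        if (dist2(i, j) <= rmax2 && out.size() < 512) out.push_back(j);
      });
      if (out.size() >= 512) break;
    }
  }
};

} // namespace

// `pts` holds one reconstructed or measured state per row (a delay
// embedding of a scalar signal, or the map's actual state trajectory);
// `n_signal` is the underlying signal length used to scale the minimum
// temporal separation.
// [[Rcpp::export]]
List cpp_wolf(NumericMatrix pts, int n_signal, int evolv,
              double min_sep_frac, double angle_max) {
  int np = pts.nrow();
  int m = pts.ncol();
  if (np < 2) stop("signal too short for the requested embedding");
  int min_sep = (int)std::lround(min_sep_frac * n_signal);
  if (min_sep < 1) min_sep = 1;
  int jmax = np - 1 - evolv;
  if (jmax < min_sep)
    stop("no admissible neighbour: need more than %d samples for a %g%% minimum temporal separation and a tracking horizon of %d; use a longer signal or a smaller separation",
         evolv + min_sep + 1, 100.0 * min_sep_frac, evolv);

  EmbeddedSet es;
  es.x = REAL(pts); es.np = np; es.m = m;
  es.build();

  int i = 0;
  double dnn;
  int j = es.nearest(i, min_sep, jmax, &dnn);
  if (j < 0)
    stop("no admissible neighbour found; use a longer signal or a smaller minimum separation");

  double sum = 0.0;
  long steps = 0;
  int nseg = 0;
  std::vector<int> cand;

  while (i + evolv <= np - 1 && j + evolv <= np - 1) {
    double d0 = std::sqrt(es.dist2(i, j));
    int i2 = i + evolv, j2 = j + evolv;
    double d1 = std::sqrt(es.dist2(i2, j2));
    if (d0 > 0.0 && d1 > 0.0) sum += std::log(d1 / d0);
    steps += evolv;
    ++nseg;
    i = i2;
    if (i + evolv > np - 1) break;

    // replacement: keep orientation relative to the fiducial point
    int jn = es.nearest(i, min_sep, jmax, &dnn);
    if (jn < 0) { j = (j2 <= jmax) ? j2 : jn; if (j < 0) break; continue; }
    double dref = std::sqrt(es.dist2(i, j2));
    if (dref <= 0.0 || d1 <= 0.0) { j = jn; continue; }
    es.within(i, min_sep, jmax, std::max(5.0 * dnn, dnn), cand);
    int best = jn;
    double best_ang = R_PosInf, best_d = R_PosInf;
    bool found_in_cone = false;
    for (size_t k = 0; k < cand.size(); ++k) {
      int c = cand[k];
      double dc = std::sqrt(es.dist2(i, c));
      if (dc <= 0.0) continue;
      double dot = 0.0;
      for (int d = 0; d < es.m; ++d)
        dot += (es.coord(c, d) - es.coord(i, d)) *
               (es.coord(j2, d) - es.coord(i, d));
      double ang = std::acos(std::min(1.0, std::max(-1.0, dot / (dc * dref))));
      if (ang <= angle_max) {
        if (!found_in_cone || dc < best_d) { best = c; best_d = dc; }
        found_in_cone = true;
      } else if (!found_in_cone && ang < best_ang) {
        best = c; best_ang = ang;
      }
    }
    j = best;
  }

  if (steps == 0) stop("no divergence segments could be tracked");
  return List::create(_["lambda"] = sum / (double)steps,
                      _["n_steps"] = (double)steps,
                      _["n_segments"] = nseg);
}
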