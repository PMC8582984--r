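// ForceAtlas2-style force-directed layout: linear edge attraction,
// degree-weighted 1/d repulsion (exact or Barnes-Hut), classic gravity and
// the adaptive global/local speed scheme. Deterministic given the initial
// positions; coincident points are separated by a small index-based jitter
// instead of a random draw.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double KS = 0.1;      // local speed scaling
static const double KSMAX = 10.0;  // displacement cap
static const double D2MIN = 1e-18; // coincident-point guard

// deterministic sub-unit jitter direction for coincident points
static inline void jitter(int i, int j, double &dx, double &dy) {
  unsigned h = (unsigned)(i * 2654435761u) ^ (unsigned)(j * 40503u + 2699u);
  double ang = 6.283185307179586 * ((h % 104729u) / 104729.0);
  dx = 1e-6 * std::cos(ang);
  dy = 1e-6 * std::sin(ang);
}

struct QuadTree {
  std::vector<double> comx, comy, mass, cx, cy, half;
  std::vector<int> child;  // 4 per node; -1 = none
  std::vector<int> body;   // body index for single-body leaves, -1 otherwise
  std::vector<int> count;  // bodies under node

  int new_node(double x, double y, double h) {
    comx.push_back(0); comy.push_back(0); mass.push_back(0);
    cx.push_back(x); cy.push_back(y); half.push_back(h);
    for (int k = 0; k < 4; ++k) child.push_back(-1);
    body.push_back(-1); count.push_back(0);
    return (int)mass.size() - 1;
  }

  int quadrant(int node, double x, double y) const {
    return (x >= cx[node] ? 1 : 0) + (y >= cy[node] ? 2 : 0);
  }

  int child_of(int node, int q) {
    int c = child[4 * node + q];
    if (c < 0) {
      double h = half[node] / 2.0;
      double x = cx[node] + (q & 1 ? h : -h);
      double y = cy[node] + (q & 2 ? h : -h);
      c = new_node(x, y, h);
      child[4 * node + q] = c;
    }
    return c;
  }

  void insert(int root, int b, double x, double y, double m) {
    int node = root, depth = 0;
    while (true) {
      mass[node] += m;
      comx[node] += m * x;
      comy[node] += m * y;
      count[node] += 1;
      if (count[node] == 1) { body[node] = b; return; }
      if (body[node] >= 0 && depth < 48) {
        // push the resident body one level down, then continue with b
        int ob = body[node];
        double ox = comx[node] / mass[node], oy = comy[node] / mass[node];
        // recover the resident body's exact position from stored aggregates:
        // before this insert, node held exactly that body, so its com was it
        ox = (comx[node] - m * x) / (mass[node] - m);
        oy = (comy[node] - m * y) / (mass[node] - m);
        double om = mass[node] - m;
        body[node] = -1;
        int qo = quadrant(node, ox, oy);
        int co = child_of(node, qo);
        mass[co] += om; comx[co] += om * ox; comy[co] += om * oy;
        count[co] += 1; body[co] = ob;
      }
      if (depth >= 48) return;  // coincident pile-up: keep aggregated
      int q = quadrant(node, x, y);
      node = child_of(node, q);
      ++depth;
    }
  }
};

static void repulsion_exact(const std::vector<double> &px,
                            const std::vector<double> &py,
                            const std::vector<double> &mass,
                            double kr, std::vector<double> &fx,
                            std::vector<double> &fy) {
  int n = (int)px.size();
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = px[i] - px[j], dy = py[i] - py[j];
      double d2 = dx * dx + dy * dy;
      if (d2 < D2MIN) { jitter(i, j, dx, dy); d2 = dx * dx + dy * dy; }
      double f = kr * mass[i] * mass[j] / d2;
      fx[i] += f * dx; fy[i] += f * dy;
      fx[j] -= f * dx; fy[j] -= f * dy;
    }
  }
}

static void repulsion_bh(const std::vector<double> &px,
                         const std::vector<double> &py,
                         const std::vector<double> &mass,
                         double kr, double theta,
                         std::vector<double> &fx, std::vector<double> &fy) {
  int n = (int)px.size();
  double xmin = px[0], xmax = px[0], ymin = py[0], ymax = py[0];
  for (int i = 1; i < n; ++i) {
    if (px[i] < xmin) xmin = px[i];
    if (px[i] > xmax) xmax = px[i];
    if (py[i] < ymin) ymin = py[i];
    if (py[i] > ymax) ymax = py[i];
  }
  double h = std::max(xmax - xmin, ymax - ymin) / 2.0 + 1e-9;
  QuadTree t;
  int root = t.new_node((xmin + xmax) / 2.0, (ymin + ymax) / 2.0, h);
  for (int i = 0; i < n; ++i) t.insert(root, i, px[i], py[i], mass[i]);

  std::vector<int> stack;
  stack.reserve(256);
  for (int i = 0; i < n; ++i) {
    stack.clear();
    stack.push_back(root);
    while (!stack.empty()) {
      int node = stack.back();
      stack.pop_back();
      if (t.count[node] == 0) continue;
      if (t.count[node] == 1 && t.body[node] == i) continue;
      double m = t.mass[node];
      double comx = t.comx[node] / m, comy = t.comy[node] / m;
      double dx = px[i] - comx, dy = py[i] - comy;
      double d2 = dx * dx + dy * dy;
      bool leafish = true;
      for (int k = 0; k < 4; ++k)
        if (t.child[4 * node + k] >= 0) { leafish = false; break; }
      double size = 2.0 * t.half[node];
      if (leafish || size * size < theta * theta * d2) {
        // aggregated interaction; drop own mass when i sits inside the cell
        double mm = m;
        if (!(t.count[node] == 1) && !leafish) {
          // cheap containment test for self-mass correction
          if (std::abs(px[i] - t.cx[node]) <= t.half[node] &&
              std::abs(py[i] - t.cy[node]) <= t.half[node])
            mm = m - mass[i];
        }
        if (mm <= 0) continue;
        if (d2 < D2MIN) { jitter(i, node, dx, dy); d2 = dx * dx + dy * dy; }
        double f = kr * mass[i] * mm / d2;
        fx[i] += f * dx; fy[i] += f * dy;
      } else {
        for (int k = 0; k < 4; ++k) {
          int c = t.child[4 * node + k];
          if (c >= 0) stack.push_back(c);
        }
      }
    }
  }
}

static void accumulate_forces(const std::vector<double> &px,
                              const std::vector<double> &py,
                              const IntegerMatrix &edges,
                              const std::vector<double> &mass,
                              double kr, double gravity, bool barnes_hut,
                              double theta, std::vector<double> &fx,
                              std::vector<double> &fy) {
  int n = (int)px.size();
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  if (barnes_hut)
    repulsion_bh(px, py, mass, kr, theta, fx, fy);
  else
    repulsion_exact(px, py, mass, kr, fx, fy);
  // linear attraction along edges: force magnitude = distance
  int ne = edges.nrow();
  for (int e = 0; e < ne; ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    double dx = px[a] - px[b], dy = py[a] - py[b];
    fx[a] -= dx; fy[a] -= dy;
    fx[b] += dx; fy[b] += dy;
  }
  // classic gravity: magnitude g * mass, toward the origin
  if (gravity > 0) {
    for (int i = 0; i < n; ++i) {
      double d = std::sqrt(px[i] * px[i] + py[i] * py[i]);
      if (d > 1e-12) {
        double f = gravity * mass[i] / d;
        fx[i] -= f * px[i];
        fy[i] -= f * py[i];
      }
    }
  }
}

// [[Rcpp::export(name = ".fa2_forces")]]
NumericMatrix fa2_forces_cpp(NumericMatrix pos, IntegerMatrix edges,
                             NumericVector mass, double kr, double gravity,
                             bool barnes_hut, double theta) {
  int n = pos.nrow();
  std::vector<double> px(n), py(n), ms(n), fx(n), fy(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos(i, 0); py[i] = pos(i, 1); ms[i] = mass[i];
  }
  accumulate_forces(px, py, edges, ms, kr, gravity, barnes_hut, theta, fx, fy);
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = fx[i]; out(i, 1) = fy[i]; }
  return out;
}

// [[Rcpp::export(name = ".fa2_run")]]
List fa2_run_cpp(NumericMatrix pos0, IntegerMatrix edges, NumericVector mass,
                 double kr, double gravity, int iterations, double tolerance,
                 bool barnes_hut, double theta) {
  int n = pos0.nrow();
  std::vector<double> px(n), py(n), ms(n), fx(n), fy(n), pfx(n, 0.0),
      pfy(n, 0.0);
  for (int i = 0; i < n; ++i) {
    px[i] = pos0(i, 0); py[i] = pos0(i, 1); ms[i] = mass[i];
  }
  NumericVector swg_trace(iterations), tra_trace(iterations);
  double speed = 1.0;
  for (int it = 0; it < iterations; ++it) {
    accumulate_forces(px, py, edges, ms, kr, gravity, barnes_hut, theta, fx, fy);
    double gswg = 0.0, gtra = 0.0, sswg = 0.0, stra = 0.0;
    for (int i = 0; i < n; ++i) {
      double dxf = fx[i] - pfx[i], dyf = fy[i] - pfy[i];
      double swg = std::sqrt(dxf * dxf + dyf * dyf);
      double sxf = fx[i] + pfx[i], syf = fy[i] + pfy[i];
      double tra = std::sqrt(sxf * sxf + syf * syf) / 2.0;
      gswg += ms[i] * swg;
      gtra += ms[i] * tra;
      sswg += swg;
      stra += tra;
      pfx[i] = swg;  // stash per-node swinging temporarily
      pfy[i] = tra;
    }
    swg_trace[it] = sswg;
    tra_trace[it] = stra;
    if (gswg > 0) {
      double target = tolerance * tolerance * gtra / gswg;
      // cap speed growth at +50% per iteration (stability)
      speed = speed + std::min(target - speed, 0.5 * speed);
      if (speed <= 1e-12) speed = 1e-12;
    }
    for (int i = 0; i < n; ++i) {
      double swg = pfx[i];
      double factor = KS * speed / (1.0 + speed * std::sqrt(swg));
      double df = std::sqrt(fx[i] * fx[i] + fy[i] * fy[i]);
      if (df > 1e-12) {
        double cap = KSMAX / df;
        if (factor > cap) factor = cap;
      }
      px[i] += fx[i] * factor;
      py[i] += fy[i] * factor;
      pfx[i] = fx[i];
      pfy[i] = fy[i];
      if (!std::isfinite(px[i]) || !std::isfinite(py[i]))
        stop("non-finite coordinates at iteration %d (node %d)", it + 1, i + 1);
    }
  }
  NumericMatrix pos(n, 2);
  for (int i = 0; i < n; ++i) { pos(i, 0) = px[i]; pos(i, 1) = py[i]; }
  return List::create(_["positions"] = pos, _["swinging"] = swg_trace,
                      _["traction"] = tra_trace);
}
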