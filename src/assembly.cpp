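// Bead-spring triangulated-shell growth simulator.
//
// The mesh is the triangulation of monomer centres: one vertex per monomer,
// harmonic springs on edges (rest length l0 = centre spacing) and a cosine
// dihedral penalty on interior edges with preferred angle theta0 encoding the
// monomer cone angle. Growth adds one triangle per step at the rim, closing
// wedges whose opening angle falls below beta_merge (the source of five-fold
// disclinations), otherwise inserting a new vertex on the energetically best
// rim edge (or a random one with probability p_random).

#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

typedef std::array<double, 3> Vec3;

static inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return Vec3{a[0] - b[0], a[1] - b[1], a[2] - b[2]};
}
static inline Vec3 add(const Vec3 &a, const Vec3 &b) {
  return Vec3{a[0] + b[0], a[1] + b[1], a[2] + b[2]};
}
static inline Vec3 scale(const Vec3 &a, double s) {
  return Vec3{a[0] * s, a[1] * s, a[2] * s};
}
static inline double dot(const Vec3 &a, const Vec3 &b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return Vec3{a[1] * b[2] - a[2] * b[1],
              a[2] * b[0] - a[0] * b[2],
              a[0] * b[1] - a[1] * b[0]};
}
static inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

// splitmix64: counter-based generator, bitwise reproducible across platforms
struct SplitMix {
  uint64_t state;
  explicit SplitMix(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int unif_int(int n) { return (int)(unif() * n) % n; }
};

struct Hinge {
  int p1, p2, p3, p4; // edge p1->p2 in tri a (opposite p3); tri b opposite p4
};

struct EdgeRec {
  int i, j;
};

struct MeshState {
  std::vector<Vec3> V;
  std::vector<std::array<int, 3>> T;
  std::vector<int> B; // ordered rim, directed like owning-triangle edges
  std::vector<EdgeRec> edges;
  std::vector<Hinge> hinges;
  std::vector<int> ntri; // triangles incident per vertex

  void rebuild() {
    // unique edges; hinge for each edge shared by two triangles
    std::map<std::pair<int, int>, std::array<int, 2>> opp; // undirected -> opposite verts
    std::map<std::pair<int, int>, int> dir_opp;            // directed edge -> opposite
    edges.clear();
    hinges.clear();
    ntri.assign(V.size(), 0);
    for (size_t t = 0; t < T.size(); ++t) {
      for (int k = 0; k < 3; ++k) ntri[T[t][k]]++;
      for (int k = 0; k < 3; ++k) {
        int a = T[t][k], b = T[t][(k + 1) % 3], c = T[t][(k + 2) % 3];
        dir_opp[{a, b}] = c;
        auto key = a < b ? std::make_pair(a, b) : std::make_pair(b, a);
        auto it = opp.find(key);
        if (it == opp.end()) {
          opp[key] = {c, -1};
          edges.push_back(EdgeRec{key.first, key.second});
        } else {
          it->second[1] = c;
        }
      }
    }
    for (auto &kv : opp) {
      if (kv.second[1] >= 0) {
        // orient hinge along the directed edge of the first triangle
        int a = kv.first.first, b = kv.first.second;
        int p1 = a, p2 = b;
        auto it = dir_opp.find({a, b});
        int c1, c2;
        if (it != dir_opp.end()) {
          c1 = it->second;
          c2 = dir_opp[{b, a}];
        } else {
          p1 = b; p2 = a;
          c1 = dir_opp[{b, a}];
          c2 = dir_opp[{a, b}];
        }
        hinges.push_back(Hinge{p1, p2, c1, c2});
      }
    }
  }
};

// signed dihedral angle across hinge; 0 for coplanar, positive when the two
// faces fold away from the face normals (convex towards the normal side)
static inline double dihedral(const std::vector<Vec3> &V, const Hinge &h) {
  Vec3 e = sub(V[h.p2], V[h.p1]);
  Vec3 n1 = cross(e, sub(V[h.p3], V[h.p1]));
  Vec3 n2 = cross(sub(V[h.p4], V[h.p1]), e);
  double le = norm(e);
  if (le <= 0) return 0.0;
  Vec3 eh = scale(e, 1.0 / le);
  double s = dot(cross(n1, n2), eh);
  double c = dot(n1, n2);
  return std::atan2(s, c);
}

static double mesh_energy(const MeshState &M, double ks, double kb,
                          double l0, double theta0) {
  double E = 0.0;
  for (const auto &e : M.edges) {
    double l = norm(sub(M.V[e.i], M.V[e.j]));
    double d = l - l0;
    E += 0.5 * ks * d * d;
  }
  for (const auto &h : M.hinges) {
    double th = dihedral(M.V, h);
    E += kb * (1.0 - std::cos(th - theta0));
  }
  return E;
}

// accumulate dE/dx into G for all terms touching free vertices
static void mesh_gradient(const MeshState &M, double ks, double kb,
                          double l0, double theta0,
                          const std::vector<char> &freev,
                          std::vector<Vec3> &G) {
  for (auto &g : G) g = Vec3{0, 0, 0};
  for (const auto &e : M.edges) {
    if (!freev[e.i] && !freev[e.j]) continue;
    Vec3 d = sub(M.V[e.i], M.V[e.j]);
    double l = norm(d);
    if (l <= 1e-12) continue;
    double f = ks * (l - l0) / l;
    Vec3 gi = scale(d, f);
    if (freev[e.i]) G[e.i] = add(G[e.i], gi);
    if (freev[e.j]) G[e.j] = sub(G[e.j], gi);
  }
  for (const auto &h : M.hinges) {
    if (!freev[h.p1] && !freev[h.p2] && !freev[h.p3] && !freev[h.p4]) continue;
    Vec3 e = sub(M.V[h.p2], M.V[h.p1]);
    double le = norm(e);
    Vec3 n1 = cross(e, sub(M.V[h.p3], M.V[h.p1]));
    Vec3 n2 = cross(sub(M.V[h.p4], M.V[h.p1]), e);
    double n1sq = dot(n1, n1), n2sq = dot(n2, n2);
    if (le <= 1e-12 || n1sq <= 1e-24 || n2sq <= 1e-24) continue;
    double th = dihedral(M.V, h);
    double dE = -kb * std::sin(th - theta0);
    // gradient of the signed dihedral (discrete-shells hinge formulas)
    Vec3 g3 = scale(n1, le / n1sq);
    Vec3 g4 = scale(n2, le / n2sq);
    double a1 = dot(sub(M.V[h.p3], M.V[h.p2]), e) / le;
    double a2 = dot(sub(M.V[h.p4], M.V[h.p2]), e) / le;
    double b1 = dot(sub(M.V[h.p3], M.V[h.p1]), e) / le;
    double b2 = dot(sub(M.V[h.p4], M.V[h.p1]), e) / le;
    Vec3 g1 = add(scale(n1, a1 / n1sq), scale(n2, a2 / n2sq));
    Vec3 g2 = add(scale(n1, -b1 / n1sq), scale(n2, -b2 / n2sq));
    if (freev[h.p3]) G[h.p3] = add(G[h.p3], scale(g3, dE));
    if (freev[h.p4]) G[h.p4] = add(G[h.p4], scale(g4, dE));
    if (freev[h.p1]) G[h.p1] = add(G[h.p1], scale(g1, dE));
    if (freev[h.p2]) G[h.p2] = add(G[h.p2], scale(g2, dE));
  }
}

// gradient descent with backtracking line search on the free vertex set
static double relax_free(MeshState &M, double ks, double kb, double l0,
                         double theta0, const std::vector<char> &freev,
                         double tol, int maxit, double &gmax_out) {
  std::vector<Vec3> G(M.V.size());
  double E = mesh_energy(M, ks, kb, l0, theta0);
  double step = 0.1 / ks;
  for (int it = 0; it < maxit; ++it) {
    mesh_gradient(M, ks, kb, l0, theta0, freev, G);
    double gmax = 0, gsq = 0;
    for (size_t i = 0; i < G.size(); ++i) {
      if (!freev[i]) continue;
      for (int k = 0; k < 3; ++k) {
        double a = std::fabs(G[i][k]);
        if (a > gmax) gmax = a;
        gsq += G[i][k] * G[i][k];
      }
    }
    gmax_out = gmax;
    if (gmax <= tol) return E;
    std::vector<Vec3> V0 = M.V;
    double t = step;
    bool ok = false;
    for (int ls = 0; ls < 30; ++ls) {
      for (size_t i = 0; i < M.V.size(); ++i)
        if (freev[i]) M.V[i] = sub(V0[i], scale(G[i], t));
      double En = mesh_energy(M, ks, kb, l0, theta0);
      if (En <= E - 0.5 * t * gsq || En < E) {
        E = En;
        ok = true;
        step = t * 1.5;
        break;
      }
      t *= 0.5;
    }
    if (!ok) {
      M.V = V0;
      gmax_out = gmax;
      return E;
    }
  }
  mesh_gradient(M, ks, kb, l0, theta0, freev, G);
  gmax_out = 0;
  for (size_t i = 0; i < G.size(); ++i) {
    if (!freev[i]) continue;
    for (int k = 0; k < 3; ++k)
      gmax_out = std::max(gmax_out, std::fabs(G[i][k]));
  }
  return E;
}

static std::vector<char> all_free(size_t n) { return std::vector<char>(n, 1); }

// vertices within graph distance `depth` of the given seeds
static std::vector<char> local_free(const MeshState &M,
                                    const std::vector<int> &seeds, int depth) {
  std::vector<std::vector<int>> adj(M.V.size());
  for (const auto &e : M.edges) {
    adj[e.i].push_back(e.j);
    adj[e.j].push_back(e.i);
  }
  std::vector<int> distv(M.V.size(), -1);
  std::vector<int> q;
  for (int s : seeds) {
    if (distv[s] < 0) {
      distv[s] = 0;
      q.push_back(s);
    }
  }
  for (size_t qi = 0; qi < q.size(); ++qi) {
    int u = q[qi];
    if (distv[u] >= depth) continue;
    for (int w : adj[u])
      if (distv[w] < 0) {
        distv[w] = distv[u] + 1;
        q.push_back(w);
      }
  }
  std::vector<char> f(M.V.size(), 0);
  for (size_t i = 0; i < M.V.size(); ++i)
    if (distv[i] >= 0) f[i] = 1;
  return f;
}

// rim opening angle at boundary position bi (angle between edges to rim
// neighbours, measured through the empty sector for filled sectors >= 180deg)
static double rim_angle(const MeshState &M, int bi) {
  int n = M.B.size();
  int u = M.B[(bi - 1 + n) % n], v = M.B[bi], x = M.B[(bi + 1) % n];
  Vec3 a = sub(M.V[u], M.V[v]), b = sub(M.V[x], M.V[v]);
  double ca = dot(a, b) / (norm(a) * norm(b));
  ca = std::max(-1.0, std::min(1.0, ca));
  return std::acos(ca);
}

// place a trial vertex outside boundary edge (a -> b), tilted by theta0
static Vec3 trial_position(const MeshState &M, int bi, double l0,
                           double theta0,
                           const std::map<std::pair<int, int>, int> &downer) {
  int n = M.B.size();
  int a = M.B[bi], b = M.B[(bi + 1) % n];
  Vec3 m = scale(add(M.V[a], M.V[b]), 0.5);
  Vec3 d = sub(M.V[b], M.V[a]);
  double ld = norm(d);
  Vec3 dh = scale(d, 1.0 / ld);
  // owning triangle normal (triangle containing directed edge a->b)
  auto it = downer.find({a, b});
  Vec3 nrm{0, 0, 1};
  if (it != downer.end()) {
    int c = it->second;
    Vec3 nn = cross(sub(M.V[b], M.V[a]), sub(M.V[c], M.V[a]));
    double ln = norm(nn);
    if (ln > 1e-12) nrm = scale(nn, 1.0 / ln);
  }
  // in-plane outward direction = d x n (outside is right of the directed rim)
  Vec3 out = cross(dh, nrm);
  double h = std::sqrt(3.0) / 2.0 * l0;
  Vec3 off = add(scale(out, h * std::cos(theta0)), scale(nrm, -h * std::sin(theta0)));
  return add(m, off);
}

static std::map<std::pair<int, int>, int> directed_owner(const MeshState &M) {
  std::map<std::pair<int, int>, int> downer;
  for (const auto &t : M.T) {
    downer[{t[0], t[1]}] = t[2];
    downer[{t[1], t[2]}] = t[0];
    downer[{t[2], t[0]}] = t[1];
  }
  return downer;
}

// trial local energy after adding vertex w on boundary edge bi: the two new
// springs plus the hinge activated on the underlying edge, with w relaxed.
// Placement preference follows maximal contact: candidates are ranked first
// by the number of rim vertices the new monomer would touch (bonds that
// subsequent wedge closures materialise), then by local elastic energy.
static double trial_energy(const MeshState &M, int bi, const Vec3 &w0,
                           double ks, double kb, double l0, double theta0,
                           const std::map<std::pair<int, int>, int> &downer,
                           Vec3 *w_out) {
  int n = M.B.size();
  int a = M.B[bi], b = M.B[(bi + 1) % n];
  auto it = downer.find({a, b});
  int c = (it != downer.end()) ? it->second : -1;
  Vec3 w = w0;
  for (int iter = 0; iter < 12; ++iter) {
    // gradient wrt w only
    Vec3 g{0, 0, 0};
    for (int vi : {a, b}) {
      Vec3 d = sub(w, M.V[vi]);
      double l = norm(d);
      if (l > 1e-12) g = add(g, scale(d, ks * (l - l0) / l));
    }
    if (c >= 0) {
      // hinge p1=b, p2=a? directed edge of new triangle (b,a,w): edge b->a.
      // hinge as stored: p1,p2 along tri1 = existing (contains a->b), p3 = c,
      // p4 = w
      Hinge h{a, b, c, -1};
      Vec3 e = sub(M.V[b], M.V[a]);
      double le = norm(e);
      Vec3 n1 = cross(e, sub(M.V[c], M.V[a]));
      Vec3 n2 = cross(sub(w, M.V[a]), e);
      double n2sq = dot(n2, n2);
      if (le > 1e-12 && n2sq > 1e-24) {
        Vec3 eh = scale(e, 1.0 / le);
        double s = dot(cross(n1, n2), eh);
        double cth = dot(n1, n2);
        double th = std::atan2(s, cth);
        double dE = -kb * std::sin(th - theta0);
        g = add(g, scale(n2, dE * le / n2sq));
      }
      (void)h;
    }
    double gl = norm(g);
    if (gl < 1e-8) break;
    w = sub(w, scale(g, 0.25 / ks));
  }
  if (w_out) *w_out = w;
  double E = 0;
  for (int vi : {a, b}) {
    double l = norm(sub(w, M.V[vi]));
    E += 0.5 * ks * (l - l0) * (l - l0);
  }
  if (c >= 0) {
    Vec3 e = sub(M.V[b], M.V[a]);
    double le = norm(e);
    Vec3 n1 = cross(e, sub(M.V[c], M.V[a]));
    Vec3 n2 = cross(sub(w, M.V[a]), e);
    if (le > 1e-12) {
      Vec3 eh = scale(e, 1.0 / le);
      double th = std::atan2(dot(cross(n1, n2), eh), dot(n1, n2));
      E += kb * (1.0 - std::cos(th - theta0));
    }
  }
  return E;
}

static MeshState state_from_R(NumericMatrix V, IntegerMatrix T,
                              IntegerVector B) {
  MeshState M;
  M.V.resize(V.nrow());
  for (int i = 0; i < V.nrow(); ++i)
    M.V[i] = Vec3{V(i, 0), V(i, 1), V(i, 2)};
  M.T.resize(T.nrow());
  for (int i = 0; i < T.nrow(); ++i)
    M.T[i] = {T(i, 0) - 1, T(i, 1) - 1, T(i, 2) - 1};
  M.B.resize(B.size());
  for (int i = 0; i < B.size(); ++i) M.B[i] = B[i] - 1;
  M.rebuild();
  return M;
}

static List state_to_R(const MeshState &M, bool closed) {
  NumericMatrix V(M.V.size(), 3);
  for (size_t i = 0; i < M.V.size(); ++i)
    for (int k = 0; k < 3; ++k) V(i, k) = M.V[i][k];
  IntegerMatrix T(M.T.size(), 3);
  for (size_t i = 0; i < M.T.size(); ++i)
    for (int k = 0; k < 3; ++k) T(i, k) = M.T[i][k] + 1;
  IntegerVector B(M.B.size());
  for (size_t i = 0; i < M.B.size(); ++i) B[i] = M.B[i] + 1;
  return List::create(_["vertices"] = V, _["triangles"] = T,
                      _["boundary"] = B, _["closed"] = closed);
}

// [[Rcpp::export(name = ".cpp_shell_energy")]]
double cpp_shell_energy(NumericMatrix V, IntegerMatrix T, double ks, double kb,
                        double l0, double theta0) {
  MeshState M = state_from_R(V, T, IntegerVector(0));
  // degenerate triangle guard
  for (const auto &t : M.T) {
    Vec3 n = cross(sub(M.V[t[1]], M.V[t[0]]), sub(M.V[t[2]], M.V[t[0]]));
    if (norm(n) < 1e-12)
      stop("degenerate (zero-area) triangle in mesh");
  }
  return mesh_energy(M, ks, kb, l0, theta0);
}

// [[Rcpp::export(name = ".cpp_shell_gradient")]]
NumericMatrix cpp_shell_gradient(NumericMatrix V, IntegerMatrix T, double ks,
                                 double kb, double l0, double theta0) {
  MeshState M = state_from_R(V, T, IntegerVector(0));
  std::vector<Vec3> G(M.V.size());
  mesh_gradient(M, ks, kb, l0, theta0, all_free(M.V.size()), G);
  NumericMatrix out(M.V.size(), 3);
  for (size_t i = 0; i < M.V.size(); ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = G[i][k];
  return out;
}

// [[Rcpp::export(name = ".cpp_relax")]]
List cpp_relax(NumericMatrix V, IntegerMatrix T, IntegerVector B, double ks,
               double kb, double l0, double theta0, double tol, int maxit) {
  MeshState M = state_from_R(V, T, B);
  double gmax = 0;
  double E = relax_free(M, ks, kb, l0, theta0, all_free(M.V.size()), tol,
                        maxit, gmax);
  List out = state_to_R(M, M.B.empty());
  out["energy"] = E;
  out["gradMax"] = gmax;
  out["converged"] = (gmax <= tol);
  return out;
}

// wedge closures at the rim, smallest opening angle first. Two tiers:
// beta_bond (default 70 deg): rim monomers within binding range bond
// unconditionally (>= 3 incident triangles; completes hexamers);
// beta_pent (default 108 deg, the pentagon corner angle): a vertex with 4
// incident triangles closes into a pentamer, creating a 5-fold disclination.
static int do_merges(MeshState &M, double beta_bond, double beta_pent) {
  int added = 0;
  while ((int)M.B.size() > 3) {
    int n = M.B.size();
    int best = -1;
    double best_beta = R_PosInf;
    for (int bi = 0; bi < n; ++bi) {
      int v = M.B[bi];
      if (M.ntri[v] < 3) continue;
      int u = M.B[(bi - 1 + n) % n], x = M.B[(bi + 1) % n];
      if (u == x) continue;
      double beta = rim_angle(M, bi);
      bool eligible = (beta < beta_bond) ||
                      (M.ntri[v] == 4 && beta < beta_pent);
      if (eligible && beta < best_beta) {
        best_beta = beta;
        best = bi;
      }
    }
    if (best < 0) break;
    int v = M.B[best];
    int u = M.B[(best - 1 + n) % n], x = M.B[(best + 1) % n];
    M.T.push_back({x, v, u});
    M.B.erase(M.B.begin() + best);
    M.rebuild();
    added++;
  }
  return added;
}

// apply the merge at boundary position bi (close wedge at vertex B[bi])
static void apply_merge(MeshState &M, int bi) {
  int n = M.B.size();
  int u = M.B[(bi - 1 + n) % n], v = M.B[bi], x = M.B[(bi + 1) % n];
  M.T.push_back({x, v, u});
  M.B.erase(M.B.begin() + bi);
  M.rebuild();
}

// grow until closure or vertex budget; one triangle per outer iteration.
// New monomers are placed on the rim edge where they form the most bonds
// (ties broken by local elastic energy, weighted by e_bind per bond), or on
// a uniformly random rim edge with probability p_random.
// [[Rcpp::export(name = ".cpp_grow")]]
List cpp_grow(NumericMatrix V, IntegerMatrix T, IntegerVector B, double ks,
              double kb, double l0, double theta0, double p_random,
              double beta_bond, double beta_pent, double e_bind,
              int max_monomers, double tol, int step_maxit, int global_every,
              int global_maxit, int final_maxit, double seed_u,
              int max_steps) {
  MeshState M = state_from_R(V, T, B);
  SplitMix rng((uint64_t)seed_u);
  bool closed = M.B.empty();
  int steps = 0;
  while (!closed && (max_steps < 0 || steps < max_steps)) {
    do_merges(M, beta_bond, beta_pent);
    if ((int)M.B.size() == 3 && (int)M.V.size() > 3) {
      M.T.push_back({M.B[2], M.B[1], M.B[0]});
      M.B.clear();
      M.rebuild();
      closed = true;
      break;
    }
    if ((int)M.V.size() >= max_monomers) break;
    auto downer = directed_owner(M);
    int nB = M.B.size();
    int pick = -1;
    if (rng.unif() < p_random) {
      pick = rng.unif_int(nB); // random monomer placement
    } else {
      double best = R_PosInf;
      double cutoff = 1.35 * l0;
      for (int bi = 0; bi < nB; ++bi) {
        Vec3 w0 = trial_position(M, bi, l0, theta0, downer);
        Vec3 w;
        double dE = trial_energy(M, bi, w0, ks, kb, l0, theta0, downer, &w);
        int a = M.B[bi], b = M.B[(bi + 1) % nB];
        int bonds = 2;
        for (int rv : M.B) {
          if (rv == a || rv == b) continue;
          if (norm(sub(w, M.V[rv])) < cutoff) bonds++;
        }
        double score = dE - e_bind * bonds;
        if (score < best) {
          best = score;
          pick = bi;
        }
      }
    }
    if (pick < 0) break;
    int a = M.B[pick], b = M.B[(pick + 1) % nB];
    Vec3 w = trial_position(M, pick, l0, theta0, downer);
    int wi = M.V.size();
    M.V.push_back(w);
    M.T.push_back({b, a, wi});
    // rim: ... a -> w -> b ...
    M.B.insert(M.B.begin() + pick + 1, wi);
    M.rebuild();
    // local relaxation around the change, periodic global sweeps
    double gmax;
    std::vector<int> seeds{wi, a, b};
    relax_free(M, ks, kb, l0, theta0, local_free(M, seeds, 2), tol,
               step_maxit, gmax);
    if (global_every > 0 && (int)M.T.size() % global_every == 0)
      relax_free(M, ks, kb, l0, theta0, all_free(M.V.size()), tol,
                 global_maxit, gmax);
    steps++;
  }
  do_merges(M, beta_bond, beta_pent);
  if (!closed && (int)M.B.size() == 3 && (int)M.V.size() > 3) {
    M.T.push_back({M.B[2], M.B[1], M.B[0]});
    M.B.clear();
    M.rebuild();
    closed = true;
  }
  double gmax = 0;
  double E = relax_free(M, ks, kb, l0, theta0, all_free(M.V.size()), tol,
                        final_maxit, gmax);
  List out = state_to_R(M, closed);
  out["energy"] = E;
  out["gradMax"] = gmax;
  return out;
}
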