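#include "vtree.h"
#include <unordered_map>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Domain
// ---------------------------------------------------------------------------

bool Domain::contains(const Vec3 &p) const {
  if (!std::isfinite(p.x) || !std::isfinite(p.y) || !std::isfinite(p.z))
    return false;
  if (type == 0 || type == 2) {
    bool inbox = p.x >= lo.x && p.x <= hi.x && p.y >= lo.y && p.y <= hi.y &&
                 p.z >= lo.z && p.z <= hi.z;
    if (type == 0 || !inbox) return inbox;
  }
  // ray-crossing parity on the watertight surface; retry with a different
  // direction when a ray grazes an edge or runs parallel to a facet
  static const Vec3 dirs[8] = {
      {0.2357022603955158, 0.5345224838248488, 0.8116641997843462},
      {-0.577350, 0.577350, 0.577350},
      {0.801784, 0.267261, -0.534522},
      {-0.359211, -0.898027, 0.254558},
      {0.447214, -0.774597, 0.447214},
      {-0.218218, 0.436436, -0.872872},
      {0.688247, -0.229416, 0.688247},
      {-0.408248, -0.816497, 0.408248}};
  for (int attempt = 0; attempt < 8; ++attempt) {
    int crossings = 0;
    bool bad = false;
    for (size_t f = 0; f < faces.size(); ++f) {
      double t;
      bool grazing;
      bool hit = ray_triangle(p, dirs[attempt], verts[faces[f][0]],
                              verts[faces[f][1]], verts[faces[f][2]], t,
                              grazing);
      if (grazing) { bad = true; break; }
      if (hit) ++crossings;
    }
    if (!bad) return (crossings % 2) == 1;
  }
  return false; // pathological point exactly on the surface lattice
}

bool Domain::segment_inside(const Vec3 &a, const Vec3 &b, int npts) const {
  // endpoints plus npts equispaced interior points
  if (!contains(a) || !contains(b)) return false;
  for (int k = 1; k <= npts; ++k) {
    double t = (double)k / (npts + 1);
    if (!contains(vadd(a, vscale(vsub(b, a), t)))) return false;
  }
  return true;
}

Vec3 Domain::sample(Xoshiro256pp &rng, long max_draws) const {
  for (long k = 0; k < max_draws; ++k) {
    Vec3 p{lo.x + rng.runif() * (hi.x - lo.x),
           lo.y + rng.runif() * (hi.y - lo.y),
           lo.z + rng.runif() * (hi.z - lo.z)};
    if (type == 0) return p;
    if (contains(p)) return p;
  }
  stop("rejection sampling failed: degenerate domain (no interior point found)");
}

Domain domain_from_r(const List &dl) {
  Domain d;
  std::string type = as<std::string>(dl["type"]);
  if (type == "box") {
    d.type = 0;
    NumericVector lo = dl["lo"], hi = dl["hi"];
    d.lo = {lo[0], lo[1], lo[2]};
    d.hi = {hi[0], hi[1], hi[2]};
    d.volume = (hi[0] - lo[0]) * (hi[1] - lo[1]) * (hi[2] - lo[2]);
  } else if (type == "mesh" || type == "boxmesh") {
    d.type = (type == "mesh") ? 1 : 2;
    NumericMatrix V = dl["vertices"];
    IntegerMatrix F = dl["faces"];
    d.verts.resize(V.nrow());
    for (int i = 0; i < V.nrow(); ++i) d.verts[i] = {V(i, 0), V(i, 1), V(i, 2)};
    d.faces.resize(F.nrow());
    for (int i = 0; i < F.nrow(); ++i)
      d.faces[i] = {F(i, 0) - 1, F(i, 1) - 1, F(i, 2) - 1};
    if (d.type == 2) {
      // partition cell: the sampling/bounding box is the cell, not the mesh
      NumericVector lo = dl["lo"], hi = dl["hi"];
      d.lo = {lo[0], lo[1], lo[2]};
      d.hi = {hi[0], hi[1], hi[2]};
    } else {
      Vec3 lo{R_PosInf, R_PosInf, R_PosInf}, hi{R_NegInf, R_NegInf, R_NegInf};
      for (const Vec3 &v : d.verts) {
        lo.x = std::min(lo.x, v.x); lo.y = std::min(lo.y, v.y); lo.z = std::min(lo.z, v.z);
        hi.x = std::max(hi.x, v.x); hi.y = std::max(hi.y, v.y); hi.z = std::max(hi.z, v.z);
      }
      d.lo = lo; d.hi = hi;
    }
    d.volume = as<double>(dl["volume"]);
  } else {
    stop("unknown domain type");
  }
  return d;
}

// ---------------------------------------------------------------------------
// Tree conversion
// ---------------------------------------------------------------------------

Tree tree_from_r(const List &tl) {
  Tree T;
  IntegerVector id = tl["id"], parent = tl["parent"], c1 = tl["c1"],
                c2 = tl["c2"], nterm = tl["nterm"], stage = tl["stage_code"];
  NumericMatrix xp = tl["xp"], xd = tl["xd"];
  NumericVector r = tl["r"], beta = tl["beta"], Q = tl["Q"], mu = tl["mu"],
                qfix = tl["qfix"];
  int n = id.size();
  T.id.assign(id.begin(), id.end());
  T.nterm.assign(nterm.begin(), nterm.end());
  T.stage.assign(stage.begin(), stage.end());
  T.r.assign(r.begin(), r.end());
  T.beta.assign(beta.begin(), beta.end());
  T.Q.assign(Q.begin(), Q.end());
  T.mu.assign(mu.begin(), mu.end());
  T.qfix.assign(qfix.begin(), qfix.end());
  T.xp.resize(n); T.xd.resize(n);
  for (int i = 0; i < n; ++i) {
    T.xp[i] = {xp(i, 0), xp(i, 1), xp(i, 2)};
    T.xd[i] = {xd(i, 0), xd(i, 1), xd(i, 2)};
  }
  // map external ids to internal indices
  std::unordered_map<int, int> idx;
  idx.reserve(2 * n);
  for (int i = 0; i < n; ++i) idx[id[i]] = i;
  T.parent.resize(n); T.c1.resize(n); T.c2.resize(n);
  for (int i = 0; i < n; ++i) {
    T.parent[i] = (parent[i] == NA_INTEGER) ? NONE : idx.at(parent[i]);
    T.c1[i] = (c1[i] == NA_INTEGER) ? NONE : idx.at(c1[i]);
    T.c2[i] = (c2[i] == NA_INTEGER) ? NONE : idx.at(c2[i]);
  }
  int root_id = as<int>(tl["root"]);
  T.root = idx.at(root_id);
  T.gamma = as<double>(tl["gamma"]);
  T.Qin = as<double>(tl["Q_in"]);
  T.r0 = as<double>(tl["r0"]);
  T.next_id = as<int>(tl["next_id"]);
  T.allowed.assign(n, true);
  if (tl.containsElementNamed("allowed") && !Rf_isNull(tl["allowed"])) {
    LogicalVector al = tl["allowed"];
    for (int i = 0; i < n; ++i) T.allowed[i] = al[i];
  }
  return T;
}

List tree_to_r(const Tree &T) {
  int n = T.n();
  IntegerVector id(n), parent(n), c1(n), c2(n), nterm(n), stage(n);
  NumericMatrix xp(n, 3), xd(n, 3);
  NumericVector r(n), beta(n), Q(n), mu(n), qfix(n);
  LogicalVector allowed(n);
  for (int i = 0; i < n; ++i) {
    id[i] = T.id[i];
    parent[i] = T.parent[i] == NONE ? NA_INTEGER : T.id[T.parent[i]];
    c1[i] = T.c1[i] == NONE ? NA_INTEGER : T.id[T.c1[i]];
    c2[i] = T.c2[i] == NONE ? NA_INTEGER : T.id[T.c2[i]];
    nterm[i] = T.nterm[i];
    stage[i] = T.stage[i];
    xp(i, 0) = T.xp[i].x; xp(i, 1) = T.xp[i].y; xp(i, 2) = T.xp[i].z;
    xd(i, 0) = T.xd[i].x; xd(i, 1) = T.xd[i].y; xd(i, 2) = T.xd[i].z;
    r[i] = T.r[i]; beta[i] = T.beta[i]; Q[i] = T.Q[i]; mu[i] = T.mu[i];
    qfix[i] = T.qfix[i];
    allowed[i] = T.allowed[i];
  }
  return List::create(
      _["id"] = id, _["parent"] = parent, _["c1"] = c1, _["c2"] = c2,
      _["xp"] = xp, _["xd"] = xd, _["r"] = r, _["beta"] = beta, _["Q"] = Q,
      _["mu"] = mu, _["qfix"] = qfix, _["nterm"] = nterm,
      _["stage_code"] = stage, _["allowed"] = allowed,
      _["root"] = T.id[T.root], _["gamma"] = T.gamma, _["Q_in"] = T.Qin,
      _["r0"] = T.r0, _["next_id"] = T.next_id);
}

ViscosityCfg visc_from_r(const List &vl) {
  ViscosityCfg v;
  std::string kind = as<std::string>(vl["kind"]);
  v.kind = (kind == "constant") ? 0 : 1;
  if (vl.containsElementNamed("mu_const_cP"))
    v.mu_const_cP = as<double>(vl["mu_const_cP"]);
  if (vl.containsElementNamed("mu_plasma_cP"))
    v.mu_plasma_cP = as<double>(vl["mu_plasma_cP"]);
  if (vl.containsElementNamed("hd")) v.hd = as<double>(vl["hd"]);
  return v;
}

StageCfg stage_from_r(const List &sl) {
  StageCfg c;
  c.gamma = as<double>(sl["gamma"]);
  c.delta = as<double>(sl["delta"]);
  c.fr = as<double>(sl["f_r"]);
  c.fn = as<double>(sl["f_n"]);
  c.nbif = as<int>(sl["n_bif"]);
  c.theta_min_deg = as<double>(sl["theta_min"]);
  c.phi_min_deg = as<double>(sl["phi_min"]);
  c.kd = as<double>(sl["k_d"]);
  c.relax_floor = as<double>(sl["relax_floor"]);
  c.insample = as<int>(sl["in_sample"]);
  c.incheck_all = as<std::string>(sl["in_check"]) == "all" ? 1 : 0;
  List cf = sl["cost"];
  std::string ck = as<std::string>(cf["kind"]);
  c.ckind = (ck == "volumetric") ? 0 : 1;
  c.cv = as<double>(cf["c_v"]);
  c.cp = as<double>(cf["c_p"]);
  c.cd = as<double>(cf["c_d"]);
  c.Vref = as<double>(cf["V_ref"]);
  c.lref = as<double>(cf["l_ref"]);
  c.rref = as<double>(cf["r_ref"]);
  c.visc = visc_from_r(sl["viscosity"]);
  return c;
}

// ---------------------------------------------------------------------------
// Core tree operations
// ---------------------------------------------------------------------------

std::vector<int> topo_order(const Tree &T) {
  std::vector<int> order;
  order.reserve(T.n());
  std::vector<int> stack{T.root};
  while (!stack.empty()) {
    int i = stack.back();
    stack.pop_back();
    order.push_back(i);
    if (T.c1[i] != NONE) stack.push_back(T.c1[i]);
    if (T.c2[i] != NONE) stack.push_back(T.c2[i]);
  }
  return order;
}

void assign_flows(Tree &T) {
  std::vector<int> order = topo_order(T);
  // terminal outflow: frozen values kept, remainder split among free terminals
  double frozen_sum = 0.0;
  int nfree = 0;
  for (int i : order) {
    if (!T.is_terminal(i)) continue;
    if (std::isnan(T.qfix[i])) ++nfree;
    else frozen_sum += T.qfix[i];
  }
  double qfree = 0.0;
  if (nfree > 0) {
    double Qpart = T.Qin - frozen_sum;
    if (Qpart <= 0.0)
      stop("remaining flow Q_part is non-positive (frozen outflows exceed Q_in)");
    qfree = Qpart / nfree;
  }
  for (auto it = order.rbegin(); it != order.rend(); ++it) {
    int i = *it;
    if (T.is_terminal(i)) {
      T.Q[i] = std::isnan(T.qfix[i]) ? qfree : T.qfix[i];
      T.nterm[i] = 1;
    } else {
      T.Q[i] = T.Q[T.c1[i]] + T.Q[T.c2[i]];
      T.nterm[i] = T.nterm[T.c1[i]] + T.nterm[T.c2[i]];
    }
  }
}

// Reduced-resistance radius rescaling under the branching power law with the
// equal-terminal-pressure closure: post-order pass computes each subtree's
// resistance at unit subtree-root radius and the daughter beta factors, then
// a pre-order pass propagates absolute radii from the fixed root radius.
void rescale_radii(Tree &T) {
  std::vector<int> order = topo_order(T);
  std::vector<double> Rstar(T.n());
  double g = T.gamma;
  for (auto it = order.rbegin(); it != order.rend(); ++it) {
    int i = *it;
    double l = T.len(i);
    if (l <= 0.0) stop("zero-length vessel in rescale_radii");
    double lu = 8.0 * T.mu[i] * l / M_PI; // Poiseuille resistance at r = 1
    if (T.is_terminal(i)) {
      Rstar[i] = lu;
    } else {
      int a = T.c1[i], b = T.c2[i];
      // (r_a / r_b)^4 = (Q_a R*_a) / (Q_b R*_b)  => equal pressure drops
      double xi4 = (T.Q[b] * Rstar[b]) / (T.Q[a] * Rstar[a]);
      double xi = std::sqrt(std::sqrt(xi4));
      double bl, br;
      if (g == 3.0) { // the common branching exponent, on the hot path
        double xig = xi * xi * xi;
        bl = 1.0 / std::cbrt(1.0 + xig);
        br = 1.0 / std::cbrt(1.0 + 1.0 / xig);
      } else {
        bl = std::pow(1.0 + std::pow(xi, g), -1.0 / g);
        br = std::pow(1.0 + std::pow(xi, -g), -1.0 / g);
      }
      T.beta[a] = bl;
      T.beta[b] = br;
      double bl2 = bl * bl, br2 = br * br;
      Rstar[i] = lu + 1.0 / (bl2 * bl2 / Rstar[a] + br2 * br2 / Rstar[b]);
    }
    if (!std::isfinite(Rstar[i])) stop("non-finite reduced resistance");
  }
  T.beta[T.root] = 1.0;
  for (int i : order) {
    T.r[i] = (T.parent[i] == NONE) ? T.r0 : T.beta[i] * T.r[T.parent[i]];
  }
}

// Pries et al. in-vitro relative viscosity (diameter d in micrometres),
// scaled by plasma viscosity; the constant model ignores d.
double viscosity_cP(double d_um, const ViscosityCfg &v) {
  if (d_um <= 0.0) stop("viscosity requires a positive diameter");
  if (v.kind == 0) return v.mu_const_cP;
  double d = d_um;
  double eta45 = 220.0 * std::exp(-1.3 * d) + 3.2 -
                 2.44 * std::exp(-0.06 * std::pow(d, 0.645));
  double dd = std::pow(d, 12);
  double frac = 1.0 / (1.0 + 1e-11 * dd);
  double C = (0.8 + std::exp(-0.075 * d)) * (-1.0 + frac) + frac;
  double num = std::pow(1.0 - v.hd, C) - 1.0;
  double den = std::pow(1.0 - 0.45, C) - 1.0;
  double eta_rel = 1.0 + (eta45 - 1.0) * num / den;
  return v.mu_plasma_cP * eta_rel;
}

void update_viscosities(Tree &T, const ViscosityCfg &v) {
  for (int i = 0; i < T.n(); ++i)
    T.mu[i] = 0.01 * viscosity_cP(2.0 * T.r[i] * 1e4, v); // cP -> poise
}

int fixed_point(Tree &T, const ViscosityCfg &v, double tol, int max_iter,
                std::vector<double> &residuals) {
  residuals.clear();
  if (v.kind == 0) {
    update_viscosities(T, v);
    rescale_radii(T);
    residuals.push_back(0.0);
    return 1;
  }
  std::vector<double> rprev;
  for (int it = 1; it <= max_iter; ++it) {
    rprev = T.r;
    update_viscosities(T, v);
    rescale_radii(T);
    double res = 0.0;
    for (int i = 0; i < T.n(); ++i)
      res = std::max(res, std::fabs(T.r[i] - rprev[i]) / T.r[i]);
    residuals.push_back(res);
    if (res < tol) return it;
  }
  return -1; // signalled as an R error by the caller
}

double vessel_cost(double l, double r, const StageCfg &cfg) {
  if (cfg.ckind == 0) return M_PI * l * r * r;
  double g = cfg.gamma;
  return cfg.cv * M_PI * l * std::pow(r, g - 1.0) / std::pow(cfg.Vref, g / 3.0) +
         cfg.cp * r / cfg.rref + cfg.cd * (l / cfg.lref) * (l / cfg.lref);
}

double tree_cost_cpp(const Tree &T, const StageCfg &cfg) {
  double s = 0.0;
  for (int i = 0; i < T.n(); ++i) s += vessel_cost(T.len(i), T.r[i], cfg);
  return s;
}

// Split vessel pidx at xbif and hang a new terminal towards xnew.  The old
// id is retired; the proximal stub, the distal sibling (which inherits the
// children) and the terminal all get fresh consecutive ids.
// Returns the internal index of the new terminal.
int add_terminal_internal(Tree &T, int pidx, const Vec3 &xbif, const Vec3 &xnew,
                          int stage_code, int *out_ids) {
  int n = T.n();
  int stub = pidx; // reuse the slot for the proximal stub, but retire the id
  int sib = n, terml = n + 1;
  // grow arrays by two
  auto push = [&](int src) {
    T.id.push_back(0);
    T.parent.push_back(NONE);
    T.c1.push_back(NONE);
    T.c2.push_back(NONE);
    T.xp.push_back(T.xp[src]);
    T.xd.push_back(T.xd[src]);
    T.r.push_back(T.r[src]);
    T.beta.push_back(1.0);
    T.Q.push_back(T.Q[src]);
    T.mu.push_back(T.mu[src]);
    T.qfix.push_back(T.qfix[src]);
    T.nterm.push_back(1);
    T.stage.push_back(stage_code);
    T.allowed.push_back(T.allowed[src]);
  };
  push(pidx); // sibling template
  push(pidx); // terminal template
  // sibling: xbif -> old distal, inherits children and frozen outflow
  T.xp[sib] = xbif;
  T.xd[sib] = T.xd[pidx];
  T.c1[sib] = T.c1[pidx];
  T.c2[sib] = T.c2[pidx];
  T.parent[sib] = stub;
  if (T.c1[sib] != NONE) T.parent[T.c1[sib]] = sib;
  if (T.c2[sib] != NONE) T.parent[T.c2[sib]] = sib;
  T.nterm[sib] = T.nterm[pidx];
  // terminal: xbif -> xnew, free outflow
  T.xp[terml] = xbif;
  T.xd[terml] = xnew;
  T.parent[terml] = stub;
  T.c1[terml] = T.c2[terml] = NONE;
  T.qfix[terml] = std::numeric_limits<double>::quiet_NaN();
  T.nterm[terml] = 1;
  // stub: old proximal -> xbif; internal, so no frozen outflow
  T.xd[stub] = xbif;
  T.c1[stub] = sib;
  T.c2[stub] = terml;
  T.qfix[stub] = std::numeric_limits<double>::quiet_NaN();
  // fresh ids: stub, sibling, terminal
  T.id[stub] = T.next_id;
  T.id[sib] = T.next_id + 1;
  T.id[terml] = T.next_id + 2;
  T.next_id += 3;
  if (out_ids) {
    out_ids[0] = T.id[stub];
    out_ids[1] = T.id[sib];
    out_ids[2] = T.id[terml];
  }
  // subtended counts: +1 along the path from the stub to the root
  for (int a = stub; a != NONE; a = T.parent[a]) T.nterm[a] += 1;
  return terml;
}

// ---------------------------------------------------------------------------
// Rcpp interface
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_mesh_contains(NumericMatrix V, IntegerMatrix F,
                                NumericMatrix P) {
  List dl = List::create(_["type"] = "mesh", _["vertices"] = V,
                         _["faces"] = F, _["volume"] = 1.0);
  Domain d = domain_from_r(dl);
  LogicalVector out(P.nrow());
  for (int i = 0; i < P.nrow(); ++i)
    out[i] = d.contains({P(i, 0), P(i, 1), P(i, 2)});
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_points(List domain, int n, double seed,
                                double stream) {
  Domain d = domain_from_r(domain);
  Xoshiro256pp rng((uint64_t)seed, (uint64_t)stream);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    Vec3 p = d.sample(rng);
    out(i, 0) = p.x; out(i, 1) = p.y; out(i, 2) = p.z;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_assign_flows(List tree) {
  Tree T = tree_from_r(tree);
  assign_flows(T);
  return tree_to_r(T);
}

// [[Rcpp::export]]
List cpp_rescale(List tree) {
  Tree T = tree_from_r(tree);
  assign_flows(T);
  rescale_radii(T);
  return tree_to_r(T);
}

// [[Rcpp::export]]
NumericVector cpp_viscosity(NumericVector d_um, List model) {
  ViscosityCfg v = visc_from_r(model);
  NumericVector out(d_um.size());
  for (int i = 0; i < d_um.size(); ++i) out[i] = viscosity_cP(d_um[i], v);
  return out;
}

// [[Rcpp::export]]
List cpp_fixed_point(List tree, List model, double tol, int max_iter) {
  Tree T = tree_from_r(tree);
  ViscosityCfg v = visc_from_r(model);
  assign_flows(T);
  std::vector<double> res;
  int it = fixed_point(T, v, tol, max_iter, res);
  return List::create(_["tree"] = tree_to_r(T), _["iterations"] = it,
                      _["residuals"] = NumericVector(res.begin(), res.end()));
}

// [[Rcpp::export]]
List cpp_solve_pressures(List tree) {
  Tree T = tree_from_r(tree);
  int n = T.n();
  NumericVector pp(n), pd(n), Rv(n);
  std::vector<int> order = topo_order(T);
  std::vector<double> pprox(n), pdist(n), res(n);
  for (int i : order) {
    double R = 8.0 * T.mu[i] * T.len(i) / (M_PI * std::pow(T.r[i], 4));
    res[i] = R;
    pprox[i] = (T.parent[i] == NONE) ? 0.0 : pdist[T.parent[i]];
    pdist[i] = pprox[i] - T.Q[i] * R;
  }
  for (int i = 0; i < n; ++i) {
    pp[i] = pprox[i] * DYNCM2_TO_MMHG;
    pd[i] = pdist[i] * DYNCM2_TO_MMHG;
    Rv[i] = res[i] * DYNCM2_TO_MMHG; // dyn s/cm^5 -> mmHg s/cm^3
  }
  return List::create(_["p_prox"] = pp, _["p_dist"] = pd, _["resistance"] = Rv);
}

// [[Rcpp::export]]
IntegerVector cpp_generations(List tree) {
  Tree T = tree_from_r(tree);
  std::vector<int> order = topo_order(T);
  std::vector<int> gen(T.n(), 0);
  for (int i : order)
    gen[i] = (T.parent[i] == NONE) ? 0 : gen[T.parent[i]] + 1;
  return IntegerVector(gen.begin(), gen.end());
}

// [[Rcpp::export]]
List cpp_add_terminal(List tree, int parent_id, NumericVector xbif,
                      NumericVector xnew, int stage_code) {
  Tree T = tree_from_r(tree);
  int pidx = NONE;
  for (int i = 0; i < T.n(); ++i)
    if (T.id[i] == parent_id) { pidx = i; break; }
  if (pidx == NONE) stop("unknown parent vessel id");
  Vec3 b{xbif[0], xbif[1], xbif[2]}, x{xnew[0], xnew[1], xnew[2]};
  if (vnorm(vsub(b, T.xp[pidx])) == 0.0 || vnorm(vsub(b, T.xd[pidx])) == 0.0)
    stop("bifurcation point coincides with a parent endpoint");
  if (vnorm(vsub(x, b)) == 0.0) stop("new distal point equals the bifurcation");
  int ids[3];
  add_terminal_internal(T, pidx, b, x, stage_code, ids);
  return List::create(_["tree"] = tree_to_r(T), _["stub_id"] = ids[0],
                      _["sibling_id"] = ids[1], _["terminal_id"] = ids[2]);
}

// [[Rcpp::export]]
double cpp_tree_cost(List tree, List stage) {
  Tree T = tree_from_r(tree);
  StageCfg cfg = stage_from_r(stage);
  return tree_cost_cpp(T, cfg);
}

// ---------------------------------------------------------------------------
// merge: replay insertion records against the baseline tree
// ---------------------------------------------------------------------------

// Records are replayed in listed order (subdomain lists in index order); the
// parent of each record is resolved through a lookup table keyed by the exact
// full-precision (x_p, x_d) coordinates, maintained under splits.  Radii are
// NOT rescaled during replay; the caller runs one global fixed-point pass
// after all insertions.

// [[Rcpp::export]]
List cpp_merge(List tree, List record_lists, IntegerVector stage_codes) {
  Tree T = tree_from_r(tree);
  typedef std::array<double, 6> Key;
  std::map<Key, int> lut; // coordinate key -> internal index
  auto key_of = [&](const Vec3 &a, const Vec3 &b) {
    return Key{a.x, a.y, a.z, b.x, b.y, b.z};
  };
  for (int i = 0; i < T.n(); ++i) lut[key_of(T.xp[i], T.xd[i])] = i;
  for (int li = 0; li < record_lists.size(); ++li) {
    NumericMatrix L = record_lists[li];
    int scode = stage_codes[li];
    for (int k = 0; k < L.nrow(); ++k) {
      Vec3 xnew{L(k, 0), L(k, 1), L(k, 2)};
      Vec3 xbif{L(k, 3), L(k, 4), L(k, 5)};
      Vec3 pxp{L(k, 6), L(k, 7), L(k, 8)};
      Vec3 pxd{L(k, 9), L(k, 10), L(k, 11)};
      auto it = lut.find(key_of(pxp, pxd));
      if (it == lut.end())
        stop("corrupted record: no vessel matches the parent coordinates of "
             "record %d in list %d",
             k + 1, li + 1);
      int pidx = it->second;
      lut.erase(it); // the parent segment is split and its key retired
      int terml = add_terminal_internal(T, pidx, xbif, xnew, scode, nullptr);
      int stub = T.parent[terml];
      int sib = (T.c1[stub] == terml) ? T.c2[stub] : T.c1[stub];
      lut[key_of(T.xp[stub], T.xd[stub])] = stub;
      lut[key_of(T.xp[sib], T.xd[sib])] = sib;
      lut[key_of(T.xp[terml], T.xd[terml])] = terml;
    }
  }
  return tree_to_r(T);
}
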