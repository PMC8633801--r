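#ifndef VASCTREE_VTREE_H
#define VASCTREE_VTREE_H

#include <Rcpp.h>
#include <vector>
#include <array>
#include <string>
#include <cmath>
#include <limits>
#include "geom.h"
#include "rng.h"

// ---------------------------------------------------------------------------
// internal index-based tree representation
// ---------------------------------------------------------------------------
// All quantities in CGS units: cm, cm3/s, poise.  Pressures are converted to
// mmHg only at the reporting boundary (1 dyn/cm2 = 7.50062e-4 mmHg).

constexpr double DYNCM2_TO_MMHG = 7.50062e-4;
constexpr int NONE = -1;

struct Tree {
  std::vector<int> id;      // stable external ids (never reused)
  std::vector<int> parent;  // internal indices, NONE for root
  std::vector<int> c1, c2;  // internal indices, NONE if absent
  std::vector<Vec3> xp, xd; // proximal / distal coordinates (cm)
  std::vector<double> r;    // radius (cm)
  std::vector<double> beta; // radius ratio to parent (root: 1)
  std::vector<double> Q;    // flow (cm3/s)
  std::vector<double> mu;   // effective viscosity (poise)
  std::vector<double> qfix; // fixed terminal outflow, NaN if free
  std::vector<int> nterm;   // subtended terminal count
  std::vector<int> stage;   // stage tag code (managed by the R layer)
  std::vector<bool> allowed; // eligible as parent during current growth

  int root = 0;      // internal index of root
  double gamma = 3.0;
  double Qin = 1.0;
  double r0 = 0.1;
  int next_id = 1;

  int n() const { return (int)id.size(); }
  bool is_terminal(int i) const { return c1[i] == NONE && c2[i] == NONE; }
  double len(int i) const { return vnorm(vsub(xd[i], xp[i])); }
};

struct Domain {
  int type = 0; // 0 = box, 1 = mesh
  Vec3 lo{0, 0, 0}, hi{1, 1, 1};          // bounding box (exact for boxes)
  std::vector<Vec3> verts;                 // mesh vertices
  std::vector<std::array<int, 3>> faces;   // mesh triangles (0-based)
  double volume = 1.0;
  bool contains(const Vec3 &p) const;
  bool segment_inside(const Vec3 &a, const Vec3 &b, int npts) const;
  Vec3 sample(Xoshiro256pp &rng, long max_draws = 1000000L) const;
};

struct ViscosityCfg {
  int kind = 0;              // 0 = constant, 1 = diameter-dependent (in vitro)
  double mu_const_cP = 3.6;  // constant model value
  double mu_plasma_cP = 1.2; // plasma viscosity for the relative-viscosity law
  double hd = 0.45;          // discharge haematocrit
};

struct StageCfg {
  double gamma = 3.0;
  double delta = 0.0;        // daughter radius-symmetry lower bound
  double fr = 0.9;           // distance-criterion relaxation factor
  double fn = 1.0;           // neighbourhood multiplier on N_term^{1/3}
  int nbif = 7;              // trial bifurcation points in the triangle
  double theta_min_deg = 0.0;
  double phi_min_deg = 0.0;
  double kd = 0.25;          // d_crit prefactor
  double relax_floor = 1e-3; // growth aborts below this relaxation
  int insample = 5;          // interior points per segment for inside test
  int incheck_all = 1;       // 0: only the new terminal segment must lie
                             // inside (multi-inlet setups where the parent
                             // network legitimately crosses the boundary)
  // cost functional
  int ckind = 0;             // 0 = volumetric, 1 = sprouting
  double cv = 1.0, cp = 0.0, cd = 0.0;
  double Vref = 1.0, lref = 1.0, rref = 1.0;
  ViscosityCfg visc;
};

// core tree operations (engine.cpp)
Tree tree_from_r(const Rcpp::List &tl);
Rcpp::List tree_to_r(const Tree &T);
Domain domain_from_r(const Rcpp::List &dl);
ViscosityCfg visc_from_r(const Rcpp::List &vl);
StageCfg stage_from_r(const Rcpp::List &sl);

std::vector<int> topo_order(const Tree &T); // parents before children
void assign_flows(Tree &T);
void rescale_radii(Tree &T);
double viscosity_cP(double d_um, const ViscosityCfg &v);
void update_viscosities(Tree &T, const ViscosityCfg &v);
int fixed_point(Tree &T, const ViscosityCfg &v, double tol, int max_iter,
                std::vector<double> &residuals);
double vessel_cost(double l, double r, const StageCfg &cfg);
double tree_cost_cpp(const Tree &T, const StageCfg &cfg);
int add_terminal_internal(Tree &T, int pidx, const Vec3 &xbif,
                          const Vec3 &xnew, int stage_code,
                          int *out_ids /* stub, sibling, terminal */);

// growth (growth.cpp)
struct InsRecord {
  Vec3 xnew, xbif, pxp, pxd;
};
struct BestInsertion {
  bool found = false;
  int parent_idx = NONE;
  int cand_idx = NONE;
  Vec3 xbif{0, 0, 0};
  double dF = std::numeric_limits<double>::infinity();
};

std::vector<Vec3> candidate_points(const Vec3 &a, const Vec3 &b, const Vec3 &c,
                                   int nbif);
std::vector<int> neighbourhood_cpp(const Tree &T, const Vec3 &x, double fn,
                                   bool restrict_allowed);
BestInsertion try_insert_cpp(const Tree &T, const Vec3 &xnew,
                             const StageCfg &cfg, const Domain &dom,
                             int valid_count_out[1]);
void grow_cpp(Tree &T, const Domain &dom, const Domain &sampledom,
              const StageCfg &cfg, int N, uint64_t seed, uint64_t stream,
              int stage_code, std::vector<InsRecord> *records);

#endif
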