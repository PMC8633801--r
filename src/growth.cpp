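#include "vtree.h"
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// candidate bifurcation points: deterministic barycentric lattice strictly
// inside the triangle, ordered by distance to the centroid so that n_bif = 1
// yields the centroid itself
// ---------------------------------------------------------------------------

std::vector<Vec3> candidate_points(const Vec3 &a, const Vec3 &b, const Vec3 &c,
                                   int nbif) {
  std::vector<Vec3> out;
  // degenerate (collinear) triangle -> no candidates
  Vec3 n = vcross(vsub(b, a), vsub(c, a));
  double area2 = vnorm(n);
  double scale = vnorm(vsub(b, a)) * vnorm(vsub(c, a));
  if (scale <= 0.0 || area2 < 1e-12 * scale) return out;
  // smallest lattice refinement m with C(m-1, 2) interior points >= nbif
  int m = 3;
  while ((m - 1) * (m - 2) / 2 < nbif) ++m;
  struct BPt {
    int i, j, k;
    double d2; // squared barycentric distance to the centroid
  };
  std::vector<BPt> pts;
  for (int i = 1; i <= m - 2; ++i)
    for (int j = 1; j <= m - 1 - i; ++j) {
      int k = m - i - j;
      double u = (double)i / m, v = (double)j / m, w = (double)k / m;
      double d2 = (u - 1.0 / 3) * (u - 1.0 / 3) + (v - 1.0 / 3) * (v - 1.0 / 3) +
                  (w - 1.0 / 3) * (w - 1.0 / 3);
      pts.push_back({i, j, k, d2});
    }
  std::sort(pts.begin(), pts.end(), [](const BPt &p, const BPt &q) {
    if (p.d2 != q.d2) return p.d2 < q.d2;
    if (p.i != q.i) return p.i < q.i;
    return p.j < q.j;
  });
  for (int t = 0; t < nbif && t < (int)pts.size(); ++t) {
    double u = (double)pts[t].i / m, v = (double)pts[t].j / m,
           w = (double)pts[t].k / m;
    out.push_back(vadd(vadd(vscale(a, u), vscale(b, v)), vscale(c, w)));
  }
  return out;
}

// ---------------------------------------------------------------------------
// neighbourhood: the max(1, round(f_n * N_term^{1/3})) vessels closest to x
// by point-to-segment distance, among allowed parents; ties broken by id
// ---------------------------------------------------------------------------

std::vector<int> neighbourhood_cpp(const Tree &T, const Vec3 &x, double fn,
                                   bool restrict_allowed) {
  int nterm = 0;
  for (int i = 0; i < T.n(); ++i)
    if (T.is_terminal(i)) ++nterm;
  int k = std::max(1, (int)std::lround(fn * std::cbrt((double)nterm)));
  struct ND {
    double d;
    int id, idx;
  };
  std::vector<ND> ds;
  ds.reserve(T.n());
  for (int i = 0; i < T.n(); ++i) {
    if (restrict_allowed && !T.allowed[i]) continue;
    ds.push_back({point_seg_dist(x, T.xp[i], T.xd[i]), T.id[i], i});
  }
  if (ds.empty()) stop("empty allowed parent set in neighbourhood search");
  auto cmp = [](const ND &a, const ND &b) {
    if (a.d != b.d) return a.d < b.d;
    return a.id < b.id;
  };
  if ((int)ds.size() > k) {
    std::partial_sort(ds.begin(), ds.begin() + k, ds.end(), cmp);
    ds.resize(k);
  } else {
    std::sort(ds.begin(), ds.end(), cmp);
  }
  std::vector<int> out;
  out.reserve(ds.size());
  for (const ND &e : ds) out.push_back(e.idx);
  return out;
}

// ---------------------------------------------------------------------------
// validity + cost of one provisional connection
// ---------------------------------------------------------------------------

static inline double angle_deg(const Vec3 &u, const Vec3 &v) {
  double c = vdot(u, v) / (vnorm(u) * vnorm(v));
  c = std::max(-1.0, std::min(1.0, c));
  return std::acos(c) * 180.0 / M_PI;
}

// geometric prechecks that do not need the rescaled radii
static int precheck_connection(const Tree &T, int pidx, const Vec3 &xbif,
                               const Vec3 &xnew, const StageCfg &cfg,
                               const Domain &dom) {
  const Vec3 &xpp = T.xp[pidx], &xpd = T.xd[pidx];
  double l_stub = vnorm(vsub(xbif, xpp));
  double l_sib = vnorm(vsub(xpd, xbif));
  double l_new = vnorm(vsub(xnew, xbif));
  if (l_stub <= 0.0 || l_sib <= 0.0 || l_new <= 0.0) return 1; // degenerate
  // daughters' opening angle and deviations from the parent direction
  Vec3 dsib = vsub(xpd, xbif), dnew = vsub(xnew, xbif), dpar = vsub(xbif, xpp);
  if (angle_deg(dsib, dnew) < cfg.theta_min_deg) return 2;
  if (cfg.phi_min_deg > 0.0 &&
      (angle_deg(dpar, dsib) < cfg.phi_min_deg ||
       angle_deg(dpar, dnew) < cfg.phi_min_deg))
    return 3;
  // provisional segments must lie inside the domain (all three, or just the
  // new terminal when the initial network legitimately crosses the boundary)
  if (!dom.segment_inside(xbif, xnew, cfg.insample)) return 4;
  if (cfg.incheck_all &&
      (!dom.segment_inside(xpp, xbif, cfg.insample) ||
       !dom.segment_inside(xbif, T.xd[pidx], cfg.insample)))
    return 4;
  return 0;
}

static inline bool veq(const Vec3 &a, const Vec3 &b) {
  return a.x == b.x && a.y == b.y && a.z == b.z;
}

// vessels are adjacent when they share a junction coordinate exactly
// (splits carry coordinates through bitwise, so exact comparison is sound)
static inline bool shares_endpoint(const Tree &S, int u, int v) {
  return veq(S.xp[u], S.xp[v]) || veq(S.xp[u], S.xd[v]) ||
         veq(S.xd[u], S.xp[v]) || veq(S.xd[u], S.xd[v]);
}

// checks on the rescaled provisional tree; S = scratch tree after insertion,
// terml = internal index of the new terminal
static int postcheck_connection(const Tree &S, int terml,
                                const StageCfg &cfg) {
  int stub = S.parent[terml];
  int sib = (S.c1[stub] == terml) ? S.c2[stub] : S.c1[stub];
  // daughter radius symmetry at the new bifurcation
  double rl = S.r[sib], rr = S.r[terml];
  if (std::min(rl, rr) / std::max(rl, rr) < cfg.delta) return 5;
  // aspect sanity: the three modified segments must not be stubbier than 2r
  if (S.len(stub) < 2.0 * S.r[stub] || S.len(sib) < 2.0 * S.r[sib] ||
      S.len(terml) < 2.0 * S.r[terml])
    return 6;
  // no intersection: each provisional segment (the new terminal and the two
  // pieces of the bent parent corridor) must clear every vessel it does not
  // meet at a junction by at least the sum of radii
  const int trio[3] = {terml, stub, sib};
  for (int i = 0; i < S.n(); ++i) {
    if (i == terml || i == stub || i == sib) continue;
    for (int u : trio) {
      if (shares_endpoint(S, u, i)) continue;
      double d = seg_seg_dist(S.xp[u], S.xd[u], S.xp[i], S.xd[i]);
      if (d < S.r[u] + S.r[i]) return 7;
    }
  }
  return 0;
}

// Evaluate one candidate: returns reason code (0 = valid) and fills dF.
static int eval_candidate(const Tree &T, Tree &scratch, int pidx,
                          const Vec3 &xbif, const Vec3 &xnew,
                          const StageCfg &cfg, const Domain &dom,
                          double cost_before, double &dF) {
  int rc = precheck_connection(T, pidx, xbif, xnew, cfg, dom);
  if (rc != 0) return rc;
  scratch = T;
  int terml = add_terminal_internal(scratch, pidx, xbif, xnew,
                                    scratch.stage[pidx], nullptr);
  // new segments start from the split vessel's current viscosity; the
  // diameter-dependent update happens in the fixed-point pass after commit
  assign_flows(scratch);
  rescale_radii(scratch);
  rc = postcheck_connection(scratch, terml, cfg);
  if (rc != 0) return rc;
  dF = tree_cost_cpp(scratch, cfg) - cost_before;
  return 0;
}

BestInsertion try_insert_cpp(const Tree &T, const Vec3 &xnew,
                             const StageCfg &cfg, const Domain &dom,
                             int valid_count_out[1]) {
  BestInsertion best;
  Tree scratch;
  double cost_before = tree_cost_cpp(T, cfg);
  std::vector<int> nb = neighbourhood_cpp(T, xnew, cfg.fn, true);
  int nvalid = 0;
  for (int pidx : nb) {
    std::vector<Vec3> cands =
        candidate_points(T.xp[pidx], T.xd[pidx], xnew, cfg.nbif);
    for (int ci = 0; ci < (int)cands.size(); ++ci) {
      double dF;
      int rc = eval_candidate(T, scratch, pidx, cands[ci], xnew, cfg, dom,
                              cost_before, dF);
      if (rc != 0) continue;
      ++nvalid;
      bool take = false;
      if (dF < best.dF) {
        take = true;
      } else if (dF == best.dF && best.found) {
        // deterministic tie-break on (parent id, candidate index)
        int pid = T.id[pidx], bpid = T.id[best.parent_idx];
        take = (pid < bpid) || (pid == bpid && ci < best.cand_idx);
      }
      if (take) {
        best.found = true;
        best.parent_idx = pidx;
        best.cand_idx = ci;
        best.xbif = cands[ci];
        best.dF = dF;
      }
    }
  }
  if (valid_count_out) valid_count_out[0] = nvalid;
  return best;
}

// ---------------------------------------------------------------------------
// sequential growth loop
// ---------------------------------------------------------------------------

void grow_cpp(Tree &T, const Domain &dom, const Domain &sampledom,
              const StageCfg &cfg, int N, uint64_t seed, uint64_t stream,
              int stage_code, std::vector<InsRecord> *records) {
  Xoshiro256pp rng(seed, stream);
  assign_flows(T);
  rescale_radii(T);
  // tag new vessels with the current stage; parents being split keep their
  // slot but their pieces adopt the current stage code
  for (int added = 0; added < N; ++added) {
    double relax = 1.0;
    int fails = 0;
    const int max_attempts = 200000;
    bool placed = false;
    // terminals currently feeding the sampling region (distal point inside)
    int n_inside = 0;
    for (int i = 0; i < T.n(); ++i)
      if (T.is_terminal(i) && sampledom.contains(T.xd[i])) ++n_inside;
    for (int att = 0; att < max_attempts && !placed; ++att) {
      Vec3 x = sampledom.sample(rng);
      double dcrit =
          cfg.kd * std::cbrt(sampledom.volume / (n_inside + 1)) * relax;
      double dmin = R_PosInf;
      for (int i = 0; i < T.n(); ++i)
        dmin = std::min(dmin, point_seg_dist(x, T.xp[i], T.xd[i]));
      bool ok = dmin >= dcrit;
      BestInsertion best;
      if (ok) {
        int nvalid;
        best = try_insert_cpp(T, x, cfg, dom, &nvalid);
        ok = best.found;
      }
      if (!ok) {
        if (++fails % 10 == 0) {
          relax *= cfg.fr;
          if (relax < cfg.relax_floor)
            stop("growth stalled: relaxation floor reached after %d failed "
                 "candidate points (%d of %d terminals placed)",
                 fails, added, N);
        }
        continue;
      }
      // commit
      if (records) {
        InsRecord rec;
        rec.xnew = x;
        rec.xbif = best.xbif;
        rec.pxp = T.xp[best.parent_idx];
        rec.pxd = T.xd[best.parent_idx];
        records->push_back(rec);
      }
      add_terminal_internal(T, best.parent_idx, best.xbif, x, stage_code,
                            nullptr);
      assign_flows(T);
      rescale_radii(T);
      // one linearized viscosity sweep per insertion; the full fixed point
      // runs at the end of the stage
      if (cfg.visc.kind != 0) {
        update_viscosities(T, cfg.visc);
        rescale_radii(T);
      }
      placed = true;
    }
    if (!placed)
      stop("growth failed: could not place terminal %d of %d", added + 1, N);
  }
  // final haemodynamic pass for the stage
  std::vector<double> res;
  int it = fixed_point(T, cfg.visc, 1e-6, 100, res);
  if (it < 0)
    stop("viscosity/radius fixed point did not converge after 100 iterations "
         "(final residual %g)",
         res.back());
}

// ---------------------------------------------------------------------------
// Rcpp interface
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_candidate_points(NumericVector a, NumericVector b,
                                   NumericVector c, int nbif) {
  std::vector<Vec3> pts = candidate_points({a[0], a[1], a[2]},
                                           {b[0], b[1], b[2]},
                                           {c[0], c[1], c[2]}, nbif);
  NumericMatrix out(pts.size(), 3);
  for (size_t i = 0; i < pts.size(); ++i) {
    out(i, 0) = pts[i].x; out(i, 1) = pts[i].y; out(i, 2) = pts[i].z;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_neighbourhood(List tree, NumericVector x, double fn,
                                bool restrict_allowed) {
  Tree T = tree_from_r(tree);
  std::vector<int> nb =
      neighbourhood_cpp(T, {x[0], x[1], x[2]}, fn, restrict_allowed);
  IntegerVector out(nb.size());
  for (size_t i = 0; i < nb.size(); ++i) out[i] = T.id[nb[i]];
  return out;
}

// [[Rcpp::export]]
List cpp_check_connection(List tree, int parent_id, NumericVector xbif,
                          NumericVector xnew, List stage, List domain) {
  Tree T = tree_from_r(tree);
  StageCfg cfg = stage_from_r(stage);
  Domain dom = domain_from_r(domain);
  assign_flows(T);
  rescale_radii(T);
  int pidx = NONE;
  for (int i = 0; i < T.n(); ++i)
    if (T.id[i] == parent_id) { pidx = i; break; }
  if (pidx == NONE) stop("unknown parent vessel id");
  Tree scratch;
  double dF = NA_REAL;
  int rc = eval_candidate(T, scratch, pidx, {xbif[0], xbif[1], xbif[2]},
                          {xnew[0], xnew[1], xnew[2]}, cfg, dom,
                          tree_cost_cpp(T, cfg), dF);
  static const char *reasons[] = {"ok",
                                  "degenerate-geometry",
                                  "angle-below-theta-min",
                                  "deviation-below-phi-min",
                                  "outside-domain",
                                  "asymmetry-below-delta",
                                  "aspect-below-2r",
                                  "segment-intersection"};
  return List::create(_["valid"] = (rc == 0), _["reason"] = reasons[rc],
                      _["dF"] = dF);
}

// [[Rcpp::export]]
List cpp_try_insert(List tree, NumericVector xnew, List stage, List domain) {
  Tree T = tree_from_r(tree);
  StageCfg cfg = stage_from_r(stage);
  Domain dom = domain_from_r(domain);
  assign_flows(T);
  rescale_radii(T);
  int nvalid;
  BestInsertion best =
      try_insert_cpp(T, {xnew[0], xnew[1], xnew[2]}, cfg, dom, &nvalid);
  if (!best.found)
    return List::create(_["found"] = false, _["n_valid"] = nvalid);
  return List::create(
      _["found"] = true, _["parent_id"] = T.id[best.parent_idx],
      _["cand_index"] = best.cand_idx + 1,
      _["x_bif"] = NumericVector::create(best.xbif.x, best.xbif.y, best.xbif.z),
      _["dF"] = best.dF, _["n_valid"] = nvalid);
}

// [[Rcpp::export]]
List cpp_grow(List tree, List domain, List sample_domain, List stage, int N,
              double seed, double stream, int stage_code, bool keep_records) {
  Tree T = tree_from_r(tree);
  Domain dom = domain_from_r(domain);
  Domain sdom = domain_from_r(sample_domain);
  StageCfg cfg = stage_from_r(stage);
  std::vector<InsRecord> recs;
  grow_cpp(T, dom, sdom, cfg, N, (uint64_t)seed, (uint64_t)stream, stage_code,
           keep_records ? &recs : nullptr);
  NumericMatrix rm(recs.size(), 12);
  for (size_t i = 0; i < recs.size(); ++i) {
    const InsRecord &r = recs[i];
    rm(i, 0) = r.xnew.x;  rm(i, 1) = r.xnew.y;  rm(i, 2) = r.xnew.z;
    rm(i, 3) = r.xbif.x;  rm(i, 4) = r.xbif.y;  rm(i, 5) = r.xbif.z;
    rm(i, 6) = r.pxp.x;   rm(i, 7) = r.pxp.y;   rm(i, 8) = r.pxp.z;
    rm(i, 9) = r.pxd.x;   rm(i, 10) = r.pxd.y;  rm(i, 11) = r.pxd.z;
  }
  return List::create(_["tree"] = tree_to_r(T), _["records"] = rm);
}
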