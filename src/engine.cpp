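// Core simulation engine: lattice adjacency, connected-component labeling,
// torus-wrapping detection, local event classification, and the
// constant-density swap dynamics that generates the event stream.
//
// Lattice kinds: 0 = square lattice with von Neumann neighbourhood (z = 4),
// 1 = six-neighbour triangular adjacency in axial coordinates on an L x L
// rhombic torus (z = 6). Sites are 0-based row-major: s = i*L + j.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

static const int TYPE_LOSS = 1;
static const int TYPE_SHRINKAGE = 2;
static const int TYPE_SPLITTING = 3;
static const int TYPE_FORMATION = 4;
static const int TYPE_ENLARGEMENT = 5;
static const int TYPE_COALESCENCE = 6;

static inline int nbr_count(int kind) { return kind == 1 ? 6 : 4; }

// Neighbours of site s; out must hold z entries.
// hex6 axial rule: (i+-1, j), (i, j+-1), (i+1, j-1), (i-1, j+1), all mod L.
static inline void site_neighbors(int kind, int L, int s, int *out) {
  int i = s / L, j = s % L;
  int ip = (i + 1 == L) ? 0 : i + 1;
  int im = (i == 0) ? L - 1 : i - 1;
  int jp = (j + 1 == L) ? 0 : j + 1;
  int jm = (j == 0) ? L - 1 : j - 1;
  out[0] = im * L + j;
  out[1] = ip * L + j;
  out[2] = i * L + jm;
  out[3] = i * L + jp;
  if (kind == 1) {
    out[4] = ip * L + jm;
    out[5] = im * L + jp;
  }
}

// [[Rcpp::export]]
IntegerVector neighbors_cpp(int kind, int L, int site) {
  int z = nbr_count(kind);
  int nb[6];
  site_neighbors(kind, L, site, nb);
  IntegerVector out(z);
  for (int d = 0; d < z; ++d) out[d] = nb[d];
  return out;
}

// Connected-component labeling by flood fill in site order. Labels are
// 1..k in order of first (row-major) appearance; 0 marks non-habitat.
// [[Rcpp::export]]
List label_cpp(IntegerVector occ, int kind, int L) {
  int N = L * L, z = nbr_count(kind);
  IntegerVector labels(N);
  std::vector<int> sizes;
  std::vector<int> stack;
  int nb[6];
  int lab = 0;
  for (int s = 0; s < N; ++s) {
    if (occ[s] != 0 && labels[s] == 0) {
      ++lab;
      int count = 0;
      labels[s] = lab;
      stack.push_back(s);
      while (!stack.empty()) {
        int u = stack.back();
        stack.pop_back();
        ++count;
        site_neighbors(kind, L, u, nb);
        for (int d = 0; d < z; ++d) {
          int w = nb[d];
          if (occ[w] != 0 && labels[w] == 0) {
            labels[w] = lab;
            stack.push_back(w);
          }
        }
      }
      sizes.push_back(count);
    }
  }
  return List::create(_["labels"] = labels, _["sizes"] = wrap(sizes));
}

// ---------------------------------------------------------------------------
// Torus-wrapping detection: union-find with relative displacement vectors.
// Each node stores the displacement to its parent in unwrapped coordinates;
// a cycle whose accumulated displacement is a non-zero multiple of L in an
// axis reveals a cluster wrapping around that axis.
// ---------------------------------------------------------------------------

struct WrapDSU {
  std::vector<int> par, sz, ox, oy; // (ox,oy): pos(parent) - pos(node)
  std::vector<int> path;
  void reset(int N) {
    par.resize(N); sz.assign(N, 1); ox.assign(N, 0); oy.assign(N, 0);
    for (int i = 0; i < N; ++i) par[i] = i;
  }
  // Find root of x; sets (accx, accy) = pos(root) - pos(x). Compresses path.
  int find(int x, int &accx, int &accy) {
    path.clear();
    int r = x;
    while (par[r] != r) { path.push_back(r); r = par[r]; }
    int prx = 0, pry = 0;
    for (int k = (int)path.size() - 1; k >= 0; --k) {
      int nd = path[k];
      int nx = ox[nd] + prx, ny = oy[nd] + pry;
      par[nd] = r; ox[nd] = nx; oy[nd] = ny;
      prx = nx; pry = ny;
    }
    if (x == r) { accx = 0; accy = 0; }
    else { accx = ox[x]; accy = oy[x]; }
    return r;
  }
};

// Scan all habitat-habitat edges; report whether any cluster wraps around
// axis 0 (rows) and/or axis 1 (columns).
static void wrap_check(const std::vector<uint8_t> &occ, int kind, int L,
                       WrapDSU &dsu, bool &wrap_row, bool &wrap_col) {
  int N = L * L;
  dsu.reset(N);
  wrap_row = false; wrap_col = false;
  // forward edge directions with displacement (di, dj)
  const int ndir = (kind == 1) ? 3 : 2;
  for (int s = 0; s < N; ++s) {
    if (!occ[s]) continue;
    int i = s / L, j = s % L;
    int ip = (i + 1 == L) ? 0 : i + 1;
    int jp = (j + 1 == L) ? 0 : j + 1;
    int jm = (j == 0) ? L - 1 : j - 1;
    int tgt[3]; int dx[3], dy[3];
    tgt[0] = ip * L + j;  dx[0] = 1; dy[0] = 0;
    tgt[1] = i * L + jp;  dx[1] = 0; dy[1] = 1;
    if (kind == 1) { tgt[2] = ip * L + jm; dx[2] = 1; dy[2] = -1; }
    for (int d = 0; d < ndir; ++d) {
      int t = tgt[d];
      if (!occ[t]) continue;
      int oax, oay, obx, oby;
      int ra = dsu.find(s, oax, oay);
      int rb = dsu.find(t, obx, oby);
      if (ra != rb) {
        // pos(t) = pos(s) + d (unwrapped)
        if (dsu.sz[ra] >= dsu.sz[rb]) {
          dsu.par[rb] = ra;
          dsu.ox[rb] = oax - dx[d] - obx;
          dsu.oy[rb] = oay - dy[d] - oby;
          dsu.sz[ra] += dsu.sz[rb];
        } else {
          dsu.par[ra] = rb;
          dsu.ox[ra] = dx[d] + obx - oax;
          dsu.oy[ra] = dy[d] + oby - oay;
          dsu.sz[rb] += dsu.sz[ra];
        }
      } else {
        int mx = oax - obx - dx[d];
        int my = oay - oby - dy[d];
        if (mx != 0) wrap_row = true;
        if (my != 0) wrap_col = true;
      }
    }
    if (wrap_row && wrap_col) return;
  }
}

// [[Rcpp::export]]
LogicalVector wrap_cpp(IntegerVector occ, int kind, int L) {
  int N = L * L;
  std::vector<uint8_t> o(N);
  for (int s = 0; s < N; ++s) o[s] = occ[s] != 0;
  WrapDSU dsu;
  bool wr, wc;
  wrap_check(o, kind, L, dsu, wr, wc);
  return LogicalVector::create(wr, wc);
}

// Wrapping probability (either axis) over a p-scan with seeded replicates.
// Uses R's RNG so set.seed() on the R side controls reproducibility.
// [[Rcpp::export]]
NumericVector wrap_scan_cpp(int kind, int L, NumericVector pvec, int reps) {
  int N = L * L;
  std::vector<int> perm(N);
  std::vector<uint8_t> occ(N);
  WrapDSU dsu;
  NumericVector out(pvec.size());
  for (int pi = 0; pi < pvec.size(); ++pi) {
    int nocc = (int)std::lround(pvec[pi] * N);
    int hits = 0;
    for (int rep = 0; rep < reps; ++rep) {
      for (int i = 0; i < N; ++i) perm[i] = i;
      std::fill(occ.begin(), occ.end(), 0);
      for (int i = 0; i < nocc; ++i) {
        int j = i + (int)(unif_rand() * (N - i));
        if (j >= N) j = N - 1;
        std::swap(perm[i], perm[j]);
        occ[perm[i]] = 1;
      }
      bool wr, wc;
      wrap_check(occ, kind, L, dsu, wr, wc);
      if (wr || wc) ++hits;
    }
    out[pi] = (double)hits / reps;
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---------------------------------------------------------------------------
// Local event classification.
//
// The habitat neighbours of the focal site are grouped into seed groups by
// mutual adjacency; a single group settles shrinkage/enlargement without any
// search. Otherwise an interleaved multi-source BFS (restricted to habitat,
// excluding the focal site for removals) resolves which groups are connected:
// groups merge when their searches touch, a search that exhausts its queue
// has sized a complete fragment exactly, and the loop stops as soon as all
// groups have merged (shrinkage) or at most one search remains active
// (splitting/coalescence confirmed; the last fragment is sized up to `cap`).
// Sizes >= cap are reported as cap with a capped flag; cap always exceeds
// every requested minimum viable patch size, so effective losses are exact.
// ---------------------------------------------------------------------------

struct Scratch {
  std::vector<int> mark_epoch; // per-site visit stamp
  std::vector<int> mark_root;  // group id (0..5) the site was claimed by
  int epoch;
  std::vector<int> queues[6];
  size_t qhead[6];
  Scratch(int N) : mark_epoch(N, 0), mark_root(N, 0), epoch(0) {}
};

// BFS patch size from `start` over habitat, capped at `cap`.
static long capped_patch_size(const std::vector<uint8_t> &occ, int kind, int L,
                              int start, int cap, Scratch &scr, bool &capped) {
  int z = nbr_count(kind);
  int nb[6];
  ++scr.epoch;
  std::vector<int> &q = scr.queues[0];
  q.clear();
  q.push_back(start);
  scr.mark_epoch[start] = scr.epoch;
  long count = 1;
  size_t head = 0;
  capped = false;
  while (head < q.size()) {
    if (count >= cap) { capped = true; return cap; }
    int u = q[head++];
    site_neighbors(kind, L, u, nb);
    for (int d = 0; d < z; ++d) {
      int w = nb[d];
      if (occ[w] && scr.mark_epoch[w] != scr.epoch) {
        scr.mark_epoch[w] = scr.epoch;
        q.push_back(w);
        ++count;
        if (count >= cap) { capped = true; return cap; }
      }
    }
  }
  return count;
}

// Classify the change at `site`. For removal = true, occ[site] must be 1 and
// the site is treated as removed during the search; for removal = false,
// occ[site] must be 0. Outputs: event type; `single` = the one-patch-side
// size (patch size before a removal, merged size after an addition);
// `parts` = the multi-patch-side sizes (fragments after a removal, joined
// patches before an addition), with per-part capped flags.
static void classify_core(const std::vector<uint8_t> &occ, int kind, int L,
                          int site, bool removal, int cap, Scratch &scr,
                          int &type, long &single, bool &single_capped,
                          std::vector<long> &parts,
                          std::vector<uint8_t> &parts_capped) {
  int z = nbr_count(kind);
  int nb[6], nb2[6];
  parts.clear();
  parts_capped.clear();
  single_capped = false;
  site_neighbors(kind, L, site, nb);
  int hn[6], k = 0;
  for (int d = 0; d < z; ++d)
    if (occ[nb[d]]) hn[k++] = nb[d];

  if (k == 0) {
    type = removal ? TYPE_LOSS : TYPE_FORMATION;
    single = 1;
    return;
  }

  // seed groups: habitat neighbours that are mutually adjacent share a patch
  int gid[6];
  for (int a = 0; a < k; ++a) gid[a] = a;
  auto gfind = [&](int x) { while (gid[x] != x) x = gid[x]; return x; };
  for (int a = 0; a < k; ++a) {
    site_neighbors(kind, L, hn[a], nb2);
    for (int b = a + 1; b < k; ++b)
      for (int d = 0; d < z; ++d)
        if (nb2[d] == hn[b]) {
          int ra = gfind(a), rb = gfind(b);
          if (ra != rb) gid[rb] = ra;
        }
  }
  int distinct = 0;
  for (int a = 0; a < k; ++a)
    if (gfind(a) == a) ++distinct;

  long rsize[6] = {0, 0, 0, 0, 0, 0};

  if (distinct > 1) {
    // interleaved multi-source BFS over the patch (excluding the focal site)
    ++scr.epoch;
    for (int a = 0; a < k; ++a) { scr.queues[a].clear(); scr.qhead[a] = 0; }
    for (int a = 0; a < k; ++a) {
      int r = gfind(a);
      if (scr.mark_epoch[hn[a]] != scr.epoch) {
        scr.mark_epoch[hn[a]] = scr.epoch;
        scr.mark_root[hn[a]] = r;
        scr.queues[r].push_back(hn[a]);
        ++rsize[r];
      }
    }
    auto merge_roots = [&](int rkeep, int rdrop) {
      gid[rdrop] = rkeep;
      rsize[rkeep] += rsize[rdrop];
      std::vector<int> &qk = scr.queues[rkeep], &qd = scr.queues[rdrop];
      qk.insert(qk.end(), qd.begin() + scr.qhead[rdrop], qd.end());
      qd.clear();
      scr.qhead[rdrop] = 0;
      --distinct;
    };
    while (distinct > 1) {
      int active = 0;
      for (int a = 0; a < k; ++a) {
        if (gfind(a) != a) continue;
        if (scr.qhead[a] >= scr.queues[a].size()) continue; // exhausted
        ++active;
        int u = scr.queues[a][scr.qhead[a]++];
        site_neighbors(kind, L, u, nb2);
        for (int d = 0; d < z; ++d) {
          int w = nb2[d];
          if (removal && w == site) continue;
          if (!occ[w]) continue;
          if (scr.mark_epoch[w] == scr.epoch) {
            int rw = gfind(scr.mark_root[w]);
            int rr = gfind(a);
            if (rw != rr) {
              merge_roots(rr, rw);
              if (distinct <= 1) break;
            }
          } else {
            scr.mark_epoch[w] = scr.epoch;
            int rr = gfind(a);
            scr.mark_root[w] = rr;
            scr.queues[rr].push_back(w);
            ++rsize[rr];
          }
        }
        if (distinct <= 1) break;
      }
      if (distinct <= 1) break;
      // count roots that still have queued work
      int pending = 0, lastp = -1;
      for (int a = 0; a < k; ++a)
        if (gfind(a) == a && scr.qhead[a] < scr.queues[a].size()) {
          ++pending;
          lastp = a;
        }
      if (pending == 0) break; // all fragments complete
      if (pending == 1) {
        // splitting/coalescence confirmed; size the last fragment up to cap
        int a = lastp;
        bool capped = false;
        while (scr.qhead[a] < scr.queues[a].size()) {
          if (rsize[a] >= cap) { capped = true; break; }
          int u = scr.queues[a][scr.qhead[a]++];
          site_neighbors(kind, L, u, nb2);
          for (int d = 0; d < z; ++d) {
            int w = nb2[d];
            if (removal && w == site) continue;
            if (!occ[w]) continue;
            if (scr.mark_epoch[w] != scr.epoch) {
              scr.mark_epoch[w] = scr.epoch;
              scr.mark_root[w] = a;
              scr.queues[a].push_back(w);
              ++rsize[a];
            }
          }
        }
        if (capped) rsize[a] = cap;
        // record which root got capped via parts_capped below
        long total = 0;
        for (int b = 0; b < k; ++b)
          if (gfind(b) == b) {
            parts.push_back(rsize[b]);
            parts_capped.push_back(b == a && capped ? 1 : 0);
            total += rsize[b];
          }
        type = removal ? TYPE_SPLITTING : TYPE_COALESCENCE;
        single = total + 1;
        single_capped = capped;
        if (single_capped) single = cap;
        return;
      }
      (void)active;
    }
    if (distinct > 1) {
      // every remaining root exhausted: all fragments complete and exact
      long total = 0;
      for (int b = 0; b < k; ++b)
        if (gfind(b) == b) {
          parts.push_back(rsize[b]);
          parts_capped.push_back(0);
          total += rsize[b];
        }
      type = removal ? TYPE_SPLITTING : TYPE_COALESCENCE;
      single = total + 1;
      return;
    }
    // fell through: all groups merged -> single patch
  }

  // one connected group: shrinkage (removal) or enlargement (addition)
  bool capped = false;
  if (removal) {
    // patch size before removal, focal site included
    single = capped_patch_size(occ, kind, L, site, cap, scr, capped);
    single_capped = capped;
    parts.push_back(single_capped ? cap : single - 1);
    parts_capped.push_back(capped ? 1 : 0);
    type = TYPE_SHRINKAGE;
  } else {
    long part = capped_patch_size(occ, kind, L, hn[0], cap, scr, capped);
    parts.push_back(part);
    parts_capped.push_back(capped ? 1 : 0);
    single = capped ? cap : part + 1;
    single_capped = capped;
    type = TYPE_ENLARGEMENT;
  }
}

// [[Rcpp::export]]
List classify_site_cpp(IntegerVector occ, int kind, int L, int site,
                       bool removal, int cap) {
  int N = L * L;
  if (site < 0 || site >= N) stop("invalid site index");
  if (removal && occ[site] == 0) stop("site is not a habitat site");
  if (!removal && occ[site] != 0) stop("site is not a non-habitat site");
  std::vector<uint8_t> o(N);
  for (int s = 0; s < N; ++s) o[s] = occ[s] != 0;
  Scratch scr(N);
  int type;
  long single;
  bool single_capped;
  std::vector<long> parts;
  std::vector<uint8_t> parts_capped;
  classify_core(o, kind, L, site, removal, cap, scr, type, single,
                single_capped, parts, parts_capped);
  IntegerVector pv(parts.size());
  LogicalVector pc(parts.size());
  for (size_t i = 0; i < parts.size(); ++i) {
    pv[i] = (int)parts[i];
    pc[i] = parts_capped[i] != 0;
  }
  return List::create(_["type"] = type, _["single"] = (double)single,
                      _["single_capped"] = single_capped, _["parts"] = pv,
                      _["parts_capped"] = pc);
}

// effective change of living area for one event, given m (cap > m assumed):
// 0 if the one-patch side is below m, else 1 + sum of exact parts below m.
static inline long effective_change(long single, bool single_capped,
                                    const std::vector<long> &parts,
                                    const std::vector<uint8_t> &parts_capped,
                                    int m) {
  if (!single_capped && single < m) return 0;
  long e = 1;
  for (size_t i = 0; i < parts.size(); ++i)
    if (!parts_capped[i] && parts[i] < m) e += parts[i];
  return e;
}

// Constant-density swap dynamics. Each pair: one uniformly chosen habitat
// site is removed and one uniformly chosen non-habitat site (of the
// pre-swap state) is added; the removal is classified and applied first,
// the addition is classified against the intermediate state and applied.
// [[Rcpp::export]]
List run_events_cpp(IntegerVector occ0, int kind, int L, int n_pairs,
                    IntegerVector m_list, bool record) {
  int N = L * L;
  std::vector<uint8_t> occ(N);
  std::vector<int> hab, non, pos(N);
  for (int s = 0; s < N; ++s) {
    occ[s] = occ0[s] != 0;
    if (occ[s]) { pos[s] = hab.size(); hab.push_back(s); }
    else { pos[s] = non.size(); non.push_back(s); }
  }
  if (hab.empty() || non.empty())
    stop("swap dynamics needs 0 < n_habitat < N");
  int nm = m_list.size();
  int maxm = 1;
  for (int i = 0; i < nm; ++i)
    if (m_list[i] > maxm) maxm = m_list[i];
  int cap = maxm + 1;

  std::vector<double> amp_sum(nm, 0.0), amp_sumsq(nm, 0.0);
  std::vector<double> gain_sum(nm, 0.0), gain_sumsq(nm, 0.0);
  double counts[7] = {0, 0, 0, 0, 0, 0, 0};

  // optional event log (flat encoding)
  std::vector<int> ev_type, ev_site, ev_single, ev_npart, ev_parts;
  std::vector<uint8_t> ev_single_cap, ev_parts_cap;
  if (record) {
    ev_type.reserve(2 * n_pairs);
    ev_site.reserve(2 * n_pairs);
  }

  Scratch scr(N);
  int type;
  long single;
  bool single_capped;
  std::vector<long> parts;
  std::vector<uint8_t> parts_capped;

  auto log_event = [&](int site) {
    ev_type.push_back(type);
    ev_site.push_back(site);
    ev_single.push_back((int)single);
    ev_single_cap.push_back(single_capped ? 1 : 0);
    ev_npart.push_back((int)parts.size());
    for (size_t i = 0; i < parts.size(); ++i) {
      ev_parts.push_back((int)parts[i]);
      ev_parts_cap.push_back(parts_capped[i]);
    }
  };

  for (int t = 0; t < n_pairs; ++t) {
    int ri = (int)(unif_rand() * hab.size());
    if (ri >= (int)hab.size()) ri = hab.size() - 1;
    int ai = (int)(unif_rand() * non.size());
    if (ai >= (int)non.size()) ai = non.size() - 1;
    int rsite = hab[ri];
    int asite = non[ai]; // pre-swap non-habitat set

    // removal
    classify_core(occ, kind, L, rsite, true, cap, scr, type, single,
                  single_capped, parts, parts_capped);
    counts[type] += 1;
    for (int i = 0; i < nm; ++i) {
      long e = effective_change(single, single_capped, parts, parts_capped,
                                m_list[i]);
      amp_sum[i] += e;
      amp_sumsq[i] += (double)e * e;
    }
    if (record) log_event(rsite);
    occ[rsite] = 0;
    { // hab -> non
      int last = hab.back();
      hab[pos[rsite]] = last;
      pos[last] = pos[rsite];
      hab.pop_back();
      pos[rsite] = non.size();
      non.push_back(rsite);
    }

    // addition, classified against the intermediate state
    classify_core(occ, kind, L, asite, false, cap, scr, type, single,
                  single_capped, parts, parts_capped);
    counts[type] += 1;
    for (int i = 0; i < nm; ++i) {
      long e = effective_change(single, single_capped, parts, parts_capped,
                                m_list[i]);
      gain_sum[i] += e;
      gain_sumsq[i] += (double)e * e;
    }
    if (record) log_event(asite);
    occ[asite] = 1;
    { // non -> hab
      int last = non.back();
      non[pos[asite]] = last;
      pos[last] = pos[asite];
      non.pop_back();
      pos[asite] = hab.size();
      hab.push_back(asite);
    }
    if ((t & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  IntegerVector occ_out(N);
  for (int s = 0; s < N; ++s) occ_out[s] = occ[s];
  NumericVector cnt(6);
  for (int i = 0; i < 6; ++i) cnt[i] = counts[i + 1];
  List out = List::create(
      _["counts"] = cnt, _["n_pairs"] = n_pairs,
      _["amp_sum"] = wrap(amp_sum), _["amp_sumsq"] = wrap(amp_sumsq),
      _["gain_sum"] = wrap(gain_sum), _["gain_sumsq"] = wrap(gain_sumsq),
      _["cap"] = cap, _["occ_final"] = occ_out);
  if (record) {
    out["ev_type"] = wrap(ev_type);
    out["ev_site"] = wrap(ev_site);
    out["ev_single"] = wrap(ev_single);
    out["ev_single_cap"] = wrap(ev_single_cap);
    out["ev_npart"] = wrap(ev_npart);
    out["ev_parts"] = wrap(ev_parts);
    out["ev_parts_cap"] = wrap(ev_parts_cap);
  }
  return out;
}
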