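// Grand-canonical kinetic Monte Carlo engine for tubule self-assembly from
// triangular monomers, plus a fixed-topology sampler used for equipartition
// checks and Einstein-solid thermodynamic integration.
//
// Mesh: oriented triangles; corner k of a triangle owns the directed
// halfedge (v[k] -> v[(k+1)%3]) with edge type TYPE[k] in {1,3,2}; a bound
// edge is a pair of opposite-direction halfedges of equal type sharing both
// vertices.  Energies in kBT, lengths in l0.
//
// Move set: vertex displacement (Metropolis), monomer association /
// dissociation against a bath at chemical potential mu, and edge fusion /
// fission in two channel classes: seam channels (pairs sharing a vertex;
// fission splitting <= 1 vertex) attempted per channel at p_seam, and
// closure channels (distant boundary pairs; two vertex merges) attempted
// per channel at f_fusion.  Attempt weights: vertex N_v, exchange
// p_ex * n_free, each fusion/fission class rate * (n_free + n_bound); time
// advances 1/W per attempt so one sweep is one attempted vertex move per
// vertex.  All acceptances carry the exact reverse/forward proposal ratio
// (total-weight ratios W/W', partner-degeneracy counts, and reversible-jump
// volume factors per merged/split vertex), so detailed balance holds in the
// grand-canonical measure with one factor 1/v_p per vertex, v_p = (2*wp)^3
// the association proposal volume.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static const int TYPE[3] = {1, 3, 2};   // edge type by corner
static const int NEXT[3] = {1, 2, 0};
static const int PREV[3] = {2, 0, 1};

// ---------------------------------------------------------------- RNG (PCG32)
struct Pcg32 {
  uint64_t state, inc;
  explicit Pcg32(uint64_t seed, uint64_t seq = 54u) {
    state = 0u; inc = (seq << 1u) | 1u;
    next(); state += seed; next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double runif() { return (next() + 0.5) * (1.0 / 4294967296.0); }
  int runif_int(int n) { return (int)(runif() * n) % n; }  // n small
};

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double a, double b, double c) : x(a), y(b), z(c) {}
  V3 operator+(const V3& o) const { return V3(x + o.x, y + o.y, z + o.z); }
  V3 operator-(const V3& o) const { return V3(x - o.x, y - o.y, z - o.z); }
  V3 operator*(double s) const { return V3(x * s, y * s, z * s); }
  double dot(const V3& o) const { return x * o.x + y * o.y + z * o.z; }
  V3 cross(const V3& o) const {
    return V3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm() const { return std::sqrt(x * x + y * y + z * z); }
};

struct Tri {
  int v[3];
  int opp[3];     // partner halfedge code 3*t+k, or -1 if free
  bool alive;
};

struct Engine {
  // state
  std::vector<V3> pos;
  std::vector<char> vAlive;
  std::vector<std::vector<int>> vtris;    // alive triangles incident to vertex
  std::vector<int> aliveVerts, vposIdx;   // uniform vertex selection
  std::vector<Tri> tris;
  std::vector<int> freeTriSlots, freeVertSlots;
  std::vector<int> freeHE;                // free halfedge codes
  std::vector<int> hePos;                 // index in freeHE, -1 otherwise
  std::vector<int> boundList;             // bound pairs (lower halfedge code)
  std::vector<int> bpPos;                 // index in boundList, -1 otherwise
  int nTri = 0, nBound = 0;

  // parameters
  double EB, Bmod, kS, l0, mu;
  double theta0[3];
  double f_fusion, p_seam, p_exchange, delta_v, r_c, wp;
  int max_monomers;                        // 0 = unlimited
  Pcg32 rng;

  // statistics
  long n_insert = 0, n_delete = 0, n_fuse = 0, n_fiss = 0;
  bool closed_flag = false;
  int N_close = -1;
  double tau_close = -1.0;

  explicit Engine(uint64_t seed) : rng(seed) {}

  // ------------------------------------------------------------- mesh admin
  int newVertex(const V3& p) {
    int v;
    if (!freeVertSlots.empty()) {
      v = freeVertSlots.back(); freeVertSlots.pop_back();
      pos[v] = p; vAlive[v] = 1; vtris[v].clear();
    } else {
      v = (int)pos.size();
      pos.push_back(p); vAlive.push_back(1); vtris.push_back({});
      vposIdx.push_back(-1);
    }
    vposIdx[v] = (int)aliveVerts.size();
    aliveVerts.push_back(v);
    return v;
  }
  void dropVertex(int v) {
    int ix = vposIdx[v], last = aliveVerts.back();
    aliveVerts[ix] = last; vposIdx[last] = ix;
    aliveVerts.pop_back(); vposIdx[v] = -1;
    vAlive[v] = 0; freeVertSlots.push_back(v);
  }
  void heMarkFree(int he) {
    hePos[he] = (int)freeHE.size();
    freeHE.push_back(he);
  }
  void heUnmarkFree(int he) {
    int ix = hePos[he], last = freeHE.back();
    freeHE[ix] = last; hePos[last] = ix;
    freeHE.pop_back(); hePos[he] = -1;
  }
  void bpAdd(int key) {
    bpPos[key] = (int)boundList.size();
    boundList.push_back(key);
  }
  void bpRemove(int key) {
    int ix = bpPos[key], last = boundList.back();
    boundList[ix] = last; bpPos[last] = ix;
    boundList.pop_back(); bpPos[key] = -1;
  }
  int newTriangle(int a, int b, int c) {
    int t;
    if (!freeTriSlots.empty()) {
      t = freeTriSlots.back(); freeTriSlots.pop_back();
    } else {
      t = (int)tris.size();
      tris.push_back(Tri());
      hePos.push_back(-1); hePos.push_back(-1); hePos.push_back(-1);
      bpPos.push_back(-1); bpPos.push_back(-1); bpPos.push_back(-1);
    }
    tris[t].v[0] = a; tris[t].v[1] = b; tris[t].v[2] = c;
    tris[t].opp[0] = tris[t].opp[1] = tris[t].opp[2] = -1;
    tris[t].alive = true;
    vtris[a].push_back(t); vtris[b].push_back(t); vtris[c].push_back(t);
    nTri++;
    return t;
  }
  void removeTriFromVertex(int v, int t) {
    auto& lst = vtris[v];
    for (size_t i = 0; i < lst.size(); ++i)
      if (lst[i] == t) { lst[i] = lst.back(); lst.pop_back(); return; }
  }

  int heTri(int he) const { return he / 3; }
  int heCorner(int he) const { return he % 3; }
  int heFrom(int he) const { return tris[he / 3].v[he % 3]; }
  int heTo(int he) const { return tris[he / 3].v[NEXT[he % 3]]; }
  int heType(int he) const { return TYPE[he % 3]; }

  int nVerts() const { return (int)aliveVerts.size(); }
  int nFree() const { return (int)freeHE.size(); }
  double totalWeight() const {
    return totalWeightWith(nVerts(), nFree(), (int)boundList.size());
  }

  // ------------------------------------------------------------- energetics
  double stretchHE(int he) const {
    V3 d = pos[heFrom(he)] - pos[heTo(he)];
    double l = d.norm();
    double w = (tris[he / 3].opp[he % 3] >= 0) ? 0.5 : 1.0;
    double dd = l - l0;
    return w * 0.5 * kS * dd * dd;
  }
  // dihedral of bound pair owned by halfedge he (flat = pi, convex < pi)
  double dihedralHE(int he, bool* ok = nullptr) const {
    int t1 = he / 3, k1 = he % 3;
    int he2 = tris[t1].opp[k1];
    int t2 = he2 / 3;
    const Tri& A = tris[t1];
    const Tri& Bt = tris[t2];
    V3 a0 = pos[A.v[0]], a1 = pos[A.v[1]], a2 = pos[A.v[2]];
    V3 b0 = pos[Bt.v[0]], b1 = pos[Bt.v[1]], b2 = pos[Bt.v[2]];
    V3 n1 = (a1 - a0).cross(a2 - a0);
    V3 n2 = (b1 - b0).cross(b2 - b0);
    double m1 = n1.norm(), m2 = n2.norm();
    if (m1 < 1e-12 || m2 < 1e-12) { if (ok) *ok = false; return M_PI; }
    if (ok) *ok = true;
    n1 = n1 * (1.0 / m1); n2 = n2 * (1.0 / m2);
    V3 e = pos[heTo(he)] - pos[heFrom(he)];
    double en = e.norm();
    if (en < 1e-12) { if (ok) *ok = false; return M_PI; }
    e = e * (1.0 / en);
    double phi = std::atan2(n1.cross(n2).dot(e), n1.dot(n2));
    return M_PI - phi;
  }
  double bendHE(int he, bool* ok = nullptr) const {
    double th = dihedralHE(he, ok);
    double d = th - theta0[heType(he) - 1];
    return 0.5 * Bmod * d * d;
  }

  // local energy around a set of triangles: stretch of their halfedges
  // (weighted) + bend of every bound pair touching the set (counted once)
  double localEnergy(const std::vector<int>& tset, bool* ok) {
    *ok = true;
    double e = 0.0;
    std::vector<int> pairs;
    for (int t : tset) {
      if (!tris[t].alive) continue;
      for (int k = 0; k < 3; ++k) {
        int he = 3 * t + k;
        e += stretchHE(he);
        int o = tris[t].opp[k];
        if (o >= 0) pairs.push_back(std::min(he, o));
      }
    }
    std::sort(pairs.begin(), pairs.end());
    pairs.erase(std::unique(pairs.begin(), pairs.end()), pairs.end());
    for (int he : pairs) {
      bool dok = true;
      e += bendHE(he, &dok);
      if (!dok) *ok = false;
    }
    return e;
  }

  // ---------------------------------------------------------- vertex move
  bool vertexMove() {
    if (aliveVerts.empty()) return false;
    int v = aliveVerts[rng.runif_int((int)aliveVerts.size())];
    if (delta_v <= 0) return true;
    std::vector<int> tset = vtris[v];
    bool ok = true;
    double e0 = localEnergy(tset, &ok);
    V3 old = pos[v];
    pos[v] = old + V3((2 * rng.runif() - 1) * delta_v,
                      (2 * rng.runif() - 1) * delta_v,
                      (2 * rng.runif() - 1) * delta_v);
    bool ok2 = true;
    double e1 = localEnergy(tset, &ok2);
    double dE = e1 - e0;
    if (!ok2 || (dE > 0 && rng.runif() > std::exp(-dE))) {
      pos[v] = old;
      return false;
    }
    return true;
  }

  // ------------------------------------------------- association helpers
  // ideal apex for attachment at free halfedge he: equilateral triangle on
  // the far side folded to the preferred dihedral of the edge type
  V3 idealApex(int he) const {
    int t = he / 3, k = he % 3;
    V3 u = pos[tris[t].v[k]];
    V3 v = pos[tris[t].v[NEXT[k]]];
    V3 o = pos[tris[t].v[PREV[k]]];
    V3 mid = (u + v) * 0.5;
    V3 e = v - u; e = e * (1.0 / e.norm());
    V3 d = o - mid; d = d - e * d.dot(e);
    double dn = d.norm();
    d = d * (1.0 / std::max(dn, 1e-12));
    V3 n = (v - u).cross(o - u);
    n = n * (1.0 / std::max(n.norm(), 1e-12));
    double ang = M_PI - theta0[TYPE[k] - 1];
    double h = 0.8660254037844386 * l0;
    return mid + (d * (-std::cos(ang)) - n * std::sin(ang)) * h;
  }
  bool apexInCube(const V3& apex, const V3& center) const {
    return std::fabs(apex.x - center.x) <= wp &&
           std::fabs(apex.y - center.y) <= wp &&
           std::fabs(apex.z - center.z) <= wp;
  }
  // removable monomer: exactly one bound edge and unshared apex vertex
  bool isRemovable(int t) const {
    if (!tris[t].alive) return false;
    int nb = 0, kb = -1;
    for (int k = 0; k < 3; ++k)
      if (tris[t].opp[k] >= 0) { nb++; kb = k; }
    if (nb != 1 || nTri <= 1) return false;
    int apex = tris[t].v[PREV[kb]];
    return vtris[apex].size() == 1;
  }
  int countRemovable() const {
    int n = 0;
    for (size_t t = 0; t < tris.size(); ++t)
      if (tris[t].alive && isRemovable((int)t)) n++;
    return n;
  }

  bool attemptAssociation() {
    if (freeHE.empty()) return false;
    if (max_monomers > 0 && nTri >= max_monomers) return false;
    int he = freeHE[rng.runif_int((int)freeHE.size())];
    int t = he / 3, k = he % 3;
    V3 center = idealApex(he);
    V3 apex = center + V3((2 * rng.runif() - 1) * wp,
                          (2 * rng.runif() - 1) * wp,
                          (2 * rng.runif() - 1) * wp);
    int u = tris[t].v[k], v = tris[t].v[NEXT[k]];
    // energy of the insertion: two new free edges + the new dihedral - EB
    V3 du = pos[u] - apex, dv = pos[v] - apex;
    double lu = du.norm(), lv = dv.norm();
    double dE = 0.5 * kS * ((lu - l0) * (lu - l0) + (lv - l0) * (lv - l0));
    // dihedral: plane of (v,u,apex) vs plane of t
    V3 n2 = (pos[u] - pos[v]).cross(apex - pos[v]);
    const Tri& A = tris[t];
    V3 n1 = (pos[A.v[1]] - pos[A.v[0]]).cross(pos[A.v[2]] - pos[A.v[0]]);
    double m1 = n1.norm(), m2 = n2.norm();
    if (m1 < 1e-12 || m2 < 1e-12) return false;
    n1 = n1 * (1.0 / m1); n2 = n2 * (1.0 / m2);
    V3 e = pos[v] - pos[u]; e = e * (1.0 / e.norm());
    double phi = std::atan2(n1.cross(n2).dot(e), n1.dot(n2));
    double th = M_PI - phi;
    double dth = th - theta0[TYPE[k] - 1];
    dE += 0.5 * Bmod * dth * dth - EB;
    // proposal bookkeeping
    double W0 = totalWeight();
    int nFree1 = nFree() + 1;               // after: -1 bound, +2 new free
    // removable monomers after insertion: the new monomer is always
    // removable; t stops being removable once it gains a second bound edge;
    // from a single monomer both halves of the new dimer are removable
    int nRem1 = (nTri == 1) ? 2
                : countRemovable() + 1 - (isRemovable(t) ? 1 : 0);
    double W1 = totalWeightWith(nVerts() + 1, nFree1,
                                (int)boundList.size() + 1);
    double acc = std::exp(mu - dE) * ((double)nFree1 * W0) / (W1 * nRem1);
    if (rng.runif() >= acc) return false;
    // apply
    int x = newVertex(apex);
    int ty = TYPE[k];
    int kk = 0; while (TYPE[kk] != ty) kk++;
    int nv[3]; nv[kk] = v; nv[NEXT[kk]] = u; nv[PREV[kk]] = x;
    int tn = newTriangle(nv[0], nv[1], nv[2]);
    tris[t].opp[k] = 3 * tn + kk;
    tris[tn].opp[kk] = he;
    heUnmarkFree(he);
    heMarkFree(3 * tn + NEXT[kk]);
    heMarkFree(3 * tn + PREV[kk]);
    nBound++;
    bpAdd(std::min(he, 3 * tn + kk));
    n_insert++;
    return true;
  }

  bool attemptDissociation() {
    // collect removable monomers
    std::vector<int> rem;
    for (size_t t = 0; t < tris.size(); ++t)
      if (tris[t].alive && isRemovable((int)t)) rem.push_back((int)t);
    if (rem.empty()) return false;
    int t = rem[rng.runif_int((int)rem.size())];
    int kb = -1;
    for (int k = 0; k < 3; ++k) if (tris[t].opp[k] >= 0) kb = k;
    int apex = tris[t].v[PREV[kb]];
    int heB = tris[t].opp[kb];              // partner halfedge (stays, frees)
    // reverse-insertion support: apex must lie in the proposal cube
    V3 center = idealApex_of_partner(heB);
    if (!apexInCube(pos[apex], center)) return false;
    // energy change: remove two free edges + the bound dihedral, +EB
    int heF1 = 3 * t + NEXT[kb], heF2 = 3 * t + PREV[kb];
    bool ok = true;
    double dE = -(stretchHE(heF1) + stretchHE(heF2)) - bendHE(3 * t + kb, &ok) + EB;
    if (!ok) return false;
    double W0 = totalWeight();
    int nFree1 = nFree() - 1;
    double W1 = totalWeightWith(nVerts() - 1, nFree1,
                                (int)boundList.size() - 1);
    double acc = std::exp(-mu - dE) * ((double)rem.size() * W0) /
                 (W1 * (double)nFree());
    if (rng.runif() >= acc) return false;
    // apply
    heUnmarkFree(heF1); heUnmarkFree(heF2);
    bpRemove(std::min(heB, 3 * t + kb));
    tris[heB / 3].opp[heB % 3] = -1;
    heMarkFree(heB);
    nBound--;
    for (int k = 0; k < 3; ++k) removeTriFromVertex(tris[t].v[k], t);
    tris[t].alive = false; nTri--; freeTriSlots.push_back(t);
    dropVertex(apex);
    n_delete++;
    return true;
  }
  // ideal apex position as the reverse insertion at partner halfedge would
  // compute it once the monomer is gone: geometry of the remaining triangle
  V3 idealApex_of_partner(int heB) const { return idealApex(heB); }

  // --------------------------------------------------- fusion and fission
  //
  // Channels are either a fusable pair of free halfedges or a fissionable
  // bound edge.  They fall into two classes: "seam" channels share at least
  // one endpoint (a growth notch or crack; fission splits <= 1 vertex) and
  // are attempted per channel at the monomer-binding timescale p_seam;
  // "closure" channels join two distant boundary segments (two vertex
  // merges; fission splits 2) and are attempted per channel at f_fusion,
  // the control parameter for tubule closure and reopening.  Channel
  // selection is uniform over the cheap superset {free halfedges} + {bound
  // edges} (invalid picks are null moves), so the class attempt weight is
  // rate * (n_free + n_bound); the acceptance carries the exact W ratios,
  // partner-degeneracy counts 1/d, and the reversible-jump volume factor
  // per merged/split vertex.

  // halfedges between vertices a,b (either direction), excluding he1, he2
  int countHEbetween(int a, int b, int ex1, int ex2) const {
    int c = 0;
    for (int t : vtris[a]) {
      for (int k = 0; k < 3; ++k) {
        int he = 3 * t + k;
        if (he == ex1 || he == ex2) continue;
        int f = heFrom(he), g = heTo(he);
        if ((f == a && g == b) || (f == b && g == a)) c++;
      }
    }
    return c;
  }
  // after merging a<-{a1,a2}: for every common neighbour w, the number of
  // halfedges between the merged vertex and w must stay <= 2, and an
  // existing bound edge (2 halfedges) must not gain more
  bool edgeMultOK(int a1, int a2, int b1, int b2, int h1, int h2) const {
    for (int t : vtris[a2]) {
      for (int k = 0; k < 3; ++k) {
        int he = 3 * t + k;
        if (he == h1 || he == h2) continue;
        int f = heFrom(he), g = heTo(he);
        int w = -1;
        if (f == a2) w = g; else if (g == a2) w = f;
        if (w < 0) continue;
        int weq = (w == b2) ? b1 : w;        // w may itself be merged
        int c2 = countHEbetween(a1, weq, h1, h2);
        int cSelf = countHEbetween(a2, w, h1, h2);
        if (c2 + cSelf > 2) return false;
        if (c2 == 2) return false;
      }
    }
    return true;
  }

  bool vertexOnBoundary(int v) const {
    for (int t : vtris[v])
      for (int k = 0; k < 3; ++k)
        if (tris[t].opp[k] < 0 &&
            (tris[t].v[k] == v || tris[t].v[NEXT[k]] == v)) return true;
    return false;
  }
  bool fissionEligible(int he) const {
    return vertexOnBoundary(heFrom(he)) || vertexOnBoundary(heTo(he));
  }

  // valid fusion partners of free halfedge h1 within one class; the
  // relation is symmetric, as detailed balance requires
  std::vector<int> partnersOf(int h1, bool seam) const {
    std::vector<int> out;
    int u = heFrom(h1), v = heTo(h1);
    for (int idx = 0; idx < (int)freeHE.size(); ++idx) {
      int h2 = freeHE[idx];
      if (h2 == h1 || h2 / 3 == h1 / 3) continue;
      if (heType(h2) != heType(h1)) continue;
      int p = heFrom(h2), q = heTo(h2);
      if (u == p || v == q) continue;       // would collapse an edge
      bool tip1 = (u == q), tip2 = (v == p);
      if (seam != (tip1 || tip2)) continue;
      if (!tip1) {
        V3 d = pos[u] - pos[q];
        if (std::fabs(d.x) >= r_c || std::fabs(d.y) >= r_c ||
            std::fabs(d.z) >= r_c) continue;
      }
      if (!tip2) {
        V3 d = pos[v] - pos[p];
        if (std::fabs(d.x) >= r_c || std::fabs(d.y) >= r_c ||
            std::fabs(d.z) >= r_c) continue;
      }
      // manifold: nothing else may land on the fused vertex pair, and no
      // pair around the merged vertices may exceed two halfedges
      if (countHEbetween(u, v, h1, h2) + countHEbetween(p, q, h1, h2) +
          countHEbetween(u, p, h1, h2) + countHEbetween(q, v, h1, h2) > 0)
        continue;
      if (!tip1 && !edgeMultOK(u, q, v, p, h1, h2)) continue;
      if (!tip2 && !edgeMultOK(v, p, u, q, h1, h2)) continue;
      out.push_back(h2);
    }
    return out;
  }

  // triangles reachable from t0 around vertex x via bound edges, excluding
  // the pair (h1,h2)
  std::vector<int> fanComponent(int x, int t0, int h1, int h2) const {
    std::vector<int> comp{t0};
    std::vector<int> stack{t0};
    while (!stack.empty()) {
      int t = stack.back(); stack.pop_back();
      for (int k = 0; k < 3; ++k) {
        int he = 3 * t + k, o = tris[t].opp[k];
        if (o < 0 || he == h1 || he == h2) continue;
        if (tris[t].v[k] != x && tris[t].v[NEXT[k]] != x) continue;
        int t2 = o / 3;
        if (std::find(comp.begin(), comp.end(), t2) == comp.end()) {
          comp.push_back(t2); stack.push_back(t2);
        }
      }
    }
    return comp;
  }
  bool globallyConnectedWithout(int h1, int h2) const {
    int t0 = h1 / 3, tgt = h2 / 3;
    std::vector<char> seen(tris.size(), 0);
    std::vector<int> stack{t0};
    seen[t0] = 1;
    while (!stack.empty()) {
      int t = stack.back(); stack.pop_back();
      if (t == tgt) return true;
      for (int k = 0; k < 3; ++k) {
        int he = 3 * t + k, o = tris[t].opp[k];
        if (o < 0 || he == h1 || o == h1) continue;
        int t2 = o / 3;
        if (!seen[t2]) { seen[t2] = 1; stack.push_back(t2); }
      }
    }
    return false;
  }

  bool attemptSeamClosure(bool seam) {
    int C = nFree() + (int)boundList.size();
    if (C == 0) return false;
    int pick = rng.runif_int(C);
    if (pick < nFree()) {
      int h1 = freeHE[pick];
      std::vector<int> cand = partnersOf(h1, seam);
      if (cand.empty()) return false;
      int h2 = cand[rng.runif_int((int)cand.size())];
      int d2 = (int)partnersOf(h2, seam).size();
      return doFusion(h1, h2, (int)cand.size(), d2);
    }
    int key = boundList[pick - nFree()];
    return doFission(key, seam);
  }

  bool doFusion(int h1, int h2, int d1, int d2) {
    int u = heFrom(h1), v = heTo(h1), p = heFrom(h2), q = heTo(h2);
    bool tip1 = (u == q), tip2 = (v == p);
    int nMerge = (tip1 ? 0 : 1) + (tip2 ? 0 : 1);
    std::vector<int> tset;
    for (int w : {u, v, p, q})
      for (int t : vtris[w]) tset.push_back(t);
    std::sort(tset.begin(), tset.end());
    tset.erase(std::unique(tset.begin(), tset.end()), tset.end());
    bool ok0 = true;
    double e0 = localEnergy(tset, &ok0);
    double W0 = totalWeight();
    // apply: merge vertices (positions averaged), link pair
    V3 oldU = pos[u], oldQ = pos[q], oldV = pos[v], oldP = pos[p];
    std::vector<std::pair<int,int>> rewired;
    if (!tip1) mergeVertexInto(q, u, rewired);
    if (!tip2) mergeVertexInto(p, v, rewired);
    if (!tip1) pos[u] = (oldU + oldQ) * 0.5;
    if (!tip2) pos[v] = (oldV + oldP) * 0.5;
    tris[h1 / 3].opp[h1 % 3] = h2;
    tris[h2 / 3].opp[h2 % 3] = h1;
    heUnmarkFree(h1); heUnmarkFree(h2);
    nBound++;
    bpAdd(std::min(h1, h2));
    bool ok1 = true;
    double e1 = localEnergy(tset, &ok1);
    double dE = e1 - e0 - EB;
    double W1 = totalWeight();
    double vp = 8.0 * wp * wp * wp;
    double volfac = std::pow(vp / (8.0 * r_c * r_c * r_c), nMerge);
    // reverse fission must be possible (interior-locked edges cannot split)
    bool rev_ok = fissionEligible(h1);
    double acc = (ok1 && rev_ok) ? std::exp(-dE) * volfac * W0 /
                 (W1 * (1.0 / d1 + 1.0 / d2)) : 0.0;
    if (rng.runif() >= acc) {
      bpRemove(std::min(h1, h2));
      nBound--;
      tris[h1 / 3].opp[h1 % 3] = -1;
      tris[h2 / 3].opp[h2 % 3] = -1;
      heMarkFree(h1); heMarkFree(h2);
      for (auto it = rewired.rbegin(); it != rewired.rend(); ++it) {
        int t = it->first, k = it->second;
        int cur = tris[t].v[k];
        int orig = (cur == u) ? q : p;
        tris[t].v[k] = orig;
        removeTriFromVertex(cur, t);
        vtris[orig].push_back(t);
      }
      if (!tip1) { pos[u] = oldU; if (!vAlive[q]) reviveVertex(q, oldQ); else pos[q] = oldQ; }
      if (!tip2) { pos[v] = oldV; if (!vAlive[p]) reviveVertex(p, oldP); else pos[p] = oldP; }
      return false;
    }
    n_fuse++;
    return true;
  }
  double totalWeightWith(int nv, int nf, int nb) const {
    return (double)nv + p_exchange * nf + (p_seam + f_fusion) * (nf + nb);
  }
  void mergeVertexInto(int from, int into, std::vector<std::pair<int,int>>& rewired) {
    std::vector<int> ts = vtris[from];
    for (int t : ts) {
      for (int k = 0; k < 3; ++k) {
        if (tris[t].v[k] == from) {
          tris[t].v[k] = into;
          rewired.push_back({t, k});
          vtris[into].push_back(t);
        }
      }
    }
    vtris[from].clear();
    dropVertex(from);
  }
  void reviveVertex(int v, const V3& p) {
    for (size_t i = 0; i < freeVertSlots.size(); ++i)
      if (freeVertSlots[i] == v) {
        freeVertSlots[i] = freeVertSlots.back(); freeVertSlots.pop_back();
        break;
      }
    pos[v] = p; vAlive[v] = 1;
    vposIdx[v] = (int)aliveVerts.size();
    aliveVerts.push_back(v);
  }

  bool doFission(int h1, bool seam) {
    int h2 = tris[h1 / 3].opp[h1 % 3];
    if (!fissionEligible(h1)) return false;   // interior edges are locked
    int u = heFrom(h1), v = heTo(h1);
    std::vector<int> fanU = fanComponent(u, h2 / 3, h1, h2);
    bool splitU = std::find(fanU.begin(), fanU.end(), h1 / 3) == fanU.end();
    std::vector<int> fanV = fanComponent(v, h2 / 3, h1, h2);
    bool splitV = std::find(fanV.begin(), fanV.end(), h1 / 3) == fanV.end();
    int nSplit = (splitU ? 1 : 0) + (splitV ? 1 : 0);
    if (seam != (nSplit <= 1)) return false;  // channel class mismatch
    if (splitU && splitV && !globallyConnectedWithout(h1, h2))
      return false;                            // would break the structure
    std::vector<int> tset;
    for (int w : {u, v}) for (int t : vtris[w]) tset.push_back(t);
    std::sort(tset.begin(), tset.end());
    tset.erase(std::unique(tset.begin(), tset.end()), tset.end());
    bool ok0 = true;
    double e0 = localEnergy(tset, &ok0);
    double W0 = totalWeight();
    // apply: unbind, split vertices with +/- delta displacements
    bpRemove(std::min(h1, h2));
    tris[h1 / 3].opp[h1 % 3] = -1;
    tris[h2 / 3].opp[h2 % 3] = -1;
    heMarkFree(h1); heMarkFree(h2);
    nBound--;
    V3 oldU = pos[u], oldV = pos[v];
    std::vector<std::pair<int,int>> rewiredU, rewiredV;
    int newU = -1, newV = -1;
    if (splitU) {
      V3 d((rng.runif() - 0.5) * r_c, (rng.runif() - 0.5) * r_c,
           (rng.runif() - 0.5) * r_c);
      newU = splitVertex(u, fanU, oldU - d, rewiredU);
      pos[u] = oldU + d;
    }
    if (splitV) {
      V3 d((rng.runif() - 0.5) * r_c, (rng.runif() - 0.5) * r_c,
           (rng.runif() - 0.5) * r_c);
      newV = splitVertex(v, fanV, oldV - d, rewiredV);
      pos[v] = oldV + d;
    }
    std::vector<int> tset2;
    for (int w : {u, v, newU, newV}) {
      if (w < 0) continue;
      for (int t : vtris[w]) tset2.push_back(t);
    }
    std::sort(tset2.begin(), tset2.end());
    tset2.erase(std::unique(tset2.begin(), tset2.end()), tset2.end());
    bool ok1 = true;
    double e1 = localEnergy(tset2, &ok1);
    double dE = e1 - e0 + EB;
    double W1 = totalWeight();
    // reverse fusion: the freed pair must see each other as partners
    std::vector<int> c1 = partnersOf(h1, seam);
    bool mutual = std::find(c1.begin(), c1.end(), h2) != c1.end();
    int d1 = (int)c1.size();
    int d2 = mutual ? (int)partnersOf(h2, seam).size() : 0;
    double vp = 8.0 * wp * wp * wp;
    double volfac = std::pow(8.0 * r_c * r_c * r_c / vp, nSplit);
    double acc = (ok1 && mutual && d2 > 0) ? std::exp(-dE) * volfac *
                 W0 * (1.0 / d1 + 1.0 / d2) / W1 : 0.0;
    if (rng.runif() >= acc) {
      if (splitV) undoSplit(v, newV, oldV, rewiredV);
      if (splitU) undoSplit(u, newU, oldU, rewiredU);
      heUnmarkFree(h1); heUnmarkFree(h2);
      tris[h1 / 3].opp[h1 % 3] = h2;
      tris[h2 / 3].opp[h2 % 3] = h1;
      nBound++;
      bpAdd(std::min(h1, h2));
      return false;
    }
    n_fiss++;
    return true;
  }
  int splitVertex(int x, const std::vector<int>& fan, const V3& p,
                  std::vector<std::pair<int,int>>& rewired) {
    int nx = newVertex(p);
    for (int t : fan) {
      for (int k = 0; k < 3; ++k) {
        if (tris[t].v[k] == x) {
          tris[t].v[k] = nx;
          rewired.push_back({t, k});
          removeTriFromVertex(x, t);
          vtris[nx].push_back(t);
        }
      }
    }
    return nx;
  }
  void undoSplit(int x, int nx, const V3& oldPos,
                 const std::vector<std::pair<int,int>>& rewired) {
    for (auto& tk : rewired) {
      tris[tk.first].v[tk.second] = x;
      vtris[x].push_back(tk.first);
    }
    pos[x] = oldPos;
    vtris[nx].clear();
    dropVertex(nx);
  }

  // ------------------------------------------------------- boundary cycles
  int boundaryCycleCount() const {
    std::vector<int> frees = freeHE;
    std::vector<char> used(tris.size() * 3, 0);
    int cycles = 0;
    for (int h0 : frees) {
      if (used[h0]) continue;
      cycles++;
      int h = h0;
      int guard = 0;
      do {
        used[h] = 1;
        // walk fan at head(h) to the outgoing free halfedge
        int t = h / 3, k = NEXT[h % 3];
        int g = 3 * t + k;
        while (tris[g / 3].opp[g % 3] >= 0) {
          int o = tris[g / 3].opp[g % 3];
          g = 3 * (o / 3) + NEXT[o % 3];
        }
        h = g;
        if (++guard > (int)frees.size() + 5) return -1;  // corrupt
      } while (h != h0);
    }
    return cycles;
  }

  // full energy (for diagnostics/tests)
  double totalEnergyFull() const {
    double e = 0.0;
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!tris[t].alive) continue;
      for (int k = 0; k < 3; ++k) {
        int he = 3 * (int)t + k;
        e += stretchHE(he);
        int o = tris[t].opp[k];
        if (o >= 0 && he < o) { bool ok; e += bendHE(he, &ok); }
      }
    }
    return e - EB * nBound;
  }
};

// helper: initialize engine from R matrices (vertices Vx3 double, triangles
// Tx3 int 1-based); reconstructs opp links from shared vertex pairs
static void initEngine(Engine& E, NumericMatrix verts, IntegerMatrix tr) {
  int V = verts.nrow(), T = tr.nrow();
  for (int i = 0; i < V; ++i)
    E.newVertex(V3(verts(i, 0), verts(i, 1), verts(i, 2)));
  for (int t = 0; t < T; ++t)
    E.newTriangle(tr(t, 0) - 1, tr(t, 1) - 1, tr(t, 2) - 1);
  // link opposite halfedges
  std::vector<std::vector<std::pair<long long, int>>> dummy;
  std::vector<std::pair<long long, int>> keys;
  keys.reserve(3 * T);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < 3; ++k) {
      long long a = E.tris[t].v[k], b = E.tris[t].v[NEXT[k]];
      long long lo = std::min(a, b), hi = std::max(a, b);
      keys.push_back({lo * 1000000LL + hi, 3 * t + k});
    }
  std::sort(keys.begin(), keys.end());
  for (size_t i = 0; i + 1 < keys.size(); ++i) {
    if (keys[i].first == keys[i + 1].first) {
      int h1 = keys[i].second, h2 = keys[i + 1].second;
      E.tris[h1 / 3].opp[h1 % 3] = h2;
      E.tris[h2 / 3].opp[h2 % 3] = h1;
      E.nBound++;
      ++i;
    }
  }
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < 3; ++k) {
      int he = 3 * t + k, o = E.tris[t].opp[k];
      if (o < 0) E.heMarkFree(he);
      else if (he < o) E.bpAdd(he);
    }
}

static List snapshotMesh(const Engine& E) {
  // compact alive vertices/triangles to 1-based R matrices
  std::vector<int> vmap(E.pos.size(), -1);
  int nv = 0;
  for (size_t v = 0; v < E.pos.size(); ++v)
    if (E.vAlive[v]) vmap[v] = nv++;
  NumericMatrix verts(nv, 3);
  for (size_t v = 0; v < E.pos.size(); ++v)
    if (E.vAlive[v]) {
      verts(vmap[v], 0) = E.pos[v].x;
      verts(vmap[v], 1) = E.pos[v].y;
      verts(vmap[v], 2) = E.pos[v].z;
    }
  int nt = 0;
  std::vector<int> tmap(E.tris.size(), -1);
  for (size_t t = 0; t < E.tris.size(); ++t)
    if (E.tris[t].alive) tmap[t] = nt++;
  IntegerMatrix tr(nt, 3);
  for (size_t t = 0; t < E.tris.size(); ++t) {
    if (!E.tris[t].alive) continue;
    for (int k = 0; k < 3; ++k) tr(tmap[t], k) = vmap[E.tris[t].v[k]] + 1;
  }
  // explicit bound pairs: a zero-width crack (two coincident FREE halfedges)
  // is otherwise indistinguishable from a bound edge in (vertices,triangles)
  std::vector<std::array<int, 4>> bp;
  for (size_t t = 0; t < E.tris.size(); ++t) {
    if (!E.tris[t].alive) continue;
    for (int k = 0; k < 3; ++k) {
      int he = 3 * (int)t + k, o = E.tris[t].opp[k];
      if (o >= 0 && he < o)
        bp.push_back({tmap[t] + 1, k + 1, tmap[o / 3] + 1, (o % 3) + 1});
    }
  }
  IntegerMatrix bpm((int)bp.size(), 4);
  for (size_t i = 0; i < bp.size(); ++i)
    for (int j = 0; j < 4; ++j) bpm((int)i, j) = bp[i][j];
  return List::create(_["vertices"] = verts, _["triangles"] = tr,
                      _["bound_pairs"] = bpm);
}

// [[Rcpp::export(name = ".run_trajectory_cpp")]]
List run_trajectory_cpp(NumericMatrix verts, IntegerMatrix triangles,
                        NumericVector theta0, double E_B, double B,
                        double k_S, double l0, double mu,
                        double f_fusion, double p_seam, double p_exchange,
                        double delta_v, double r_c, double wp,
                        double max_sweeps, int stop_N,
                        int max_monomers, double record_every,
                        int seed, bool log_bound_types) {
  Engine E((uint64_t)seed * 2654435761ULL + 1ULL);
  E.EB = E_B; E.Bmod = B; E.kS = k_S; E.l0 = l0; E.mu = mu;
  for (int i = 0; i < 3; ++i) E.theta0[i] = theta0[i];
  E.f_fusion = f_fusion; E.p_seam = p_seam; E.p_exchange = p_exchange;
  E.delta_v = delta_v; E.r_c = r_c; E.wp = wp;
  E.max_monomers = max_monomers;
  initEngine(E, verts, triangles);

  double tau = 0.0, nextRec = 0.0;
  std::vector<double> recTau;
  std::vector<int> recN, recBound, recCycles, recBTypes;
  int cycles = E.boundaryCycleCount();

  auto record = [&]() {
    recTau.push_back(tau);
    recN.push_back(E.nTri);
    recBound.push_back(E.nBound);
    recCycles.push_back(cycles);
    if (log_bound_types) {
      int code = 0;
      int cnt[4] = {0, 0, 0, 0};
      for (size_t t = 0; t < E.tris.size(); ++t) {
        if (!E.tris[t].alive) continue;
        for (int k = 0; k < 3; ++k) {
          int he = 3 * (int)t + k, o = E.tris[t].opp[k];
          if (o >= 0 && he < o) cnt[TYPE[k]]++;
        }
      }
      code = cnt[1] + 16 * cnt[2] + 256 * cnt[3];
      recBTypes.push_back(code);
    }
  };
  record();

  bool finished = false;
  long guard_attempts = 0;
  while (tau < max_sweeps) {
    double W = E.totalWeight();
    double u = E.rng.runif() * W;
    double C = (double)(E.nFree() + (int)E.boundList.size());
    double a1 = (double)E.nVerts();
    double a2 = a1 + E.p_exchange * E.nFree();
    double a3 = a2 + E.p_seam * C;
    if (u < a1) {
      E.vertexMove();
    } else if (u < a2) {
      bool assoc = E.rng.runif() < 0.5;
      if (assoc) E.attemptAssociation(); else E.attemptDissociation();
    } else {
      bool acc = E.attemptSeamClosure(u < a3);
      if (acc) {
        int c2 = E.boundaryCycleCount();
        if (!E.closed_flag && cycles == 1 && c2 == 2) {
          E.closed_flag = true;
          E.N_close = E.nTri;
          E.tau_close = tau;
        }
        cycles = c2;
      }
    }
    tau += 1.0 / W;
    if (tau >= nextRec) {
      cycles = E.boundaryCycleCount();
      record();
      nextRec += record_every;
    }
    if (stop_N > 0 && E.nTri >= stop_N) { finished = true; break; }
    if (++guard_attempts > 4000000000L) break;
  }
  if (!finished && tau >= max_sweeps) finished = false;
  cycles = E.boundaryCycleCount();
  record();

  List mesh = snapshotMesh(E);
  List series = List::create(
    _["tau"] = recTau, _["N"] = recN, _["bound_edges"] = recBound,
    _["boundary_cycles"] = recCycles);
  if (log_bound_types) series["bound_type_code"] = recBTypes;
  return List::create(
    _["mesh"] = mesh, _["series"] = series,
    _["closed"] = E.closed_flag, _["N_close"] = E.N_close,
    _["tau_close"] = E.tau_close, _["tau_end"] = tau,
    _["finished"] = finished, _["N_final"] = E.nTri,
    _["boundary_cycles"] = cycles,
    _["events"] = IntegerVector::create(
      _["insertions"] = (int)E.n_insert, _["deletions"] = (int)E.n_delete,
      _["fusions"] = (int)E.n_fuse, _["fissions"] = (int)E.n_fiss),
    _["energy"] = E.totalEnergyFull());
}

// Zero-temperature quench of a fixed-topology sheet: downhill-only vertex
// moves with a geometrically shrinking step, returning the relaxed vertex
// positions (approximate minimum of stretching + bending).
// [[Rcpp::export(name = ".quench_fixed_topology_cpp")]]
NumericMatrix quench_fixed_topology_cpp(NumericMatrix verts,
                                        IntegerMatrix triangles,
                                        NumericVector theta0, double B,
                                        double k_S, double l0,
                                        int sweeps, double delta0,
                                        int seed) {
  Engine E((uint64_t)seed * 2654435761ULL + 29ULL);
  E.EB = 0.0; E.Bmod = B; E.kS = k_S; E.l0 = l0; E.mu = 0.0;
  for (int i = 0; i < 3; ++i) E.theta0[i] = theta0[i];
  E.f_fusion = 0; E.p_seam = 0; E.p_exchange = 0; E.delta_v = delta0;
  E.r_c = 0.1; E.wp = 0.5; E.max_monomers = 0;
  initEngine(E, verts, triangles);
  int V = E.nVerts();
  double shrink = std::pow(0.01, 1.0 / std::max(sweeps - 1, 1));
  double step = delta0;
  for (int sweep = 0; sweep < sweeps; ++sweep) {
    for (int it = 0; it < V; ++it) {
      int v = E.aliveVerts[E.rng.runif_int(V)];
      std::vector<int>& tset = E.vtris[v];
      bool ok0 = true;
      double e0 = E.localEnergy(tset, &ok0);
      V3 old = E.pos[v];
      E.pos[v] = old + V3((2 * E.rng.runif() - 1) * step,
                          (2 * E.rng.runif() - 1) * step,
                          (2 * E.rng.runif() - 1) * step);
      bool ok1 = true;
      double e1 = E.localEnergy(tset, &ok1);
      if (!ok1 || e1 >= e0) E.pos[v] = old;
    }
    step *= shrink;
  }
  NumericMatrix out(V, 3);
  for (int i = 0; i < V; ++i) {
    out(i, 0) = E.pos[i].x; out(i, 1) = E.pos[i].y; out(i, 2) = E.pos[i].z;
  }
  return out;
}

// Fixed-topology vertex-move sampler.  Samples the mixed Hamiltonian
//   H_lambda = lambda * H_model + (1 - lambda) * H_ref + H_anchor
// with H_model = stretching + bending (binding is constant at fixed
// topology), H_ref = sum (k_t/2)|x - x_ref|^2 over all vertices, and
// H_anchor = sum (k_anchor/2)|x - x_ref|^2 over `anchors` (1-based ids),
// which pins rigid-body modes at all lambda.  Returns per-sweep samples of
// H_model and H_ref after equilibration.
// [[Rcpp::export(name = ".sample_fixed_topology_cpp")]]
List sample_fixed_topology_cpp(NumericMatrix verts, IntegerMatrix triangles,
                               NumericVector theta0, double B, double k_S,
                               double l0, double lambda, double k_t,
                               IntegerVector anchors, double k_anchor,
                               int sweeps_eq, int sweeps_sample,
                               double delta_v, int seed,
                               bool return_positions = false) {
  Engine E((uint64_t)seed * 2654435761ULL + 17ULL);
  E.EB = 0.0; E.Bmod = B; E.kS = k_S; E.l0 = l0; E.mu = 0.0;
  for (int i = 0; i < 3; ++i) E.theta0[i] = theta0[i];
  E.f_fusion = 0; E.p_seam = 0; E.p_exchange = 0; E.delta_v = delta_v;
  E.r_c = 0.1; E.wp = 0.5; E.max_monomers = 0;
  initEngine(E, verts, triangles);
  int V = E.nVerts();
  std::vector<V3> ref(V);
  for (int i = 0; i < V; ++i) ref[i] = E.pos[i];
  std::vector<double> kanc(V, 0.0);
  for (int i = 0; i < anchors.size(); ++i) kanc[anchors[i] - 1] = k_anchor;

  auto refE = [&](int v) {
    V3 d = E.pos[v] - ref[v];
    double r2 = d.dot(d);
    return 0.5 * (k_t * (1.0 - lambda) + kanc[v]) * r2;
  };
  long acc = 0, tot = 0;
  std::vector<double> sModel, sRef;
  sModel.reserve(sweeps_sample); sRef.reserve(sweeps_sample);
  NumericMatrix posOut;
  if (return_positions) posOut = NumericMatrix(3 * V, sweeps_sample);
  int sampIdx = 0;
  for (int sweep = 0; sweep < sweeps_eq + sweeps_sample; ++sweep) {
    for (int it = 0; it < V; ++it) {
      int v = E.aliveVerts[E.rng.runif_int(V)];
      std::vector<int>& tset = E.vtris[v];
      bool ok0 = true;
      double e0 = lambda * E.localEnergy(tset, &ok0) + refE(v);
      V3 old = E.pos[v];
      E.pos[v] = old + V3((2 * E.rng.runif() - 1) * delta_v,
                          (2 * E.rng.runif() - 1) * delta_v,
                          (2 * E.rng.runif() - 1) * delta_v);
      bool ok1 = true;
      double e1 = lambda * E.localEnergy(tset, &ok1) + refE(v);
      double dE = e1 - e0;
      tot++;
      if (!ok1 || (dE > 0 && E.rng.runif() > std::exp(-dE))) E.pos[v] = old;
      else acc++;
    }
    if (sweep >= sweeps_eq) {
      double em = E.totalEnergyFull();     // EB = 0: stretch + bend only
      double er = 0.0;
      for (int i = 0; i < V; ++i) {
        V3 d = E.pos[i] - ref[i];
        er += 0.5 * k_t * d.dot(d);
      }
      sModel.push_back(em);
      sRef.push_back(er);
      if (return_positions) {
        for (int i = 0; i < V; ++i) {
          posOut(3 * i + 0, sampIdx) = E.pos[i].x;
          posOut(3 * i + 1, sampIdx) = E.pos[i].y;
          posOut(3 * i + 2, sampIdx) = E.pos[i].z;
        }
        sampIdx++;
      }
    }
  }
  List out = List::create(
    _["H_model"] = sModel, _["H_ref"] = sRef,
    _["acceptance"] = (double)acc / std::max(tot, 1L));
  if (return_positions) out["positions"] = posOut;
  return out;
}

// Stretching + bending energy of a static sheet (diagnostics and numeric
// Hessians in tests); binding is -E_B per bound pair, added by the caller.
// [[Rcpp::export(name = ".sheet_energy_cpp")]]
double sheet_energy_cpp(NumericMatrix verts, IntegerMatrix triangles,
                        NumericVector theta0, double B, double k_S,
                        double l0) {
  Engine E(1u);
  E.EB = 0.0; E.Bmod = B; E.kS = k_S; E.l0 = l0; E.mu = 0.0;
  for (int i = 0; i < 3; ++i) E.theta0[i] = theta0[i];
  E.f_fusion = 0; E.p_seam = 0; E.p_exchange = 0; E.delta_v = 0;
  E.r_c = 0.1; E.wp = 0.5; E.max_monomers = 0;
  initEngine(E, verts, triangles);
  return E.totalEnergyFull();
}
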