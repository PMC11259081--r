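// Monte Carlo core of rwsim.
//
// The whole simulation state lives here while a run executes: an N x N
// toroidal grid of rooms holding nucleotide precursors (counts), free
// nucleotides (counts per base) and RNA entities.  An entity is either a
// plain strand (linear or circular) or a template complex: a template
// strand plus bound substrate segments.  One Monte Carlo step applies ten
// event phases in a fixed, documented order; all randomness comes from a
// single mt19937_64 generator so a (config, seed) pair replays exactly.
//
// Conventions: bases are coded 0=A, 1=C, 2=G, 3=U (Watson-Crick complement
// is 3-b); sequences are 5'->3'; template positions are 0-based, taken
// modulo length on circular templates.  A bound segment's `start` is the
// template position paired by the substrate's 3'-most residue, so substrate
// index j pairs template position start + len-1 - j (antiparallel).

#include <Rcpp.h>
#include <random>
#include <sstream>
#include <string>
#include <vector>
#include <array>
#include <map>
#include <deque>
#include <chrono>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const char BASES[4] = {'A', 'C', 'G', 'U'};

static inline int base_index(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'U': return 3;
  }
  return -1;
}
static inline int comp_base(int b) { return 3 - b; }

typedef std::vector<uint8_t> Seq;

static Seq seq_from_string(const std::string& s) {
  Seq out(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base_index(s[i]);
    if (b < 0) stop("invalid RNA base '%s' in sequence '%s'", std::string(1, s[i]), s);
    out[i] = (uint8_t)b;
  }
  return out;
}
static std::string seq_to_string(const Seq& s) {
  std::string out(s.size(), 'A');
  for (size_t i = 0; i < s.size(); ++i) out[i] = BASES[s[i]];
  return out;
}

static bool seq_search(const Seq& hay, const Seq& needle) {
  if (needle.empty()) return true;
  if (needle.size() > hay.size()) return false;
  return std::search(hay.begin(), hay.end(), needle.begin(), needle.end()) != hay.end();
}

// rotation-invariant containment: substring test on the doubled ring
static bool seq_contains(const Seq& s, bool circular, const Seq& motif) {
  if (motif.empty()) return true;
  if (motif.size() > s.size()) return false;
  if (!circular) return seq_search(s, motif);
  Seq d(s);
  d.insert(d.end(), s.begin(), s.end());
  return seq_search(d, motif);
}

// canonical form of a ring: lexicographically smallest rotation
static Seq canonical_rotation_cpp(const Seq& s) {
  size_t n = s.size();
  if (n <= 1) return s;
  size_t best = 0;
  for (size_t cand = 1; cand < n; ++cand) {
    for (size_t k = 0; k < n; ++k) {
      uint8_t a = s[(cand + k) % n], b = s[(best + k) % n];
      if (a < b) { best = cand; break; }
      if (a > b) break;
    }
  }
  Seq out(n);
  for (size_t k = 0; k < n; ++k) out[k] = s[(best + k) % n];
  return out;
}

static Seq revcomp_cpp(const Seq& s) {
  Seq out(s.size());
  for (size_t i = 0; i < s.size(); ++i) out[s.size() - 1 - i] = (uint8_t)comp_base(s[i]);
  return out;
}

// ---------------------------------------------------------------------------
// parameters

struct Pars {
  double P_AT, P_BB, P_EL, P_FP, P_MN, P_MNP, P_ND, P_NDE, P_NF, P_NFR,
         P_RL, P_SP, P_TL, P_TLR;
  int N;
  double T_NPB;
  int T_REP, T_NR;
  double F_DA, F_LT;
  Seq CS_REP, CS_NR, CS_CT;
};

static Pars pars_from_list(List p) {
  Pars P;
  P.P_AT = as<double>(p["P_AT"]);   P.P_BB = as<double>(p["P_BB"]);
  P.P_EL = as<double>(p["P_EL"]);   P.P_FP = as<double>(p["P_FP"]);
  P.P_MN = as<double>(p["P_MN"]);   P.P_MNP = as<double>(p["P_MNP"]);
  P.P_ND = as<double>(p["P_ND"]);   P.P_NDE = as<double>(p["P_NDE"]);
  P.P_NF = as<double>(p["P_NF"]);   P.P_NFR = as<double>(p["P_NFR"]);
  P.P_RL = as<double>(p["P_RL"]);   P.P_SP = as<double>(p["P_SP"]);
  P.P_TL = as<double>(p["P_TL"]);   P.P_TLR = as<double>(p["P_TLR"]);
  P.N = as<int>(p["N"]);
  P.T_NPB = as<double>(p["T_NPB"]);
  P.T_REP = as<int>(p["T_REP"]);    P.T_NR = as<int>(p["T_NR"]);
  P.F_DA = as<double>(p["F_DA"]);   P.F_LT = as<double>(p["F_LT"]);
  P.CS_REP = seq_from_string(as<std::string>(p["CS_REP"]));
  P.CS_NR  = seq_from_string(as<std::string>(p["CS_NR"]));
  P.CS_CT  = seq_from_string(as<std::string>(p["CS_CT"]));
  return P;
}

// ---------------------------------------------------------------------------
// entities

struct Seg {
  Seq sub;                     // substrate, 5'->3', fully paired
  std::vector<uint8_t> mm;     // per-residue mismatch flags
  int start;                   // template position paired by sub's 3' residue
};

struct Ent {
  Seq seq;                     // template / strand sequence
  std::vector<Seg> segs;       // empty -> plain strand
  bool circular = false;
  int room = 0;
  bool alive = false;
  int fn_cache = -1;           // bit0: REP-functional, bit1: NR-functional; -1 unknown
};

struct Counters {
  long long nt_formed = 0, nt_formed_enz = 0, nt_decayed = 0,
            random_ligations = 0, circularizations = 0, attractions = 0,
            mismatches = 0, template_ligations = 0, template_ligations_enz = 0,
            circular_releases = 0, separations = 0, bond_breaks = 0,
            end_decays = 0, moves = 0;
};

struct Scope {            // species-scoped F_LT override
  double value;
  int topo;               // 0 any, 1 linear, 2 circular
  bool has_motif;
  Seq motif, motif_rc;
  bool use_rc;
};

// ---------------------------------------------------------------------------
// engine

struct Engine {
  Pars P;
  int N = 0, R = 0;
  std::vector<long long> pre;                 // precursors per room
  std::vector<std::array<long long, 4>> nt;   // free nucleotides per room/base
  std::deque<Ent> ents;   // deque: references stay valid while entities are created
  std::vector<int> free_ids;
  std::vector<std::vector<int>> room_ents;
  std::mt19937_64 rng;
  long long step_no = 0;
  long long inoculated = 0;                   // cumulative inoculated residues
  std::vector<Scope> flt_scopes;
  Counters ct;

  // --- rng helpers -------------------------------------------------------
  double u01() { return (rng() >> 11) * (1.0 / 9007199254740992.0); }
  int ri(int n) { return (int)(rng() % (uint64_t)n); }

  // binomial sampling: Bernoulli loop for small n, geometric skips (with a
  // memoized log1p(-p), since p repeats within a phase) otherwise
  double memo_p = -1.0, memo_l1p = 0.0;
  long long binom(long long n, double p) {
    if (n <= 0 || p <= 0) return 0;
    if (p >= 1) return n;
    if (n <= 8) {
      long long k = 0;
      for (long long i = 0; i < n; ++i) if (u01() < p) ++k;
      return k;
    }
    if (p != memo_p) { memo_p = p; memo_l1p = std::log1p(-p); }
    double l1p = memo_l1p;
    long long k = 0, idx = -1;
    while (true) {
      double u = u01();
      if (u <= 0) u = 5e-324;
      double skip = std::floor(std::log(u) / l1p);
      if (skip > (double)n) break;
      idx += 1 + (long long)skip;
      if (idx >= n) break;
      ++k;
    }
    return k;
  }

  int pick_weighted_base(const std::array<long long, 4>& w, long long tot) {
    long long x = (long long)(u01() * (double)tot);
    if (x >= tot) x = tot - 1;
    for (int b = 0; b < 4; ++b) { if (x < w[b]) return b; x -= w[b]; }
    return 3;
  }

  // --- bookkeeping --------------------------------------------------------
  int new_ent() {
    int id;
    if (!free_ids.empty()) { id = free_ids.back(); free_ids.pop_back(); }
    else { ents.push_back(Ent()); id = (int)ents.size() - 1; }
    ents[id] = Ent();
    ents[id].alive = true;
    return id;
  }
  void add_to_room(int id, int room) {
    ents[id].room = room;
    room_ents[room].push_back(id);
  }
  void remove_from_room(int id) {
    std::vector<int>& v = room_ents[ents[id].room];
    v.erase(std::find(v.begin(), v.end(), id));
  }
  void kill(int id) {
    remove_from_room(id);
    ents[id].alive = false;
    ents[id].seq.clear();
    ents[id].segs.clear();
    free_ids.push_back(id);
  }
  // add a free strand; lone residues re-enter the nucleotide pool
  void add_strand(Seq s, bool circ, int room) {
    if (s.empty()) return;
    if (!circ && s.size() == 1) { nt[room][s[0]]++; return; }
    if (circ) s = canonical_rotation_cpp(s);
    int id = new_ent();
    ents[id].seq = std::move(s);
    ents[id].circular = circ;
    add_to_room(id, room);
  }
  // convert an existing entity that degraded to a lone free residue
  void normalize_ent(int id) {
    Ent& e = ents[id];
    if (!e.alive) return;
    if (e.seq.empty() && e.segs.empty()) { kill(id); return; }
    if (e.segs.empty() && !e.circular && e.seq.size() == 1) {
      int room = e.room; int b = e.seq[0];
      kill(id);
      nt[room][b]++;
    }
  }

  long long ent_mass(const Ent& e) const {
    long long m = (long long)e.seq.size();
    for (size_t i = 0; i < e.segs.size(); ++i) m += (long long)e.segs[i].sub.size();
    return m;
  }
  long long total_mass() const {
    long long m = 0;
    for (int r = 0; r < R; ++r) {
      m += pre[r];
      for (int b = 0; b < 4; ++b) m += nt[r][b];
    }
    for (size_t i = 0; i < ents.size(); ++i)
      if (ents[i].alive) m += ent_mass(ents[i]);
    return m;
  }

  int neighbour(int room, int dir) const {
    int r = room / N, c = room % N;
    switch (dir) {
      case 0: r = (r + 1) % N; break;
      case 1: r = (r + N - 1) % N; break;
      case 2: c = (c + 1) % N; break;
      default: c = (c + N - 1) % N; break;
    }
    return r * N + c;
  }

  bool functional_seq(const Ent& e, const Seq& cs) const {
    return !e.circular &&
           (double)e.seq.size() < 1.5 * (double)cs.size() &&
           seq_contains(e.seq, false, cs);
  }
  // cached: folding ability depends only on the (immutable-between-edits)
  // sequence; a strand engaged as a template or bound as a substrate is not
  // free to fold and supplies no turnovers that step
  bool functional_free(Ent& e, bool nr) {
    if (!e.alive || !e.segs.empty()) return false;
    if (e.fn_cache < 0) {
      e.fn_cache = (functional_seq(e, P.CS_REP) ? 1 : 0) |
                   (functional_seq(e, P.CS_NR) ? 2 : 0);
    }
    return (e.fn_cache & (nr ? 2 : 1)) != 0;
  }

  double eff_FLT(const Ent& e) const {
    double v = P.F_LT;
    for (size_t i = 0; i < flt_scopes.size(); ++i) {
      const Scope& sc = flt_scopes[i];
      if (sc.topo == 1 && e.circular) continue;
      if (sc.topo == 2 && !e.circular) continue;
      if (sc.has_motif) {
        bool m = seq_contains(e.seq, e.circular, sc.motif);
        if (!m && sc.use_rc) m = seq_contains(e.seq, e.circular, sc.motif_rc);
        if (!m) continue;
      }
      v = sc.value;   // later interventions win
    }
    return v;
  }

  // --- setup --------------------------------------------------------------
  void init_grid(int n) {
    N = n; R = N * N;
    pre.assign(R, 0);
    std::array<long long, 4> z = {0, 0, 0, 0};
    nt.assign(R, z);
    room_ents.assign(R, std::vector<int>());
    ents.clear(); free_ids.clear();
    step_no = 0; inoculated = 0;
    flt_scopes.clear();
    ct = Counters();
  }

  // place T_NPB precursors independently and uniformly over rooms
  void seed_precursors(long long total) {
    long long remaining = total;
    for (int r = 0; r < R; ++r) {
      if (r == R - 1) { pre[r] += remaining; break; }
      long long k = binom(remaining, 1.0 / (double)(R - r));
      pre[r] += k;
      remaining -= k;
    }
  }

  void inoculate(const Seq& s, bool circ, long long count) {
    for (long long i = 0; i < count; ++i) {
      int room = ri(R);
      add_strand(s, circ, room);
      inoculated += (long long)s.size();
    }
  }

  // ==========================================================================
  // phases

  void phase_formation(std::vector<int>& nrT) {
    for (int r = 0; r < R; ++r) {
      long long p = pre[r];
      if (p <= 0) continue;
      if (nrT[r] > 0) {
        long long attempts = std::min((long long)nrT[r], p);
        long long succ = binom(attempts, P.P_NFR);
        nrT[r] -= (int)attempts;
        p -= succ;
        for (long long i = 0; i < succ; ++i) nt[r][ri(4)]++;
        ct.nt_formed_enz += succ;
        long long untried = p - (attempts - succ);
        long long k = binom(untried, P.P_NF);
        p -= k;
        for (long long i = 0; i < k; ++i) nt[r][ri(4)]++;
        ct.nt_formed += k;
      } else {
        long long k = binom(p, P.P_NF);
        p -= k;
        for (long long i = 0; i < k; ++i) nt[r][ri(4)]++;
        ct.nt_formed += k;
      }
      pre[r] = p;
    }
  }

  void phase_nt_decay() {
    for (int r = 0; r < R; ++r)
      for (int b = 0; b < 4; ++b) {
        long long k = binom(nt[r][b], P.P_ND);
        nt[r][b] -= k;
        pre[r] += k;
        ct.nt_decayed += k;
      }
  }

  std::vector<int> rl_buf;
  void phase_random_ligation() {
    if (P.P_RL <= 0) return;
    for (int r = 0; r < R; ++r) {
      long long nfree = 0;
      for (size_t i = 0; i < room_ents[r].size(); ++i) {
        int id = room_ents[r][i];
        if (!ents[id].circular && ents[id].segs.empty()) nfree++;
      }
      long long ntot0 = nt[r][0] + nt[r][1] + nt[r][2] + nt[r][3];
      if (nfree + ntot0 < 2) continue;
      // strand initiators: binomial count, then uniform choice -- exactly
      // equivalent to an independent Bernoulli attempt per strand
      long long ks = binom(nfree, P.P_RL);
      if (ks > 0) {
        std::vector<int>& snap = rl_buf;
        snap.clear();
        for (size_t i = 0; i < room_ents[r].size(); ++i) {
          int id = room_ents[r][i];
          if (!ents[id].circular && ents[id].segs.empty()) snap.push_back(id);
        }
        for (long long i = 0; i < ks; ++i) {
          int id = snap[ri((int)snap.size())];
          if (!ents[id].alive || !ents[id].segs.empty() || ents[id].circular) continue;
          do_random_ligation(r, id);
        }
      }
      // nucleotide initiators (count drawn from the phase-start pool)
      long long k = binom(ntot0, P.P_RL);
      for (long long i = 0; i < k; ++i) {
        long long ntot = nt[r][0] + nt[r][1] + nt[r][2] + nt[r][3];
        if (ntot < 1) break;
        int b = pick_weighted_base(nt[r], ntot);
        nt[r][b]--;                       // initiator leaves the pool
        Seq left(1, (uint8_t)b);
        int id = new_ent();               // temporary carrier for the initiator
        ents[id].seq = left;
        add_to_room(id, r);
        if (!do_random_ligation(r, id)) { // no partner: put it back
          kill(id);
          nt[r][b]++;
        }
      }
    }
  }

  // join initiator (left) with a uniformly chosen other free linear molecule
  bool do_random_ligation(int r, int init_id) {
    std::vector<int> partners;
    for (size_t i = 0; i < room_ents[r].size(); ++i) {
      int id = room_ents[r][i];
      if (id == init_id) continue;
      if (ents[id].alive && !ents[id].circular && ents[id].segs.empty())
        partners.push_back(id);
    }
    long long ntot = nt[r][0] + nt[r][1] + nt[r][2] + nt[r][3];
    long long W = (long long)partners.size() + ntot;
    if (W < 1) return false;
    long long x = (long long)(u01() * (double)W);
    if (x >= W) x = W - 1;
    Seq right;
    if (x < (long long)partners.size()) {
      int pid = partners[x];
      right = ents[pid].seq;
      kill(pid);
    } else {
      int b = pick_weighted_base(nt[r], ntot);
      nt[r][b]--;
      right.assign(1, (uint8_t)b);
    }
    Seq joined = ents[init_id].seq;
    joined.insert(joined.end(), right.begin(), right.end());
    kill(init_id);
    add_strand(joined, false, r);
    ct.random_ligations++;
    return true;
  }

  void phase_circularization() {
    if (P.P_EL <= 0) return;
    // binomial count over eligible molecules, then uniform choice: exactly
    // an independent Bernoulli attempt per eligible free linear strand
    std::vector<int>& snap = snap_buf;
    snap.clear();
    for (int r = 0; r < R; ++r)
      for (size_t i = 0; i < room_ents[r].size(); ++i) {
        Ent& e = ents[room_ents[r][i]];
        if (!e.circular && e.segs.empty() && e.seq.size() >= 3)
          snap.push_back(room_ents[r][i]);
      }
    if (snap.empty()) return;
    long long k = binom((long long)snap.size(), P.P_EL);
    for (long long i = 0; i < k; ++i) {
      Ent& e = ents[snap[ri((int)snap.size())]];
      if (!e.alive || e.circular || !e.segs.empty() || e.seq.size() < 3) continue;
      e.seq = canonical_rotation_cpp(e.seq);
      e.circular = true;
      e.fn_cache = -1;
      ct.circularizations++;
    }
  }

  // empty (uncovered) runs of a template, as (start, len) pairs
  void empty_runs(const Ent& e, std::vector<std::pair<int, int>>& runs,
                  bool& full_ring) const {
    runs.clear();
    full_ring = false;
    int L = (int)e.seq.size();
    if (e.segs.empty()) {
      if (e.circular) full_ring = true;
      runs.push_back(std::make_pair(0, L));
      return;
    }
    // segs kept sorted by start
    if (!e.circular) {
      int cur = 0;
      for (size_t i = 0; i < e.segs.size(); ++i) {
        int s = e.segs[i].start, len = (int)e.segs[i].sub.size();
        if (s > cur) runs.push_back(std::make_pair(cur, s - cur));
        cur = s + len;
      }
      if (cur < L) runs.push_back(std::make_pair(cur, L - cur));
    } else {
      size_t m = e.segs.size();
      for (size_t i = 0; i < m; ++i) {
        int endi = e.segs[i].start + (int)e.segs[i].sub.size();   // may exceed L (wrap)
        int nxt = e.segs[(i + 1) % m].start;
        int gap = ((nxt - endi) % L + L) % L;
        if (m == 1) gap = L - (int)e.segs[0].sub.size();
        if (gap > 0) runs.push_back(std::make_pair(endi % L, gap));
      }
    }
  }

  bool covered(const Ent& e, int pos) const {
    int L = (int)e.seq.size();
    for (size_t i = 0; i < e.segs.size(); ++i) {
      int s = e.segs[i].start, len = (int)e.segs[i].sub.size();
      if (!e.circular) {
        if (pos >= s && pos < s + len) return true;
      } else {
        int off = ((pos - s) % L + L) % L;
        if (off < len) return true;
      }
    }
    return false;
  }

  void insert_seg_sorted(Ent& e, Seg seg) {
    size_t i = 0;
    while (i < e.segs.size() && e.segs[i].start < seg.start) ++i;
    e.segs.insert(e.segs.begin() + i, seg);
  }

  std::vector<double> attr_posw;
  std::vector<int> attr_starts;
  std::vector<uint8_t> attr_cov, attr_cov2;
  std::vector<std::pair<int, int>> attr_queue;
  std::vector<std::pair<int, long long>> attr_cands;

  // per-room substrate pool, cached for the phase and updated on consumption
  struct SubPool {
    long long ntot;
    std::vector<int> freelin;   // ids of free linear strands (may die mid-phase)
  };
  SubPool pool;

  void phase_attraction() {
    if (P.P_AT <= 0) return;
    std::vector<int> snap;
    for (int r = 0; r < R; ++r) {
      snap.clear();
      pool.ntot = nt[r][0] + nt[r][1] + nt[r][2] + nt[r][3];
      pool.freelin.clear();
      for (size_t i = 0; i < room_ents[r].size(); ++i) {
        int id = room_ents[r][i];
        snap.push_back(id);
        const Ent& e = ents[id];
        if (!e.circular && e.segs.empty()) pool.freelin.push_back(id);
      }
      if (pool.ntot == 0 && pool.freelin.empty()) continue;   // nothing to bind
      for (size_t i = 0; i < snap.size(); ++i) {
        int id = snap[i];
        if (ents[id].alive) attempt_attraction(id);
      }
    }
  }

  // One attraction attempt per empty site: the initial queue holds the
  // template's maximal unpaired runs; when a substrate lands inside a run,
  // the uncovered remainders re-enter the queue (their edge placements are
  // then primer-adjacent, the "primer effect").  An empty circular template
  // is one cyclic site admitting all rotational placements.  The substrate
  // and position are uniform over every placement that fits; each newly
  // paired residue is recorded as the Watson-Crick complement of its
  // template residue, or, with the error rate P_FP, as a uniformly chosen
  // non-complementary base -- substitution at copying time is the model's
  // mutation mechanism, and bound material is raw material.
  void attempt_attraction(int id) {
    Ent& e = ents[id];
    int r = e.room;
    int L = (int)e.seq.size();
    if (L < 1) return;
    std::vector<std::pair<int, int>>& queue = attr_queue;
    bool full_ring;
    empty_runs(e, queue, full_ring);
    double flt = e.circular ? 1.0 : eff_FLT(e);
    double p_max = P.P_AT * flt;          // primer-adjacent success ceiling
    if (p_max <= 0) return;
    size_t qi = 0;
    while (qi < queue.size()) {
      int run_start = queue[qi].first, run_len = queue[qi].second;
      bool ring = full_ring && qi == 0;
      ++qi;
      if (run_len < 1) continue;

      // success requires u < p(placement) <= p_max: reject early, choose the
      // placement only when the draw could succeed (exact two-stage sampling)
      double u = u01();
      if (e.segs.empty()) {                // every placement is de novo
        if (u >= p_max / P.F_DA) continue;
      } else if (u >= p_max) continue;

      long long ntot = pool.ntot;
      // placements within this run for a substrate of length s
      long long p1 = ring ? (long long)L : (long long)run_len;
      long long W = ntot * p1;
      std::vector<std::pair<int, long long>>& strand_cands = attr_cands;
      strand_cands.clear();
      for (size_t i = 0; i < pool.freelin.size(); ++i) {
        int sid = pool.freelin[i];
        if (sid == id) continue;
        const Ent& s = ents[sid];
        if (!s.alive || !s.segs.empty()) continue;
        int sl = (int)s.seq.size();
        long long pl = ring ? (sl <= L ? (long long)L : 0)
                            : (sl <= run_len ? (long long)(run_len - sl + 1) : 0);
        if (pl > 0) { strand_cands.push_back(std::make_pair(sid, pl)); W += pl; }
      }
      if (W < 1) continue;

      // uniform over (substrate, position) placements within the site
      long long x = (long long)(u01() * (double)W);
      if (x >= W) x = W - 1;
      int sub_len = 1, sub_strand = -1;
      long long npl;
      if (x < ntot * p1) {
        sub_len = 1; npl = p1;
      } else {
        x -= ntot * p1;
        size_t i = 0;
        while (x >= strand_cands[i].second) { x -= strand_cands[i].second; ++i; }
        sub_strand = strand_cands[i].first;
        sub_len = (int)ents[sub_strand].seq.size();
        npl = strand_cands[i].second;
      }
      long long px = ri((int)std::min<long long>(npl, 2147483647LL));
      int t = run_start + (int)px;
      if (e.circular) t %= L;

      // primer-adjacent if the placement abuts an existing segment
      bool primer = false;
      if (!e.segs.empty()) {
        if (e.circular) {
          primer = covered(e, ((t - 1) % L + L) % L) || covered(e, (t + sub_len) % L);
        } else {
          if (t - 1 >= 0 && covered(e, t - 1)) primer = true;
          if (t + sub_len < L && covered(e, t + sub_len)) primer = true;
        }
      }
      double pr = p_max;
      if (!primer) pr /= P.F_DA;
      if (u >= pr) continue;

      // consume the substrate
      if (sub_len == 1) {
        long long nn = nt[r][0] + nt[r][1] + nt[r][2] + nt[r][3];
        if (nn < 1) continue;
        int b = pick_weighted_base(nt[r], nn);
        nt[r][b]--;
        pool.ntot--;
      } else {
        kill(sub_strand);
      }
      // record residues by templating, with per-residue false pairing
      Seg seg;
      seg.start = t;
      seg.sub.resize(sub_len);
      seg.mm.assign(sub_len, 0);
      for (int j = 0; j < sub_len; ++j) {
        int pos = t + sub_len - 1 - j;
        if (e.circular) pos %= L;
        int c = comp_base(e.seq[pos]);
        if (P.P_FP > 0 && u01() < P.P_FP) {
          int y = ri(3);
          c = (y >= c) ? y + 1 : y;      // uniform among the 3 non-complements
          seg.mm[j] = 1;
          ct.mismatches++;
        }
        seg.sub[j] = (uint8_t)c;
      }
      insert_seg_sorted(e, seg);
      ct.attractions++;
      // remainders of the site become sites of their own
      if (ring) {
        if (L - sub_len > 0) {
          queue.push_back(std::make_pair((t + sub_len) % L, L - sub_len));
        }
      } else {
        int left_len = t - run_start;
        if (e.circular) left_len = ((t - run_start) % L + L) % L;
        if (left_len > 0) queue.push_back(std::make_pair(run_start, left_len));
        int right_start = t + sub_len;
        if (e.circular) right_start %= L;
        int right_len = run_len - left_len - sub_len;
        if (right_len > 0) queue.push_back(std::make_pair(right_start, right_len));
      }
    }
  }

  void phase_template_ligation(std::vector<int>& repT) {
    std::vector<int>& snap = snap_buf;
    snap.clear();
    for (int r = 0; r < R; ++r)
      for (size_t i = 0; i < room_ents[r].size(); ++i)
        if (!ents[room_ents[r][i]].segs.empty()) snap.push_back(room_ents[r][i]);
    for (size_t i = 0; i < snap.size(); ++i) {
      int id = snap[i];
      if (ents[id].alive && !ents[id].segs.empty()) attempt_template_ligation(id);
    }
  }

  bool ligation_fires(int room, std::vector<int>& repT) {
    double pp;
    if (repT[room] > 0) { repT[room]--; pp = P.P_TLR; }
    else pp = P.P_TL;
    if (u01() < pp) {
      ct.template_ligations++;
      if (pp == P.P_TLR && P.T_REP > 0) ct.template_ligations_enz++;
      return true;
    }
    return false;
  }

  void attempt_template_ligation(int id) {
    // repT belongs to the step; stored in member set by do_step
    Ent& e = ents[id];
    int L = (int)e.seq.size();
    int room = e.room;
    // linear-order junction scan (also covers non-wrap junctions on circles)
    size_t k = 0;
    while (e.segs.size() >= 2 && k + 1 < e.segs.size()) {
      Seg& A = e.segs[k];
      Seg& B = e.segs[k + 1];
      if (A.start + (int)A.sub.size() == B.start) {
        if (ligation_fires(room, *step_repT)) {
          Seq merged = B.sub;
          merged.insert(merged.end(), A.sub.begin(), A.sub.end());
          std::vector<uint8_t> mmm = B.mm;
          mmm.insert(mmm.end(), A.mm.begin(), A.mm.end());
          A.sub = merged;
          A.mm = mmm;
          e.segs.erase(e.segs.begin() + k + 1);
          continue;                 // new junction may form at same k
        }
      }
      ++k;
    }
    if (e.circular) {
      // wrap junction between last and first segment
      if (e.segs.size() >= 2) {
        Seg& A = e.segs.back();
        Seg& B = e.segs.front();
        if ((A.start + (int)A.sub.size()) % L == B.start) {
          if (ligation_fires(room, *step_repT)) {
            Seq merged = B.sub;
            merged.insert(merged.end(), A.sub.begin(), A.sub.end());
            std::vector<uint8_t> mmm = B.mm;
            mmm.insert(mmm.end(), A.mm.begin(), A.mm.end());
            A.sub = merged;
            A.mm = mmm;
            e.segs.erase(e.segs.begin());
          }
        }
      }
      // full cover: circularize the complement and release it
      if (e.segs.size() == 1 && (int)e.segs[0].sub.size() == L && L >= 3) {
        if (ligation_fires(room, *step_repT)) {
          Seq rel = e.segs[0].sub;
          e.segs.clear();
          add_strand(rel, true, room);
          ct.circular_releases++;
        }
      }
    }
  }

  double bb15_p = -1.0, bb15 = 0.0;
  double pbb15() {
    if (P.P_BB != bb15_p) { bb15_p = P.P_BB; bb15 = std::pow(P.P_BB, 1.5); }
    return bb15;
  }
  double nde15_p = -1.0, nde15 = 0.0;
  double pnde15() {
    if (P.P_NDE != nde15_p) { nde15_p = P.P_NDE; nde15 = std::pow(P.P_NDE, 1.5); }
    return nde15;
  }
  double sep_cache_p = -1.0;
  std::vector<double> sep_cache;
  double sep_prob(int n) {
    if (P.P_SP != sep_cache_p) {
      sep_cache_p = P.P_SP;
      sep_cache.assign(65, 0.0);
      for (int i = 1; i <= 64; ++i)
        sep_cache[i] = std::pow(P.P_SP, std::sqrt((double)i));
    }
    if (n <= 64) return sep_cache[n];
    return std::pow(P.P_SP, std::sqrt((double)n));
  }

  void phase_separation() {
    if (P.P_SP <= 0) return;
    std::vector<int>& snap = snap_buf;
    snap.clear();
    for (int r = 0; r < R; ++r)
      for (size_t i = 0; i < room_ents[r].size(); ++i)
        if (!ents[room_ents[r][i]].segs.empty()) snap.push_back(room_ents[r][i]);
    for (size_t i = 0; i < snap.size(); ++i) {
      Ent& e = ents[snap[i]];
      if (!e.alive) continue;
      int room = e.room;
      for (size_t s = 0; s < e.segs.size();) {
        int n = (int)e.segs[s].sub.size();
        if (u01() < sep_prob(n)) {
          add_strand(e.segs[s].sub, false, room);
          e.segs.erase(e.segs.begin() + s);
          ct.separations++;
        } else ++s;
      }
      normalize_ent(snap[i]);
    }
  }

  void phase_breaking() {
    if (P.P_BB <= 0) return;
    std::vector<int>& snap = all_ids_snapshot();
    for (size_t i = 0; i < snap.size(); ++i)
      if (ents[snap[i]].alive) attempt_break(snap[i]);
  }

  std::vector<uint8_t> ds_buf;
  void attempt_break(int id) {
    Ent& e = ents[id];
    int L = (int)e.seq.size();
    int nbonds = e.circular ? L : L - 1;
    if (nbonds < 1) return;
    double pss = P.P_BB, pds = pbb15();
    // a bond is double-stranded iff one segment covers both flanking
    // residues; count of such bonds = segment length - 1, summed
    int nds = 0;
    for (size_t s = 0; s < e.segs.size(); ++s) nds += (int)e.segs[s].sub.size() - 1;
    double H = (double)(nbonds - nds) * pss + (double)nds * pds;
    if (H < 1 && u01() >= H) return;
    std::vector<uint8_t>& ds = ds_buf;
    ds.assign(nbonds, 0);
    for (size_t s = 0; s < e.segs.size(); ++s) {
      int st = e.segs[s].start, len = (int)e.segs[s].sub.size();
      for (int q = 0; q < len - 1; ++q) {
        int bond = st + q;
        if (e.circular) bond %= L;
        if (bond >= 0 && bond < nbonds) ds[bond] = 1;
      }
    }
    double x = u01() * H;
    int bond = nbonds - 1;
    for (int b = 0; b < nbonds; ++b) {
      double w = ds[b] ? pds : pss;
      if (x < w) { bond = b; break; }
      x -= w;
    }
    do_break(id, bond, ds[bond] != 0);
    ct.bond_breaks++;
  }

  void do_break(int id, int bond, bool both) {
    Ent& e = ents[id];
    int L = (int)e.seq.size();
    int room = e.room;
    if (e.circular) {
      // linearize: new position of old p is (p - bond - 1) mod L
      int off = bond + 1;
      Seq ns(L);
      for (int p = 0; p < L; ++p) ns[p] = e.seq[(p + off) % L];
      e.seq = ns;
      e.circular = false;
      e.fn_cache = -1;
      for (size_t s = 0; s < e.segs.size(); ++s)
        e.segs[s].start = ((e.segs[s].start - off) % L + L) % L;
      if (both) {
        // the covering segment now spans the new chain ends: split it
        for (size_t s = 0; s < e.segs.size(); ++s) {
          Seg& sg = e.segs[s];
          int len = (int)sg.sub.size();
          if (sg.start + len > L) {
            int len1 = L - sg.start;        // covers start..L-1 (upper part)
            int len2 = len - len1;          // covers 0..len2-1
            Seg lower, upper;
            upper.start = sg.start;
            upper.sub.assign(sg.sub.begin() + len2, sg.sub.end());
            upper.mm.assign(sg.mm.begin() + len2, sg.mm.end());
            lower.start = 0;
            lower.sub.assign(sg.sub.begin(), sg.sub.begin() + len2);
            lower.mm.assign(sg.mm.begin(), sg.mm.begin() + len2);
            e.segs.erase(e.segs.begin() + s);
            if (!lower.sub.empty()) insert_seg_sorted(e, lower);
            if (!upper.sub.empty()) insert_seg_sorted(e, upper);
            break;
          }
        }
      }
      std::sort(e.segs.begin(), e.segs.end(),
                [](const Seg& a, const Seg& b) { return a.start < b.start; });
      normalize_ent(id);
      return;
    }
    // linear template
    if (both) {
      // split the covering segment at the bond first
      for (size_t s = 0; s < e.segs.size(); ++s) {
        Seg& sg = e.segs[s];
        int st = sg.start, len = (int)sg.sub.size();
        if (st <= bond && bond < st + len - 1) {
          int lenL = bond - st + 1;          // covers st..bond
          int lenR = len - lenL;             // covers bond+1..st+len-1
          Seg left, right;
          right.start = bond + 1;
          right.sub.assign(sg.sub.begin(), sg.sub.begin() + lenR);
          right.mm.assign(sg.mm.begin(), sg.mm.begin() + lenR);
          left.start = st;
          left.sub.assign(sg.sub.begin() + lenR, sg.sub.end());
          left.mm.assign(sg.mm.begin() + lenR, sg.mm.end());
          e.segs.erase(e.segs.begin() + s);
          insert_seg_sorted(e, left);
          insert_seg_sorted(e, right);
          break;
        }
      }
    }
    // split the template chain
    Seq leftSeq(e.seq.begin(), e.seq.begin() + bond + 1);
    Seq rightSeq(e.seq.begin() + bond + 1, e.seq.end());
    std::vector<Seg> leftSegs, rightSegs;
    for (size_t s = 0; s < e.segs.size(); ++s) {
      Seg sg = e.segs[s];
      if (sg.start + (int)sg.sub.size() - 1 <= bond) leftSegs.push_back(sg);
      else { sg.start -= bond + 1; rightSegs.push_back(sg); }
    }
    e.seq = leftSeq;
    e.segs = leftSegs;
    e.fn_cache = -1;
    if (!rightSeq.empty()) {
      if (rightSegs.empty()) {
        add_strand(rightSeq, false, room);
      } else {
        int nid = new_ent();
        ents[nid].seq = rightSeq;
        ents[nid].segs = rightSegs;
        ents[nid].circular = false;
        add_to_room(nid, room);
        normalize_ent(nid);
      }
    }
    normalize_ent(id);
  }

  std::vector<int> plain_buf;
  void phase_end_decay() {
    if (P.P_NDE <= 0) return;
    std::vector<int>& snap = snap_buf;
    std::vector<int>& plain = plain_buf;
    snap.clear(); plain.clear();
    for (int r = 0; r < R; ++r)
      for (size_t i = 0; i < room_ents[r].size(); ++i) {
        int id = room_ents[r][i];
        const Ent& e = ents[id];
        if (!e.segs.empty()) snap.push_back(id);
        else if (!e.circular) plain.push_back(id);
      }
    for (size_t i = 0; i < snap.size(); ++i)
      if (ents[snap[i]].alive) attempt_end_decay(snap[i]);
    // free linear strands: binomial over the 2n unpaired chain ends, then
    // uniform choice without replacement -- per-end Bernoulli, aggregated
    if (plain.empty()) return;
    long long nends = 2 * (long long)plain.size();
    long long k = binom(nends, P.P_NDE);
    std::vector<long long> used;
    for (long long i = 0; i < k && (long long)used.size() < nends; ++i) {
      long long idx;
      int guard = 0;
      do {
        idx = (long long)(u01() * (double)nends);
        if (idx >= nends) idx = nends - 1;
      } while (std::find(used.begin(), used.end(), idx) != used.end() &&
               ++guard < 64);
      if (guard >= 64) {       // dense case: first unused end
        for (idx = 0; idx < nends; ++idx)
          if (std::find(used.begin(), used.end(), idx) == used.end()) break;
      }
      used.push_back(idx);
      int id = plain[idx / 2];
      Ent& e = ents[id];
      if (!e.alive || !e.segs.empty() || e.seq.empty()) continue;
      int room = e.room;
      if (idx % 2 == 0) e.seq.erase(e.seq.begin());
      else e.seq.pop_back();
      e.fn_cache = -1;
      pre[room] += 1;
      ct.end_decays += 1;
      normalize_ent(id);
    }
  }

  void attempt_end_decay(int id) {
    Ent& e = ents[id];
    if (e.circular && e.segs.empty()) return;   // a ring has no ends
    int room = e.room;
    double pse = P.P_NDE, pde = pnde15();
    // flags: duplex ends already attempted from the template side
    std::vector<uint8_t> f5(e.segs.size(), 0), f3(e.segs.size(), 0);

    if (!e.circular && !e.seq.empty()) {
      // 5' template end (position 0)
      int L = (int)e.seq.size();
      int cov = -1;
      for (size_t s = 0; s < e.segs.size(); ++s)
        if (e.segs[s].start == 0) { cov = (int)s; break; }
      if (cov >= 0) {
        f3[cov] = 1;    // partner is that segment's 3' (sub.back) residue
        if (u01() < pde) {
          e.seq.erase(e.seq.begin());
          e.fn_cache = -1;
          for (size_t s = 0; s < e.segs.size(); ++s) e.segs[s].start -= 1;
          Seg& sg = e.segs[cov];
          sg.start += 1;            // back to 0: coverage lost its bottom position
          sg.sub.pop_back();
          sg.mm.pop_back();
          pre[room] += 2;
          ct.end_decays += 2;
          if (sg.sub.empty()) {
            e.segs.erase(e.segs.begin() + cov);
            f5.erase(f5.begin() + cov);
            f3.erase(f3.begin() + cov);
          }
        }
      } else if (u01() < pse) {
        e.seq.erase(e.seq.begin());
        e.fn_cache = -1;
        for (size_t s = 0; s < e.segs.size(); ++s) e.segs[s].start -= 1;
        pre[room] += 1;
        ct.end_decays += 1;
      }
      // 3' template end (position L-1), if anything remains
      L = (int)e.seq.size();
      if (L >= 1 && !(L == 1 && false)) {
        cov = -1;
        for (size_t s = 0; s < e.segs.size(); ++s)
          if (e.segs[s].start + (int)e.segs[s].sub.size() - 1 == L - 1)
            { cov = (int)s; break; }
        if (cov >= 0) {
          f5[cov] = 1;  // partner is that segment's 5' (sub.front) residue
          if (u01() < pde) {
            e.seq.pop_back();
            Seg& sg = e.segs[cov];
            sg.sub.erase(sg.sub.begin());
            sg.mm.erase(sg.mm.begin());
            pre[room] += 2;
            ct.end_decays += 2;
            if (sg.sub.empty()) {
              e.segs.erase(e.segs.begin() + cov);
              f5.erase(f5.begin() + cov);
              f3.erase(f3.begin() + cov);
            }
          }
        } else if (u01() < pse) {
          e.seq.pop_back();
          e.fn_cache = -1;
          pre[room] += 1;
          ct.end_decays += 1;
        }
      }
    }
    // substrate ends whose duplex end was not already attempted; each paired
    // terminal residue decays with P_NDE^(3/2); an internal partner stays
    int L = (int)e.seq.size();
    for (size_t s = 0; s < e.segs.size();) {
      Seg& sg = e.segs[s];
      bool removed = false;
      if (!f3[s] && u01() < pde) {        // substrate 3' end pairs template pos start
        sg.sub.pop_back();
        sg.mm.pop_back();
        sg.start += 1;
        if (e.circular && L > 0) sg.start %= L;
        pre[room] += 1;
        ct.end_decays += 1;
        if (sg.sub.empty()) {
          e.segs.erase(e.segs.begin() + s);
          f5.erase(f5.begin() + s);
          f3.erase(f3.begin() + s);
          removed = true;
        }
      }
      if (!removed && !sg.sub.empty() && !f5[s] && u01() < pde) {
        sg.sub.erase(sg.sub.begin());
        sg.mm.erase(sg.mm.begin());
        pre[room] += 1;
        ct.end_decays += 1;
        if (sg.sub.empty()) {
          e.segs.erase(e.segs.begin() + s);
          f5.erase(f5.begin() + s);
          f3.erase(f3.begin() + s);
          removed = true;
        }
      }
      if (!removed) ++s;
    }
    normalize_ent(id);
  }

  double move_cache_p = -1.0;
  std::vector<double> move_cache;
  double move_p(long long m) {
    if (P.P_MN != move_cache_p) {
      move_cache_p = P.P_MN;
      move_cache.assign(129, 0.0);
      for (int i = 1; i <= 128; ++i)
        move_cache[i] = P.P_MN / std::sqrt((double)i);
    }
    if (m <= 128) return move_cache[(size_t)m];
    return P.P_MN / std::sqrt((double)m);
  }

  void phase_movement() {
    // counts move via buffered binomial splits so nothing moves twice
    std::vector<long long> preBuf(R, 0);
    std::vector<std::array<long long, 4>> ntBuf(R, std::array<long long, 4>{0, 0, 0, 0});
    for (int r = 0; r < R; ++r) {
      long long k = binom(pre[r], P.P_MNP);
      pre[r] -= k;
      for (long long i = 0; i < k; ++i) preBuf[neighbour(r, ri(4))]++;
      for (int b = 0; b < 4; ++b) {
        long long kb = binom(nt[r][b], P.P_MN);
        nt[r][b] -= kb;
        for (long long i = 0; i < kb; ++i) ntBuf[neighbour(r, ri(4))][b]++;
      }
    }
    for (int r = 0; r < R; ++r) {
      pre[r] += preBuf[r];
      for (int b = 0; b < 4; ++b) nt[r][b] += ntBuf[r][b];
    }
    // strands and complexes move whole, rate P_MN / sqrt(mass)
    std::vector<int>& snap = all_ids_snapshot();
    for (size_t i = 0; i < snap.size(); ++i) {
      int id = snap[i];
      Ent& e = ents[id];
      if (!e.alive) continue;
      long long m = ent_mass(e);
      if (m < 1) continue;
      if (u01() < move_p(m)) {
        int dest = neighbour(e.room, ri(4));
        remove_from_room(id);
        add_to_room(id, dest);
        ct.moves++;
      }
    }
  }

  std::vector<int>* step_repT = 0;
  std::vector<int> snap_buf;
  std::vector<int>& all_ids_snapshot() {
    snap_buf.clear();
    for (int r = 0; r < R; ++r)
      for (size_t i = 0; i < room_ents[r].size(); ++i)
        snap_buf.push_back(room_ents[r][i]);
    return snap_buf;
  }

  double phase_ns[12] = {0,0,0,0,0,0,0,0,0,0,0,0};
  bool profile = false;

  void do_step() {
    std::vector<int> repT(R, 0), nrT(R, 0);
    using clk = std::chrono::steady_clock;
    clk::time_point t0, t1;
    if (profile) t0 = clk::now();
    for (int r = 0; r < R; ++r)
      for (size_t i = 0; i < room_ents[r].size(); ++i) {
        Ent& e = ents[room_ents[r][i]];
        if (functional_free(e, false)) repT[r] += P.T_REP;
        if (functional_free(e, true)) nrT[r] += P.T_NR;
      }
    step_repT = &repT;
#define PHASE(i, call) call; if (profile) { t1 = clk::now(); \
    phase_ns[i] += std::chrono::duration<double, std::nano>(t1 - t0).count(); t0 = t1; }
    PHASE(0, )
    PHASE(1, phase_formation(nrT))
    PHASE(2, phase_nt_decay())
    PHASE(3, phase_random_ligation())
    PHASE(4, phase_circularization())
    PHASE(5, phase_attraction())
    PHASE(6, phase_template_ligation(repT))
    PHASE(7, phase_separation())
    PHASE(8, phase_breaking())
    PHASE(9, phase_end_decay())
    PHASE(10, phase_movement())
#undef PHASE
    step_repT = 0;
    step_no++;
  }

  // --- census ---------------------------------------------------------------

  // category indices (column order of the time series)
  // 0 cir_rep, 1 cir_repcom, 2 lin_rep, 3 lin_repcom, 4 cir_ct, 5 cir_ctcom,
  // 6 cir_repnr, 7 cir_nr, 8 lin_rep_rib, 9 lin_nr_rib
  void classify(const Seq& s, bool circ, long long* out) const {
    bool hasR = seq_contains(s, circ, P.CS_REP);
    bool hasN = seq_contains(s, circ, P.CS_NR);
    bool hasC = seq_contains(s, circ, P.CS_CT);
    for (int i = 0; i < 10; ++i) out[i] = 0;
    if (circ) {
      if (hasR && hasN) out[6] = 1;
      else if (hasR) out[0] = 1;
      else if (hasN) out[7] = 1;
      if (!hasR && seq_contains(s, circ, rcREP)) out[1] = 1;
      if (hasC) out[4] = 1;
      else if (seq_contains(s, circ, rcCT)) out[5] = 1;
    } else {
      if (hasR) {
        out[2] = 1;
        if ((double)s.size() < 1.5 * (double)P.CS_REP.size()) out[8] = 1;
      } else if (seq_contains(s, circ, rcREP)) out[3] = 1;
      if (hasN && (double)s.size() < 1.5 * (double)P.CS_NR.size()) out[9] = 1;
    }
  }
  Seq rcREP, rcNR, rcCT;
  void refresh_rc() {
    rcREP = revcomp_cpp(P.CS_REP);
    rcNR = revcomp_cpp(P.CS_NR);
    rcCT = revcomp_cpp(P.CS_CT);
  }

  struct CensusOut {
    long long raw[10], occ[10];
    std::map<int, long long> hist;   // genome-length histogram (circular, CS_REP)
    long long npre, nnt, nstrand;
    long long mass;
  };

  void census(CensusOut& out) {
    for (int i = 0; i < 10; ++i) { out.raw[i] = 0; out.occ[i] = 0; }
    out.hist.clear();
    out.npre = 0; out.nnt = 0; out.nstrand = 0;
    long long tmp[10];
    for (int r = 0; r < R; ++r) {
      out.npre += pre[r];
      for (int b = 0; b < 4; ++b) out.nnt += nt[r][b];
    }
    for (size_t i = 0; i < ents.size(); ++i) {
      const Ent& e = ents[i];
      if (!e.alive) continue;
      bool occupied = !e.segs.empty();
      classify(e.seq, e.circular, tmp);
      out.nstrand++;
      for (int k = 0; k < 10; ++k) {
        out.raw[k] += tmp[k];
        if (occupied) out.occ[k] += tmp[k];
      }
      if (e.circular && (tmp[0] || tmp[6])) out.hist[(int)e.seq.size()]++;
      for (size_t s = 0; s < e.segs.size(); ++s) {
        classify(e.segs[s].sub, false, tmp);
        out.nstrand++;
        for (int k = 0; k < 10; ++k) { out.raw[k] += tmp[k]; out.occ[k] += tmp[k]; }
      }
    }
    out.mass = total_mass();
  }

  // per-room spatial snapshot: precursors, free nucleotides, 10 categories
  List snapshot() {
    IntegerMatrix preM(N, N), ntM(N, N);
    std::vector<IntegerMatrix> cat;
    for (int k = 0; k < 10; ++k) cat.push_back(IntegerMatrix(N, N));
    long long tmp[10];
    for (int r = 0; r < R; ++r) {
      int row = r / N, col = r % N;
      preM(row, col) = (int)pre[r];
      ntM(row, col) = (int)(nt[r][0] + nt[r][1] + nt[r][2] + nt[r][3]);
      for (size_t i = 0; i < room_ents[r].size(); ++i) {
        const Ent& e = ents[room_ents[r][i]];
        classify(e.seq, e.circular, tmp);
        for (int k = 0; k < 10; ++k) cat[k](row, col) += (int)tmp[k];
        for (size_t s = 0; s < e.segs.size(); ++s) {
          classify(e.segs[s].sub, false, tmp);
          for (int k = 0; k < 10; ++k) cat[k](row, col) += (int)tmp[k];
        }
      }
    }
    List ch = List::create(
      _["precursors"] = preM, _["free_nucleotides"] = ntM,
      _["cir_rep"] = cat[0], _["cir_repcom"] = cat[1], _["lin_rep"] = cat[2],
      _["lin_repcom"] = cat[3], _["cir_ct"] = cat[4], _["cir_ctcom"] = cat[5],
      _["cir_repnr"] = cat[6], _["cir_nr"] = cat[7], _["lin_rep_rib"] = cat[8],
      _["lin_nr_rib"] = cat[9]);
    return ch;
  }

  // --- state (de)serialization ---------------------------------------------

  std::string rng_state() const {
    std::ostringstream os;
    os << rng;
    return os.str();
  }
  void set_rng_state(const std::string& s) {
    std::istringstream is(s);
    is >> rng;
  }

  List to_state() {
    IntegerMatrix preM(N, N);
    IntegerVector ntA(N * N * 4);
    ntA.attr("dim") = IntegerVector::create(N, N, 4);
    for (int r = 0; r < R; ++r) {
      int row = r / N, col = r % N;
      preM(row, col) = (int)pre[r];
      for (int b = 0; b < 4; ++b) ntA[row + N * col + N * N * b] = (int)nt[r][b];
    }
    List el;
    for (int r = 0; r < R; ++r) {
      for (size_t i = 0; i < room_ents[r].size(); ++i) {
        const Ent& e = ents[room_ents[r][i]];
        List segs;
        for (size_t s = 0; s < e.segs.size(); ++s) {
          const Seg& sg = e.segs[s];
          LogicalVector mm(sg.mm.size());
          for (size_t j = 0; j < sg.mm.size(); ++j) mm[j] = sg.mm[j] != 0;
          segs.push_back(List::create(
            _["substrate"] = seq_to_string(sg.sub),
            _["start"] = sg.start,
            _["mismatch"] = mm));
        }
        el.push_back(List::create(
          _["sequence"] = seq_to_string(e.seq),
          _["topology"] = e.circular ? "circular" : "linear",
          _["row"] = r / N + 1, _["col"] = r % N + 1,
          _["segments"] = segs));
      }
    }
    return List::create(
      _["N"] = N,
      _["step"] = (double)step_no,
      _["precursors"] = preM,
      _["nucleotides"] = ntA,
      _["entities"] = el,
      _["inoculated"] = (double)inoculated,
      _["rng"] = rng_state());
  }

  void from_state(List st, List params) {
    P = pars_from_list(params);
    refresh_rc();
    int n = as<int>(st["N"]);
    init_grid(n);
    step_no = (long long)as<double>(st["step"]);
    inoculated = (long long)as<double>(st["inoculated"]);
    IntegerMatrix preM = st["precursors"];
    IntegerVector ntA = st["nucleotides"];
    for (int r = 0; r < R; ++r) {
      int row = r / N, col = r % N;
      pre[r] = preM(row, col);
      for (int b = 0; b < 4; ++b) nt[r][b] = ntA[row + N * col + N * N * b];
    }
    List el = st["entities"];
    for (int i = 0; i < el.size(); ++i) {
      List ent = el[i];
      std::string seq = as<std::string>(ent["sequence"]);
      bool circ = as<std::string>(ent["topology"]) == "circular";
      int row = as<int>(ent["row"]) - 1, col = as<int>(ent["col"]) - 1;
      int room = row * N + col;
      int id = new_ent();
      ents[id].seq = seq_from_string(seq);
      if (circ) ents[id].seq = canonical_rotation_cpp(ents[id].seq);
      ents[id].circular = circ;
      List segs = ent["segments"];
      for (int s = 0; s < segs.size(); ++s) {
        List sl = segs[s];
        Seg sg;
        sg.sub = seq_from_string(as<std::string>(sl["substrate"]));
        sg.start = as<int>(sl["start"]);
        if (sl.containsElementNamed("mismatch") && !Rf_isNull(sl["mismatch"])) {
          LogicalVector mm = sl["mismatch"];
          for (int j = 0; j < mm.size(); ++j) sg.mm.push_back(mm[j] ? 1 : 0);
        }
        while (sg.mm.size() < sg.sub.size()) sg.mm.push_back(0);
        insert_seg_sorted(ents[id], sg);
      }
      add_to_room(id, room);
    }
    if (st.containsElementNamed("rng") && !Rf_isNull(st["rng"])) {
      std::string rs = as<std::string>(st["rng"]);
      if (!rs.empty()) set_rng_state(rs);
    }
  }
};

// ---------------------------------------------------------------------------
// exported entry points

static NumericVector counters_to_R(const Counters& c) {
  return NumericVector::create(
    _["nt_formed"] = (double)c.nt_formed,
    _["nt_formed_enzymatic"] = (double)c.nt_formed_enz,
    _["nt_decayed"] = (double)c.nt_decayed,
    _["random_ligations"] = (double)c.random_ligations,
    _["circularizations"] = (double)c.circularizations,
    _["attractions"] = (double)c.attractions,
    _["mismatches"] = (double)c.mismatches,
    _["template_ligations"] = (double)c.template_ligations,
    _["template_ligations_enzymatic"] = (double)c.template_ligations_enz,
    _["circular_releases"] = (double)c.circular_releases,
    _["separations"] = (double)c.separations,
    _["bond_breaks"] = (double)c.bond_breaks,
    _["end_decays"] = (double)c.end_decays,
    _["moves"] = (double)c.moves);
}

static const char* CATS[10] = {
  "cir_rep", "cir_repcom", "lin_rep", "lin_repcom", "cir_ct", "cir_ctcom",
  "cir_repnr", "cir_nr", "lin_rep_rib", "lin_nr_rib"};

// [[Rcpp::export]]
List cpp_run(List cfg) {
  Engine eng;
  List params = cfg["params"];
  eng.P = pars_from_list(params);
  eng.refresh_rc();
  eng.init_grid(eng.P.N);
  int seed = as<int>(cfg["seed"]);
  eng.rng.seed((uint64_t)seed);
  long long steps = (long long)as<double>(cfg["steps"]);
  long long observe_every = (long long)as<double>(cfg["observe_every"]);
  std::vector<long long> snapshot_steps;
  if (!Rf_isNull(cfg["snapshot_steps"])) {
    NumericVector ss = cfg["snapshot_steps"];
    for (int i = 0; i < ss.size(); ++i) snapshot_steps.push_back((long long)ss[i]);
  }
  bool record_mass = as<bool>(cfg["record_mass"]);
  if (cfg.containsElementNamed("profile")) eng.profile = as<bool>(cfg["profile"]);
  bool keep_state = as<bool>(cfg["keep_state"]);
  int verbose = as<int>(cfg["verbose"]);

  // inoculations: parallel vectors
  std::vector<long long> in_step, in_every, in_count;
  std::vector<bool> in_until_stop, in_active;
  std::vector<Seq> in_seq;
  std::vector<bool> in_circ;
  if (!Rf_isNull(cfg["inoculations"])) {
    List io = cfg["inoculations"];
    NumericVector stp = io["step"], evr = io["every"], cnt = io["count"];
    CharacterVector sq = io["sequence"], tp = io["topology"];
    LogicalVector us = io["until_stop"];
    for (int i = 0; i < stp.size(); ++i) {
      in_step.push_back((long long)stp[i]);
      in_every.push_back((long long)evr[i]);
      in_count.push_back((long long)cnt[i]);
      in_seq.push_back(seq_from_string(as<std::string>(sq[i])));
      in_circ.push_back(as<std::string>(tp[i]) == "circular");
      in_until_stop.push_back(us[i]);
      in_active.push_back(true);
    }
  }
  // interventions
  std::vector<long long> iv_step;
  std::vector<std::string> iv_param;
  std::vector<double> iv_value;
  std::vector<int> iv_topo;
  std::vector<std::string> iv_motif;
  std::vector<bool> iv_rc, iv_scoped;
  if (!Rf_isNull(cfg["interventions"])) {
    List iv = cfg["interventions"];
    NumericVector stp = iv["step"], val = iv["value"];
    CharacterVector par = iv["parameter"], topo = iv["scope_topology"], mot = iv["scope_motif"];
    LogicalVector rc = iv["scope_revcomp"], scoped = iv["scoped"];
    for (int i = 0; i < stp.size(); ++i) {
      iv_step.push_back((long long)stp[i]);
      iv_param.push_back(as<std::string>(par[i]));
      iv_value.push_back(val[i]);
      iv_scoped.push_back(scoped[i]);
      if (scoped[i]) {
        std::string t = CharacterVector::is_na(topo[i]) ? "any" : as<std::string>(topo[i]);
        iv_topo.push_back(t == "linear" ? 1 : (t == "circular" ? 2 : 0));
        iv_motif.push_back(CharacterVector::is_na(mot[i]) ? "" : as<std::string>(mot[i]));
        iv_rc.push_back(rc[i]);
      } else {
        iv_topo.push_back(0);
        iv_motif.push_back("");
        iv_rc.push_back(false);
      }
    }
  }
  // stop rule
  bool has_stop = false;
  int stop_cat = 0; long long stop_threshold = 0; int stop_consecutive = 0;
  if (!Rf_isNull(cfg["stop_rule"])) {
    List sr = cfg["stop_rule"];
    has_stop = true;
    std::string cat = as<std::string>(sr["category"]);
    stop_cat = -1;
    for (int k = 0; k < 10; ++k) if (cat == CATS[k]) stop_cat = k;
    if (stop_cat < 0) stop("unknown stop-rule category '%s'", cat);
    stop_threshold = (long long)as<double>(sr["threshold"]);
    stop_consecutive = as<int>(sr["consecutive"]);
  }
  int stop_run = 0;
  bool stopped = false;
  long long stopped_at = -1;

  eng.seed_precursors((long long)eng.P.T_NPB);

  long long nobs_max = steps / observe_every + 2;
  std::vector<double> obs_step; obs_step.reserve(nobs_max);
  std::vector<std::array<long long, 24>> rows; rows.reserve(nobs_max);
  std::vector<double> hist_step, hist_len, hist_count;
  std::vector<double> mass_trace, mass_expected;
  if (record_mass) { mass_trace.reserve(steps); mass_expected.reserve(steps); }
  List snaps;

  Engine::CensusOut co;
  for (long long s = 1; s <= steps; ++s) {
    if ((s & 1023) == 0) Rcpp::checkUserInterrupt();
    // interventions scheduled for step s fire before the step executes
    // (step 0 means "before the first step")
    for (size_t i = 0; i < iv_step.size(); ++i) {
      if (std::max(iv_step[i], (long long)1) != s) continue;
      const std::string& pn = iv_param[i];
      double v = iv_value[i];
      if (iv_scoped[i]) {
        if (pn != "F_LT") stop("species-scoped interventions are supported for F_LT only");
        Scope sc;
        sc.value = v;
        sc.topo = iv_topo[i];
        sc.has_motif = !iv_motif[i].empty();
        if (sc.has_motif) {
          sc.motif = seq_from_string(iv_motif[i]);
          sc.motif_rc = revcomp_cpp(sc.motif);
        }
        sc.use_rc = iv_rc[i];
        eng.flt_scopes.push_back(sc);
      } else {
        Pars& P = eng.P;
        if (pn == "P_AT") P.P_AT = v; else if (pn == "P_BB") P.P_BB = v;
        else if (pn == "P_EL") P.P_EL = v; else if (pn == "P_FP") P.P_FP = v;
        else if (pn == "P_MN") P.P_MN = v; else if (pn == "P_MNP") P.P_MNP = v;
        else if (pn == "P_ND") P.P_ND = v; else if (pn == "P_NDE") P.P_NDE = v;
        else if (pn == "P_NF") P.P_NF = v; else if (pn == "P_NFR") P.P_NFR = v;
        else if (pn == "P_RL") P.P_RL = v; else if (pn == "P_SP") P.P_SP = v;
        else if (pn == "P_TL") P.P_TL = v; else if (pn == "P_TLR") P.P_TLR = v;
        else if (pn == "F_DA") P.F_DA = v; else if (pn == "F_LT") P.F_LT = v;
        else if (pn == "T_REP") P.T_REP = (int)v; else if (pn == "T_NR") P.T_NR = (int)v;
        else stop("cannot intervene on parameter '%s'", pn);
      }
    }
    // inoculations scheduled for step s (step 0 fires before step 1)
    for (size_t i = 0; i < in_step.size(); ++i) {
      if (!in_active[i]) continue;
      long long st0 = std::max(in_step[i], (long long)1);
      bool fire = (in_every[i] <= 0)
        ? (st0 == s)
        : (s >= st0 && (s - st0) % in_every[i] == 0);
      if (fire) eng.inoculate(in_seq[i], in_circ[i], in_count[i]);
      if (in_every[i] <= 0 && st0 == s) in_active[i] = false;
    }

    eng.do_step();

    if (record_mass) {
      mass_trace.push_back((double)eng.total_mass());
      mass_expected.push_back(eng.P.T_NPB + (double)eng.inoculated);
    }
    bool last = (s == steps);
    if (s % observe_every == 0 || last) {
      eng.census(co);
      obs_step.push_back((double)s);
      std::array<long long, 24> row;
      for (int k = 0; k < 10; ++k) { row[k] = co.raw[k]; row[10 + k] = co.occ[k]; }
      row[20] = co.mass; row[21] = co.npre; row[22] = co.nnt; row[23] = co.nstrand;
      rows.push_back(row);
      for (std::map<int, long long>::iterator it = co.hist.begin(); it != co.hist.end(); ++it) {
        hist_step.push_back((double)s);
        hist_len.push_back((double)it->first);
        hist_count.push_back((double)it->second);
      }
      if (has_stop && !stopped) {
        if (co.raw[stop_cat] >= stop_threshold) stop_run++; else stop_run = 0;
        if (stop_run >= stop_consecutive) {
          stopped = true;
          stopped_at = s;
          for (size_t i = 0; i < in_active.size(); ++i)
            if (in_until_stop[i]) in_active[i] = false;
        }
      }
      if (verbose > 0 && (verbose > 1 || last)) {
        Rcpp::Rcerr << "step " << s << " cir_rep=" << co.raw[0]
                    << " cir_repnr=" << co.raw[6] << " strands=" << co.nstrand << "\n";
      }
    }
    for (size_t i = 0; i < snapshot_steps.size(); ++i) {
      if (snapshot_steps[i] == s) {
        snaps.push_back(List::create(_["step"] = (double)s, _["channels"] = eng.snapshot()));
        break;
      }
    }
  }

  size_t nr = rows.size();
  NumericMatrix census(nr, 24);
  for (size_t i = 0; i < nr; ++i)
    for (int k = 0; k < 24; ++k) census(i, k) = (double)rows[i][k];
  CharacterVector cn(24);
  for (int k = 0; k < 10; ++k) { cn[k] = CATS[k]; cn[10 + k] = std::string(CATS[k]) + "_occ"; }
  cn[20] = "total_mass"; cn[21] = "n_precursors"; cn[22] = "n_nucleotides"; cn[23] = "n_strands";
  colnames(census) = cn;

  List out = List::create(
    _["step"] = wrap(obs_step),
    _["census"] = census,
    _["hist_step"] = wrap(hist_step),
    _["hist_length"] = wrap(hist_len),
    _["hist_count"] = wrap(hist_count),
    _["snapshots"] = snaps,
    _["counters"] = counters_to_R(eng.ct),
    _["phase_ns"] = NumericVector(eng.phase_ns, eng.phase_ns + 12),
    _["stopped_at"] = (double)stopped_at,
    _["inoculated"] = (double)eng.inoculated,
    _["mass_trace"] = record_mass ? wrap(mass_trace) : R_NilValue,
    _["mass_expected"] = record_mass ? wrap(mass_expected) : R_NilValue,
    _["final_state"] = keep_state ? (SEXP)eng.to_state() : R_NilValue);
  return out;
}

// [[Rcpp::export]]
List cpp_step_state(List state, List params, int nsteps, SEXP seed, bool record_mass) {
  Engine eng;
  eng.from_state(state, params);
  if (!Rf_isNull(seed)) eng.rng.seed((uint64_t)as<int>(seed));
  else if (!state.containsElementNamed("rng") || Rf_isNull(state["rng"]) ||
           as<std::string>(state["rng"]).empty())
    stop("state carries no RNG state; supply `seed`");
  std::vector<double> mass_trace, mass_expected;
  for (int s = 0; s < nsteps; ++s) {
    if ((s & 1023) == 0) Rcpp::checkUserInterrupt();
    eng.do_step();
    if (record_mass) {
      mass_trace.push_back((double)eng.total_mass());
      mass_expected.push_back((double)eng.inoculated);   // relative to creation baseline
    }
  }
  List st = eng.to_state();
  return List::create(
    _["state"] = st,
    _["mass_trace"] = record_mass ? wrap(mass_trace) : R_NilValue);
}

// [[Rcpp::export]]
List cpp_census_state(List state, List params) {
  Engine eng;
  eng.from_state(state, params);
  Engine::CensusOut co;
  eng.census(co);
  NumericVector raw(10), occ(10);
  CharacterVector nm(10);
  for (int k = 0; k < 10; ++k) { raw[k] = (double)co.raw[k]; occ[k] = (double)co.occ[k]; nm[k] = CATS[k]; }
  raw.names() = nm; occ.names() = nm;
  NumericVector hl, hc;
  for (std::map<int, long long>::iterator it = co.hist.begin(); it != co.hist.end(); ++it) {
    hl.push_back((double)it->first);
    hc.push_back((double)it->second);
  }
  return List::create(
    _["counts"] = raw, _["occupied"] = occ,
    _["hist_length"] = hl, _["hist_count"] = hc,
    _["mass"] = (double)co.mass,
    _["n_precursors"] = (double)co.npre,
    _["n_nucleotides"] = (double)co.nnt,
    _["n_strands"] = (double)co.nstrand);
}

// [[Rcpp::export]]
List cpp_snapshot_state(List state, List params) {
  Engine eng;
  eng.from_state(state, params);
  return eng.snapshot();
}

// [[Rcpp::export]]
std::string cpp_canonical_rotation(std::string s) {
  return seq_to_string(canonical_rotation_cpp(seq_from_string(s)));
}

// [[Rcpp::export]]
bool cpp_contains(std::string s, bool circular, std::string motif) {
  return seq_contains(seq_from_string(s), circular, seq_from_string(motif));
}
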