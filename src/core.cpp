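// Compiled kernels: affine-gap (Gotoh) alignment with traceback, k-mer
// anchored long-read alignment, pileup counting, and reference-guided
// majority consensus. Cigars use the extended ops =, X, I, D (and S for
// unalignable read ends); coordinates are 0-based half-open throughout.
#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <string>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

typedef std::vector<std::pair<char,int> > Ops;

static const int NEG = -100000000;

static inline int b2i(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  }
  return -1;
}

static void push_op(Ops &o, char c, int l) {
  if (l <= 0) return;
  if (!o.empty() && o.back().first == c) o.back().second += l;
  else o.push_back(std::make_pair(c, l));
}

static Ops parse_cigar(const std::string &s) {
  Ops out;
  int l = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    char c = s[i];
    if (c >= '0' && c <= '9') l = l * 10 + (c - '0');
    else { push_op(out, c, l); l = 0; }
  }
  return out;
}

static std::string ops_str(const Ops &o) {
  std::string s;
  char buf[16];
  for (size_t i = 0; i < o.size(); ++i) {
    snprintf(buf, sizeof(buf), "%d%c", o[i].second, o[i].first);
    s += buf;
  }
  return s;
}

static long ops_score(const Ops &o, int ma, int mi, int go, int ge) {
  long s = 0;
  for (size_t i = 0; i < o.size(); ++i) {
    char c = o[i].first; int l = o[i].second;
    if (c == '=') s += (long)ma * l;
    else if (c == 'X') s += (long)mi * l;
    else if (c == 'I' || c == 'D') s += go + (long)ge * l;
  }
  return s;
}

// ---------------------------------------------------------------- Gotoh ---
// Global affine alignment of query a against reference b, optionally with a
// cost-free unaligned prefix/suffix on the reference side (used for read
// head/tail segments).  Deterministic tie-break: H > D(gap in query) >
// I(gap in ref); traceback prefers the diagonal.
struct AlnRes {
  long score;
  Ops ops;          // over the aligned region only
  int b_start, b_end;
  bool ok;
};

static AlnRes gotoh(const std::string &a, const std::string &b,
                    int ma, int mi, int go, int ge,
                    bool free_b_lead, bool free_b_trail,
                    double max_cells = 2.6e7) {
  AlnRes res; res.ok = false; res.score = NEG; res.b_start = 0; res.b_end = 0;
  int n = (int)a.size(), m = (int)b.size();
  if ((double)(n + 1) * (double)(m + 1) > max_cells) return res;
  if (n == 0) {
    res.ok = true;
    if (free_b_lead || free_b_trail) { res.score = 0; res.b_start = free_b_lead ? m : 0; res.b_end = res.b_start; }
    else { res.score = (m > 0) ? (go + (long)ge * m) : 0; push_op(res.ops, 'D', m); res.b_start = 0; res.b_end = m; }
    return res;
  }
  size_t W = (size_t)m + 1;
  std::vector<int> H((size_t)(n + 1) * W, NEG), E(H), F(H);
  std::vector<uint8_t> tH((size_t)(n + 1) * W, 0), tE(tH), tF(tH);
  // tH: 0=fromH,1=fromE,2=fromF at diag step; at i==0 means "start here"
  // tE: 0=extend,1=openH,2=openF ; tF: 0=extend,1=openH,2=openE
  H[0] = 0;
  for (int j = 1; j <= m; ++j) {
    if (free_b_lead) { H[j] = 0; }
    else {
      E[j] = go + ge * j;           // leading deletion
      tE[j] = (j == 1) ? 1 : 0;
    }
  }
  for (int i = 1; i <= n; ++i) {
    F[(size_t)i * W] = go + ge * i;
    tF[(size_t)i * W] = (i == 1) ? 1 : 0;
    for (int j = 1; j <= m; ++j) {
      size_t c = (size_t)i * W + j, up = c - W, lf = c - 1, dg = up - 1;
      // E: gap consuming b (deletion in query)
      int e1 = (E[lf] > NEG) ? E[lf] + ge : NEG;
      int e2 = (H[lf] > NEG) ? H[lf] + go + ge : NEG;
      int e3 = (F[lf] > NEG) ? F[lf] + go + ge : NEG;
      if (e2 >= e1 && e2 >= e3) { E[c] = e2; tE[c] = 1; }
      else if (e1 >= e3)        { E[c] = e1; tE[c] = 0; }
      else                      { E[c] = e3; tE[c] = 2; }
      // F: gap consuming a (insertion wrt ref)
      int f1 = (F[up] > NEG) ? F[up] + ge : NEG;
      int f2 = (H[up] > NEG) ? H[up] + go + ge : NEG;
      int f3 = (E[up] > NEG) ? E[up] + go + ge : NEG;
      if (f2 >= f1 && f2 >= f3) { F[c] = f2; tF[c] = 1; }
      else if (f1 >= f3)        { F[c] = f1; tF[c] = 0; }
      else                      { F[c] = f3; tF[c] = 2; }
      // H: diagonal
      int best = H[dg]; uint8_t tb = 0;
      if (E[dg] > best) { best = E[dg]; tb = 1; }
      if (F[dg] > best) { best = F[dg]; tb = 2; }
      if (best > NEG) {
        int s = (a[i - 1] == b[j - 1]) ? ma : mi;
        H[c] = best + s; tH[c] = tb;
      }
    }
  }
  // terminal cell
  int bi = n, bj = m; char st = 'H'; long bs = NEG;
  if (free_b_trail) {
    for (int j = 0; j <= m; ++j) {
      size_t c = (size_t)n * W + j;
      if (H[c] > bs) { bs = H[c]; bj = j; st = 'H'; }
      if (F[c] > bs) { bs = F[c]; bj = j; st = 'F'; }
    }
  } else {
    size_t c = (size_t)n * W + m;
    bs = H[c]; st = 'H';
    if (E[c] > bs) { bs = E[c]; st = 'E'; }
    if (F[c] > bs) { bs = F[c]; st = 'F'; }
  }
  if (bs <= NEG) return res;
  res.b_end = bj;
  Ops rev;
  int i = bi, j = bj;
  while (!(i == 0 && j == 0)) {
    size_t c = (size_t)i * W + j;
    if (st == 'H') {
      if (i == 0) break;           // H[0][j] == 0 start cell (free_b_lead)
      uint8_t tb = tH[c];
      push_op(rev, (a[i - 1] == b[j - 1]) ? '=' : 'X', 1);
      --i; --j;
      st = (tb == 0) ? 'H' : (tb == 1 ? 'E' : 'F');
    } else if (st == 'E') {
      uint8_t tb = tE[c];
      push_op(rev, 'D', 1);
      --j;
      st = (tb == 0) ? 'E' : (tb == 1 ? 'H' : 'F');
    } else {
      uint8_t tb = tF[c];
      push_op(rev, 'I', 1);
      --i;
      st = (tb == 0) ? 'F' : (tb == 1 ? 'H' : 'E');
    }
  }
  res.b_start = j;
  // collapse reversed ops
  Ops fw;
  for (int k2 = (int)rev.size() - 1; k2 >= 0; --k2) push_op(fw, rev[k2].first, rev[k2].second);
  res.ops = fw;
  res.score = bs;
  res.ok = true;
  return res;
}

// [[Rcpp::export]]
List cpp_align_global(std::string a, std::string b,
                      int match, int mismatch, int gap_open, int gap_extend,
                      bool free_b_lead = false, bool free_b_trail = false) {
  AlnRes r = gotoh(a, b, match, mismatch, gap_open, gap_extend,
                   free_b_lead, free_b_trail, 3.0e8);
  if (!r.ok) stop("alignment problem too large for quadratic DP");
  return List::create(_["score"] = (double)r.score,
                      _["cigar"] = ops_str(r.ops),
                      _["b_start"] = r.b_start,
                      _["b_end"] = r.b_end);
}

// ------------------------------------------------------------ k-mer index --
struct KIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<int> > pos;
};

static bool kmer_at(const std::string &s, int i, int k, uint64_t &out) {
  uint64_t v = 0;
  for (int j = 0; j < k; ++j) {
    int b = b2i(s[i + j]);
    if (b < 0) return false;
    v = (v << 2) | (uint64_t)b;
  }
  out = v;
  return true;
}

static void build_index(const std::string &s, int k, int step, KIndex &ix) {
  ix.k = k;
  ix.pos.clear();
  if ((int)s.size() < k) return;
  ix.pos.reserve(s.size() / step + 16);
  uint64_t v;
  for (int i = 0; i + k <= (int)s.size(); i += step)
    if (kmer_at(s, i, k, v)) ix.pos[v].push_back(i);
}

static std::string revcomp(const std::string &s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    char c = s[s.size() - 1 - i], o = 'N';
    switch (c) {
    case 'A': o = 'T'; break; case 'C': o = 'G'; break;
    case 'G': o = 'C'; break; case 'T': o = 'A'; break;
    case 'a': o = 't'; break; case 'c': o = 'g'; break;
    case 'g': o = 'c'; break; case 't': o = 'a'; break;
    }
    r[i] = o;
  }
  return r;
}

struct Anchor { int q, r; };

// longest chain with strictly increasing q and r (patience LIS on r after
// sorting by q; ties on q processed with descending r)
static std::vector<Anchor> chain_anchors(std::vector<Anchor> &an) {
  std::sort(an.begin(), an.end(), [](const Anchor &x, const Anchor &y) {
    if (x.q != y.q) return x.q < y.q;
    return x.r > y.r;
  });
  int n = (int)an.size();
  std::vector<int> tails;           // indices into an
  std::vector<int> prev(n, -1), tailAt(n, -1);
  for (int i = 0; i < n; ++i) {
    int lo = 0, hi = (int)tails.size();
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (an[tails[mid]].r < an[i].r) lo = mid + 1; else hi = mid;
    }
    if (lo > 0) prev[i] = tails[lo - 1];
    if (lo == (int)tails.size()) tails.push_back(i); else tails[lo] = i;
  }
  std::vector<Anchor> out;
  if (tails.empty()) return out;
  int cur = tails.back();
  std::vector<int> idx;
  while (cur >= 0) { idx.push_back(cur); cur = prev[cur]; }
  for (int i = (int)idx.size() - 1; i >= 0; --i) out.push_back(an[idx[i]]);
  return out;
}

// Drop spurious chain segments: a stray k-mer hit elsewhere in the
// reference can extend the LIS by one, creating a bogus mega-gap.  Split
// the chain at large gaps and keep only segments with real support.
static std::vector<Anchor> filter_chain(const std::vector<Anchor> &ch, int k) {
  std::vector<std::vector<Anchor> > segs;
  for (size_t i = 0; i < ch.size(); ++i) {
    if (segs.empty() || ch[i].q - segs.back().back().q > 2000 ||
        ch[i].r - segs.back().back().r > 2000)
      segs.push_back(std::vector<Anchor>());
    segs.back().push_back(ch[i]);
  }
  std::vector<Anchor> out;
  for (size_t s = 0; s < segs.size(); ++s) {
    int qspan = segs[s].back().q + k - segs[s].front().q;
    if ((int)segs[s].size() >= 3 || qspan >= 150)
      out.insert(out.end(), segs[s].begin(), segs[s].end());
  }
  return out;
}

// Canonical (leftmost) gap placement: shift every I/D run left while the
// alignment score is unchanged, so equivalent placements inside repeats
// agree across reads.
static void left_align_ops(Ops &ops, const std::string &q,
                           const std::string &b, int r_start) {
  if (ops.size() < 2) return;
  // positions of each op
  for (size_t i = 1; i < ops.size(); ++i) {
    char c = ops[i].first;
    if (c != 'I' && c != 'D') continue;
    if (ops[i - 1].first != '=') continue;
    // compute q, r at start of op i
    int qp = 0, rp = r_start;
    for (size_t j = 0; j < i; ++j) {
      char cj = ops[j].first; int lj = ops[j].second;
      if (cj == '=' || cj == 'X' || cj == 'M') { qp += lj; rp += lj; }
      else if (cj == 'I' || cj == 'S') qp += lj;
      else if (cj == 'D') rp += lj;
    }
    int l = ops[i].second, s = 0, maxs = ops[i - 1].second;
    if (c == 'I') {
      while (s < maxs && qp - 1 - s >= 0 &&
             q[qp + l - 1 - s] == b[rp - 1 - s]) ++s;
    } else {
      while (s < maxs && rp - 1 - s >= 0 &&
             b[rp + l - 1 - s] == b[rp - 1 - s]) ++s;
    }
    if (s == 0) continue;
    ops[i - 1].second -= s;
    if (i + 1 < ops.size() && ops[i + 1].first == '=') {
      ops[i + 1].second += s;
    } else {
      ops.insert(ops.begin() + i + 1, std::make_pair('=', s));
    }
    if (ops[i - 1].second == 0) ops.erase(ops.begin() + (i - 1));
  }
  // collapse any now-adjacent same ops
  Ops out;
  for (size_t i = 0; i < ops.size(); ++i) push_op(out, ops[i].first, ops[i].second);
  ops = out;
}

// [[Rcpp::export]]
std::string cpp_left_align_cigar(std::string cigar, std::string qseq,
                                 std::string ref, int ref_start) {
  Ops ops = parse_cigar(cigar);
  left_align_ops(ops, qseq, ref, ref_start);
  return ops_str(ops);
}

// Build an alignment of full query q against reference b from an anchor
// chain; k = anchor length.  Gaps between anchors filled with Gotoh; a
// one-sided gap becomes a pure I/D run.  Head/tail are semi-global.
static bool anchors_to_alignment(const std::string &q, const std::string &b,
                                 std::vector<Anchor> chain, int k,
                                 int ma, int mi, int go, int ge,
                                 int &r_start, Ops &out) {
  if (chain.empty()) return false;
  // merge/trim overlapping anchors: keep subset with q step >= k unless on
  // the same diagonal (extendable run)
  std::vector<Anchor> ch;
  for (size_t i = 0; i < chain.size(); ++i) {
    if (ch.empty()) { ch.push_back(chain[i]); continue; }
    Anchor &p = ch.back();
    long dq = chain[i].q - p.q, dr = chain[i].r - p.r;
    if (dq == dr && dq < k) continue;                 // same diagonal overlap, covered
    if (dq < k || dr < k) continue;                   // conflicting overlap, drop
    ch.push_back(chain[i]);
  }
  Ops ops;
  // head
  int q0 = ch.front().q, r0 = ch.front().r;
  int pad = q0 + q0 / 4 + 32;
  int hb = std::max(0, r0 - pad);
  if (q0 > 0) {
    if (q0 > 20000) return false;
    AlnRes hr = gotoh(q.substr(0, q0), b.substr(hb, r0 - hb),
                      ma, mi, go, ge, true, false);
    if (!hr.ok) return false;
    r_start = hb + hr.b_start;
    for (size_t i = 0; i < hr.ops.size(); ++i) push_op(ops, hr.ops[i].first, hr.ops[i].second);
  } else r_start = r0;
  push_op(ops, '=', k);
  int cq = q0 + k, cr = r0 + k;
  for (size_t i = 1; i < ch.size(); ++i) {
    int nq = ch[i].q, nr = ch[i].r;
    int gl = nq - cq, gr = nr - cr;
    if (gl < 0 || gr < 0) continue;       // shouldn't happen after trim
    if (gl == 0 && gr == 0) {
      push_op(ops, '=', k);
    } else if (gl == 0) {
      push_op(ops, 'D', gr); push_op(ops, '=', k);
    } else if (gr == 0) {
      push_op(ops, 'I', gl); push_op(ops, '=', k);
    } else {
      AlnRes sr = gotoh(q.substr(cq, gl), b.substr(cr, gr),
                        ma, mi, go, ge, false, false);
      if (!sr.ok) {
        // fallback for oversized segment: pair off min length, indel the rest
        int mn = std::min(gl, gr);
        push_op(ops, 'X', mn);
        if (gl > mn) push_op(ops, 'I', gl - mn);
        if (gr > mn) push_op(ops, 'D', gr - mn);
      } else {
        for (size_t j = 0; j < sr.ops.size(); ++j) push_op(ops, sr.ops[j].first, sr.ops[j].second);
      }
      push_op(ops, '=', k);
    }
    cq = nq + k; cr = nr + k;
  }
  // tail
  int tq = (int)q.size() - cq;
  if (tq > 0) {
    if (tq > 20000) return false;
    int te = std::min((int)b.size(), cr + tq + tq / 4 + 32);
    AlnRes tr = gotoh(q.substr(cq, tq), b.substr(cr, te - cr),
                      ma, mi, go, ge, false, true);
    if (!tr.ok) return false;
    for (size_t i = 0; i < tr.ops.size(); ++i) push_op(ops, tr.ops[i].first, tr.ops[i].second);
  }
  left_align_ops(ops, q, b, r_start);
  out = ops;
  return true;
}

// anchored pairwise alignment of two sequences (global in both; ends via
// semi-global head/tail against b)
// [[Rcpp::export]]
List cpp_anchored_align(std::string a, std::string b, int k,
                        int match, int mismatch, int gap_open, int gap_extend,
                        int max_occ = 8) {
  KIndex ix; build_index(b, k, 1, ix);
  std::vector<Anchor> an;
  uint64_t v;
  int step = std::max(1, (int)(a.size() / 4000));
  for (int i = 0; i + k <= (int)a.size(); i += step) {
    if (!kmer_at(a, i, k, v)) continue;
    std::unordered_map<uint64_t, std::vector<int> >::const_iterator it = ix.pos.find(v);
    if (it == ix.pos.end() || (int)it->second.size() > max_occ) continue;
    for (size_t j = 0; j < it->second.size(); ++j) {
      Anchor x; x.q = i; x.r = it->second[j]; an.push_back(x);
    }
  }
  std::vector<Anchor> chain = filter_chain(chain_anchors(an), k);
  Ops ops; int rs = 0;
  if (!anchors_to_alignment(a, b, chain, k, match, mismatch, gap_open, gap_extend, rs, ops))
    return List::create(_["ok"] = false);
  return List::create(_["ok"] = true,
                      _["score"] = (double)ops_score(ops, match, mismatch, gap_open, gap_extend),
                      _["cigar"] = ops_str(ops),
                      _["b_start"] = rs);
}

// ------------------------------------------------------------- read maps ---
// Map many reads against one reference.  Orientation chosen by raw k-mer
// hit count; position by colinear chain.  Returns one row per read.
// [[Rcpp::export]]
DataFrame cpp_map_reads(std::string ref, CharacterVector reads, int k,
                        int qstep, int max_occ,
                        int match, int mismatch, int gap_open, int gap_extend,
                        int min_anchors = 3) {
  KIndex ix; build_index(ref, k, 1, ix);
  int n = reads.size();
  IntegerVector pos(n, NA_INTEGER), strand(n, 1L);
  NumericVector score(n, NA_REAL), ident(n, NA_REAL);
  CharacterVector cig(n, NA_STRING), oseq(n, NA_STRING);
  LogicalVector mapped(n, false);
  for (int ri = 0; ri < n; ++ri) {
    std::string fw = as<std::string>(reads[ri]);
    std::string rv = revcomp(fw);
    std::vector<Anchor> best_chain; int best_strand = 1; size_t best_len = 0;
    std::string best_seq;
    for (int s = 0; s < 2; ++s) {
      const std::string &q = (s == 0) ? fw : rv;
      std::vector<Anchor> an;
      uint64_t v;
      for (int i = 0; i + k <= (int)q.size(); i += qstep) {
        if (!kmer_at(q, i, k, v)) continue;
        std::unordered_map<uint64_t, std::vector<int> >::const_iterator it = ix.pos.find(v);
        if (it == ix.pos.end() || (int)it->second.size() > max_occ) continue;
        for (size_t j = 0; j < it->second.size(); ++j) {
          Anchor x; x.q = i; x.r = it->second[j]; an.push_back(x);
        }
      }
      std::vector<Anchor> ch = filter_chain(chain_anchors(an), k);
      if (ch.size() > best_len) {
        best_len = ch.size(); best_chain = ch; best_strand = (s == 0) ? 1 : -1;
        best_seq = q;
      }
    }
    if ((int)best_len < min_anchors) continue;
    Ops ops; int rs = 0;
    if (!anchors_to_alignment(best_seq, ref, best_chain, k,
                              match, mismatch, gap_open, gap_extend, rs, ops))
      continue;
    long mt = 0, al = 0;
    for (size_t i = 0; i < ops.size(); ++i) {
      if (ops[i].first == '=') { mt += ops[i].second; al += ops[i].second; }
      else if (ops[i].first == 'X') al += ops[i].second;
    }
    if (al == 0) continue;
    pos[ri] = rs; strand[ri] = best_strand;
    cig[ri] = ops_str(ops);
    oseq[ri] = best_seq;
    score[ri] = (double)ops_score(ops, match, mismatch, gap_open, gap_extend);
    ident[ri] = (double)mt / (double)al;
    mapped[ri] = true;
  }
  return DataFrame::create(_["pos"] = pos, _["strand"] = strand,
                           _["cigar"] = cig, _["aln_seq"] = oseq,
                           _["score"] = score, _["identity"] = ident,
                           _["mapped"] = mapped,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------- pileup ---
// counts: 5 x L matrix (A, C, G, T, del) from alignments
// [[Rcpp::export]]
IntegerMatrix cpp_pileup(int ref_len, IntegerVector pos, CharacterVector cigar,
                         CharacterVector seq) {
  IntegerMatrix M(5, ref_len);
  for (int i = 0; i < pos.size(); ++i) {
    if (pos[i] == NA_INTEGER) continue;
    Ops ops = parse_cigar(as<std::string>(cigar[i]));
    std::string s = as<std::string>(seq[i]);
    int r = pos[i], q = 0;
    for (size_t j = 0; j < ops.size(); ++j) {
      char c = ops[j].first; int l = ops[j].second;
      if (c == '=' || c == 'X' || c == 'M') {
        for (int t = 0; t < l; ++t) {
          int bb = b2i(s[q + t]);
          if (bb >= 0 && r + t >= 0 && r + t < ref_len) M(bb, r + t)++;
        }
        r += l; q += l;
      } else if (c == 'D') {
        for (int t = 0; t < l; ++t) if (r + t >= 0 && r + t < ref_len) M(4, r + t)++;
        r += l;
      } else if (c == 'I' || c == 'S') {
        q += l;
      }
    }
  }
  return M;
}

// base carried by each read at each site: 0 = not covered, 1..4 = ACGT,
// 5 = deleted
// [[Rcpp::export]]
IntegerMatrix cpp_read_bases_at(IntegerVector pos, CharacterVector cigar,
                                CharacterVector seq, IntegerVector sites) {
  int n = pos.size(), m = sites.size();
  IntegerMatrix M(n, m);
  std::vector<int> ss(sites.begin(), sites.end());
  for (int i = 0; i < n; ++i) {
    if (pos[i] == NA_INTEGER) continue;
    Ops ops = parse_cigar(as<std::string>(cigar[i]));
    std::string s = as<std::string>(seq[i]);
    int r = pos[i], q = 0;
    size_t si = std::lower_bound(ss.begin(), ss.end(), r) - ss.begin();
    for (size_t j = 0; j < ops.size() && si < ss.size(); ++j) {
      char c = ops[j].first; int l = ops[j].second;
      if (c == '=' || c == 'X' || c == 'M') {
        while (si < ss.size() && ss[si] < r + l) {
          int bb = b2i(s[q + (ss[si] - r)]);
          M(i, si) = (bb >= 0) ? bb + 1 : 0;
          ++si;
        }
        r += l; q += l;
      } else if (c == 'D') {
        while (si < ss.size() && ss[si] < r + l) { M(i, si) = 5; ++si; }
        r += l;
      } else if (c == 'I' || c == 'S') q += l;
    }
  }
  return M;
}

// ------------------------------------------------------------- consensus ---
// Majority consensus over one layout chain of reads, in reference
// coordinates.  Returns pieces split at zero-coverage columns; each piece
// carries its reference start, consensus sequence, cigar vs reference and
// mean column agreement.
// [[Rcpp::export]]
List cpp_consensus(std::string ref, IntegerVector pos, CharacterVector cigar,
                   CharacterVector seq, int span_start, int span_end) {
  int L = span_end - span_start;
  if (L <= 0) return List::create();
  std::vector<int> cnt(5 * (size_t)L, 0);
  std::vector<int> cov((size_t)L, 0), spancov((size_t)L, 0);
  std::map<int, std::map<std::string, int> > ins;
  for (int i = 0; i < pos.size(); ++i) {
    if (pos[i] == NA_INTEGER) continue;
    Ops ops = parse_cigar(as<std::string>(cigar[i]));
    std::string s = as<std::string>(seq[i]);
    int r = pos[i], q = 0;
    int rd_start = r, rd_end = r;
    for (size_t j = 0; j < ops.size(); ++j) {
      char c = ops[j].first; int l = ops[j].second;
      if (c == '=' || c == 'X' || c == 'M') {
        for (int t = 0; t < l; ++t) {
          int p = r + t - span_start;
          if (p >= 0 && p < L) {
            int bb = b2i(s[q + t]);
            if (bb >= 0) { cnt[(size_t)p * 5 + bb]++; cov[p]++; }
          }
        }
        r += l; q += l;
      } else if (c == 'D') {
        for (int t = 0; t < l; ++t) {
          int p = r + t - span_start;
          if (p >= 0 && p < L) { cnt[(size_t)p * 5 + 4]++; cov[p]++; }
        }
        r += l;
      } else if (c == 'I') {
        int p = r - span_start;
        if (p >= 0 && p <= L) ins[r][s.substr(q, l)]++;
        q += l;
      } else if (c == 'S') q += l;
    }
    rd_end = r;
    for (int p = std::max(rd_start + 1, span_start); p < std::min(rd_end, span_end); ++p)
      spancov[p - span_start]++;
  }
  // emit pieces
  List pieces;
  int p = 0;
  while (p < L) {
    while (p < L && cov[p] == 0) ++p;
    if (p >= L) break;
    int p0 = p;
    std::string cons; cons.reserve(4096);
    Ops ops;
    double qsum = 0; long qn = 0;
    while (p < L && cov[p] > 0) {
      int rp = span_start + p;
      // insertion before column rp (skip at piece start: belongs upstream)
      if (p > p0) {
        std::map<int, std::map<std::string, int> >::iterator it = ins.find(rp);
        if (it != ins.end()) {
          int bestc = 0; const std::string *bests = 0;
          for (std::map<std::string, int>::iterator m = it->second.begin(); m != it->second.end(); ++m)
            if (m->second > bestc) { bestc = m->second; bests = &m->first; }
          int denom = std::max(1, spancov[p]);
          if (bests && 2 * bestc > denom) {
            cons += *bests;
            push_op(ops, 'I', (int)bests->size());
            double agr = std::min(1.0, (double)bestc / denom);
            double err = 1.0 - agr;
            double qv = (err < 1e-6) ? 60.0 : std::min(60.0, -10.0 * std::log10(err));
            qsum += qv * (double)bests->size(); qn += (long)bests->size();
          }
        }
      }
      int best = 0, bi = 0, tot = 0;
      for (int bb = 0; bb < 5; ++bb) {
        int v = cnt[(size_t)p * 5 + bb]; tot += v;
        if (v > best) { best = v; bi = bb; }
      }
      double agr = (tot > 0) ? (double)best / tot : 0;
      double err = 1.0 - agr;
      double qv = (err < 1e-6) ? 60.0 : std::min(60.0, -10.0 * std::log10(err));
      qsum += qv; qn += 1;
      if (bi == 4) {
        push_op(ops, 'D', 1);
      } else {
        char bc = "ACGT"[bi];
        cons += bc;
        push_op(ops, (bc == ref[rp]) ? '=' : 'X', 1);
      }
      ++p;
    }
    // trim leading/trailing D ops (deletions at piece edges are just
    // non-coverage of the flanking sequence)
    while (!ops.empty() && ops.front().first == 'D') { p0 += ops.front().second; ops.erase(ops.begin()); }
    while (!ops.empty() && ops.back().first == 'D') ops.pop_back();
    if (ops.empty() || cons.empty()) continue;
    pieces.push_back(List::create(_["ref_start"] = span_start + p0,
                                  _["seq"] = cons,
                                  _["cigar"] = ops_str(ops),
                                  _["mean_qv"] = (qn > 0) ? qsum / qn : 0.0,
                                  _["n_reads"] = (int)pos.size()));
  }
  return pieces;
}

// best end-overlap diagonal between a and b: returns diag d (b starts at
// a-position d) with vote count
// [[Rcpp::export]]
List cpp_overlap_diag(std::string a, std::string b, int k, int max_occ = 4) {
  KIndex ix; build_index(a, k, 1, ix);
  std::map<int, int> votes, exact;
  uint64_t v;
  int step = std::max(1, (int)(b.size() / 2000));
  for (int i = 0; i + k <= (int)b.size(); i += step) {
    if (!kmer_at(b, i, k, v)) continue;
    std::unordered_map<uint64_t, std::vector<int> >::const_iterator it = ix.pos.find(v);
    if (it == ix.pos.end() || (int)it->second.size() > max_occ) continue;
    for (size_t j = 0; j < it->second.size(); ++j) {
      int d = it->second[j] - i;
      votes[(d >= 0 ? d : d - 49) / 50]++;   // bin to tolerate small indels
      exact[d]++;
    }
  }
  int bestb = 0, bestc = 0;
  for (std::map<int, int>::iterator m = votes.begin(); m != votes.end(); ++m)
    if (m->second > bestc) { bestc = m->second; bestb = m->first; }
  if (bestc == 0) return List::create(_["diag"] = NA_INTEGER, _["votes"] = 0);
  // mode of exact diagonals within the winning bin
  int bestd = NA_INTEGER, bestdc = 0;
  for (std::map<int, int>::iterator m = exact.begin(); m != exact.end(); ++m) {
    int bin = (m->first >= 0 ? m->first : m->first - 49) / 50;
    if (bin == bestb && m->second > bestdc) { bestdc = m->second; bestd = m->first; }
  }
  return List::create(_["diag"] = bestd, _["votes"] = bestc);
}

// cigar helpers ------------------------------------------------------------
// [[Rcpp::export]]
int cpp_cigar_ref_len(std::string cigar) {
  Ops ops = parse_cigar(cigar);
  int l = 0;
  for (size_t i = 0; i < ops.size(); ++i)
    if (ops[i].first == '=' || ops[i].first == 'X' || ops[i].first == 'M' || ops[i].first == 'D')
      l += ops[i].second;
  return l;
}

// per-alignment event extraction: rows (kind, ref_start, ref_end, q_start,
// q_end) with kind 1 = X run, 2 = I, 3 = D
// [[Rcpp::export]]
IntegerMatrix cpp_cigar_events(std::string cigar, int ref_start) {
  Ops ops = parse_cigar(cigar);
  std::vector<int> rows;
  int r = ref_start, q = 0;
  for (size_t i = 0; i < ops.size(); ++i) {
    char c = ops[i].first; int l = ops[i].second;
    if (c == '=') { r += l; q += l; }
    else if (c == 'X' || c == 'M') {
      rows.push_back(1); rows.push_back(r); rows.push_back(r + l);
      rows.push_back(q); rows.push_back(q + l);
      r += l; q += l;
    } else if (c == 'I') {
      rows.push_back(2); rows.push_back(r); rows.push_back(r);
      rows.push_back(q); rows.push_back(q + l);
      q += l;
    } else if (c == 'D') {
      rows.push_back(3); rows.push_back(r); rows.push_back(r + l);
      rows.push_back(q); rows.push_back(q);
      r += l;
    } else if (c == 'S') q += l;
  }
  int n = (int)rows.size() / 5;
  IntegerMatrix M(n, 5);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 5; ++j) M(i, j) = rows[(size_t)i * 5 + j];
  colnames(M) = CharacterVector::create("kind", "ref_start", "ref_end", "q_start", "q_end");
  return M;
}

// project reference interval [s, e) into query coordinates along an
// alignment; returns c(q_start, q_end, fully_covered)
// [[Rcpp::export]]
IntegerVector cpp_project_interval(std::string cigar, int ref_start,
                                   int s, int e) {
  Ops ops = parse_cigar(cigar);
  int r = ref_start, q = 0;
  int qs = -1, qe = -1;
  bool started = false;
  for (size_t i = 0; i < ops.size(); ++i) {
    char c = ops[i].first; int l = ops[i].second;
    int rl = (c == '=' || c == 'X' || c == 'M' || c == 'D') ? l : 0;
    int ql = (c == '=' || c == 'X' || c == 'M' || c == 'I' || c == 'S') ? l : 0;
    bool consumes_q = (c == '=' || c == 'X' || c == 'M');
    if (rl > 0) {
      if (!started && s >= r && s < r + rl) {
        qs = consumes_q ? q + (s - r) : q;
        started = true;
      }
      if (started && e > r && e <= r + rl) {
        qe = consumes_q ? q + (e - r) : q;
      }
    }
    r += rl; q += ql;
  }
  int cov = (qs >= 0 && qe >= 0) ? 1 : 0;
  return IntegerVector::create(qs, qe, cov);
}
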