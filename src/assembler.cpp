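// Greedy overlap-consensus assembler and read-to-contig mapper.
//
// Overlap candidates between reads and the growing consensus are found by
// exact k-mer matching with diagonal voting; every candidate is then
// verified by a banded free-end-gap dynamic-programming alignment (band
// +-`band` around the voted diagonal), and accepted only if the aligned
// region reaches `min_overlap` columns at `min_identity`. The consensus is
// a per-column base-count majority vote; ties fall back to the base
// contributed by the earliest-joined read, then to alphabetical order.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cstdint>
#include <deque>
#include <queue>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int baseIdx(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;  // N and friends
  }
}
static const char BASES[4] = {'A', 'C', 'G', 'T'};

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default: c = 'N'; break;
    }
  }
  return r;
}

static inline uint64_t rcKmer(uint64_t x, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL - (x & 3ULL));
    x >>= 2;
  }
  return r;
}

// Sorted flat k-mer index over a sequence collection.
struct KmerIndex {
  struct Ent {
    uint64_t key;
    int32_t seq, pos;
  };
  std::vector<Ent> ents;
  int k;

  void build(const std::vector<std::string>& seqs, int k_, int stride) {
    k = k_;
    uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    for (size_t r = 0; r < seqs.size(); ++r) {
      const std::string& s = seqs[r];
      if ((int)s.size() < k) continue;
      uint64_t cur = 0;
      int valid = 0;
      for (size_t i = 0; i < s.size(); ++i) {
        int b = baseIdx(s[i]);
        if (b < 0) { valid = 0; cur = 0; continue; }
        cur = ((cur << 2) | (uint64_t)b) & mask;
        if (++valid >= k) {
          int p = (int)i - k + 1;
          if (p % stride == 0)
            ents.push_back({cur, (int32_t)r, (int32_t)p});
        }
      }
    }
    std::sort(ents.begin(), ents.end(), [](const Ent& a, const Ent& b) {
      if (a.key != b.key) return a.key < b.key;
      if (a.seq != b.seq) return a.seq < b.seq;
      return a.pos < b.pos;
    });
  }

  std::pair<size_t, size_t> range(uint64_t q) const {
    Ent probe{q, 0, 0};
    auto lo = std::lower_bound(ents.begin(), ents.end(), probe,
      [](const Ent& a, const Ent& b) { return a.key < b.key; });
    auto hi = std::upper_bound(lo, ents.end(), probe,
      [](const Ent& a, const Ent& b) { return a.key < b.key; });
    return {(size_t)(lo - ents.begin()), (size_t)(hi - ents.begin())};
  }
};

// ---------------------------------------------------------------------------
// Banded overlap alignment

struct AlnResult {
  bool ok = false;
  int matches = 0;
  int alnCols = 0;
  int readStart = 0, readEnd = 0;  // [readStart, readEnd) aligned
  int startJ = 0, endJ = 0;        // consensus chars consumed before/after
  bool clippedRight = false;       // path ended at the consensus 3' end
  std::vector<std::pair<int, int>> pairs;  // (readPos, consPos) diagonals
};

static const int SC_MATCH = 1, SC_MISMATCH = -1, SC_GAP = -3;
static const int NEG = -100000000;

// Align read (already oriented) against consensus around diagonal d
// (read[i] ~ cons[i + d]) within +-band; free end gaps on the consensus
// side and free read overhangs at the consensus boundaries.
static AlnResult bandedOverlap(const std::string& read,
                               const std::string& cons, int d, int band,
                               bool wantPairs) {
  AlnResult res;
  const int Lr = (int)read.size(), Lc = (int)cons.size();
  const int W = 2 * band + 1;
  int i0 = std::max(0, -d - band);
  int i1 = std::min(Lr, Lc - d + band);
  if (i1 - i0 < 1) return res;
  const int NR = i1 - i0 + 1;
  std::vector<int> F((size_t)NR * W, NEG);
  std::vector<int8_t> dir((size_t)NR * W, -1);  // 0=start,1=diag,2=rgap,3=cgap
  auto jOf = [&](int i, int o) { return i + d + o - band; };
  auto idx = [&](int i, int o) { return (size_t)(i - i0) * W + o; };

  for (int o = 0; o < W; ++o) {
    int j = jOf(i0, o);
    if (j >= 0 && j <= Lc) { F[idx(i0, o)] = 0; dir[idx(i0, o)] = 0; }
  }
  for (int i = i0; i <= i1; ++i) {
    for (int o = 0; o < W; ++o) {
      int j = jOf(i, o);
      if (j < 0 || j > Lc) continue;
      int best = F[idx(i, o)];
      int8_t bd = dir[idx(i, o)];
      if (j == 0 && best < 0) { best = 0; bd = 0; }  // free left boundary
      if (i > i0 && j > 0) {  // diagonal
        int prev = F[idx(i - 1, o)];
        if (prev > NEG) {
          int bi = baseIdx(read[i - 1]), bj = baseIdx(cons[j - 1]);
          int sc = prev + ((bi >= 0 && bi == bj) ? SC_MATCH : SC_MISMATCH);
          if (sc > best) { best = sc; bd = 1; }
        }
      }
      if (o > 0 && j > 0) {  // gap in read (consume consensus)
        int prev = F[idx(i, o - 1)];
        if (prev > NEG && prev + SC_GAP > best) {
          best = prev + SC_GAP; bd = 2;
        }
      }
      if (i > i0 && o < W - 1) {  // gap in consensus (consume read)
        int prev = F[idx(i - 1, o + 1)];
        if (prev > NEG && prev + SC_GAP > best) {
          best = prev + SC_GAP; bd = 3;
        }
      }
      F[idx(i, o)] = best;
      dir[idx(i, o)] = bd;
    }
  }
  // best end: last read row, or the consensus right boundary
  int bestScore = NEG, bi = -1, bo = -1;
  for (int o = 0; o < W; ++o) {
    int j = jOf(i1, o);
    if (j >= 0 && j <= Lc && F[idx(i1, o)] > bestScore) {
      bestScore = F[idx(i1, o)]; bi = i1; bo = o;
    }
  }
  for (int i = i0; i <= i1; ++i) {
    int o = Lc - i - d + band;
    if (o >= 0 && o < W && F[idx(i, o)] > bestScore) {
      bestScore = F[idx(i, o)]; bi = i; bo = o;
    }
  }
  if (bi < 0 || bestScore <= NEG) return res;
  // traceback
  int i = bi, o = bo, matches = 0, cols = 0;
  if (wantPairs) res.pairs.reserve(i1 - i0);
  while (dir[idx(i, o)] != 0) {
    int8_t dd = dir[idx(i, o)];
    int j = jOf(i, o);
    if (dd == 1) {
      int br = baseIdx(read[i - 1]), bc = baseIdx(cons[j - 1]);
      if (br >= 0 && br == bc) ++matches;
      if (wantPairs) res.pairs.push_back({i - 1, j - 1});
      --i;
    } else if (dd == 2) {
      --o;
    } else {
      --i; ++o;
    }
    ++cols;
  }
  res.ok = true;
  res.matches = matches;
  res.alnCols = cols;
  res.readStart = i;
  res.readEnd = bi;
  res.startJ = jOf(i, o);
  res.endJ = jOf(bi, bo);
  res.clippedRight = (res.endJ == Lc);
  if (wantPairs) std::reverse(res.pairs.begin(), res.pairs.end());
  return res;
}

// ---------------------------------------------------------------------------
// Contig under construction

struct Contig {
  std::string cons;
  std::deque<std::array<int32_t, 4>> cnt;
  std::deque<std::array<int32_t, 4>> firstJoin;
  std::vector<int> members;          // read indices
  std::vector<int> orient;           // 0 fwd, 1 rev
  int version = 0;
  int shift = 0;                     // total bases prepended so far

  void init(const std::string& seed, int readIdx) {
    cons = seed;
    cnt.assign(seed.size(), {0, 0, 0, 0});
    firstJoin.assign(seed.size(), {INT32_MAX, INT32_MAX, INT32_MAX,
                                   INT32_MAX});
    for (size_t p = 0; p < seed.size(); ++p) {
      int b = baseIdx(seed[p]);
      if (b >= 0) { cnt[p][b] = 1; firstJoin[p][b] = 0; }
    }
    members.push_back(readIdx);
    orient.push_back(0);
  }

  char callColumn(size_t p) const {
    int bestB = -1, bestC = -1;
    int32_t bestF = INT32_MAX;
    for (int b = 0; b < 4; ++b) {
      if (cnt[p][b] > bestC ||
          (cnt[p][b] == bestC && firstJoin[p][b] < bestF)) {
        bestC = cnt[p][b]; bestF = firstJoin[p][b]; bestB = b;
      }
    }
    return bestC > 0 ? BASES[bestB] : 'N';
  }

  // merge an oriented read given its verified alignment
  void merge(const std::string& read, int readIdx, int ori,
             const AlnResult& a) {
    int join = (int)members.size();
    for (auto& pr : a.pairs) {
      int b = baseIdx(read[pr.first]);
      if (b < 0) continue;
      size_t j = (size_t)pr.second;
      cnt[j][b] += 1;
      if (firstJoin[j][b] == INT32_MAX) firstJoin[j][b] = join;
      cons[j] = callColumn(j);
    }
    if (a.readEnd < (int)read.size() && a.endJ == (int)cons.size()) {
      for (int p = a.readEnd; p < (int)read.size(); ++p) {
        int b = baseIdx(read[p]);
        std::array<int32_t, 4> c{0, 0, 0, 0};
        std::array<int32_t, 4> f{INT32_MAX, INT32_MAX, INT32_MAX,
                                 INT32_MAX};
        if (b >= 0) { c[b] = 1; f[b] = join; }
        cnt.push_back(c);
        firstJoin.push_back(f);
        cons.push_back(b >= 0 ? read[p] : 'N');
      }
    }
    if (a.readStart > 0 && a.startJ == 0) {
      for (int p = a.readStart - 1; p >= 0; --p) {
        int b = baseIdx(read[p]);
        std::array<int32_t, 4> c{0, 0, 0, 0};
        std::array<int32_t, 4> f{INT32_MAX, INT32_MAX, INT32_MAX,
                                 INT32_MAX};
        if (b >= 0) { c[b] = 1; f[b] = join; }
        cnt.push_front(c);
        firstJoin.push_front(f);
        cons.insert(cons.begin(), b >= 0 ? read[p] : 'N');
        shift += 1;
      }
    }
    members.push_back(readIdx);
    orient.push_back(ori);
    version += 1;
  }
};

struct Cand {
  int read, ori;
  int diag;       // relative to consensus coordinates at registration
  int shiftReg;   // contig shift at registration
  int votes = 1;
  // evaluation
  bool evaluated = false;
  int version = -1;
  int matches = 0, alnCols = 0;
  bool pass = false;
};

struct HeapEnt {
  int matches, alnCols, idRank, candIdx;
};
struct HeapCmp {
  bool operator()(const HeapEnt& a, const HeapEnt& b) const {
    if (a.matches != b.matches) return a.matches < b.matches;
    if (a.alnCols != b.alnCols) return a.alnCols < b.alnCols;
    return a.idRank > b.idRank;  // smaller id wins
  }
};

// [[Rcpp::export]]
List cpp_assemble(CharacterVector reads, CharacterVector ids,
                  int min_overlap, double min_identity, int band, int k,
                  int stride) {
  const int n = reads.size();
  std::vector<std::string> fwd(n), rev(n);
  std::vector<int> lens(n);
  for (int i = 0; i < n; ++i) {
    fwd[i] = as<std::string>(reads[i]);
    for (char c : fwd[i])
      if (baseIdx(c) < 0 && c != 'N')
        stop("read '%s' contains non-nucleotide characters",
             as<std::string>(ids[i]).c_str());
    rev[i] = revcomp(fwd[i]);
    lens[i] = (int)fwd[i].size();
  }
  // lexicographic rank of read ids (for deterministic tie-breaks)
  std::vector<int> ord(n), idRank(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::vector<std::string> idStr(n);
  for (int i = 0; i < n; ++i) idStr[i] = as<std::string>(ids[i]);
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return idStr[a] < idStr[b];
  });
  for (int r = 0; r < n; ++r) idRank[ord[r]] = r;
  // seeding order: longest first, ties by id
  std::vector<int> seedOrder(n);
  for (int i = 0; i < n; ++i) seedOrder[i] = i;
  std::sort(seedOrder.begin(), seedOrder.end(), [&](int a, int b) {
    if (lens[a] != lens[b]) return lens[a] > lens[b];
    return idStr[a] < idStr[b];
  });

  KmerIndex ix;
  ix.build(fwd, k, stride);
  uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;

  std::vector<char> assigned(n, 0);
  std::vector<int> stamp(2 * (size_t)n, -1);
  std::vector<int> stampIdx(2 * (size_t)n, -1);

  std::vector<std::string> outCons;
  std::vector<std::vector<int>> outMembers;
  std::vector<int> singles;

  int contigIter = -1;
  for (int s : seedOrder) {
    if (assigned[s]) continue;
    ++contigIter;
    assigned[s] = 1;
    Contig ctg;
    ctg.init(fwd[s], s);
    std::vector<Cand> cands;
    std::priority_queue<HeapEnt, std::vector<HeapEnt>, HeapCmp> heap;

    auto registerHits = [&](int lo, int hi) {
      // scan consensus k-mers (dense) in [lo, hi)
      lo = std::max(0, lo);
      hi = std::min(hi, (int)ctg.cons.size() - k + 1);
      uint64_t cur = 0;
      int valid = 0;
      for (int p = lo; p < hi + k - 1 && p < (int)ctg.cons.size(); ++p) {
        int b = baseIdx(ctg.cons[p]);
        if (b < 0) { valid = 0; cur = 0; continue; }
        cur = ((cur << 2) | (uint64_t)b) & mask;
        if (++valid < k) continue;
        int cpos = p - k + 1;
        if (cpos >= hi) break;
        for (int strand = 0; strand < 2; ++strand) {
          uint64_t q = strand == 0 ? cur : rcKmer(cur, k);
          auto rg = ix.range(q);
          for (size_t e = rg.first; e < rg.second; ++e) {
            int r = ix.ents[e].seq;
            if (assigned[r]) continue;
            int ori = strand;  // 0: read fwd matches; 1: read revcomp
            int diag = (ori == 0)
              ? cpos - ix.ents[e].pos
              : cpos - (lens[r] - ix.ents[e].pos - k);
            size_t key = 2 * (size_t)r + ori;
            if (stamp[key] != contigIter) {
              stamp[key] = contigIter;
              stampIdx[key] = (int)cands.size();
              Cand c;
              c.read = r; c.ori = ori; c.diag = diag;
              c.shiftReg = ctg.shift;
              cands.push_back(c);
            } else {
              Cand& c = cands[stampIdx[key]];
              int adjDiag = diag - (ctg.shift - c.shiftReg);
              if (adjDiag == c.diag) c.votes += 1;
              else if (--c.votes < 0) { c.diag = adjDiag; c.votes = 1; }
            }
          }
        }
      }
    };

    auto evaluate = [&](Cand& c) {
      const std::string& rs = c.ori == 0 ? fwd[c.read] : rev[c.read];
      int d = c.diag + (ctg.shift - c.shiftReg);
      AlnResult a = bandedOverlap(rs, ctg.cons, d, band, false);
      c.evaluated = true;
      c.version = ctg.version;
      c.matches = a.ok ? a.matches : 0;
      c.alnCols = a.ok ? a.alnCols : 0;
      double ident = a.alnCols > 0 ? (double)a.matches / a.alnCols : 0.0;
      c.pass = a.ok && a.alnCols >= min_overlap && ident >= min_identity;
    };

    registerHits(0, (int)ctg.cons.size());
    for (size_t ci = 0; ci < cands.size(); ++ci) {
      evaluate(cands[ci]);
      heap.push({cands[ci].matches, cands[ci].alnCols,
                 idRank[cands[ci].read], (int)ci});
    }

    while (!heap.empty()) {
      HeapEnt top = heap.top();
      heap.pop();
      Cand& c = cands[top.candIdx];
      if (assigned[c.read]) continue;
      if (top.matches != c.matches || top.alnCols != c.alnCols)
        continue;  // superseded heap entry
      if (c.version != ctg.version) {
        evaluate(c);
        heap.push({c.matches, c.alnCols, idRank[c.read], top.candIdx});
        continue;
      }
      if (!c.pass) continue;
      const std::string& rs = c.ori == 0 ? fwd[c.read] : rev[c.read];
      int d = c.diag + (ctg.shift - c.shiftReg);
      AlnResult a = bandedOverlap(rs, ctg.cons, d, band, true);
      if (!a.ok) continue;
      int oldLen = (int)ctg.cons.size();
      int oldShift = ctg.shift;
      assigned[c.read] = 1;
      ctg.merge(rs, c.read, c.ori, a);
      int grewLeft = ctg.shift - oldShift;
      int grewRight = (int)ctg.cons.size() - oldLen - grewLeft;
      size_t before = cands.size();
      if (grewLeft > 0) registerHits(0, grewLeft + k);
      if (grewRight > 0)
        registerHits((int)ctg.cons.size() - grewRight - k + 1,
                     (int)ctg.cons.size());
      for (size_t ci = before; ci < cands.size(); ++ci) {
        evaluate(cands[ci]);
        heap.push({cands[ci].matches, cands[ci].alnCols,
                   idRank[cands[ci].read], (int)ci});
      }
    }

    if ((int)ctg.members.size() >= 2) {
      outCons.push_back(ctg.cons);
      outMembers.push_back(ctg.members);
    } else {
      singles.push_back(s);
    }
  }

  List membersList(outMembers.size());
  CharacterVector consOut(outCons.size());
  for (size_t i = 0; i < outCons.size(); ++i) {
    consOut[i] = outCons[i];
    CharacterVector mm(outMembers[i].size());
    for (size_t j = 0; j < outMembers[i].size(); ++j)
      mm[j] = idStr[outMembers[i][j]];
    membersList[i] = mm;
  }
  CharacterVector singleOut(singles.size());
  for (size_t i = 0; i < singles.size(); ++i) singleOut[i] = idStr[singles[i]];
  return List::create(_["consensus"] = consOut,
                      _["members"] = membersList,
                      _["singletons"] = singleOut);
}

// ---------------------------------------------------------------------------
// Read-to-contig mapping

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, CharacterVector readIds,
                   CharacterVector contigs, CharacterVector contigIds,
                   int min_aln, double min_identity, int band, int k) {
  const int n = reads.size(), m = contigs.size();
  std::vector<std::string> ctg(m);
  std::vector<std::string> cid(m);
  for (int j = 0; j < m; ++j) {
    ctg[j] = as<std::string>(contigs[j]);
    cid[j] = as<std::string>(contigIds[j]);
  }
  // lexicographic rank of contig ids
  std::vector<int> ord(m), cRank(m);
  for (int j = 0; j < m; ++j) ord[j] = j;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return cid[a] < cid[b];
  });
  for (int r = 0; r < m; ++r) cRank[ord[r]] = r;

  KmerIndex ix;
  ix.build(ctg, k, 1);
  uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;

  IntegerVector assign(n, NA_INTEGER);
  LogicalVector ambiguous(n, false);

  struct Vote { int diag; int votes; };

  for (int i = 0; i < n; ++i) {
    std::string rs = as<std::string>(reads[i]);
    for (char c : rs)
      if (baseIdx(c) < 0 && c != 'N')
        stop("read '%s' contains non-nucleotide characters",
             as<std::string>(readIds[i]).c_str());
    int Lr = (int)rs.size();
    if (Lr < k) continue;
    std::string rc = revcomp(rs);
    // votes per (contig, orient)
    std::vector<std::array<Vote, 2>> votes(m);
    for (auto& v : votes) { v[0] = {0, 0}; v[1] = {0, 0}; }
    std::vector<char> seen(m, 0);
    for (int ori = 0; ori < 2; ++ori) {
      const std::string& q = ori == 0 ? rs : rc;
      uint64_t cur = 0;
      int valid = 0;
      for (int p = 0; p < (int)q.size(); ++p) {
        int b = baseIdx(q[p]);
        if (b < 0) { valid = 0; cur = 0; continue; }
        cur = ((cur << 2) | (uint64_t)b) & mask;
        if (++valid < k) continue;
        int qpos = p - k + 1;
        auto rg = ix.range(cur);
        for (size_t e = rg.first; e < rg.second; ++e) {
          int cix = ix.ents[e].seq;
          int diag = ix.ents[e].pos - qpos;
          Vote& v = votes[cix][ori];
          seen[cix] = 1;
          if (v.votes == 0) { v.diag = diag; v.votes = 1; }
          else if (v.diag == diag) v.votes += 1;
          else if (--v.votes < 0) { v.diag = diag; v.votes = 1; }
        }
      }
    }
    // evaluate candidates, deterministically ordered
    struct Res { int matches, alnCols, cix; };
    std::vector<Res> passes;
    std::vector<int> candContigs;
    for (int cix = 0; cix < m; ++cix) if (seen[cix]) candContigs.push_back(cix);
    std::sort(candContigs.begin(), candContigs.end(), [&](int a, int b) {
      return cRank[a] < cRank[b];
    });
    for (int cix : candContigs) {
      for (int ori = 0; ori < 2; ++ori) {
        if (votes[cix][ori].votes <= 0) continue;
        const std::string& q = ori == 0 ? rs : rc;
        AlnResult a = bandedOverlap(q, ctg[cix], votes[cix][ori].diag,
                                    band, false);
        if (!a.ok || a.alnCols < min_aln) continue;
        double ident = (double)a.matches / a.alnCols;
        if (ident < min_identity) continue;
        passes.push_back({a.matches, a.alnCols, cix});
      }
    }
    if (passes.empty()) continue;
    std::sort(passes.begin(), passes.end(), [&](const Res& a, const Res& b) {
      if (a.matches != b.matches) return a.matches > b.matches;
      if (a.alnCols != b.alnCols) return a.alnCols > b.alnCols;
      return cRank[a.cix] < cRank[b.cix];
    });
    assign[i] = passes[0].cix + 1;
    if (passes.size() > 1 && passes[1].cix != passes[0].cix &&
        passes[1].matches == passes[0].matches &&
        passes[1].alnCols == passes[0].alnCols)
      ambiguous[i] = true;
  }
  return List::create(_["contig"] = assign, _["ambiguous"] = ambiguous);
}

// Exposed for unit testing of the overlap kernel.
// [[Rcpp::export]]
List cpp_overlap_align(std::string read, std::string cons, int diag,
                       int band) {
  AlnResult a = bandedOverlap(read, cons, diag, band, true);
  return List::create(_["ok"] = a.ok, _["matches"] = a.matches,
                      _["alnCols"] = a.alnCols,
                      _["readStart"] = a.readStart,
                      _["readEnd"] = a.readEnd, _["startJ"] = a.startJ,
                      _["endJ"] = a.endJ);
}
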