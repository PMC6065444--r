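// Forward simulation of admixed haploid genomes under pulse migration
// histories.  Two engines share the meiosis primitive:
//   * finite-population pools (drift, bounded memory), and
//   * an infinite-population branching recursion in which every parent is
//     a fresh independent draw (no drift; matches the assumptions of the
//     analytic tract model).
// All randomness goes through R's RNG so set.seed() governs everything.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// A haploid chromosome as maximal same-ancestry segments.
// Segment i spans [ends[i-1] (or 0), ends[i]) with ancestry anc[i];
// ends.back() equals the chromosome length (Morgans).
struct Hap {
  std::vector<double> ends;
  std::vector<int> anc;
};

static inline void push_seg(Hap &h, double end, int a) {
  if (!h.anc.empty() && h.anc.back() == a) {
    h.ends.back() = end;
  } else {
    h.ends.push_back(end);
    h.anc.push_back(a);
  }
}

static Hap pure_hap(double L, int a) {
  Hap h;
  h.ends.push_back(L);
  h.anc.push_back(a);
  return h;
}

// Append the restriction of h to [from, to) onto out.
static void append_interval(const Hap &h, double from, double to, Hap &out) {
  if (to <= from) return;
  size_t i = std::upper_bound(h.ends.begin(), h.ends.end(), from) -
             h.ends.begin();
  if (i >= h.ends.size()) i = h.ends.size() - 1;
  double pos = from;
  while (pos < to && i < h.ends.size()) {
    double seg_end = std::min(h.ends[i], to);
    if (seg_end > pos) push_seg(out, seg_end, h.anc[i]);
    pos = seg_end;
    ++i;
  }
}

// Meiotic product of two haplotypes: Poisson(L) crossovers at uniform
// genetic positions, no interference, random starting phase.
static Hap meiosis(const Hap &h1, const Hap &h2, double L) {
  int k = (int)::Rf_rpois(L);
  if (k == 0) return (unif_rand() < 0.5) ? h1 : h2;
  std::vector<double> xo(k);
  for (int i = 0; i < k; ++i) xo[i] = unif_rand() * L;
  std::sort(xo.begin(), xo.end());
  bool first = unif_rand() < 0.5;
  Hap out;
  double pos = 0.0;
  const Hap *cur = first ? &h1 : &h2;
  const Hap *oth = first ? &h2 : &h1;
  for (int i = 0; i <= k; ++i) {
    double end = (i == k) ? L : xo[i];
    append_interval(*cur, pos, end, out);
    pos = end;
    std::swap(cur, oth);
  }
  return out;
}

// Draw an ancestry index from (a slice of) a migrant-fraction row,
// normalized to its own sum.
static int draw_ancestry(const NumericMatrix &m, int row, double rowsum) {
  double u = unif_rand() * rowsum, acc = 0.0;
  int A = m.ncol();
  for (int a = 0; a < A; ++a) {
    acc += m(row, a);
    if (u <= acc) return a;
  }
  return A - 1;
}

static double row_sum(const NumericMatrix &m, int row) {
  double s = 0.0;
  for (int a = 0; a < m.ncol(); ++a) s += m(row, a);
  return s;
}

// ---------------------------------------------------------------------------
// Output assembly
// ---------------------------------------------------------------------------

struct TractSink {
  std::vector<int> hap, chrom, anc;
  std::vector<double> start, end;
  void add(int hap_id, int chrom_id, const Hap &h) {
    double pos = 0.0;
    for (size_t i = 0; i < h.ends.size(); ++i) {
      hap.push_back(hap_id);
      chrom.push_back(chrom_id);
      anc.push_back(h.anc[i] + 1);  // 1-based codes on the R side
      start.push_back(pos);
      end.push_back(h.ends[i]);
      pos = h.ends[i];
    }
  }
  List as_list() const {
    return List::create(_["haplotype"] = hap, _["chrom"] = chrom,
                        _["ancestry"] = anc, _["start"] = start,
                        _["end"] = end);
  }
};

// Sample n distinct indices in [0, pop) via partial Fisher-Yates.
static std::vector<int> sample_indices(int pop, int n) {
  std::vector<int> idx(pop);
  for (int i = 0; i < pop; ++i) idx[i] = i;
  for (int i = 0; i < n; ++i) {
    int j = i + (int)(unif_rand() * (pop - i));
    if (j >= pop) j = pop - 1;
    std::swap(idx[i], idx[j]);
  }
  idx.resize(n);
  return idx;
}

// ---------------------------------------------------------------------------
// Finite-population haploid pool (unsexed)
// ---------------------------------------------------------------------------

// m: T_max x A migrant fractions, row t-1 holds time t (generations before
// present).  X chromosomes (is_x) recombine with probability 2/3 per
// transmission (the fraction of X transmissions that pass through females).
// [[Rcpp::export]]
List sim_pool_cpp(NumericVector chrom_len, LogicalVector chrom_is_x,
                  NumericMatrix m, int pop_size, int n_sample) {
  int T_max = m.nrow(), C = chrom_len.size();
  std::vector<std::vector<Hap> > pool(pop_size), next(pop_size);
  // founding generation: all pure migrants
  for (int i = 0; i < pop_size; ++i) {
    int a = draw_ancestry(m, T_max - 1, row_sum(m, T_max - 1));
    pool[i].resize(C);
    for (int c = 0; c < C; ++c) pool[i][c] = pure_hap(chrom_len[c], a);
  }
  for (int t = T_max - 1; t >= 0; --t) {
    double M = (t >= 1) ? row_sum(m, t - 1) : 0.0;
    for (int i = 0; i < pop_size; ++i) {
      next[i].clear();
      next[i].resize(C);
      if (t >= 1 && unif_rand() < M) {
        int a = draw_ancestry(m, t - 1, M);
        for (int c = 0; c < C; ++c) next[i][c] = pure_hap(chrom_len[c], a);
      } else {
        int p1 = (int)(unif_rand() * pop_size);
        int p2 = (int)(unif_rand() * (pop_size - 1));
        if (p2 >= p1) ++p2;
        for (int c = 0; c < C; ++c) {
          if (chrom_is_x[c] && unif_rand() >= 2.0 / 3.0) {
            next[i][c] = (unif_rand() < 0.5) ? pool[p1][c] : pool[p2][c];
          } else {
            next[i][c] = meiosis(pool[p1][c], pool[p2][c], chrom_len[c]);
          }
        }
      }
    }
    pool.swap(next);
  }
  std::vector<int> take = sample_indices(pop_size, n_sample);
  TractSink sink;
  for (int i = 0; i < n_sample; ++i)
    for (int c = 0; c < C; ++c) sink.add(i + 1, c + 1, pool[take[i]][c]);
  return sink.as_list();
}

// ---------------------------------------------------------------------------
// Infinite-population branching recursion (unsexed)
// ---------------------------------------------------------------------------

struct Piece {
  double a, b;
};

typedef std::vector<std::pair<std::pair<double, double>, int> > SegList;

static void emit_pieces(const std::vector<Piece> &ivs, int anc, SegList &out) {
  for (size_t i = 0; i < ivs.size(); ++i)
    out.push_back(std::make_pair(std::make_pair(ivs[i].a, ivs[i].b), anc));
}

// Split interval set by a crossover process over its span; parity 0 pieces
// go to parent A, parity 1 to parent B.
static void split_pieces(const std::vector<Piece> &ivs, double span_lo,
                         double span_hi, std::vector<Piece> &pa,
                         std::vector<Piece> &pb) {
  int k = (int)::Rf_rpois(span_hi - span_lo);
  std::vector<double> xo(k);
  for (int i = 0; i < k; ++i) xo[i] = span_lo + unif_rand() * (span_hi - span_lo);
  std::sort(xo.begin(), xo.end());
  int phase = unif_rand() < 0.5 ? 0 : 1;
  for (size_t i = 0; i < ivs.size(); ++i) {
    double pos = ivs[i].a;
    // crossovers inside (pos, b); parity before pos:
    size_t j = std::lower_bound(xo.begin(), xo.end(), pos) - xo.begin();
    int par = (phase + (int)j) % 2;
    while (pos < ivs[i].b) {
      double end = (j < xo.size() && xo[j] < ivs[i].b) ? xo[j] : ivs[i].b;
      if (end > pos) {
        Piece p;
        p.a = pos;
        p.b = end;
        (par == 0 ? pa : pb).push_back(p);
      }
      pos = end;
      ++j;
      par = 1 - par;
    }
  }
}

static void sim_node(int t, const NumericMatrix &m, const std::vector<Piece> &ivs,
                     bool is_x, SegList &out) {
  int T_max = m.nrow();
  double M = (t >= 1 && t <= T_max) ? row_sum(m, t - 1) : 0.0;
  if (t >= 1 && (t == T_max || unif_rand() < M)) {
    emit_pieces(ivs, draw_ancestry(m, t - 1, M), out);
    return;
  }
  if (is_x && unif_rand() >= 2.0 / 3.0) {  // male transmission: intact
    sim_node(t + 1, m, ivs, is_x, out);
    return;
  }
  std::vector<Piece> pa, pb;
  split_pieces(ivs, 0.0, ivs.back().b, pa, pb);
  // span from 0 keeps phase correlation across gaps exact
  if (!pa.empty()) sim_node(t + 1, m, pa, is_x, out);
  if (!pb.empty()) sim_node(t + 1, m, pb, is_x, out);
}

static void seglist_to_hap(SegList &segs, double L, Hap &h) {
  std::sort(segs.begin(), segs.end());
  for (size_t i = 0; i < segs.size(); ++i)
    push_seg(h, segs[i].first.second, segs[i].second);
  if (h.ends.empty() || std::abs(h.ends.back() - L) > 1e-9)
    stop("internal error: segments do not tile the chromosome");
  h.ends.back() = L;
}

// [[Rcpp::export]]
List sim_branching_cpp(NumericVector chrom_len, LogicalVector chrom_is_x,
                       NumericMatrix m, int n_hap) {
  int C = chrom_len.size();
  TractSink sink;
  for (int i = 0; i < n_hap; ++i) {
    for (int c = 0; c < C; ++c) {
      std::vector<Piece> whole(1);
      whole[0].a = 0.0;
      whole[0].b = chrom_len[c];
      SegList segs;
      sim_node(0, m, whole, chrom_is_x[c], segs);
      Hap h;
      seglist_to_hap(segs, chrom_len[c], h);
      sink.add(i + 1, c + 1, h);
    }
  }
  return sink.as_list();
}

// ---------------------------------------------------------------------------
// Finite-population sexed cohort
// ---------------------------------------------------------------------------

struct Indiv {
  int sex;  // 0 female, 1 male
  // auto_h[c][0] maternal, [1] paternal; x[0] maternal, x[1] paternal (F only)
  std::vector<Hap> auto_m, auto_p;
  Hap x_m, x_p;
};

// sf, sm: T_max x A sex-specific migrant fractions (fraction of the female /
// male population at time t that are new migrants of ancestry a).
// [[Rcpp::export]]
List sim_sexed_cpp(NumericVector auto_len, double x_len, NumericMatrix sf,
                   NumericMatrix sm, int pop_size, int n_ind) {
  int T_max = sf.nrow(), C = auto_len.size();
  std::vector<Indiv> pop(pop_size), next(pop_size);
  std::vector<int> females, males;

  for (int i = 0; i < pop_size; ++i) {
    Indiv &I = pop[i];
    I.sex = (unif_rand() < 0.5) ? 0 : 1;
    const NumericMatrix &s = (I.sex == 0) ? sf : sm;
    int a = draw_ancestry(s, T_max - 1, row_sum(s, T_max - 1));
    I.auto_m.resize(C);
    I.auto_p.resize(C);
    for (int c = 0; c < C; ++c) {
      I.auto_m[c] = pure_hap(auto_len[c], a);
      I.auto_p[c] = pure_hap(auto_len[c], a);
    }
    I.x_m = pure_hap(x_len, a);
    if (I.sex == 0) I.x_p = pure_hap(x_len, a);
  }

  for (int t = T_max - 1; t >= 0; --t) {
    females.clear();
    males.clear();
    for (int i = 0; i < pop_size; ++i)
      (pop[i].sex == 0 ? females : males).push_back(i);
    if (females.empty() || males.empty())
      stop("population lost one sex entirely; increase pop_size");
    for (int i = 0; i < pop_size; ++i) {
      Indiv &I = next[i];
      I = Indiv();
      I.sex = (unif_rand() < 0.5) ? 0 : 1;
      const NumericMatrix &s = (I.sex == 0) ? sf : sm;
      double S = (t >= 1) ? row_sum(s, t - 1) : 0.0;
      if (t >= 1 && unif_rand() < S) {
        int a = draw_ancestry(s, t - 1, S);
        I.auto_m.resize(C);
        I.auto_p.resize(C);
        for (int c = 0; c < C; ++c) {
          I.auto_m[c] = pure_hap(auto_len[c], a);
          I.auto_p[c] = pure_hap(auto_len[c], a);
        }
        I.x_m = pure_hap(x_len, a);
        if (I.sex == 0) I.x_p = pure_hap(x_len, a);
      } else {
        const Indiv &mo = pop[females[(int)(unif_rand() * females.size())]];
        const Indiv &fa = pop[males[(int)(unif_rand() * males.size())]];
        I.auto_m.resize(C);
        I.auto_p.resize(C);
        for (int c = 0; c < C; ++c) {
          I.auto_m[c] = meiosis(mo.auto_m[c], mo.auto_p[c], auto_len[c]);
          I.auto_p[c] = meiosis(fa.auto_m[c], fa.auto_p[c], auto_len[c]);
        }
        I.x_m = meiosis(mo.x_m, mo.x_p, x_len);
        if (I.sex == 0) I.x_p = fa.x_m;  // father's X, unrecombined
      }
    }
    pop.swap(next);
  }

  std::vector<int> take = sample_indices(pop_size, n_ind);
  TractSink sink;
  IntegerVector sex(n_ind);
  // haplotype slots per individual: chrom c in 1..C autosomes, C+1 is X;
  // encode hap id = individual, extra columns carried separately
  std::vector<int> slot;  // 1 maternal, 2 paternal
  TractSink dummy;
  std::vector<int> ind_v, chrom_v, anc_v, slot_v;
  std::vector<double> start_v, end_v;
  for (int i = 0; i < n_ind; ++i) {
    const Indiv &I = pop[take[i]];
    sex[i] = I.sex;
    for (int c = 0; c < C; ++c) {
      for (int sl = 0; sl < 2; ++sl) {
        const Hap &h = (sl == 0) ? I.auto_m[c] : I.auto_p[c];
        double pos = 0.0;
        for (size_t k = 0; k < h.ends.size(); ++k) {
          ind_v.push_back(i + 1);
          chrom_v.push_back(c + 1);
          slot_v.push_back(sl + 1);
          anc_v.push_back(h.anc[k] + 1);
          start_v.push_back(pos);
          end_v.push_back(h.ends[k]);
          pos = h.ends[k];
        }
      }
    }
    int nx = (I.sex == 0) ? 2 : 1;
    for (int sl = 0; sl < nx; ++sl) {
      const Hap &h = (sl == 0) ? I.x_m : I.x_p;
      double pos = 0.0;
      for (size_t k = 0; k < h.ends.size(); ++k) {
        ind_v.push_back(i + 1);
        chrom_v.push_back(C + 1);  // X is the last chromosome
        slot_v.push_back(sl + 1);
        anc_v.push_back(h.anc[k] + 1);
        start_v.push_back(pos);
        end_v.push_back(h.ends[k]);
        pos = h.ends[k];
      }
    }
  }
  return List::create(_["individual"] = ind_v, _["chrom"] = chrom_v,
                      _["slot"] = slot_v, _["ancestry"] = anc_v,
                      _["start"] = start_v, _["end"] = end_v,
                      _["sex"] = sex);
}

// ---------------------------------------------------------------------------
// Infinite-population sexed recursion
// ---------------------------------------------------------------------------

// What an individual of generation g and given sex transmits to a child of
// generation g-1, restricted to an interval set.
static void transmit_auto(int g, int sex, const NumericMatrix &sf,
                          const NumericMatrix &sm, const std::vector<Piece> &ivs,
                          SegList &out) {
  int T_max = sf.nrow();
  const NumericMatrix &s = (sex == 0) ? sf : sm;
  double S = (g <= T_max) ? row_sum(s, g - 1) : 0.0;
  if (g == T_max || unif_rand() < S) {
    emit_pieces(ivs, draw_ancestry(s, g - 1, S), out);
    return;
  }
  std::vector<Piece> pa, pb;
  split_pieces(ivs, 0.0, ivs.back().b, pa, pb);
  if (!pa.empty()) transmit_auto(g + 1, 0, sf, sm, pa, out);
  if (!pb.empty()) transmit_auto(g + 1, 1, sf, sm, pb, out);
}

static void transmit_x(int g, int sex, const NumericMatrix &sf,
                       const NumericMatrix &sm, const std::vector<Piece> &ivs,
                       SegList &out) {
  int T_max = sf.nrow();
  const NumericMatrix &s = (sex == 0) ? sf : sm;
  double S = (g <= T_max) ? row_sum(s, g - 1) : 0.0;
  if (g == T_max || unif_rand() < S) {
    emit_pieces(ivs, draw_ancestry(s, g - 1, S), out);
    return;
  }
  if (sex == 1) {  // male transmits his single, maternally derived X intact
    transmit_x(g + 1, 0, sf, sm, ivs, out);
    return;
  }
  std::vector<Piece> pa, pb;
  split_pieces(ivs, 0.0, ivs.back().b, pa, pb);
  if (!pa.empty()) transmit_x(g + 1, 0, sf, sm, pa, out);
  if (!pb.empty()) transmit_x(g + 1, 1, sf, sm, pb, out);
}

// [[Rcpp::export]]
List sim_branching_sexed_cpp(NumericVector auto_len, double x_len,
                             NumericMatrix sf, NumericMatrix sm, int n_ind) {
  int C = auto_len.size();
  std::vector<int> ind_v, chrom_v, anc_v, slot_v;
  std::vector<double> start_v, end_v;
  IntegerVector sex(n_ind);
  for (int i = 0; i < n_ind; ++i) {
    int sx = (unif_rand() < 0.5) ? 0 : 1;
    sex[i] = sx;
    for (int c = 0; c < C; ++c) {
      for (int sl = 0; sl < 2; ++sl) {
        std::vector<Piece> whole(1);
        whole[0].a = 0.0;
        whole[0].b = auto_len[c];
        SegList segs;
        transmit_auto(1, sl, sf, sm, whole, segs);
        Hap h;
        seglist_to_hap(segs, auto_len[c], h);
        double pos = 0.0;
        for (size_t k = 0; k < h.ends.size(); ++k) {
          ind_v.push_back(i + 1);
          chrom_v.push_back(c + 1);
          slot_v.push_back(sl + 1);
          anc_v.push_back(h.anc[k] + 1);
          start_v.push_back(pos);
          end_v.push_back(h.ends[k]);
          pos = h.ends[k];
        }
      }
    }
    int nx = (sx == 0) ? 2 : 1;
    for (int sl = 0; sl < nx; ++sl) {
      std::vector<Piece> whole(1);
      whole[0].a = 0.0;
      whole[0].b = x_len;
      SegList segs;
      transmit_x(1, sl, sf, sm, whole, segs);
      Hap h;
      seglist_to_hap(segs, x_len, h);
      double pos = 0.0;
      for (size_t k = 0; k < h.ends.size(); ++k) {
        ind_v.push_back(i + 1);
        chrom_v.push_back(C + 1);
        slot_v.push_back(sl + 1);
        anc_v.push_back(h.anc[k] + 1);
        start_v.push_back(pos);
        end_v.push_back(h.ends[k]);
        pos = h.ends[k];
      }
    }
  }
  return List::create(_["individual"] = ind_v, _["chrom"] = chrom_v,
                      _["slot"] = slot_v, _["ancestry"] = anc_v,
                      _["start"] = start_v, _["end"] = end_v,
                      _["sex"] = sex);
}
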