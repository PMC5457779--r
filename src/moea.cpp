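// Mixed-variable multiobjective EA core for per-equation S-System inference.
//
// One candidate describes a single decoupled equation i:
//   bits  bx (length 2N): connection indicators for (g_i1..g_iN, h_i1..h_iN)
//   reals rx (length 2N+2): candidate kinetic orders, then alpha_i, beta_i
// Objectives (both minimised):
//   err = sum_k ( S[k] - (alpha*cg*prod_j X_j^g_j - beta*ch*prod_j X_j^h_j) )^2
//   l0  = popcount(bx)
// cg/ch are known constant multipliers (product of independent-variable terms
// of the generating model; 1 for fully dependent systems).
//
// All randomness comes from R's RNG (unif_rand), so set.seed() on the R side
// makes every run bit-reproducible.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <unordered_map>

using namespace Rcpp;

typedef uint64_t mask_t;

static inline int popcount64(mask_t x) { return __builtin_popcountll(x); }

static inline int rand_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct Prob {
  int N;                     // dependent components
  int K;                     // total (condition x time) points
  std::vector<double> logX;  // K x N, column-major
  std::vector<double> S;     // estimated slopes for the target component
  double cg, ch;             // constant multipliers on production/degradation
};

static double eval_err(const Prob &P, mask_t bx, const std::vector<double> &rx) {
  const int N = P.N, K = P.K;
  const double a = rx[2 * N] * P.cg, b = rx[2 * N + 1] * P.ch;
  double err = 0.0;
  for (int k = 0; k < K; ++k) {
    double sg = 0.0, sh = 0.0;
    for (int j = 0; j < N; ++j) {
      const double lx = P.logX[k + (size_t)j * K];
      if ((bx >> j) & 1ULL) sg += rx[j] * lx;
      if ((bx >> (N + j)) & 1ULL) sh += rx[N + j] * lx;
    }
    const double d = P.S[k] - (a * std::exp(sg) - b * std::exp(sh));
    err += d * d;
  }
  if (!std::isfinite(err)) err = 1e300;  // overflowing candidates simply lose
  return err;
}

struct Ind {
  mask_t bx;
  std::vector<double> rx;
  double err;
  int l0;
};

// --- variation operators ----------------------------------------------------

// Per bit: where b2 and b3 agree, inherit b1's bit with probability keep_prob,
// otherwise take the agreed value; where they disagree, flip b1's bit with
// probability flip_prob, otherwise keep it.
static mask_t bin_recombine(mask_t b1, mask_t b2, mask_t b3, int len,
                            double keep_prob, double flip_prob) {
  mask_t out = 0;
  for (int j = 0; j < len; ++j) {
    const int v1 = (b1 >> j) & 1ULL, v2 = (b2 >> j) & 1ULL, v3 = (b3 >> j) & 1ULL;
    int bit;
    if (v2 == v3) {
      bit = (unif_rand() < keep_prob) ? v1 : v2;
    } else {
      bit = (unif_rand() < flip_prob) ? 1 - v1 : v1;
    }
    if (bit) out |= (1ULL << j);
  }
  return out;
}

static inline double reflect_into(double x, double lo, double hi) {
  if (lo >= hi) return lo;
  for (int it = 0; it < 64 && (x < lo || x > hi); ++it) {
    if (x < lo) x = lo + (lo - x);
    if (x > hi) x = hi - (x - hi);
  }
  if (x < lo) x = lo;
  if (x > hi) x = hi;
  return x;
}

// DE/rand/1 mutant v = r1 + F (r2 - r3), binomial crossover against the
// target vector with rate CR and one guaranteed mutant index, reflection into
// the box bounds. The plain three-parent form uses r1 itself as the target.
static std::vector<double> real_recombine_t(const std::vector<double> &target,
                                            const std::vector<double> &r1,
                                            const std::vector<double> &r2,
                                            const std::vector<double> &r3,
                                            double F, double CR,
                                            const std::vector<double> &lo,
                                            const std::vector<double> &hi) {
  const int D = (int)r1.size();
  std::vector<double> out(D);
  const int jrand = rand_int(D);
  for (int j = 0; j < D; ++j) {
    double v = r1[j] + F * (r2[j] - r3[j]);
    double x = (j == jrand || unif_rand() < CR) ? v : target[j];
    out[j] = reflect_into(x, lo[j], hi[j]);
  }
  return out;
}

static std::vector<double> real_recombine(const std::vector<double> &r1,
                                          const std::vector<double> &r2,
                                          const std::vector<double> &r3,
                                          double F, double CR,
                                          const std::vector<double> &lo,
                                          const std::vector<double> &hi) {
  return real_recombine_t(r1, r1, r2, r3, F, CR, lo, hi);
}

// --- dominance machinery ----------------------------------------------------

static inline bool dominates_pair(double e1, int n1, double e2, int n2) {
  return (e1 <= e2 && n1 <= n2) && (e1 < e2 || n1 < n2);
}

// Fast nondominated sorting (dominance depth) on (err, l0).
static std::vector<int> dominance_ranks(const std::vector<double> &err,
                                        const std::vector<int> &l0) {
  const int n = (int)err.size();
  std::vector<int> rank(n, -1), ndom(n, 0);
  std::vector<std::vector<int>> dset(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      if (dominates_pair(err[i], l0[i], err[j], l0[j])) dset[i].push_back(j);
      else if (dominates_pair(err[j], l0[j], err[i], l0[i])) ndom[i]++;
    }
  std::vector<int> cur;
  for (int i = 0; i < n; ++i) if (ndom[i] == 0) { rank[i] = 0; cur.push_back(i); }
  int r = 0;
  while (!cur.empty()) {
    std::vector<int> nxt;
    for (int i : cur)
      for (int j : dset[i])
        if (--ndom[j] == 0) { rank[j] = r + 1; nxt.push_back(j); }
    cur.swap(nxt);
    ++r;
  }
  return rank;
}

// Order: rank asc, then l0 asc, then err asc, then insertion order.
static std::vector<int> truncate_order(const std::vector<double> &err,
                                       const std::vector<int> &l0) {
  std::vector<int> rank = dominance_ranks(err, l0);
  const int n = (int)err.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (rank[a] != rank[b]) return rank[a] < rank[b];
    if (l0[a] != l0[b]) return l0[a] < l0[b];
    return err[a] < err[b];
  });
  return ord;
}

// --- archive ----------------------------------------------------------------

struct Archive {
  std::vector<Ind> mem;
  std::unordered_map<mask_t, int> counts;

  void init_counts() {
    counts.clear();
    for (auto &m : mem) counts[m.bx]++;
  }

  // Replacement by topology novelty: a candidate with a bitstring already in
  // the archive competes only against the worst holder of that bitstring; a
  // novel bitstring evicts the worst member among duplicated bitstrings (the
  // worst member overall if all bitstrings are unique), provided it improves it.
  void update(const Ind &x) {
    const int n = (int)mem.size();
    auto it = counts.find(x.bx);
    if (it != counts.end() && it->second > 0) {
      int w = -1; double we = -1.0;
      for (int m = 0; m < n; ++m)
        if (mem[m].bx == x.bx && mem[m].err > we) { we = mem[m].err; w = m; }
      if (w >= 0 && x.err < mem[w].err) mem[w] = x;  // same mask: counts unchanged
      return;
    }
    bool anydup = false;
    for (auto &kv : counts) if (kv.second >= 2) { anydup = true; break; }
    int w = -1; double we = -1.0;
    for (int m = 0; m < n; ++m) {
      if (anydup && counts[mem[m].bx] < 2) continue;
      if (mem[m].err > we) { we = mem[m].err; w = m; }
    }
    if (w >= 0 && x.err < mem[w].err) {
      if (--counts[mem[w].bx] == 0) counts.erase(mem[w].bx);
      mem[w] = x;
      counts[x.bx]++;
    }
  }
};

// --- helpers to cross the R boundary ----------------------------------------

static Prob make_prob(const NumericMatrix &logX, const NumericVector &S,
                      double cg, double ch) {
  Prob P;
  P.N = logX.ncol();
  P.K = logX.nrow();
  P.logX.assign(logX.begin(), logX.end());
  P.S.assign(S.begin(), S.end());
  P.cg = cg;
  P.ch = ch;
  if ((int)P.S.size() != P.K) stop("slope vector length must match data rows");
  if (P.N > 31) stop("at most 31 components are supported");
  return P;
}

static mask_t as_mask(const IntegerVector &b) {
  mask_t m = 0;
  for (int j = 0; j < b.size(); ++j) if (b[j]) m |= (1ULL << j);
  return m;
}

static IntegerVector mask_to_bits(mask_t m, int len) {
  IntegerVector out(len);
  for (int j = 0; j < len; ++j) out[j] = (int)((m >> j) & 1ULL);
  return out;
}

// [[Rcpp::export]]
double cpp_eval_err(NumericMatrix logX, NumericVector S, double cg, double ch,
                    IntegerVector bx, NumericVector rx) {
  Prob P = make_prob(logX, S, cg, ch);
  if (bx.size() != 2 * P.N || rx.size() != 2 * P.N + 2) stop("bad solution length");
  std::vector<double> r(rx.begin(), rx.end());
  return eval_err(P, as_mask(bx), r);
}

// [[Rcpp::export]]
IntegerVector cpp_binary_recombine(IntegerVector b1, IntegerVector b2,
                                   IntegerVector b3, double keep_prob,
                                   double flip_prob) {
  const int len = b1.size();
  if (b2.size() != len || b3.size() != len) stop("bit vectors must have equal length");
  RNGScope scope;
  return mask_to_bits(bin_recombine(as_mask(b1), as_mask(b2), as_mask(b3),
                                    len, keep_prob, flip_prob), len);
}

// [[Rcpp::export]]
NumericVector cpp_real_recombine(NumericVector r1, NumericVector r2,
                                 NumericVector r3, double F, double CR,
                                 NumericVector lo, NumericVector hi) {
  const int D = r1.size();
  if (r2.size() != D || r3.size() != D || lo.size() != D || hi.size() != D)
    stop("real vectors must have equal length");
  RNGScope scope;
  std::vector<double> a(r1.begin(), r1.end()), b(r2.begin(), r2.end()),
      c(r3.begin(), r3.end()), l(lo.begin(), lo.end()), h(hi.begin(), hi.end());
  std::vector<double> out = real_recombine(a, b, c, F, CR, l, h);
  return NumericVector(out.begin(), out.end());
}

// [[Rcpp::export]]
IntegerVector cpp_dominance_ranks(NumericVector err, IntegerVector l0) {
  std::vector<double> e(err.begin(), err.end());
  std::vector<int> n(l0.begin(), l0.end());
  std::vector<int> r = dominance_ranks(e, n);
  return IntegerVector(r.begin(), r.end());
}

// [[Rcpp::export]]
IntegerVector cpp_truncate_order(NumericVector err, IntegerVector l0) {
  std::vector<double> e(err.begin(), err.end());
  std::vector<int> n(l0.begin(), l0.end());
  std::vector<int> ord = truncate_order(e, n);
  IntegerVector out(ord.size());
  for (size_t i = 0; i < ord.size(); ++i) out[i] = ord[i] + 1;  // 1-based
  return out;
}

// Archive update exposed for unit tests: members given as a bit matrix,
// real matrix and error vector; returns the updated members.
// [[Rcpp::export]]
List cpp_update_archive(IntegerMatrix B, NumericMatrix R, NumericVector err,
                        IntegerVector cand_b, NumericVector cand_r,
                        double cand_err) {
  const int n = B.nrow(), L = B.ncol(), D = R.ncol();
  Archive arc;
  arc.mem.resize(n);
  for (int m = 0; m < n; ++m) {
    mask_t bm = 0;
    for (int j = 0; j < L; ++j) if (B(m, j)) bm |= (1ULL << j);
    arc.mem[m].bx = bm;
    arc.mem[m].rx.assign(R(m, _).begin(), R(m, _).end());
    arc.mem[m].err = err[m];
    arc.mem[m].l0 = popcount64(bm);
  }
  arc.init_counts();
  Ind x;
  x.bx = as_mask(cand_b);
  x.rx.assign(cand_r.begin(), cand_r.end());
  x.err = cand_err;
  x.l0 = popcount64(x.bx);
  arc.update(x);
  IntegerMatrix Bo(n, L);
  NumericMatrix Ro(n, D);
  NumericVector eo(n);
  for (int m = 0; m < n; ++m) {
    for (int j = 0; j < L; ++j) Bo(m, j) = (int)((arc.mem[m].bx >> j) & 1ULL);
    for (int j = 0; j < D; ++j) Ro(m, j) = arc.mem[m].rx[j];
    eo[m] = arc.mem[m].err;
  }
  return List::create(_["bits"] = Bo, _["reals"] = Ro, _["err"] = eo);
}

// --- the full generational loop ---------------------------------------------

static Ind random_ind(const Prob &P, int L, int D,
                      const std::vector<double> &lo, const std::vector<double> &hi) {
  Ind x;
  x.bx = 0;
  for (int j = 0; j < L; ++j) if (unif_rand() < 0.5) x.bx |= (1ULL << j);
  x.rx.resize(D);
  for (int j = 0; j < D; ++j) x.rx[j] = lo[j] + unif_rand() * (hi[j] - lo[j]);
  x.err = eval_err(P, x.bx, x.rx);
  x.l0 = popcount64(x.bx);
  return x;
}

// [[Rcpp::export]]
List cpp_run_equation(NumericMatrix logX, NumericVector S, double cg, double ch,
                      int pop_size, int iters, double p1, double p2, double p3,
                      double F, double CR, double keep_prob, double flip_prob,
                      NumericVector lo, NumericVector hi,
                      double f_jitter = 0.0, int max_dup = 5) {
  Prob P = make_prob(logX, S, cg, ch);
  const int N = P.N, L = 2 * N, D = 2 * N + 2;
  if (lo.size() != D || hi.size() != D) stop("bounds must have length 2N+2");
  if (pop_size <= L + 1) stop("pop_size must exceed 2N+1");
  RNGScope scope;

  std::vector<double> vlo(lo.begin(), lo.end()), vhi(hi.begin(), hi.end());
  const int PS = pop_size;

  // Step 1: initialisation
  std::vector<Ind> pop(PS), oldpop(PS);
  Archive arc;
  arc.mem.resize(PS);
  for (int i = 0; i < PS; ++i) pop[i] = random_ind(P, L, D, vlo, vhi);
  for (int i = 0; i < PS; ++i) oldpop[i] = random_ind(P, L, D, vlo, vhi);
  for (int i = 0; i < PS; ++i) arc.mem[i] = random_ind(P, L, D, vlo, vhi);
  arc.init_counts();

  std::vector<std::vector<std::vector<double>>> pool(
      PS, std::vector<std::vector<double>>(PS, std::vector<double>(D)));
  std::vector<std::vector<double>> poolerr(PS, std::vector<double>(PS));
  std::vector<char> dirty(PS, 0);
  for (int i = 0; i < PS; ++i)
    for (int m = 0; m < PS; ++m) {
      for (int j = 0; j < D; ++j) pool[i][m][j] = vlo[j] + unif_rand() * (vhi[j] - vlo[j]);
      poolerr[i][m] = eval_err(P, pop[i].bx, pool[i][m]);
    }
  Ind gbest = pop[rand_int(PS)];

  std::vector<Ind> off(PS);
  for (int gen = 0; gen < iters; ++gen) {
    // Step 2: recombination
    for (int i = 0; i < PS; ++i) {
      const Ind *par1, *par2, *par3;
      if (unif_rand() < p1) {
        par1 = &pop[rand_int(PS)];
        par2 = &oldpop[rand_int(PS)];
        par3 = &pop[rand_int(PS)];
      } else {
        par1 = &arc.mem[rand_int(PS)];
        par2 = &arc.mem[rand_int(PS)];
        par3 = &arc.mem[rand_int(PS)];
      }
      // per-offspring dithered DE scale
      const double Fi = f_jitter > 0.0 ? F + f_jitter * (2.0 * unif_rand() - 1.0) : F;
      mask_t boff = bin_recombine(par1->bx, par2->bx, par3->bx, L, keep_prob, flip_prob);
      std::vector<double> roff;
      if (unif_rand() < p2) {
        roff = real_recombine(par1->rx, par2->rx, par3->rx, Fi, CR, vlo, vhi);
      } else {
        const std::vector<double> &q2 = pool[i][rand_int(PS)];
        const std::vector<double> &q3 = pool[i][rand_int(PS)];
        roff = real_recombine(par1->rx, q2, q3, Fi, CR, vlo, vhi);
      }
      off[i].bx = boff;
      off[i].rx = std::move(roff);
      off[i].err = eval_err(P, boff, off[i].rx);
      off[i].l0 = popcount64(boff);
    }

    // Step 3: refresh pool caches (bitstring of the owner may have changed),
    // locate each pool's worst member, rank IPop = Pop u Off.
    std::vector<int> worst(PS);
    for (int i = 0; i < PS; ++i) {
      if (dirty[i]) {
        for (int m = 0; m < PS; ++m) poolerr[i][m] = eval_err(P, pop[i].bx, pool[i][m]);
        dirty[i] = 0;
      }
      int w = 0;
      for (int m = 1; m < PS; ++m) if (poolerr[i][m] > poolerr[i][w]) w = m;
      worst[i] = w;
    }

    // Step 4: OldPop <- Pop; pool update by offspring; environmental selection;
    // archive update by the truncated remainder; gbest refresh.
    oldpop = pop;
    for (int i = 0; i < PS; ++i) {
      // admission judged under the owner's bitstring: pools are elite real
      // vectors FOR that topology, so the comparison must be like-for-like
      const double roff_err = eval_err(P, pop[i].bx, off[i].rx);
      if (roff_err < poolerr[i][worst[i]]) {
        pool[i][worst[i]] = off[i].rx;
        poolerr[i][worst[i]] = roff_err;
      }
    }

    std::vector<double> ierr(2 * PS);
    std::vector<int> il0(2 * PS);
    for (int i = 0; i < PS; ++i) { ierr[i] = pop[i].err; il0[i] = pop[i].l0; }
    for (int i = 0; i < PS; ++i) { ierr[PS + i] = off[i].err; il0[PS + i] = off[i].l0; }
    std::vector<int> ord = truncate_order(ierr, il0);

    // survivors in truncation order, holding at most max_dup members per
    // bitstring so near-clone chains (notably the empty topology) cannot
    // crowd out the sparse-topology chains the real-parameter search needs
    std::vector<Ind> newpop;
    newpop.reserve(PS);
    std::vector<int> rest;
    std::unordered_map<mask_t, int> ncopies;
    for (int k = 0; k < 2 * PS; ++k) {
      const int id = ord[k];
      const Ind &x = (id < PS) ? pop[id] : off[id - PS];
      if ((int)newpop.size() < PS && (max_dup <= 0 || ncopies[x.bx] < max_dup)) {
        newpop.push_back(x);
        ncopies[x.bx]++;
      } else {
        rest.push_back(id);
      }
    }
    // top up from the skipped ones (in order) if the cap left empty slots
    size_t ri = 0;
    while ((int)newpop.size() < PS && ri < rest.size()) {
      const int id = rest[ri];
      newpop.push_back(id < PS ? pop[id] : off[id - PS]);
      rest.erase(rest.begin() + ri);
    }
    for (int id : rest) arc.update(id < PS ? pop[id] : off[id - PS]);

    // pools follow their owner's bitstring across the re-sorted population:
    // a slot whose mask survives keeps that mask's pool (and cached errors);
    // only slots holding a mask new to the population need re-evaluation
    {
      std::unordered_map<mask_t, std::vector<int>> prevslots;
      for (int j = 0; j < PS; ++j) prevslots[pop[j].bx].push_back(j);
      std::vector<int> srcfor(PS, -1);
      std::vector<char> taken(PS, 0);
      for (int i = 0; i < PS; ++i) {
        auto it = prevslots.find(newpop[i].bx);
        if (it != prevslots.end() && !it->second.empty()) {
          srcfor[i] = it->second.back();
          it->second.pop_back();
          taken[srcfor[i]] = 1;
        }
      }
      std::vector<int> spare;
      for (int j = 0; j < PS; ++j) if (!taken[j]) spare.push_back(j);
      std::vector<std::vector<std::vector<double>>> npool(PS);
      std::vector<std::vector<double>> npoolerr(PS);
      std::vector<char> ndirty(PS, 0);
      for (int i = 0; i < PS; ++i) {
        if (srcfor[i] >= 0) {
          npool[i] = std::move(pool[srcfor[i]]);
          npoolerr[i] = std::move(poolerr[srcfor[i]]);
          ndirty[i] = dirty[srcfor[i]];
        } else {
          const int j = spare.back();
          spare.pop_back();
          npool[i] = std::move(pool[j]);
          npoolerr[i] = std::move(poolerr[j]);
          ndirty[i] = 1;
        }
      }
      pool.swap(npool);
      poolerr.swap(npoolerr);
      dirty.swap(ndirty);
    }
    pop.swap(newpop);

    gbest = (unif_rand() < p3) ? pop[rand_int(PS)] : arc.mem[rand_int(PS)];
    if ((gen & 63) == 0) Rcpp::checkUserInterrupt();
  }

  // Output Pop u Arc; the R side applies the nondominated filter.
  const int n = 2 * PS;
  IntegerMatrix Bo(n, L);
  NumericMatrix Ro(n, D);
  NumericVector eo(n);
  IntegerVector no(n);
  for (int i = 0; i < n; ++i) {
    const Ind &x = (i < PS) ? pop[i] : arc.mem[i - PS];
    for (int j = 0; j < L; ++j) Bo(i, j) = (int)((x.bx >> j) & 1ULL);
    for (int j = 0; j < D; ++j) Ro(i, j) = x.rx[j];
    eo[i] = x.err;
    no[i] = x.l0;
  }
  return List::create(_["bits"] = Bo, _["reals"] = Ro, _["err"] = eo, _["l0"] = no);
}
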