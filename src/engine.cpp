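// Forward-time engine for the fitness-associated dispersal simulator.
//
// All randomness comes from R's RNG (unif_rand / R::rpois / R::rbinom), so a
// single set.seed() on the R side makes every run reproducible.  Draws happen
// in a fixed, documented order:
//   dispersal:    per individual in storage order (UNI Bernoulli), then per
//                 FAD group (binomial count, then one tie-break key per group
//                 member in storage order), then per marked disperser in
//                 storage order (cost survival, then target deme).
//   reproduction: per conception attempt: deme draw, two parent draws,
//                 gamete 1 (crossover count, breakpoints, start copy),
//                 modifier allele 1, gamete 2, allele 2, mutation count and
//                 placements, heterozygote phenotype coin, survival draw.
//
// Haplotypes are sorted vectors of 0-based mutant locus indices.  The
// modifier locus is represented by two allele *slots* (0 and 1); each slot
// carries a dispersal strategy (0 = UNI, 1 = FAD) and a dispersal rate, which
// lets one simulation hold e.g. two UNI alleles with different rates.

#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <deque>
#include <map>
#include <vector>
using namespace Rcpp;

typedef std::vector<int> Hap;

struct Params {
  int L;
  double s, h, U, R;
  int strat[2];      // strategy per allele slot: 0 = UNI, 1 = FAD
  double alpha[2];   // dispersal rate per allele slot
  double c;          // cost of dispersal (probability a disperser dies)
  bool fad_per_deme; // rank FAD dispersers within demes instead of globally
  double attempt_factor; // conception-attempt ceiling = factor * n_total
};

struct Pop {
  std::vector<Hap> hapA, hapB;
  std::vector<int> modA, modB; // allele slot (0/1) per chromosome copy
  std::vector<int> pheno;      // expressed allele slot, fixed at birth
  std::vector<double> fit;     // viability, cached at birth
  std::vector<int> deme;       // 0-based deme id
  int n_demes;
  int n_total;  // target census size, constant across generations
  int capacity; // deme capacity K
  int n() const { return (int)fit.size(); }
};

// ---------------------------------------------------------------------------
// conversions at the R boundary (R side uses 1-based deme ids / allele slots)

static Pop pop_from_r(const List& p) {
  Pop P;
  List ha = p["hap_a"], hb = p["hap_b"];
  IntegerVector ma = p["mod_a"], mb = p["mod_b"], ph = p["phenotype"],
                dm = p["deme"];
  NumericVector ft = p["fitness"];
  int N = ft.size();
  P.hapA.resize(N);
  P.hapB.resize(N);
  for (int i = 0; i < N; i++) {
    P.hapA[i] = as<Hap>(ha[i]);
    P.hapB[i] = as<Hap>(hb[i]);
  }
  P.modA.assign(ma.begin(), ma.end());
  P.modB.assign(mb.begin(), mb.end());
  P.pheno.assign(ph.begin(), ph.end());
  P.deme.assign(dm.begin(), dm.end());
  for (int i = 0; i < N; i++) {
    P.modA[i]--; P.modB[i]--; P.pheno[i]--; P.deme[i]--;
  }
  P.fit.assign(ft.begin(), ft.end());
  P.n_demes = as<int>(p["n_demes"]);
  P.n_total = as<int>(p["n_total"]);
  P.capacity = as<int>(p["capacity"]);
  return P;
}

static List pop_to_r(const Pop& P) {
  int N = P.n();
  List ha(N), hb(N);
  IntegerVector ma(N), mb(N), ph(N), dm(N);
  NumericVector ft(N);
  for (int i = 0; i < N; i++) {
    ha[i] = wrap(P.hapA[i]);
    hb[i] = wrap(P.hapB[i]);
    ma[i] = P.modA[i] + 1;
    mb[i] = P.modB[i] + 1;
    ph[i] = P.pheno[i] + 1;
    dm[i] = P.deme[i] + 1;
    ft[i] = P.fit[i];
  }
  return List::create(_["hap_a"] = ha, _["hap_b"] = hb, _["mod_a"] = ma,
                      _["mod_b"] = mb, _["phenotype"] = ph, _["fitness"] = ft,
                      _["deme"] = dm, _["n_demes"] = P.n_demes,
                      _["n_total"] = P.n_total, _["capacity"] = P.capacity);
}

static Params params_from_r(const List& q) {
  Params par;
  par.L = as<int>(q["L"]);
  par.s = as<double>(q["s"]);
  par.h = as<double>(q["h"]);
  par.U = as<double>(q["U"]);
  par.R = as<double>(q["R"]);
  IntegerVector st = q["strategy"];
  NumericVector al = q["alpha"];
  par.strat[0] = st[0]; par.strat[1] = st[1];
  par.alpha[0] = al[0]; par.alpha[1] = al[1];
  par.c = as<double>(q["cost"]);
  par.fad_per_deme = as<bool>(q["fad_per_deme"]);
  par.attempt_factor = as<double>(q["attempt_factor"]);
  return par;
}

// ---------------------------------------------------------------------------
// genetic primitives

static inline double fitness_mn(int m, int n, double s, double h) {
  return std::pow(1.0 - s, m) * std::pow(1.0 - h * s, n);
}

// m = homozygous mutant loci, n = heterozygous mutant loci (two-pointer scan
// over the sorted haplotypes)
static void count_classes(const Hap& a, const Hap& b, int& m, int& n) {
  m = 0;
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] == b[j]) { m++; i++; j++; }
    else if (a[i] < b[j]) i++;
    else j++;
  }
  n = (int)(a.size() + b.size()) - 2 * m;
}

static inline int unif_index(int k) { // uniform in {0, ..., k-1}
  int v = (int)(unif_rand() * k);
  return v >= k ? k - 1 : v;
}

// splice a gamete from two parental haplotypes given sorted crossover
// breakpoints; breakpoint value b (1..L-1) sits between loci b-1 and b.
// One merged pass over both (sorted) haplotypes: for each mutant locus the
// segment index is the number of breakpoints at or below it, and the locus
// is transmitted iff it sits on the currently active parental copy.
static void splice_into(const Hap& A, const Hap& B, const int* bp, int x,
                        bool start_a, Hap& out) {
  out.clear();
  size_t i = 0, j = 0;
  int k = 0;
  while (i < A.size() || j < B.size()) {
    int la = i < A.size() ? A[i] : INT_MAX;
    int lb = j < B.size() ? B[j] : INT_MAX;
    int l = la < lb ? la : lb;
    while (k < x && bp[k] <= l) k++; // k = number of breakpoints <= l
    bool from_a = ((k % 2) == 0) == start_a;
    if (from_a ? (la == l) : (lb == l)) out.push_back(l);
    if (la == l) i++;
    if (lb == l) j++;
  }
}

// x ~ Poisson(R) breakpoints placed uniformly without replacement among the
// L-1 inter-locus intervals (x capped at L-1), sorted into the scratch
// buffer; returns x
static int draw_breakpoints(double rate, int L, std::vector<int>& bp) {
  int x = (int)R::rpois(rate);
  if (x > L - 1) x = L - 1;
  if ((int)bp.size() < x) bp.resize(x);
  int k = 0;
  while (k < x) {
    int v = 1 + unif_index(L - 1);
    bool dup = false;
    for (int t = 0; t < k; t++)
      if (bp[t] == v) { dup = true; break; }
    if (!dup) bp[k++] = v;
  }
  std::sort(bp.begin(), bp.begin() + x);
  return x;
}

struct GameteScratch {
  std::vector<int> bp;
  Hap g1, g2;
};

static void draw_gamete_into(const Hap& A, const Hap& B, double rate, int L,
                             std::vector<int>& bp, Hap& out) {
  int x = draw_breakpoints(rate, L, bp);
  bool start_a = unif_rand() < 0.5;
  splice_into(A, B, bp.data(), x, start_a, out);
}

static Hap draw_gamete(const Hap& A, const Hap& B, double rate, int L) {
  GameteScratch sc;
  draw_gamete_into(A, B, rate, L, sc.bp, sc.g1);
  return sc.g1;
}

// k ~ Poisson(U) target allele copies uniform among the 2L copies of the
// diploid genome; wild-type copies become mutant, mutant copies stay mutant
static void apply_mutations(Hap& a, Hap& b, double U, int L) {
  int k = (int)R::rpois(U);
  for (int i = 0; i < k; i++) {
    Hap& h = (unif_rand() < 0.5) ? a : b;
    int locus = unif_index(L);
    Hap::iterator it = std::lower_bound(h.begin(), h.end(), locus);
    if (it == h.end() || *it != locus) h.insert(it, locus);
  }
}

// homozygotes express their allele; heterozygotes express either allele with
// probability 1/2, decided once at birth
static inline int draw_phenotype(int ma, int mb) {
  if (ma == mb) return ma;
  return (unif_rand() < 0.5) ? ma : mb;
}

// ---------------------------------------------------------------------------
// lifecycle stages

static void dispersal_stage(Pop& P, const Params& par) {
  int N = P.n();
  if (N == 0) stop("population is empty");
  std::vector<char> mark(N, 0);
  // FAD individuals grouped by allele slot (and deme, in per-deme mode)
  std::map<std::pair<int, int>, std::vector<int> > groups;
  for (int i = 0; i < N; i++) {
    int e = P.pheno[i];
    if (par.strat[e] == 0) {
      if (unif_rand() < par.alpha[e]) mark[i] = 1;
    } else {
      int key2 = par.fad_per_deme ? P.deme[i] : 0;
      groups[std::make_pair(e, key2)].push_back(i);
    }
  }
  for (std::map<std::pair<int, int>, std::vector<int> >::iterator g =
           groups.begin();
       g != groups.end(); ++g) {
    std::vector<int>& idx = g->second;
    int e = g->first.first;
    int d = (int)R::rbinom((double)idx.size(), par.alpha[e]);
    if (d <= 0) continue;
    if (d >= (int)idx.size()) {
      for (size_t k = 0; k < idx.size(); k++) mark[idx[k]] = 1;
      continue;
    }
    // lowest fitness disperses first; ties broken by a uniform key
    std::vector<double> key(idx.size());
    for (size_t k = 0; k < idx.size(); k++) key[k] = unif_rand();
    std::vector<int> ord(idx.size());
    for (size_t k = 0; k < idx.size(); k++) ord[k] = (int)k;
    const std::vector<double>& fit = P.fit;
    const std::vector<int>& ii = idx;
    std::sort(ord.begin(), ord.end(), [&](int x, int y) {
      if (fit[ii[x]] != fit[ii[y]]) return fit[ii[x]] < fit[ii[y]];
      return key[x] < key[y];
    });
    for (int r = 0; r < d; r++) mark[idx[ord[r]]] = 1;
  }
  // cost of dispersal, then island-model relocation of the survivors
  int D = P.n_demes;
  std::vector<char> dead(N, 0);
  for (int i = 0; i < N; i++) {
    if (!mark[i]) continue;
    if (unif_rand() < par.c) { dead[i] = 1; continue; }
    P.deme[i] = unif_index(D);
  }
  int keep = 0;
  for (int i = 0; i < N; i++) {
    if (dead[i]) continue;
    if (keep != i) {
      P.hapA[keep] = std::move(P.hapA[i]);
      P.hapB[keep] = std::move(P.hapB[i]);
      P.modA[keep] = P.modA[i];
      P.modB[keep] = P.modB[i];
      P.pheno[keep] = P.pheno[i];
      P.fit[keep] = P.fit[i];
      P.deme[keep] = P.deme[i];
    }
    keep++;
  }
  P.hapA.resize(keep); P.hapB.resize(keep);
  P.modA.resize(keep); P.modB.resize(keep);
  P.pheno.resize(keep); P.fit.resize(keep); P.deme.resize(keep);
  if (keep == 0)
    stop("population went extinct: every individual dispersed and perished");
}

static Pop reproduction_stage(const Pop& P, const Params& par) {
  int D = P.n_demes;
  std::vector<std::vector<int> > members(D);
  for (int i = 0; i < P.n(); i++) members[P.deme[i]].push_back(i);
  // demes need two distinct parents (no selfing); weights fixed for the
  // whole stage because parents are not consumed
  std::vector<double> cum(D, 0.0);
  double tot = 0.0;
  for (int d = 0; d < D; d++) {
    if (members[d].size() >= 2) tot += (double)members[d].size();
    cum[d] = tot;
  }
  if (tot <= 0.0)
    stop("population cannot reproduce: no deme has two or more adults");

  Pop Q;
  Q.n_demes = P.n_demes;
  Q.n_total = P.n_total;
  Q.capacity = P.capacity;
  Q.hapA.reserve(P.n_total); Q.hapB.reserve(P.n_total);
  Q.modA.reserve(P.n_total); Q.modB.reserve(P.n_total);
  Q.pheno.reserve(P.n_total); Q.fit.reserve(P.n_total);
  Q.deme.reserve(P.n_total);

  double ceiling = par.attempt_factor * (double)P.n_total;
  double attempts = 0;
  GameteScratch sc; // reused across conceptions; rejections allocate nothing
  while (Q.n() < P.n_total) {
    if (++attempts > ceiling)
      stop("conception attempt ceiling exceeded (%.0f attempts for %d "
           "offspring); check selection parameters",
           attempts - 1, Q.n());
    double u = unif_rand() * tot;
    int d = (int)(std::upper_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (d >= D) d = D - 1;
    const std::vector<int>& mem = members[d];
    int sz = (int)mem.size();
    int i1 = unif_index(sz);
    int i2 = unif_index(sz - 1);
    if (i2 >= i1) i2++;
    int p1 = mem[i1], p2 = mem[i2];
    draw_gamete_into(P.hapA[p1], P.hapB[p1], par.R, par.L, sc.bp, sc.g1);
    int a1 = (unif_rand() < 0.5) ? P.modA[p1] : P.modB[p1];
    draw_gamete_into(P.hapA[p2], P.hapB[p2], par.R, par.L, sc.bp, sc.g2);
    int a2 = (unif_rand() < 0.5) ? P.modA[p2] : P.modB[p2];
    apply_mutations(sc.g1, sc.g2, par.U, par.L);
    int m, n;
    count_classes(sc.g1, sc.g2, m, n);
    double f = fitness_mn(m, n, par.s, par.h);
    int ph = draw_phenotype(a1, a2);
    if (unif_rand() < f) { // viability selection on the juvenile
      Q.hapA.push_back(Hap(sc.g1.begin(), sc.g1.end()));
      Q.hapB.push_back(Hap(sc.g2.begin(), sc.g2.end()));
      Q.modA.push_back(a1);
      Q.modB.push_back(a2);
      Q.pheno.push_back(ph);
      Q.fit.push_back(f);
      Q.deme.push_back(d); // offspring join their parents' deme
    }
  }
  return Q;
}

// demes exceeding capacity K are split into random halves of size
// floor(n/2) / ceil(n/2); halves still above K are re-split
static void split_demes(Pop& P, int K) {
  std::vector<std::vector<int> > members(P.n_demes);
  for (int i = 0; i < P.n(); i++) members[P.deme[i]].push_back(i);
  std::vector<std::vector<int> > out;
  out.reserve(members.size());
  std::deque<std::vector<int> > work(members.begin(), members.end());
  while (!work.empty()) {
    std::vector<int> v = std::move(work.front());
    work.pop_front();
    if ((int)v.size() <= K) {
      out.push_back(std::move(v));
      continue;
    }
    // uniformly random halves via Fisher-Yates
    for (int k = (int)v.size() - 1; k > 0; k--) {
      int j = unif_index(k + 1);
      std::swap(v[k], v[j]);
    }
    size_t half = v.size() / 2;
    std::vector<int> lo(v.begin(), v.begin() + half);
    std::vector<int> hi(v.begin() + half, v.end());
    work.push_front(std::move(hi));
    work.push_front(std::move(lo));
  }
  for (size_t d = 0; d < out.size(); d++)
    for (size_t k = 0; k < out[d].size(); k++) P.deme[out[d][k]] = (int)d;
  P.n_demes = (int)out.size();
}

static void drop_empty_demes(Pop& P) {
  std::vector<int> count(P.n_demes, 0);
  for (int i = 0; i < P.n(); i++) count[P.deme[i]]++;
  std::vector<int> newid(P.n_demes, -1);
  int next = 0;
  for (int d = 0; d < P.n_demes; d++)
    if (count[d] > 0) newid[d] = next++;
  for (int i = 0; i < P.n(); i++) P.deme[i] = newid[P.deme[i]];
  P.n_demes = next;
}

static void step_generation(Pop& P, const Params& par) {
  dispersal_stage(P, par);
  P = reproduction_stage(P, par);
  split_demes(P, P.capacity);
  drop_empty_demes(P);
}

// ---------------------------------------------------------------------------
// summaries

// expected dispersal-mortality-inclusive fitness: each adult's viability is
// discounted by c times its probability of dispersing this generation (its
// strategy's rate for UNI carriers; the exact rank-based marked-set
// probability for FAD carriers, ties sharing their block's average).
// Returns the per-capita sum over the census.
static double costed_mean_fitness(const Pop& P, const Params& par) {
  int N = P.n();
  double total = 0.0;
  std::map<std::pair<int, int>, std::vector<int> > groups;
  for (int i = 0; i < N; i++) {
    int e = P.pheno[i];
    if (par.strat[e] == 0) {
      total += P.fit[i] * (1.0 - par.c * par.alpha[e]);
    } else {
      int key2 = par.fad_per_deme ? P.deme[i] : 0;
      groups[std::make_pair(e, key2)].push_back(i);
    }
  }
  for (std::map<std::pair<int, int>, std::vector<int> >::iterator g =
           groups.begin();
       g != groups.end(); ++g) {
    std::vector<int>& idx = g->second;
    int nf = (int)idx.size();
    double alpha = par.alpha[g->first.first];
    const std::vector<double>& fit = P.fit;
    std::sort(idx.begin(), idx.end(),
              [&](int x, int y) { return fit[x] < fit[y]; });
    // P(individual at ascending-fitness rank r is marked) = P(count > r)
    std::vector<double> pr(nf);
    for (int r = 0; r < nf; r++)
      pr[r] = 1.0 - R::pbinom((double)r, (double)nf, alpha, 1, 0);
    int r0 = 0;
    while (r0 < nf) { // average the mark probability across tied blocks
      int r1 = r0;
      while (r1 + 1 < nf && fit[idx[r1 + 1]] == fit[idx[r0]]) r1++;
      double pbar = 0.0;
      for (int r = r0; r <= r1; r++) pbar += pr[r];
      pbar /= (r1 - r0 + 1);
      for (int r = r0; r <= r1; r++)
        total += fit[idx[r]] * (1.0 - par.c * pbar);
      r0 = r1 + 1;
    }
  }
  return total / N;
}

// columns: mean_fitness, het_fraction, freq_slot2, n_demes,
//          mean_fitness_fad, mean_fitness_uni, mean_het_loci,
//          mean_fitness_costed
// The per-strategy fitness means are allele-copy-weighted: the mean
// viability of the carriers of FAD-strategy (resp. UNI-strategy) modifier
// allele copies, each individual counting once per copy carried.
static void summarize(const Pop& P, const Params& par, double* row) {
  int N = P.n();
  if (N == 0) stop("cannot summarize an empty population");
  double sfit = 0.0;
  double sn = 0.0, s2m = 0.0;
  double n2 = 0.0;
  double sfad = 0.0, suni = 0.0;
  double nfad = 0.0, nuni = 0.0;
  for (int i = 0; i < N; i++) {
    sfit += P.fit[i];
    int m, n;
    count_classes(P.hapA[i], P.hapB[i], m, n);
    sn += n;
    s2m += 2.0 * m;
    n2 += (P.modA[i] == 1) + (P.modB[i] == 1);
    int cf = (par.strat[P.modA[i]] == 1) + (par.strat[P.modB[i]] == 1);
    sfad += cf * P.fit[i];
    nfad += cf;
    suni += (2 - cf) * P.fit[i];
    nuni += 2 - cf;
  }
  row[0] = sfit / N;
  double denom = sn + s2m;
  row[1] = denom > 0 ? sn / denom : 0.0; // pooled: 0/0 defined as 0
  row[2] = n2 / (2.0 * N);
  row[3] = (double)P.n_demes;
  row[4] = nfad > 0 ? sfad / nfad : NA_REAL;
  row[5] = nuni > 0 ? suni / nuni : NA_REAL;
  row[6] = sn / N;
  row[7] = costed_mean_fitness(P, par);
}

#define N_STATS 8

static NumericMatrix records_matrix(const std::vector<double>& rec, int rows) {
  NumericMatrix M(rows, N_STATS + 1);
  for (int r = 0; r < rows; r++) {
    M(r, 0) = (double)r; // generation index, 0 = initial state
    for (int c = 0; c < N_STATS; c++) M(r, c + 1) = rec[r * N_STATS + c];
  }
  colnames(M) = CharacterVector::create("generation", "mean_fitness",
                                        "het_fraction", "freq_slot2",
                                        "n_demes", "mean_fitness_fad",
                                        "mean_fitness_uni", "mean_het_loci",
                                        "mean_fitness_costed");
  return M;
}

// ---------------------------------------------------------------------------
// exported single operations (R-level module surface)

// [[Rcpp::export]]
IntegerVector engine_count_classes(IntegerVector hap_a, IntegerVector hap_b) {
  Hap a = as<Hap>(hap_a), b = as<Hap>(hap_b);
  int m, n;
  count_classes(a, b, m, n);
  return IntegerVector::create(_["m"] = m, _["n"] = n);
}

// [[Rcpp::export]]
IntegerMatrix engine_mn_matrix(List pop) {
  Pop P = pop_from_r(pop);
  IntegerMatrix M(P.n(), 2);
  for (int i = 0; i < P.n(); i++) {
    int m, n;
    count_classes(P.hapA[i], P.hapB[i], m, n);
    M(i, 0) = m;
    M(i, 1) = n;
  }
  colnames(M) = CharacterVector::create("m", "n");
  return M;
}

// [[Rcpp::export]]
IntegerVector engine_splice_gamete(IntegerVector hap_a, IntegerVector hap_b,
                                   IntegerVector breakpoints, bool start_a) {
  Hap a = as<Hap>(hap_a), b = as<Hap>(hap_b), bp = as<Hap>(breakpoints);
  std::sort(bp.begin(), bp.end());
  Hap g;
  splice_into(a, b, bp.data(), (int)bp.size(), start_a, g);
  return wrap(g);
}

// [[Rcpp::export]]
List engine_make_gamete(IntegerVector hap_a, IntegerVector hap_b, int mod_a,
                        int mod_b, double rate, int L) {
  Hap a = as<Hap>(hap_a), b = as<Hap>(hap_b);
  Hap g = draw_gamete(a, b, rate, L);
  int allele = (unif_rand() < 0.5) ? mod_a : mod_b;
  return List::create(_["hap"] = wrap(g), _["allele"] = allele);
}

// [[Rcpp::export]]
List engine_apply_mutations(IntegerVector hap_a, IntegerVector hap_b,
                            double U, int L) {
  Hap a = as<Hap>(hap_a), b = as<Hap>(hap_b);
  apply_mutations(a, b, U, L);
  return List::create(_["hap_a"] = wrap(a), _["hap_b"] = wrap(b));
}

// [[Rcpp::export]]
int engine_assign_phenotype(int mod_a, int mod_b) {
  return draw_phenotype(mod_a, mod_b);
}

// [[Rcpp::export]]
List engine_dispersal_stage(List pop, List params) {
  Pop P = pop_from_r(pop);
  Params par = params_from_r(params);
  dispersal_stage(P, par);
  return pop_to_r(P);
}

// [[Rcpp::export]]
List engine_reproduction_stage(List pop, List params) {
  Pop P = pop_from_r(pop);
  Params par = params_from_r(params);
  Pop Q = reproduction_stage(P, par);
  return pop_to_r(Q);
}

// [[Rcpp::export]]
List engine_split_demes(List pop) {
  Pop P = pop_from_r(pop);
  split_demes(P, P.capacity);
  return pop_to_r(P);
}

// [[Rcpp::export]]
List engine_drop_empty_demes(List pop) {
  Pop P = pop_from_r(pop);
  drop_empty_demes(P);
  return pop_to_r(P);
}

// [[Rcpp::export]]
List engine_step_generation(List pop, List params) {
  Pop P = pop_from_r(pop);
  Params par = params_from_r(params);
  step_generation(P, par);
  return pop_to_r(P);
}

// [[Rcpp::export]]
NumericVector engine_summary(List pop, List params) {
  Pop P = pop_from_r(pop);
  Params par = params_from_r(params);
  double row[N_STATS];
  summarize(P, par, row);
  NumericVector out(N_STATS);
  for (int i = 0; i < N_STATS; i++) out[i] = row[i];
  out.names() = CharacterVector::create("mean_fitness", "het_fraction",
                                        "freq_slot2", "n_demes",
                                        "mean_fitness_fad",
                                        "mean_fitness_uni", "mean_het_loci",
                                        "mean_fitness_costed");
  return out;
}

// multi-generation driver; keeps everything on the C++ side.
// stop_on_absorption halts once allele slot 2 reaches frequency 0 or 1.
// [[Rcpp::export]]
List engine_run(List pop, List params, int max_gens,
                bool stop_on_absorption = false, bool record = true) {
  Pop P = pop_from_r(pop);
  Params par = params_from_r(params);
  std::vector<double> rec;
  if (record) rec.reserve((size_t)(max_gens + 1) * N_STATS);
  double row[N_STATS];
  summarize(P, par, row);
  if (record) rec.insert(rec.end(), row, row + N_STATS);
  int g = 0;
  bool absorbed = stop_on_absorption && (row[2] <= 0.0 || row[2] >= 1.0);
  while (g < max_gens && !absorbed) {
    step_generation(P, par);
    g++;
    summarize(P, par, row);
    if (record) rec.insert(rec.end(), row, row + N_STATS);
    if (stop_on_absorption && (row[2] <= 0.0 || row[2] >= 1.0))
      absorbed = true;
    if (g % 256 == 0) checkUserInterrupt();
  }
  List out = List::create(
      _["pop"] = pop_to_r(P), _["generations"] = g, _["absorbed"] = absorbed,
      _["final_freq"] = row[2],
      _["records"] = record ? (SEXP)records_matrix(rec, g + 1)
                            : (SEXP)R_NilValue);
  return out;
}
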