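#include <Rcpp.h>
#include <string>
#include <vector>
#include <map>
#include <set>
#include <cstdio>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Sequence helpers
// ---------------------------------------------------------------------------

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static void encode_seq(const std::string& seq, std::vector<int>& out) {
  const int n = (int)seq.size();
  out.resize(n);
  for (int i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) stop("invalid character '%s' at position %d (alphabet is A,C,G,T)",
                    std::string(1, seq[i]).c_str(), i + 1);
    out[i] = c;
  }
}

struct Site {
  int gene;    // 0-based
  int tf;      // 0-based
  int pos;     // 0-based forward-strand window start
  int strand;  // 0 = forward, 1 = reverse
  double llr;  // bits
  double qbase; // exp((llr - llr_max) * llr_scale)
};

// Scan one promoter with one PWM (log2 odds matrix, 4 x L), both strands.
// A reverse-strand site at forward window [pos, pos+L) is scored on the
// reverse complement read 3'->5' relative to the forward strand.
static void scan_into(const std::vector<int>& code, const double* lo, int L,
                      double llrmax, double minllr, double llr_scale,
                      int gene, int tf, std::vector<Site>& out) {
  const int n = (int)code.size();
  if (n < L) return;
  for (int pos = 0; pos <= n - L; ++pos) {
    double sf = 0.0, sr = 0.0;
    for (int k = 0; k < L; ++k) {
      sf += lo[code[pos + k] + 4 * k];
      sr += lo[(3 - code[pos + L - 1 - k]) + 4 * k];
    }
    if (sf >= minllr)
      out.push_back(Site{gene, tf, pos, 0, sf, std::exp((sf - llrmax) * llr_scale)});
    if (sr >= minllr)
      out.push_back(Site{gene, tf, pos, 1, sr, std::exp((sr - llrmax) * llr_scale)});
  }
}

// [[Rcpp::export]]
DataFrame cpp_scan_promoter(std::string seq, NumericMatrix logodds,
                            double llr_max, double min_llr, double llr_scale) {
  if (logodds.nrow() != 4) stop("log-odds matrix must have 4 rows");
  std::vector<int> code;
  encode_seq(seq, code);
  std::vector<Site> sites;
  scan_into(code, REAL(logodds), logodds.ncol(), llr_max, min_llr, llr_scale,
            0, 0, sites);
  const int m = (int)sites.size();
  IntegerVector pos(m), strand(m);
  NumericVector llr(m), qb(m);
  for (int i = 0; i < m; ++i) {
    pos[i] = sites[i].pos;
    strand[i] = sites[i].strand;
    llr[i] = sites[i].llr;
    qb[i] = sites[i].qbase;
  }
  return DataFrame::create(_["position"] = pos, _["strand"] = strand,
                           _["llr"] = llr, _["q_base"] = qb);
}

// ---------------------------------------------------------------------------
// Thermodynamic expression dynamics
// ---------------------------------------------------------------------------

// Promoter activation E = Z_ON / (Z_ON + Z_OFF), computed in log space.
// basal_mode: 0 = exclude-empty (Z_ON = prod(1+q*alpha) - 1),
//             1 = include-empty (Z_ON = prod(1+q*alpha)),
//             2 = btm-weight   (Z_ON = q_btm * prod(1+q*alpha)).
static inline double activation_from_logs(double logZon_full, double logZoff,
                                          int basal_mode, double q_btm) {
  double logZon;
  if (basal_mode == 0) {
    if (logZon_full <= 0.0) return 0.0;
    logZon = (logZon_full < 30.0) ? std::log(std::expm1(logZon_full)) : logZon_full;
  } else if (basal_mode == 1) {
    logZon = logZon_full;
  } else {
    logZon = std::log(q_btm) + logZon_full;
  }
  return 1.0 / (1.0 + std::exp(logZoff - logZon));
}

struct DynSettings {
  int G, C, P, nTF, T;
  double b;
  int basal_mode;
  double q_btm;
  bool chromatin;
  double beta, delta;
  const double* alpha;
  const double* kmax;
  const double* rho;
  const double* sigma;
};

// Synchronous Euler integration of expression (and optionally chromatin).
// x layout: x[g + G*c + G*C*t]; phi layout (per gene, per cell): vector of
// G*C slots each of length P, phi[(g + G*c)*P + i].
static void run_dynamics_core(const std::vector<std::vector<Site>>& sites,
                              const DynSettings& st, const double* x0,
                              std::vector<double>& x, std::vector<double>& Ecache,
                              std::vector<double>& phi) {
  const int G = st.G, C = st.C, P = st.P, T = st.T;
  x.assign((size_t)G * C * (T + 1), 0.0);
  Ecache.assign((size_t)G * C, 0.0);
  for (int c = 0; c < C; ++c)
    for (int g = 0; g < G; ++g) x[g + (size_t)G * c] = x0[g + (size_t)G * c];
  if (st.chromatin) phi.assign((size_t)G * C * P, 1.0);

  std::vector<double> newphi;
  // per-sigma table of exp(-d^2 / (2 sigma^2)) for d = 0..P-1 (exact reuse)
  std::map<double, std::vector<double>> gauss;
  if (st.chromatin) {
    newphi.resize((size_t)P);
    for (int h = 0; h < st.nTF; ++h) {
      double sd = st.sigma[h];
      if (gauss.find(sd) == gauss.end()) {
        std::vector<double> tab(P);
        for (int d = 0; d < P; ++d)
          tab[d] = std::exp(-((double)d * d) / (2.0 * sd * sd));
        gauss[sd] = tab;
      }
    }
  }

  for (int t = 1; t <= T; ++t) {
    const double* xt = &x[(size_t)G * C * (t - 1)];
    double* xn = &x[(size_t)G * C * t];
    for (int c = 0; c < C; ++c) {
      for (int g = 0; g < G; ++g) {
        const std::vector<Site>& sg = sites[g];
        double logZoff = 0.0, logZon = 0.0;
        for (size_t s = 0; s < sg.size(); ++s) {
          const Site& si = sg[s];
          double conc = xt[si.tf + (size_t)G * c];
          double acc = st.chromatin ? phi[((size_t)g + (size_t)G * c) * P + si.pos] : 1.0;
          double q = acc * conc * st.kmax[si.tf] * si.qbase;
          logZoff += std::log1p(q);
          logZon += std::log1p(q * st.alpha[si.tf]);
        }
        double E = activation_from_logs(logZon, logZoff, st.basal_mode, st.q_btm);
        Ecache[g + (size_t)G * c] = E;
        double xv = xt[g + (size_t)G * c] + (E - st.b * xt[g + (size_t)G * c]);
        if (xv < 0.0) xv = 0.0;
        if (!R_finite(xv))
          stop("non-finite expression for gene %d, cell %d at step %d", g + 1, c + 1, t);
        xn[g + (size_t)G * c] = xv;
      }
      if (st.chromatin) {
        for (int g = 0; g < G; ++g) {
          const std::vector<Site>& sg = sites[g];
          const double H = (double)sg.size();
          double* ph = &phi[((size_t)g + (size_t)G * c) * P];
          std::fill(newphi.begin(), newphi.end(), 0.0);
          if (H > 0) {
            for (size_t s = 0; s < sg.size(); ++s) {
              const Site& si = sg[s];
              double conc = xt[si.tf + (size_t)G * c];
              if (conc == 0.0) continue;
              double coef = conc * st.kmax[si.tf] * st.rho[si.tf] * si.qbase;
              const std::vector<double>& tab = gauss[st.sigma[si.tf]];
              for (int i = 0; i < P; ++i)
                newphi[i] += coef * tab[std::abs(i - si.pos)];
            }
            for (int i = 0; i < P; ++i) newphi[i] /= H;
          }
          for (int i = 0; i < P; ++i) {
            double pv = ph[i] + st.beta * (newphi[i] + st.delta * ph[i]);
            if (pv < 0.0) pv = 0.0;
            ph[i] = pv;
          }
        }
      }
    }
  }
}

static std::vector<std::vector<Site>> sites_from_vectors(
    const IntegerVector& gene, const IntegerVector& tf, const IntegerVector& pos,
    const IntegerVector& strand, const NumericVector& llr, const NumericVector& qbase,
    int G) {
  std::vector<std::vector<Site>> sites(G);
  const int m = gene.size();
  for (int i = 0; i < m; ++i) {
    int g = gene[i] - 1;
    if (g < 0 || g >= G) stop("site gene index out of range");
    sites[g].push_back(Site{g, tf[i] - 1, pos[i], strand[i], llr[i], qbase[i]});
  }
  return sites;
}

// [[Rcpp::export]]
List cpp_run_dynamics(IntegerVector site_gene, IntegerVector site_tf,
                      IntegerVector site_pos, IntegerVector site_strand,
                      NumericVector site_llr, NumericVector site_qbase,
                      int G, int C, int P, int nTF, NumericMatrix x0,
                      NumericVector alpha, NumericVector kmax,
                      NumericVector rho, NumericVector sigma,
                      double b, int T, int basal_mode, double q_btm,
                      bool chromatin, double beta, double delta) {
  DynSettings st{G, C, P, nTF, T, b, basal_mode, q_btm, chromatin, beta, delta,
                 REAL(alpha), REAL(kmax), REAL(rho), REAL(sigma)};
  std::vector<std::vector<Site>> sites =
    sites_from_vectors(site_gene, site_tf, site_pos, site_strand, site_llr,
                       site_qbase, G);
  std::vector<double> x, E, phi;
  run_dynamics_core(sites, st, REAL(x0), x, E, phi);
  NumericVector xr(x.begin(), x.end());
  xr.attr("dim") = IntegerVector::create(G, C, T + 1);
  NumericVector Er(E.begin(), E.end());
  Er.attr("dim") = IntegerVector::create(G, C);
  List out = List::create(_["x"] = xr, _["E"] = Er);
  if (chromatin) {
    NumericVector ph(phi.begin(), phi.end());
    // stored as [position, gene, cell]
    ph.attr("dim") = IntegerVector::create(P, G, C);
    out["phi"] = ph;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Evolutionary loop
// ---------------------------------------------------------------------------

struct Individual {
  std::vector<std::string> prom;
  std::vector<std::vector<Site>> sites;
  std::vector<double> final_x; // G*C
  double mse;
};

static inline int unif_int(int n) {
  int v = (int)(unif_rand() * n);
  return (v >= n) ? n - 1 : v;
}

struct PwmSet {
  std::vector<const double*> lo;
  std::vector<int> L;
  std::vector<double> llrmax, minllr;
  double llr_scale;
};

static void scan_gene(Individual& ind, int g, const PwmSet& pw, int nTF) {
  std::vector<int> code;
  encode_seq(ind.prom[g], code);
  ind.sites[g].clear();
  for (int h = 0; h < nTF; ++h)
    scan_into(code, pw.lo[h], pw.L[h], pw.llrmax[h], pw.minllr[h], pw.llr_scale,
              g, h, ind.sites[g]);
}

static double eval_mse(const std::vector<double>& final_x, const double* optimal,
                       const std::vector<int>& term_idx, int G, int C) {
  double acc = 0.0;
  for (int c = 0; c < C; ++c) {
    double gc = 0.0;
    for (size_t k = 0; k < term_idx.size(); ++k) {
      int g = term_idx[k];
      double d = final_x[g + (size_t)G * c] - optimal[g + (size_t)G * c];
      gc += d * d;
    }
    acc += gc / (double)term_idx.size();
  }
  return acc / (double)C;
}

static void eval_individual(Individual& ind, const DynSettings& st,
                            const double* x0, const double* optimal,
                            const std::vector<int>& term_idx) {
  std::vector<double> x, E, phi;
  run_dynamics_core(ind.sites, st, x0, x, E, phi);
  const int G = st.G, C = st.C, T = st.T;
  ind.final_x.assign(x.begin() + (size_t)G * C * T, x.end());
  ind.mse = eval_mse(ind.final_x, optimal, term_idx, G, C);
}

// tournament: draw k distinct indices, return index of min-mse (tie: lower index)
static int tournament(const std::vector<Individual>& pop, int k,
                      std::vector<int>& scratch) {
  const int N = (int)pop.size();
  for (int i = 0; i < N; ++i) scratch[i] = i;
  int best = -1;
  for (int d = 0; d < k; ++d) {
    int j = d + unif_int(N - d);
    std::swap(scratch[d], scratch[j]);
    int cand = scratch[d];
    if (best < 0 || pop[cand].mse < pop[best].mse ||
        (pop[cand].mse == pop[best].mse && cand < best))
      best = cand;
  }
  return best;
}

// Mosaic of two parental promoters with sorted crossover points, starting
// from parent `first`.
static std::string crossover(const std::string& a, const std::string& b,
                             int first, const std::vector<int>& points) {
  const int P = (int)a.size();
  std::string out;
  out.reserve(P);
  int src = first, prev = 0;
  for (size_t i = 0; i <= points.size(); ++i) {
    int end = (i == points.size()) ? P : points[i];
    const std::string& s = (src == 0) ? a : b;
    out.append(s, prev, end - prev);
    prev = end;
    src = 1 - src;
  }
  return out;
}

static inline int64_t site_key(const Site& s, int nTF, int P) {
  return ((((int64_t)s.gene * nTF + s.tf) * P) + s.pos) * 2 + s.strand;
}

// [[Rcpp::export]]
List cpp_evolve(int G, int C, int P, int nTF,
                NumericMatrix x0, NumericMatrix optimal, IntegerVector terminal_idx,
                List pwm_logodds, NumericVector pwm_llrmax, NumericVector pwm_minllr,
                double llr_scale,
                NumericVector alpha, NumericVector kmax, NumericVector rho,
                NumericVector sigma,
                double b, int T, int basal_mode, double q_btm,
                bool chromatin, double beta, double delta,
                int N, int k_base, int k_late, double r_rate, double epsilon,
                int max_generations, NumericVector m_sched, IntegerVector m_breaks,
                double clip_lo, double clip_hi,
                bool track_sites, int progress_every) {
  DynSettings st{G, C, P, nTF, T, b, basal_mode, q_btm, chromatin, beta, delta,
                 REAL(alpha), REAL(kmax), REAL(rho), REAL(sigma)};
  PwmSet pw;
  pw.llr_scale = llr_scale;
  std::vector<NumericMatrix> keep;
  for (int h = 0; h < nTF; ++h) {
    NumericMatrix m = pwm_logodds[h];
    keep.push_back(m);
    pw.lo.push_back(REAL(keep.back()));
    pw.L.push_back(m.ncol());
    pw.llrmax.push_back(pwm_llrmax[h]);
    pw.minllr.push_back(pwm_minllr[h]);
  }
  std::vector<int> term_idx(terminal_idx.begin(), terminal_idx.end());
  const double genome_kb = (double)G * P / 1000.0;

  static const char BASES[] = "ACGT";
  std::vector<Individual> pop(N);
  for (int i = 0; i < N; ++i) {
    pop[i].prom.resize(G);
    pop[i].sites.resize(G);
    for (int g = 0; g < G; ++g) {
      std::string s(P, 'A');
      for (int j = 0; j < P; ++j) s[j] = BASES[unif_int(4)];
      pop[i].prom[g] = s;
      scan_gene(pop[i], g, pw, nTF);
    }
    eval_individual(pop[i], st, REAL(x0), REAL(optimal), term_idx);
  }

  // site tracking state
  std::unordered_map<int64_t, int> alive; // key -> birth generation
  std::vector<int64_t> ev_key;
  std::vector<int> ev_birth, ev_death;
  auto track_generation = [&](int gen) {
    std::unordered_set<int64_t> current;
    for (int i = 0; i < N; ++i)
      for (int g = 0; g < G; ++g)
        for (size_t s = 0; s < pop[i].sites[g].size(); ++s)
          current.insert(site_key(pop[i].sites[g][s], nTF, P));
    for (auto it = alive.begin(); it != alive.end();) {
      if (current.find(it->first) == current.end()) {
        ev_key.push_back(it->first);
        ev_birth.push_back(it->second);
        ev_death.push_back(gen);
        it = alive.erase(it);
      } else ++it;
    }
    for (int64_t k : current)
      if (alive.find(k) == alive.end()) alive[k] = gen;
  };

  std::vector<double> mse_mean, mse_best;
  auto record = [&](void) {
    double mn = 0.0, bs = R_PosInf;
    for (int i = 0; i < N; ++i) {
      mn += pop[i].mse;
      if (pop[i].mse < bs) bs = pop[i].mse;
    }
    mse_mean.push_back(mn / N);
    mse_best.push_back(bs);
    return mn / N;
  };

  double mean_mse = record();
  if (track_sites) track_generation(0);
  bool converged = mean_mse < epsilon;
  int gen = 0;

  std::vector<int> scratch(N);
  std::vector<Individual> next(N);
  while (!converged && gen < max_generations) {
    ++gen;
    if (gen % 50 == 0) checkUserInterrupt();
    // mutation-rate schedule (per kb), k schedule
    double m_base;
    if (gen < m_breaks[0]) m_base = m_sched[0];
    else if (gen < m_breaks[1]) m_base = m_sched[1];
    else if (gen < m_breaks[2]) m_base = m_sched[2] / genome_kb;
    else m_base = m_sched[3] / genome_kb;
    int k = (gen > m_breaks[1] && mean_mse < 0.5) ? k_late : k_base;

    for (int i = 0; i < N; ++i) {
      int pa = tournament(pop, k, scratch);
      int pb = tournament(pop, k, scratch);
      double rel = ((pop[pa].mse + pop[pb].mse) / 2.0) / mean_mse;
      if (rel < clip_lo) rel = clip_lo;
      if (rel > clip_hi) rel = clip_hi;
      double m_i = m_base * rel;

      Individual& ch = next[i];
      ch.prom.resize(G);
      ch.sites.resize(G);
      for (int g = 0; g < G; ++g) {
        int first = (unif_rand() < 0.5) ? 0 : 1;
        const std::string& sa = pop[pa].prom[g];
        const std::string& sb = pop[pb].prom[g];
        int ncross = (int)R::rpois(r_rate * P / 1000.0);
        std::string s;
        if (ncross > 0 && sa != sb) {
          std::vector<int> pts(ncross);
          for (int q = 0; q < ncross; ++q) pts[q] = 1 + unif_int(P - 1);
          std::sort(pts.begin(), pts.end());
          s = crossover(sa, sb, first, pts);
        } else {
          s = (first == 0) ? sa : sb;
        }
        int nsub = (int)R::rpois(m_i * P / 1000.0);
        for (int q = 0; q < nsub; ++q) {
          int posq = unif_int(P);
          int old = base_code(s[posq]);
          s[posq] = BASES[(old + 1 + unif_int(3)) % 4];
        }
        ch.prom[g] = s;
        if (s == sa) ch.sites[g] = pop[pa].sites[g];
        else if (s == sb) ch.sites[g] = pop[pb].sites[g];
        else scan_gene(ch, g, pw, nTF);
      }
      eval_individual(ch, st, REAL(x0), REAL(optimal), term_idx);
    }
    pop.swap(next);
    mean_mse = record();
    if (track_sites) track_generation(gen);
    if (progress_every > 0 && gen % progress_every == 0)
      Rcout << "generation " << gen << " mean MSE " << mean_mse
            << " best " << mse_best.back() << "\n";
    converged = mean_mse < epsilon;
  }

  int best = 0;
  for (int i = 1; i < N; ++i) if (pop[i].mse < pop[best].mse) best = i;

  // outputs
  CharacterMatrix prommat(G, N);
  NumericVector msevec(N);
  for (int i = 0; i < N; ++i) {
    msevec[i] = pop[i].mse;
    for (int g = 0; g < G; ++g) prommat(g, i) = pop[i].prom[g];
  }
  // best individual full trajectory
  std::vector<double> x, E, phi;
  run_dynamics_core(pop[best].sites, st, REAL(x0), x, E, phi);
  NumericVector xr(x.begin(), x.end());
  xr.attr("dim") = IntegerVector::create(G, C, T + 1);

  // best sites as columns
  int nb = 0;
  for (int g = 0; g < G; ++g) nb += (int)pop[best].sites[g].size();
  IntegerVector sg(nb), stf(nb), sp(nb), ss(nb);
  NumericVector sl(nb), sq(nb);
  int w = 0;
  for (int g = 0; g < G; ++g)
    for (size_t s = 0; s < pop[best].sites[g].size(); ++s) {
      const Site& si = pop[best].sites[g][s];
      sg[w] = si.gene + 1; stf[w] = si.tf + 1; sp[w] = si.pos;
      ss[w] = si.strand; sl[w] = si.llr; sq[w] = si.qbase; ++w;
    }

  List events = R_NilValue;
  if (track_sites) {
    // close out still-alive sites as persisted
    int ndead = (int)ev_key.size();
    int nalive = (int)alive.size();
    int ne = ndead + nalive;
    IntegerVector eg(ne), et(ne), ep(ne), es(ne), eb(ne), ed(ne);
    LogicalVector pers(ne);
    int j = 0;
    auto decode = [&](int64_t kk, int idx) {
      es[idx] = (int)(kk & 1); kk >>= 1;
      ep[idx] = (int)(kk % P); kk /= P;
      et[idx] = (int)(kk % nTF) + 1; kk /= nTF;
      eg[idx] = (int)kk + 1;
    };
    for (int q = 0; q < ndead; ++q) {
      decode(ev_key[q], j);
      eb[j] = ev_birth[q]; ed[j] = ev_death[q]; pers[j] = false; ++j;
    }
    for (auto& kv : alive) {
      decode(kv.first, j);
      eb[j] = kv.second; ed[j] = NA_INTEGER; pers[j] = true; ++j;
    }
    events = DataFrame::create(_["gene_id"] = eg, _["tf_id"] = et,
                               _["position"] = ep, _["strand"] = es,
                               _["birth_gen"] = eb, _["death_gen"] = ed,
                               _["persisted"] = pers);
  }

  return List::create(
    _["population"] = prommat, _["mse"] = msevec, _["best_index"] = best + 1,
    _["best_sites"] = DataFrame::create(_["gene_id"] = sg, _["tf_id"] = stf,
                                        _["position"] = sp, _["strand"] = ss,
                                        _["llr"] = sl, _["q_base"] = sq),
    _["best_trajectory"] = xr,
    _["mse_mean"] = NumericVector(mse_mean.begin(), mse_mean.end()),
    _["mse_best"] = NumericVector(mse_best.begin(), mse_best.end()),
    _["generations"] = gen, _["converged"] = converged,
    _["site_events"] = events);
}

// ---------------------------------------------------------------------------
// Typed subgraph enumeration and canonicalization
// ---------------------------------------------------------------------------

// Canonical key of a typed digraph of size k (k <= 6): minimum adjacency
// bit-encoding over all node orderings that put TF nodes in the leading
// slots (type-respecting relabeling). Returns the min encoding and, if
// asked, the ordering of original node indices achieving it.
static uint64_t canonical_bits(const std::vector<std::vector<int>>& adj,
                               const std::vector<int>& nodes,
                               const std::vector<bool>& is_tf,
                               std::vector<int>* best_order) {
  const int k = (int)nodes.size();
  std::vector<int> tfn, ntn;
  for (int i = 0; i < k; ++i)
    (is_tf[nodes[i]] ? tfn : ntn).push_back(nodes[i]);
  std::sort(tfn.begin(), tfn.end());
  std::sort(ntn.begin(), ntn.end());
  uint64_t best = ~0ULL;
  std::vector<int> order(k);
  std::vector<int> ptf = tfn;
  do {
    std::vector<int> pnt = ntn;
    do {
      for (size_t i = 0; i < ptf.size(); ++i) order[i] = ptf[i];
      for (size_t i = 0; i < pnt.size(); ++i) order[ptf.size() + i] = pnt[i];
      uint64_t bits = 0;
      for (int i = 0; i < k; ++i)
        for (int j = 0; j < k; ++j)
          if (adj[order[i]][order[j]]) bits |= (1ULL << (i * k + j));
      if (bits < best) {
        best = bits;
        if (best_order) *best_order = order;
      }
    } while (std::next_permutation(pnt.begin(), pnt.end()));
  } while (std::next_permutation(ptf.begin(), ptf.end()));
  return best;
}

static std::string key_string(int k, int ntf, uint64_t bits) {
  char buf[64];
  snprintf(buf, sizeof(buf), "s%d.t%d.a%llu", k, ntf, (unsigned long long)bits);
  return std::string(buf);
}

// Retention filter on an induced typed subgraph:
//  - every TF node has out-degree >= 1
//  - every non-lineage TF node has in-degree >= 1
//  - at least one lineage TF node is present
//  - at least one non-TF node with in-degree >= 1 is present
static bool retained(const std::vector<std::vector<int>>& adj,
                     const std::vector<int>& nodes,
                     const std::vector<bool>& is_tf,
                     const std::vector<bool>& is_lineage) {
  const int k = (int)nodes.size();
  bool any_lineage = false, any_nontf_in = false;
  for (int i = 0; i < k; ++i) {
    int u = nodes[i];
    int indeg = 0, outdeg = 0;
    for (int j = 0; j < k; ++j) {
      if (j == i) continue;
      if (adj[u][nodes[j]]) ++outdeg;
      if (adj[nodes[j]][u]) ++indeg;
    }
    if (is_tf[u]) {
      if (outdeg == 0) return false;
      if (!is_lineage[u] && indeg == 0) return false;
      if (is_lineage[u]) any_lineage = true;
    } else {
      if (indeg >= 1) any_nontf_in = true;
    }
  }
  return any_lineage && any_nontf_in;
}

struct EnumState {
  const std::vector<std::vector<int>>* adj;
  const std::vector<std::vector<int>>* nbr; // undirected neighbor lists
  const std::vector<bool>* is_tf;
  const std::vector<bool>* is_lineage;
  std::vector<bool> want_size; // indexed by size
  int max_size;
  bool instances;
  std::map<std::string, int> counts;
  std::vector<std::string> inst_key;
  std::vector<std::vector<int>> inst_nodes; // canonical order, original ids
};

static void process_subset(EnumState& st, const std::vector<int>& sub) {
  if (!retained(*st.adj, sub, *st.is_tf, *st.is_lineage)) return;
  int ntf = 0;
  for (int u : sub) if ((*st.is_tf)[u]) ++ntf;
  std::vector<int> order;
  uint64_t bits = canonical_bits(*st.adj, sub, *st.is_tf,
                                 st.instances ? &order : nullptr);
  std::string key = key_string((int)sub.size(), ntf, bits);
  st.counts[key] += 1;
  if (st.instances) {
    st.inst_key.push_back(key);
    st.inst_nodes.push_back(order);
  }
}

// ESU extension: enumerates every connected induced subgraph up to max_size
// exactly once.
static void esu_extend(EnumState& st, std::vector<int>& sub,
                       std::vector<int> ext, int v,
                       std::vector<int>& in_nbrhood) {
  int k = (int)sub.size();
  if (k >= 3 && k <= st.max_size && st.want_size[k]) process_subset(st, sub);
  if (k == st.max_size) return;
  while (!ext.empty()) {
    int w = ext.back();
    ext.pop_back();
    std::vector<int> ext2 = ext;
    std::vector<int> added;
    for (int u : (*st.nbr)[w]) {
      if (u > v && !in_nbrhood[u]) {
        ext2.push_back(u);
        in_nbrhood[u] = 1;
        added.push_back(u);
      }
    }
    sub.push_back(w);
    esu_extend(st, sub, ext2, v, in_nbrhood);
    sub.pop_back();
    for (int u : added) in_nbrhood[u] = 0;
  }
}

// [[Rcpp::export]]
List cpp_enumerate_subgraphs(IntegerMatrix adjacency, LogicalVector is_tf,
                             LogicalVector is_lineage, IntegerVector sizes,
                             bool return_instances) {
  const int n = adjacency.nrow();
  std::vector<std::vector<int>> adj(n, std::vector<int>(n, 0));
  std::vector<std::vector<int>> nbr(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && adjacency(i, j) != 0) adj[i][j] = 1;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && (adj[i][j] || adj[j][i])) nbr[i].push_back(j);
  std::vector<bool> tfv(n), linv(n);
  for (int i = 0; i < n; ++i) {
    tfv[i] = is_tf[i];
    linv[i] = is_lineage[i];
  }
  EnumState st;
  st.adj = &adj;
  st.nbr = &nbr;
  st.is_tf = &tfv;
  st.is_lineage = &linv;
  int mx = 0;
  for (int s : sizes) mx = std::max(mx, s);
  if (mx > 6) stop("subgraph sizes above 6 are not supported");
  st.max_size = mx;
  st.want_size.assign(mx + 1, false);
  for (int s : sizes) if (s >= 1 && s <= mx) st.want_size[s] = true;
  st.instances = return_instances;

  std::vector<int> in_nbrhood(n, 0);
  for (int v = 0; v < n; ++v) {
    std::vector<int> sub{v};
    std::vector<int> ext;
    for (int u : nbr[v]) if (u > v) { ext.push_back(u); in_nbrhood[u] = 1; }
    in_nbrhood[v] = 1;
    esu_extend(st, sub, ext, v, in_nbrhood);
    std::fill(in_nbrhood.begin(), in_nbrhood.end(), 0);
  }

  CharacterVector keys(st.counts.size());
  IntegerVector counts(st.counts.size());
  int i = 0;
  for (auto& kv : st.counts) { keys[i] = kv.first; counts[i] = kv.second; ++i; }
  List out = List::create(_["key"] = keys, _["count"] = counts);
  if (return_instances) {
    int m = (int)st.inst_key.size();
    CharacterVector ik(m);
    IntegerVector isz(m);
    int tot = 0;
    for (int q = 0; q < m; ++q) tot += (int)st.inst_nodes[q].size();
    IntegerVector nodes(tot);
    int w = 0;
    for (int q = 0; q < m; ++q) {
      ik[q] = st.inst_key[q];
      isz[q] = (int)st.inst_nodes[q].size();
      for (int u : st.inst_nodes[q]) nodes[w++] = u + 1; // 1-based for R
    }
    out["instance_key"] = ik;
    out["instance_size"] = isz;
    out["instance_nodes"] = nodes;
  }
  return out;
}

// [[Rcpp::export]]
std::string cpp_canonical_key(IntegerMatrix adjacency, LogicalVector is_tf) {
  const int n = adjacency.nrow();
  if (n > 6) stop("graphs above 6 nodes are not supported");
  std::vector<std::vector<int>> adj(n, std::vector<int>(n, 0));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && adjacency(i, j) != 0) adj[i][j] = 1;
  std::vector<bool> tfv(n);
  int ntf = 0;
  std::vector<int> nodes(n);
  for (int i = 0; i < n; ++i) {
    tfv[i] = is_tf[i];
    if (tfv[i]) ++ntf;
    nodes[i] = i;
  }
  uint64_t bits = canonical_bits(adj, nodes, tfv, nullptr);
  return key_string(n, ntf, bits);
}

static bool weakly_connected(const std::vector<std::vector<int>>& adj, int n) {
  std::vector<int> seen(n, 0), stack{0};
  seen[0] = 1;
  int cnt = 1;
  while (!stack.empty()) {
    int u = stack.back();
    stack.pop_back();
    for (int v = 0; v < n; ++v) {
      if (!seen[v] && (adj[u][v] || adj[v][u])) {
        seen[v] = 1;
        ++cnt;
        stack.push_back(v);
      }
    }
  }
  return cnt == n;
}

// Every weakly connected component of the graph contains at least one
// non-TF node (with the degree constraints below, this makes the graph a
// disjoint union of admissible connected subgraphs).
static bool components_have_nontf(const std::vector<std::vector<int>>& adj,
                                  const std::vector<bool>& tfv, int n) {
  std::vector<int> comp(n, -1);
  int ncomp = 0;
  for (int s = 0; s < n; ++s) {
    if (comp[s] >= 0) continue;
    std::vector<int> stack{s};
    comp[s] = ncomp;
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      for (int v = 0; v < n; ++v)
        if (comp[v] < 0 && (adj[u][v] || adj[v][u])) {
          comp[v] = ncomp;
          stack.push_back(v);
        }
    }
    ++ncomp;
  }
  std::vector<bool> has(ncomp, false);
  for (int i = 0; i < n; ++i)
    if (!tfv[i]) has[comp[i]] = true;
  for (int c = 0; c < ncomp; ++c)
    if (!has[c]) return false;
  return true;
}

// Brute-force enumeration of all admissible typed digraph classes of a given
// size: >= 1 non-TF node, non-TF out-degree 0, no self-loops, every TF node
// with out-degree >= 1, every non-TF node with in-degree >= 1; counted up to
// type-respecting isomorphism. With connected = true the graph must be
// weakly connected; with connected = false it must be a disjoint union of
// such pieces (every component carries a regulated non-TF node).
// [[Rcpp::export]]
CharacterVector cpp_possible_classes(int size, bool connected) {
  if (size < 2 || size > 5) stop("size must be between 2 and 5");
  std::set<std::string> classes;
  for (int ntf = 1; ntf < size; ++ntf) {
    // nodes 0..ntf-1 are TFs; edge slots from each TF to every other node
    std::vector<std::pair<int, int>> slots;
    for (int i = 0; i < ntf; ++i)
      for (int j = 0; j < size; ++j)
        if (i != j) slots.push_back({i, j});
    const int E = (int)slots.size();
    std::vector<bool> tfv(size, false);
    std::vector<int> nodes(size);
    for (int i = 0; i < size; ++i) nodes[i] = i;
    for (int i = 0; i < ntf; ++i) tfv[i] = true;
    for (uint64_t mask = 0; mask < (1ULL << E); ++mask) {
      std::vector<std::vector<int>> adj(size, std::vector<int>(size, 0));
      for (int e = 0; e < E; ++e)
        if (mask & (1ULL << e)) adj[slots[e].first][slots[e].second] = 1;
      bool ok = true;
      for (int i = 0; i < ntf && ok; ++i) {
        int outdeg = 0;
        for (int j = 0; j < size; ++j) outdeg += adj[i][j];
        if (outdeg == 0) ok = false;
      }
      for (int i = ntf; i < size && ok; ++i) {
        int indeg = 0;
        for (int j = 0; j < size; ++j) indeg += adj[j][i];
        if (indeg == 0) ok = false;
      }
      if (!ok) continue;
      if (connected) {
        if (!weakly_connected(adj, size)) continue;
      } else {
        if (!components_have_nontf(adj, tfv, size)) continue;
      }
      uint64_t bits = canonical_bits(adj, nodes, tfv, nullptr);
      classes.insert(key_string(size, ntf, bits));
    }
  }
  return CharacterVector(classes.begin(), classes.end());
}
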