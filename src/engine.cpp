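// Population engine for the bicellular life-history simulator.
//
// One individual = two cells (type 1, type 2) sharing a clonal genotype:
// per-type allocation genes (x, y), resource-signal genes (g, signal =
// exp(g)), damage-retention genes (q, retention = logistic(q)) and 16
// bi-allelic viability loci stored as bit masks (one mask per cell so the
// extra-mutation variant can give the type-2 lineage a higher load).
//
// Per cycle, in fixed order for every individual (storage order, cell 1
// first): softmax allocation of the current pool; foraging with joint
// redistribution by signalled shares; exponential damage increment;
// exponential repair; reproduction (offspring buffered, join before the
// cull); mortality round 1 (damage), round 2 (expressed viability locus),
// individual resolution with regeneration probability r; cull to N;
// age increment. All randomness comes from R's RNG, so set.seed() on the
// R side makes runs exactly reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Cfg {
  int N, n_loci, max_age;
  double f_max, h, lambda, a, b, c, D, m2, r;
  double mu, sigma, mu_v0, mu_v1, mu_d, kappa, offspring_endowment;
  bool extra2, share_on, retention_on;
  std::vector<double> bounds; // interior window boundaries, length n_loci - 1
};

struct Ind {
  double x[2], y[2], g[2], q[2]; // genotype: per-type continuous genes
  double d[2], res[2];           // cell state: damage, resource pool
  unsigned v[2];                 // viability bit mask per cell
  int age;
};

inline double logistic(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// intrinsic (damage-dependent) mortality, clamped to [0, 1]
inline double m1_of(double d, const Cfg& C) {
  double u = d / C.D;
  double m = (1.0 - C.c) * u + C.c * u * u * u * u;
  if (m > 1.0) m = 1.0;
  if (m < 0.0) m = 0.0;
  return m;
}

// 0-based index of the damage window containing d (overflow -> last locus)
inline int locus_of(double d, const Cfg& C) {
  return (int)(std::upper_bound(C.bounds.begin(), C.bounds.end(), d) -
               C.bounds.begin());
}

// one round of biased bit-flip mutation over the 16 viability loci
inline unsigned mutate_viab(unsigned v, const Cfg& C) {
  for (int k = 0; k < C.n_loci; ++k) {
    unsigned bit = 1u << k;
    if (v & bit) {
      if (C.mu_v1 > 0.0 && unif_rand() < C.mu_v1) v &= ~bit;
    } else {
      if (C.mu_v0 > 0.0 && unif_rand() < C.mu_v0) v |= bit;
    }
  }
  return v;
}

// Gaussian perturbation of the continuous genes on their unconstrained
// scales (x, y, g additively; q = logit retention), fixed gene order
inline void mutate_cont(Ind& o, const Cfg& C) {
  double* genes[6] = { &o.x[0], &o.y[0], &o.x[1], &o.y[1], &o.g[0], &o.g[1] };
  if (C.mu > 0.0)
    for (int i = 0; i < 6; ++i)
      if (unif_rand() < C.mu) *genes[i] += C.sigma * norm_rand();
  if (C.retention_on && C.mu_d > 0.0)
    for (int t = 0; t < 2; ++t)
      if (unif_rand() < C.mu_d) o.q[t] += C.sigma * norm_rand();
}

} // namespace

// state columns: age, damage_1, damage_2, resources_1, resources_2,
//                x_1, y_1, x_2, y_2, g_1, g_2, q_1, q_2
// [[Rcpp::export]]
List run_engine(List par, NumericMatrix state, IntegerMatrix viab1,
                IntegerMatrix viab2, int cycles) {
  Cfg C;
  C.N = as<int>(par["N"]);
  C.n_loci = as<int>(par["n_loci"]);
  C.max_age = as<int>(par["max_age_class"]);
  C.f_max = as<double>(par["f_max"]);
  C.h = as<double>(par["h"]);
  C.lambda = as<double>(par["lambda"]);
  C.a = as<double>(par["a"]);
  C.b = as<double>(par["b"]);
  C.c = as<double>(par["c"]);
  C.D = as<double>(par["D"]);
  C.m2 = as<double>(par["m2"]);
  C.r = as<double>(par["r"]);
  C.mu = as<double>(par["mu"]);
  C.sigma = as<double>(par["sigma"]);
  C.mu_v0 = as<double>(par["mu_v0"]);
  C.mu_v1 = as<double>(par["mu_v1"]);
  C.mu_d = as<double>(par["mu_d"]);
  C.kappa = as<double>(par["kappa"]);
  C.offspring_endowment = as<double>(par["offspring_endowment"]);
  C.extra2 = as<bool>(par["extra_mutation_type2"]);
  C.share_on = as<bool>(par["evolvable_sharing"]);
  C.retention_on = as<bool>(par["evolvable_retention"]);
  C.bounds = as<std::vector<double> >(par["damage_bins"]);
  if ((int)C.bounds.size() != C.n_loci - 1)
    stop("damage_bins must hold n_loci - 1 interior boundaries");
  if (C.n_loci < 1 || C.n_loci > 30) stop("n_loci must be in 1..30");

  const int n_init = state.nrow();
  std::vector<Ind> pop;
  pop.reserve(std::max(3 * C.N + 16, 3 * n_init + 16));
  for (int i = 0; i < n_init; ++i) {
    Ind I;
    I.age = (int)state(i, 0);
    I.d[0] = state(i, 1); I.d[1] = state(i, 2);
    I.res[0] = state(i, 3); I.res[1] = state(i, 4);
    I.x[0] = state(i, 5); I.y[0] = state(i, 6);
    I.x[1] = state(i, 7); I.y[1] = state(i, 8);
    I.g[0] = state(i, 9); I.g[1] = state(i, 10);
    I.q[0] = state(i, 11); I.q[1] = state(i, 12);
    I.v[0] = I.v[1] = 0u;
    for (int k = 0; k < C.n_loci; ++k) {
      if (viab1(i, k)) I.v[0] |= (1u << k);
      if (viab2(i, k)) I.v[1] |= (1u << k);
    }
    pop.push_back(I);
  }

  const int A = C.max_age;
  const int nstat = 17 + C.n_loci;
  NumericMatrix stats(cycles, nstat);
  IntegerMatrix deaths(cycles, A + 1), expos(cycles, A + 1);
  bool extinct = pop.empty() && cycles > 0;
  int done = 0;

  std::vector<Ind> offspring, nxt;
  std::vector<char> keep;
  std::vector<double> vc(C.n_loci);

  for (int cyc = 0; cyc < cycles; ++cyc) {
    const int n0 = (int)pop.size();
    if (n0 == 0) { extinct = true; break; }

    double spx[2] = {0, 0}, spy[2] = {0, 0}, spz[2] = {0, 0};
    double sd[2] = {0, 0}, sres[2] = {0, 0}, sret[2] = {0, 0}, ssh = 0.0;
    std::fill(vc.begin(), vc.end(), 0.0);
    int births = 0, ndeaths = 0;
    offspring.clear();
    keep.assign(n0, 1);

    for (int i = 0; i < n0; ++i) {
      Ind& I = pop[i];
      double fr[2], ya[2], za[2];

      // (1)-(2) allocation of the start-of-cycle pool, foraging returns
      for (int t = 0; t < 2; ++t) {
        sd[t] += I.d[t]; sres[t] += I.res[t]; sret[t] += logistic(I.q[t]);
        double ex = std::exp(I.x[t]), ey = std::exp(I.y[t]);
        double den = 1.0 + ex + ey;
        double px = ex / den, py = ey / den, pz = 1.0 / den;
        spx[t] += px; spy[t] += py; spz[t] += pz;
        double pool = I.res[t];
        double xa = px * pool;
        ya[t] = py * pool;
        za[t] = pz * pool;
        fr[t] = (xa > 0.0) ? C.f_max * xa / (xa + C.h) : 0.0;
      }
      for (int k = 0; k < C.n_loci; ++k) vc[k] += (I.v[0] >> k) & 1u;

      // joint redistribution of foraged resources -> next cycle's pools
      double tot = fr[0] + fr[1];
      double sh = 0.5;
      if (C.share_on) {
        double e0 = std::exp(I.g[0]), e1 = std::exp(I.g[1]);
        sh = e0 / (e0 + e1);
      }
      ssh += sh;
      I.res[0] = tot * sh;
      I.res[1] = tot * (1.0 - sh);

      // (3)-(4) damage increment then repair
      for (int t = 0; t < 2; ++t) {
        I.d[t] += exp_rand() / C.lambda;
        if (ya[t] > 0.0) I.d[t] *= std::exp(-C.a * ya[t]);
      }

      // (5) reproduction; mother keeps retention * damage, the propagule
      // gets the rest. New cells receive the standard endowment, or
      // kappa * z split between them in the proportional-inheritance
      // variant (offspring_endowment = 0)
      for (int t = 0; t < 2; ++t) {
        if (za[t] <= 0.0) continue;
        double p = 1.0 - std::exp(-C.b * za[t]);
        if (p > 0.0 && unif_rand() < p) {
          double ret = logistic(I.q[t]);
          double pd = (1.0 - ret) * I.d[t];
          I.d[t] *= ret;
          double pres = C.kappa * za[t];
          Ind ch = I;
          unsigned vin = I.v[t];
          mutate_cont(ch, C);
          ch.v[0] = mutate_viab(vin, C);
          ch.v[1] = C.extra2 ? mutate_viab(ch.v[0], C) : ch.v[0];
          ch.d[0] = ch.d[1] = 0.5 * pd;
          if (C.offspring_endowment > 0.0)
            ch.res[0] = ch.res[1] = C.offspring_endowment;
          else
            ch.res[0] = ch.res[1] = 0.5 * pres;
          ch.age = -1; // incremented to 0 at end of this cycle
          offspring.push_back(ch);
          ++births;
        }
      }

      // (6)-(7) mortality rounds: damage curve, then expressed locus
      bool al[2];
      for (int t = 0; t < 2; ++t) {
        al[t] = true;
        double m1 = m1_of(I.d[t], C);
        if (m1 > 0.0 && unif_rand() < m1) { al[t] = false; continue; }
        int k = locus_of(I.d[t], C);
        if (((I.v[t] >> k) & 1u) && C.m2 > 0.0 && unif_rand() < C.m2)
          al[t] = false;
      }

      // (8) individual resolution; regeneration with probability r
      int ac = I.age < A ? I.age : A;
      expos(cyc, ac)++;
      if (al[0] && al[1]) {
        // intact
      } else if (!al[0] && !al[1]) {
        keep[i] = 0; deaths(cyc, ac)++; ++ndeaths;
      } else {
        bool reg = C.r >= 1.0 ? true
                 : (C.r <= 0.0 ? false : unif_rand() < C.r);
        if (reg) {
          int s = al[0] ? 0 : 1;
          double dd = 0.5 * I.d[s], rr = 0.5 * I.res[s];
          I.d[0] = I.d[1] = dd;
          I.res[0] = I.res[1] = rr;
          I.v[0] = I.v[1] = I.v[s];
        } else {
          keep[i] = 0; deaths(cyc, ac)++; ++ndeaths;
        }
      }
    }

    double inv = 1.0 / n0;
    stats(cyc, 0) = cyc + 1;
    stats(cyc, 1) = spx[0] * inv; stats(cyc, 2) = spy[0] * inv;
    stats(cyc, 3) = spz[0] * inv;
    stats(cyc, 4) = spx[1] * inv; stats(cyc, 5) = spy[1] * inv;
    stats(cyc, 6) = spz[1] * inv;
    stats(cyc, 7) = ssh * inv;
    stats(cyc, 8) = sd[0] * inv; stats(cyc, 9) = sd[1] * inv;
    stats(cyc, 10) = sres[0] * inv; stats(cyc, 11) = sres[1] * inv;
    stats(cyc, 12) = sret[0] * inv; stats(cyc, 13) = sret[1] * inv;
    stats(cyc, 14) = n0; stats(cyc, 15) = births; stats(cyc, 16) = ndeaths;
    for (int k = 0; k < C.n_loci; ++k) stats(cyc, 17 + k) = vc[k] * inv;

    // (9) offspring join, (10) uniform cull back to N, (11) ages increment
    nxt.clear();
    nxt.reserve(n0 + offspring.size());
    for (int i = 0; i < n0; ++i) if (keep[i]) nxt.push_back(pop[i]);
    for (size_t i = 0; i < offspring.size(); ++i) nxt.push_back(offspring[i]);
    pop.swap(nxt);

    int M = (int)pop.size();
    if (M > C.N) {
      std::vector<int> idx(M);
      for (int i = 0; i < M; ++i) idx[i] = i;
      for (int i = 0; i < C.N; ++i) {
        int j = i + (int)R_unif_index((double)(M - i));
        std::swap(idx[i], idx[j]);
      }
      std::vector<Ind> culled;
      culled.reserve(C.N);
      for (int i = 0; i < C.N; ++i) culled.push_back(pop[idx[i]]);
      pop.swap(culled);
    }
    for (size_t i = 0; i < pop.size(); ++i) pop[i].age += 1;
    done = cyc + 1;
    if (pop.empty()) { extinct = true; break; }
  }

  const int M = (int)pop.size();
  NumericMatrix fs(M, 13);
  IntegerMatrix fv1(M, C.n_loci), fv2(M, C.n_loci);
  for (int i = 0; i < M; ++i) {
    const Ind& I = pop[i];
    fs(i, 0) = I.age;
    fs(i, 1) = I.d[0]; fs(i, 2) = I.d[1];
    fs(i, 3) = I.res[0]; fs(i, 4) = I.res[1];
    fs(i, 5) = I.x[0]; fs(i, 6) = I.y[0];
    fs(i, 7) = I.x[1]; fs(i, 8) = I.y[1];
    fs(i, 9) = I.g[0]; fs(i, 10) = I.g[1];
    fs(i, 11) = I.q[0]; fs(i, 12) = I.q[1];
    for (int k = 0; k < C.n_loci; ++k) {
      fv1(i, k) = (I.v[0] >> k) & 1u;
      fv2(i, k) = (I.v[1] >> k) & 1u;
    }
  }

  return List::create(
    _["stats"] = stats, _["deaths"] = deaths, _["exposures"] = expos,
    _["final_state"] = fs, _["final_v1"] = fv1, _["final_v2"] = fv2,
    _["extinct"] = extinct, _["cycles_run"] = done);
}
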