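#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <cmath>
#include <algorithm>
#include <functional>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// helpers
// ---------------------------------------------------------------------------

// canonical first-appearance relabeling of lab[idx]; result in out (1-based)
static void canon_relabel(const std::vector<int>& lab, const std::vector<int>& idx,
                          std::vector<int>& out) {
  std::unordered_map<int, int> remap;
  out.resize(idx.size());
  int next = 0;
  for (size_t i = 0; i < idx.size(); ++i) {
    int v = lab[idx[i]];
    auto it = remap.find(v);
    if (it == remap.end()) { remap[v] = ++next; out[i] = next; }
    else out[i] = it->second;
  }
}

static std::string key_of(const std::vector<int>& canon) {
  std::string k;
  k.reserve(canon.size() * 2);
  for (int v : canon) { k.push_back((char)(v & 0xff)); k.push_back((char)((v >> 8) & 0xff)); }
  return k;
}

// P(observed unordered genotype g | latent ordered pair with x alt copies)
static void penetrance_table(double eps, double pen[3][3]) {
  double c = 1.0 - eps, e = eps;
  pen[0][0] = c * c; pen[0][1] = 2 * c * e; pen[0][2] = e * e;
  pen[1][0] = c * e; pen[1][1] = c * c + e * e; pen[1][2] = c * e;
  pen[2][0] = e * e; pen[2][1] = 2 * c * e; pen[2][2] = c * c;
}

// ---------------------------------------------------------------------------
// Lander-Green state tables for one pedigree component
// ---------------------------------------------------------------------------

// father/mother: 0-based member indices (-1 for founders), members in
// topological order. obs: 0-based member indices of genotyped individuals.
// Meiosis bit order: for the j-th non-founder, bit 2j = paternal meiosis,
// bit 2j+1 = maternal (matching the pedigree's meiosis list).
// [[Rcpp::export]]
List lg_state_tables(IntegerVector father, IntegerVector mother, IntegerVector obs) {
  int n = father.size();
  int m = 0;
  for (int i = 0; i < n; ++i) if (father[i] >= 0) m += 2;
  if (m > 28) stop("meiosis count %d too large for exact state tables", m);
  int S = 1 << m, n_slots = 2 * n;
  if ((double)S * n_slots > 6e8) stop("state table too large");

  IntegerMatrix fgl(S, n_slots);
  IntegerVector full_group(S), obs_group(S);
  std::unordered_map<std::string, int> full_map, obs_map;
  std::vector<std::vector<int>> obs_canons;

  std::vector<int> lab(n_slots), canon;
  std::vector<int> all_idx(n_slots), obs_idx;
  for (int t = 0; t < n_slots; ++t) all_idx[t] = t;
  for (int oi = 0; oi < obs.size(); ++oi) {
    obs_idx.push_back(2 * obs[oi]);
    obs_idx.push_back(2 * obs[oi] + 1);
  }

  for (int s = 0; s < S; ++s) {
    int fglc = 0, j = 0;
    for (int i = 0; i < n; ++i) {
      if (father[i] < 0) { lab[2 * i] = ++fglc; lab[2 * i + 1] = ++fglc; }
      else {
        int bp = (s >> (2 * j)) & 1, bm = (s >> (2 * j + 1)) & 1;
        lab[2 * i] = lab[2 * father[i] + bp];
        lab[2 * i + 1] = lab[2 * mother[i] + bm];
        ++j;
      }
    }
    for (int t = 0; t < n_slots; ++t) fgl(s, t) = lab[t];
    canon_relabel(lab, all_idx, canon);
    std::string fk = key_of(canon);
    auto itf = full_map.find(fk);
    if (itf == full_map.end()) { int id = full_map.size() + 1; full_map[fk] = id; full_group[s] = id; }
    else full_group[s] = itf->second;
    if (!obs_idx.empty()) {
      canon_relabel(lab, obs_idx, canon);
      std::string ok = key_of(canon);
      auto ito = obs_map.find(ok);
      if (ito == obs_map.end()) {
        int id = obs_map.size() + 1; obs_map[ok] = id; obs_group[s] = id;
        obs_canons.push_back(canon);
      } else obs_group[s] = ito->second;
    } else obs_group[s] = 1;
  }
  IntegerMatrix obs_labels(std::max((size_t)1, obs_canons.size()),
                           std::max(1, (int)obs_idx.size()));
  for (size_t g = 0; g < obs_canons.size(); ++g)
    for (size_t t = 0; t < obs_canons[g].size(); ++t)
      obs_labels(g, t) = obs_canons[g][t];
  return List::create(_["fgl"] = fgl, _["full_group"] = full_group,
                      _["obs_group"] = obs_group, _["obs_labels"] = obs_labels,
                      _["n_meioses"] = m);
}

// ---------------------------------------------------------------------------
// per-marker emission probabilities per observed-partition group
// ---------------------------------------------------------------------------

// obs_labels: n_groups x (2*n_obs) canonical class labels (paternal, maternal
// per observed individual); geno: M x n_obs (0/1/2, -1 missing); freq: M.
// [[Rcpp::export]]
NumericMatrix lg_emissions(IntegerMatrix obs_labels, IntegerMatrix geno,
                           NumericVector freq, double eps) {
  int G = obs_labels.nrow(), M = geno.nrow(), n_obs = geno.ncol();
  double pen[3][3];
  penetrance_table(eps, pen);
  NumericMatrix out(G, M);
  std::vector<int> pat(n_obs), mat(n_obs);
  for (int g = 0; g < G; ++g) {
    int c = 0;
    for (int i = 0; i < n_obs; ++i) {
      pat[i] = obs_labels(g, 2 * i) - 1;
      mat[i] = obs_labels(g, 2 * i + 1) - 1;
      c = std::max(c, std::max(pat[i], mat[i]) + 1);
    }
    if (c > 26) stop("too many IBD classes among observed slots");
    int A = 1 << c;
    for (int j = 0; j < M; ++j) {
      double p = freq[j], tot = 0.0;
      for (int a = 0; a < A; ++a) {
        double w = 1.0;
        for (int b = 0; b < c; ++b) w *= ((a >> b) & 1) ? p : (1.0 - p);
        for (int i = 0; i < n_obs && w > 0; ++i) {
          int gobs = geno(j, i);
          if (gobs < 0) continue;
          int x = ((a >> pat[i]) & 1) + ((a >> mat[i]) & 1);
          w *= pen[x][gobs];
        }
        tot += w;
      }
      out(g, j) = tot;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// exact forward pass, backward sampling and marginals over IV states
// ---------------------------------------------------------------------------

// in-place butterfly: one Markov step where each of m bits flips w.p. th
static void bit_mix(std::vector<double>& f, int m, double th) {
  int S = 1 << m;
  for (int b = 0; b < m; ++b) {
    int bit = 1 << b;
    for (int s = 0; s < S; ++s) {
      if (s & bit) continue;
      double f0 = f[s], f1 = f[s | bit];
      f[s] = (1 - th) * f0 + th * f1;
      f[s | bit] = th * f0 + (1 - th) * f1;
    }
  }
}

// emis: n_groups x M; obs_group: S (1-based); theta: M-1. Returns sampled
// state paths (K x M, 0-based states), the total log-likelihood (natural
// log, including the uniform 2^-m IV prior), and per-marker posterior state
// marginals if want_marginals.
// [[Rcpp::export]]
List lg_forward_sample(NumericMatrix emis, IntegerVector obs_group,
                       NumericVector theta, int m, int K,
                       bool want_marginals = false) {
  int S = 1 << m, M = emis.ncol();
  if ((double)S * M > 2.5e8) stop("forward matrix too large; reduce the meiosis cap");
  std::vector<double> fwd((size_t)S * M);
  std::vector<double> f(S);
  double loglik = -m * std::log(2.0);
  for (int j = 0; j < M; ++j) {
    if (j == 0) for (int s = 0; s < S; ++s) f[s] = emis(obs_group[s] - 1, 0);
    else {
      bit_mix(f, m, theta[j - 1]);
      for (int s = 0; s < S; ++s) f[s] *= emis(obs_group[s] - 1, j);
    }
    double norm = 0.0;
    for (int s = 0; s < S; ++s) norm += f[s];
    if (norm <= 0) stop("zero likelihood at marker %d (inconsistent genotypes?)", j + 1);
    for (int s = 0; s < S; ++s) { f[s] /= norm; fwd[(size_t)j * S + s] = f[s]; }
    loglik += std::log(norm);
  }
  // loglik = -m log 2 + sum_j log(norm_j): the uniform 2^-m IV prior enters
  // once, the first normalisation having summed plain emissions over states.

  IntegerMatrix paths(K, M);
  {
    for (int k = 0; k < K; ++k) {
      // sample last marker
      const double* fM = &fwd[(size_t)(M - 1) * S];
      double u = R::runif(0, 1), acc = 0;
      int s = S - 1;
      for (int t = 0; t < S; ++t) { acc += fM[t]; if (u <= acc) { s = t; break; } }
      paths(k, M - 1) = s;
      for (int j = M - 2; j >= 0; --j) {
        double th = theta[j];
        const double* fj = &fwd[(size_t)j * S];
        // transition weight depends only on hamming distance to s
        double lth = std::log(th > 0 ? th : 1), l1 = std::log(1 - th);
        double tot = 0;
        // two-pass categorical sampling
        if (th <= 0) { paths(k, j) = s; continue; }
        std::vector<double> w(S);
        for (int t = 0; t < S; ++t) {
          int h = __builtin_popcount((unsigned)(t ^ s));
          w[t] = fj[t] * std::exp(h * lth + (m - h) * l1);
          tot += w[t];
        }
        double u2 = R::runif(0, 1) * tot, acc2 = 0;
        int pick = S - 1;
        for (int t = 0; t < S; ++t) { acc2 += w[t]; if (u2 <= acc2) { pick = t; break; } }
        paths(k, j) = pick;
        s = pick;
      }
    }
  }

  List out = List::create(_["paths"] = paths, _["loglik"] = loglik);
  if (want_marginals) {
    // backward pass for exact per-marker posteriors
    NumericMatrix marg(S, M);
    std::vector<double> b(S, 1.0);
    for (int j = M - 1; j >= 0; --j) {
      const double* fj = &fwd[(size_t)j * S];
      double tot = 0;
      for (int s = 0; s < S; ++s) { marg(s, j) = fj[s] * b[s]; tot += marg(s, j); }
      for (int s = 0; s < S; ++s) marg(s, j) /= tot;
      if (j > 0) {
        for (int s = 0; s < S; ++s) b[s] *= emis(obs_group[s] - 1, j);
        bit_mix(b, m, theta[j - 1]);
        double bn = 0;
        for (int s = 0; s < S; ++s) bn += b[s];
        for (int s = 0; s < S; ++s) b[s] /= bn;
      }
    }
    out["marginals"] = marg;
  }
  return out;
}

// ---------------------------------------------------------------------------
// haplotype-stitching sampler (sequential copying model, soft phase)
// ---------------------------------------------------------------------------

// geno: M x n_ind (0/1/2/-1). Returns list of K label matrices
// (M x 2*n_ind): per marker, canonical IBD classes from the copy edges.
//
// Each haplotype slot's latent allele is tracked as a posterior
// probability q = P(allele = 1 | genotype, sampled copying path): phase is
// integrated ("soft") rather than coin-flipped, because with markers in
// linkage equilibrium the only phase information comes from IBD partners -
// a hard-sampled phase mosaic would make shared haplotypes uncopyable.
// Sweep 1 introduces slots sequentially; later sweeps re-sample every
// slot's copying path given all other slots. Copy switches occur at rate
// rho per cM; a switch founds novel material with probability nu.
// [[Rcpp::export]]
List stitch_core(IntegerMatrix geno, NumericVector freq, NumericVector cm,
                 double rho, double nu, double eps, int K, bool phased_input,
                 IntegerMatrix hap0, IntegerMatrix hap1, int sweeps = 1) {
  int M = geno.nrow(), n_ind = geno.ncol(), n_slots = 2 * n_ind;
  List out(K);
  std::vector<std::vector<double>> q(n_slots, std::vector<double>(M));
  std::vector<std::vector<int>> tmpl(n_slots, std::vector<int>(M, -1)); // -1 novel
  std::vector<double> stay(M > 1 ? M - 1 : 0);
  for (int j = 0; j + 1 < M; ++j) stay[j] = std::exp(-rho * (cm[j + 1] - cm[j]));

  std::vector<double> fmat, f, w;
  std::vector<int> path(M);

  // genotype-only allele posterior (partner integrated at frequency)
  auto q_init = [&](int t) {
    int ind = t / 2;
    for (int j = 0; j < M; ++j) {
      if (phased_input) {
        int a = (t % 2 ? hap1 : hap0)(j, ind);
        q[t][j] = a < 0 ? freq[j] : (double)a;
      } else {
        int g = geno(j, ind);
        q[t][j] = g < 0 ? freq[j] : (g == 0 ? 0.0 : (g == 2 ? 1.0 : 0.5));
      }
    }
  };

  // sample the copying path of slot t against template slots < limit
  // (sweep 1) or all slots except t (refinement), then update q[t]
  auto sample_path = [&](int t, int limit) {
    int ind = t / 2, partner = (t % 2 == 0) ? t + 1 : t - 1;
    bool partner_resolved = partner < (limit >= 0 ? limit : n_slots);
    std::vector<int> temps;
    for (int u = 0; u < (limit >= 0 ? limit : n_slots); ++u)
      if (u != t) temps.push_back(u);
    int nt = temps.size(), ns = nt + 1;      // copy templates + novel
    double jump_copy = nt > 0 ? (1.0 - nu) / nt : 0.0;
    // per-marker channel probability that the copied/novel allele is 1
    auto chan = [&](int si, int j) -> double {
      if (si == nt) return freq[j];
      double qu = q[temps[si]][j];
      return qu * (1 - eps) + (1 - qu) * eps;
    };
    auto emit = [&](int si, int j) -> double {
      if (phased_input) {
        int a = (t % 2 ? hap1 : hap0)(j, ind);
        if (a < 0) return 1.0;
        double pb1 = chan(si, j);
        return a == 1 ? pb1 : 1 - pb1;
      }
      int g = geno(j, ind);
      if (g < 0) return 1.0;
      double p = freq[j];
      if (si < nt && temps[si] == partner) {
        // copying one's own partner makes the genotype autozygous: both
        // observed alleles descend from one latent founder allele, so the
        // channel cannot be treated as independent of the partner
        double e = eps;
        if (g == 1) return 2 * e * (1 - e);
        double pa = g == 2 ? p : 1 - p;
        return pa * (1 - e) * (1 - e) + (1 - pa) * e * e;
      }
      double pb1 = chan(si, j);
      // partner allele: resolved partner's q if available, else frequency
      double qp = partner_resolved ? q[partner][j] : p;
      if (g == 0) return (1 - pb1) * (1 - qp);
      if (g == 2) return pb1 * qp;
      return pb1 * (1 - qp) + (1 - pb1) * qp;
    };
    fmat.assign((size_t)ns * M, 0.0);
    f.assign(ns, 0.0);
    for (int j = 0; j < M; ++j) {
      if (j == 0) {
        for (int si = 0; si < ns; ++si)
          f[si] = (si == nt ? nu : jump_copy) * emit(si, 0);
      } else {
        double F = 0;
        for (int si = 0; si < ns; ++si) F += f[si];
        double st = stay[j - 1];
        for (int si = 0; si < ns; ++si)
          f[si] = (st * f[si] + (1 - st) * (si == nt ? nu : jump_copy) * F) * emit(si, j);
      }
      double norm = 0;
      for (int si = 0; si < ns; ++si) norm += f[si];
      if (norm <= 0) stop("stitch: zero likelihood at marker %d", j + 1);
      for (int si = 0; si < ns; ++si) { f[si] /= norm; fmat[(size_t)j * ns + si] = f[si]; }
    }
    // backward sampling
    {
      const double* fM = &fmat[(size_t)(M - 1) * ns];
      double u2 = unif_rand(), acc = 0;
      int si = ns - 1;
      for (int q2 = 0; q2 < ns; ++q2) { acc += fM[q2]; if (u2 <= acc) { si = q2; break; } }
      path[M - 1] = si;
      for (int j = M - 2; j >= 0; --j) {
        const double* fj = &fmat[(size_t)j * ns];
        double st = stay[j];
        int snext = path[j + 1];
        double jn = (snext == nt ? nu : jump_copy);
        w.assign(ns, 0.0);
        double tot = 0;
        for (int q2 = 0; q2 < ns; ++q2) {
          w[q2] = fj[q2] * (1 - st) * jn;
          if (q2 == snext) w[q2] += fj[q2] * st;
          tot += w[q2];
        }
        double u3 = unif_rand() * tot, acc2 = 0;
        int pick = ns - 1;
        for (int q2 = 0; q2 < ns; ++q2) { acc2 += w[q2]; if (u3 <= acc2) { pick = q2; break; } }
        path[j] = pick;
      }
    }
    // update this slot's allele posterior given its sampled path, and the
    // partner's residual posterior when the genotype ties them together
    for (int j = 0; j < M; ++j) {
      int si = path[j];
      tmpl[t][j] = si == nt ? -1 : temps[si];
      if (phased_input) continue;
      int g = geno(j, ind);
      if (g == 0) { q[t][j] = 0; continue; }
      if (g == 2) { q[t][j] = 1; continue; }
      if (si < nt && temps[si] == partner) { if (g > 0) q[t][j] = 0.5; continue; }
      double pb1 = chan(si, j);
      if (g < 0) { q[t][j] = pb1; continue; }
      double qp = partner_resolved ? q[partner][j] : freq[j];
      double w1 = pb1 * (1 - qp), w0 = (1 - pb1) * qp;
      q[t][j] = w1 / (w1 + w0);
      if (partner_resolved) q[partner][j] = 1 - q[t][j];
    }
  };

  for (int k = 0; k < K; ++k) {
    for (auto& v : tmpl) std::fill(v.begin(), v.end(), -1);
    for (int t = 0; t < n_slots; ++t) q_init(t);
    // sweep 1: sequential introduction (slot 0 founds its own material)
    for (int t = 1; t < n_slots; ++t) sample_path(t, t);
    // refinement sweeps over all slots with full template sets
    for (int sw = 1; sw < sweeps; ++sw)
      for (int t = 0; t < n_slots; ++t) sample_path(t, -1);
    // per-marker partitions from the copy edges (union-find)
    IntegerMatrix lab(M, n_slots);
    std::vector<int> parent(n_slots), remap(n_slots + 1);
    for (int j = 0; j < M; ++j) {
      for (int t = 0; t < n_slots; ++t) parent[t] = t;
      std::function<int(int)> find = [&](int x) {
        while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
        return x;
      };
      for (int t = 0; t < n_slots; ++t) {
        int u = tmpl[t][j];
        if (u >= 0) {
          int a = find(t), b = find(u);
          if (a != b) parent[a] = b;
        }
      }
      std::fill(remap.begin(), remap.end(), 0);
      int next = 0;
      for (int t = 0; t < n_slots; ++t) {
        int r = find(t);
        if (remap[r] == 0) remap[r] = ++next;
        lab(j, t) = remap[r];
      }
    }
    out[k] = lab;
  }
  return out;
}

// ---------------------------------------------------------------------------
// partition join (finest common coarsening) for graph merging
// ---------------------------------------------------------------------------

// rows of `parts` are label vectors over the same slots; slots sharing a
// label in ANY row end up in one class. 0 entries mean "unconstrained"
// (slot is its own singleton in that row). Returns canonical labels.
// [[Rcpp::export]]
IntegerVector join_partitions(IntegerMatrix parts) {
  int R = parts.nrow(), S = parts.ncol();
  std::vector<int> parent(S);
  for (int s = 0; s < S; ++s) parent[s] = s;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int r = 0; r < R; ++r) {
    std::unordered_map<int, int> first;
    for (int s = 0; s < S; ++s) {
      int v = parts(r, s);
      if (v == 0 || v == NA_INTEGER) continue;
      auto it = first.find(v);
      if (it == first.end()) first[v] = s;
      else {
        int a = find(it->second), b = find(s);
        if (a != b) parent[a] = b;
      }
    }
  }
  IntegerVector out(S);
  std::unordered_map<int, int> remap;
  int next = 0;
  for (int s = 0; s < S; ++s) {
    int r = find(s);
    auto it = remap.find(r);
    if (it == remap.end()) { remap[r] = ++next; out[s] = next; }
    else out[s] = it->second;
  }
  return out;
}

// ---------------------------------------------------------------------------
// QTL trait likelihood on IBD graphs: exact variable elimination over the
// class graph, with message caching per connectivity group
// ---------------------------------------------------------------------------

struct Factor {
  std::vector<int> vars;        // ascending binary-variable ids
  std::vector<double> tab;      // 2^vars.size() values, vars[0] fastest bit
};

// multiply all factors containing v, sum v out, push the result
static void eliminate_one(std::vector<Factor>& facs, int v, double& logscale,
                          int width_cap) {
  std::vector<int> uni;
  std::vector<Factor> keep, use;
  for (auto& f : facs) {
    if (std::find(f.vars.begin(), f.vars.end(), v) != f.vars.end()) use.push_back(f);
    else keep.push_back(f);
  }
  if (use.empty()) { return; }
  for (auto& f : use)
    for (int x : f.vars) if (std::find(uni.begin(), uni.end(), x) == uni.end()) uni.push_back(x);
  std::sort(uni.begin(), uni.end());
  int w = uni.size();
  if (w > width_cap) stop("elimination width %d exceeds cap", w);
  std::vector<double> tab((size_t)1 << w, 1.0);
  for (auto& f : use) {
    int fw = f.vars.size();
    std::vector<int> pos(fw);
    for (int i = 0; i < fw; ++i)
      pos[i] = std::lower_bound(uni.begin(), uni.end(), f.vars[i]) - uni.begin();
    for (size_t a = 0; a < tab.size(); ++a) {
      size_t ia = 0;
      for (int i = 0; i < fw; ++i) if ((a >> pos[i]) & 1) ia |= ((size_t)1 << i);
      tab[a] *= f.tab[ia];
    }
  }
  int vp = std::lower_bound(uni.begin(), uni.end(), v) - uni.begin();
  Factor res;
  for (int x : uni) if (x != v) res.vars.push_back(x);
  res.tab.assign((size_t)1 << res.vars.size(), 0.0);
  for (size_t a = 0; a < tab.size(); ++a) {
    size_t b = 0;
    int bi = 0;
    for (int i = 0; i < w; ++i) {
      if (i == vp) continue;
      if ((a >> i) & 1) b |= ((size_t)1 << bi);
      ++bi;
    }
    res.tab[b] += tab[a];
  }
  double mx = 0;
  for (double t : res.tab) mx = std::max(mx, t);
  if (mx > 0 && (mx < 1e-200 || mx > 1e200)) {
    for (auto& t : res.tab) t /= mx;
    logscale += std::log(mx);
  }
  keep.push_back(res);
  facs.swap(keep);
}

// eliminate the listed variables (min-width greedy); then multiply what is
// left into one factor over the union of surviving variables
static Factor eliminate_vars(std::vector<Factor> facs, std::vector<int> elim,
                             double& logscale, int width_cap = 25) {
  while (!elim.empty()) {
    int best = -1, bestw = 1 << 30, besti = -1;
    for (size_t e = 0; e < elim.size(); ++e) {
      int v = elim[e];
      std::vector<int> uni;
      bool present = false;
      for (auto& f : facs)
        if (std::find(f.vars.begin(), f.vars.end(), v) != f.vars.end()) {
          present = true;
          for (int x : f.vars) if (std::find(uni.begin(), uni.end(), x) == uni.end()) uni.push_back(x);
        }
      int w = present ? (int)uni.size() : 0;
      if (w < bestw) { bestw = w; best = v; besti = e; }
    }
    eliminate_one(facs, best, logscale, width_cap);
    elim.erase(elim.begin() + besti);
  }
  // combine survivors
  std::vector<int> uni;
  for (auto& f : facs)
    for (int x : f.vars) if (std::find(uni.begin(), uni.end(), x) == uni.end()) uni.push_back(x);
  std::sort(uni.begin(), uni.end());
  Factor out;
  out.vars = uni;
  out.tab.assign((size_t)1 << uni.size(), 1.0);
  for (auto& f : facs) {
    int fw = f.vars.size();
    std::vector<int> pos(fw);
    for (int i = 0; i < fw; ++i)
      pos[i] = std::lower_bound(uni.begin(), uni.end(), f.vars[i]) - uni.begin();
    for (size_t a = 0; a < out.tab.size(); ++a) {
      size_t ia = 0;
      for (int i = 0; i < fw; ++i) if ((a >> pos[i]) & 1) ia |= ((size_t)1 << i);
      out.tab[a] *= f.tab[ia];
    }
  }
  return out;
}

// factors of one group: priors for the given classes + penetrances
static std::vector<Factor> group_factors(const std::vector<int>& prior_vars,
                                         const std::vector<int>& pat,
                                         const std::vector<int>& mat,
                                         const std::vector<double>& y,
                                         double q, const double* mu, double sd) {
  std::vector<Factor> facs;
  for (int v : prior_vars) {
    Factor f; f.vars = {v}; f.tab = {1 - q, q};
    facs.push_back(f);
  }
  for (size_t i = 0; i < y.size(); ++i) {
    if (ISNAN(y[i])) continue;
    Factor f;
    if (pat[i] == mat[i]) {
      f.vars = {pat[i]};
      f.tab = {R::dnorm(y[i], mu[0], sd, 0), R::dnorm(y[i], mu[2], sd, 0)};
    } else {
      int a = std::min(pat[i], mat[i]), b = std::max(pat[i], mat[i]);
      f.vars = {a, b};
      double d0 = R::dnorm(y[i], mu[0], sd, 0), d1 = R::dnorm(y[i], mu[1], sd, 0),
             d2 = R::dnorm(y[i], mu[2], sd, 0);
      bool swapped = pat[i] > mat[i];
      (void)swapped;              // symmetric in an additive/dominance table
      f.tab = {d0, d1, d1, d2};
    }
    facs.push_back(f);
  }
  return facs;
}

// pat/mat: 0-based class ids per phenotyped member; y: traits (NA skipped);
// natural-log likelihood, exact
// [[Rcpp::export]]
double component_loglik_core(IntegerVector pat, IntegerVector mat, int c,
                             NumericVector y, double q, double mu0, double mu1,
                             double mu2, double sigma2) {
  double mu[3] = {mu0, mu1, mu2};
  std::vector<int> p(pat.begin(), pat.end()), m(mat.begin(), mat.end());
  std::vector<double> yy(y.begin(), y.end());
  std::vector<int> vars(c);
  for (int v = 0; v < c; ++v) vars[v] = v;
  double logscale = 0;
  std::vector<Factor> facs = group_factors(vars, p, m, yy, q, mu, std::sqrt(sigma2));
  Factor res = eliminate_vars(facs, vars, logscale);
  double tot = 0;
  for (double t : res.tab) tot += t;
  if (tot <= 0) return R_NegInf;
  return std::log(tot) + logscale;
}

// ---------------------------------------------------------------------------
// full LOD-curve numerator with group-message equivalence caching
// ---------------------------------------------------------------------------

struct GroupStruct {
  std::vector<int> members;     // phenotyped individual indices
  std::vector<int> pat, mat;    // local class ids per member
  int n_class;
  std::vector<int> boundary;    // local ids of boundary (multi-group) classes
};

struct CpRecord {
  int pos;                                  // 1-based marker index
  std::vector<int> gids;                    // group registry ids
  std::vector<std::vector<int>> bmap;       // per group: outer var per boundary slot
};

// message of one group for one trait: sum over internal class alleles of
// priors x penetrances, tabulated over the boundary classes. Fast path:
// direct enumeration over 2^c assignments for small groups.
static void group_message(const GroupStruct& gs, const std::vector<double>& y,
                          double q, const double* mu, double sd,
                          std::vector<double>& tab, std::vector<int>& vslots,
                          double& logoff) {
  int c = gs.n_class, b = gs.boundary.size();
  if (c <= 14) {
    std::vector<char> is_bnd(c, 0);
    std::vector<int> bpos(c, 0);
    for (int i = 0; i < b; ++i) { is_bnd[gs.boundary[i]] = 1; bpos[gs.boundary[i]] = i; }
    tab.assign((size_t)1 << b, 0.0);
    vslots.resize(b);
    for (int i = 0; i < b; ++i) vslots[i] = i;
    logoff = 0;
    int A = 1 << c;
    // precompute per-member penetrance by allele count
    size_t n = gs.members.size();
    std::vector<double> pen(3 * n);
    std::vector<char> use(n);
    for (size_t i = 0; i < n; ++i) {
      use[i] = !ISNAN(y[i]);
      if (use[i])
        for (int x = 0; x < 3; ++x) pen[3 * i + x] = R::dnorm(y[i], mu[x], sd, 0);
    }
    for (int a = 0; a < A; ++a) {
      double w = 1.0;
      size_t bi = 0;
      for (int v = 0; v < c; ++v) {
        int al = (a >> v) & 1;
        if (is_bnd[v]) { if (al) bi |= ((size_t)1 << bpos[v]); }
        else w *= al ? q : 1 - q;
      }
      if (w > 0) {
        for (size_t i = 0; i < n && w > 0; ++i) {
          if (!use[i]) continue;
          int x = ((a >> gs.pat[i]) & 1) + ((a >> gs.mat[i]) & 1);
          w *= pen[3 * i + x];
        }
        tab[bi] += w;
      }
    }
    // boundary assignments are each visited 2^(c-b) times; enumeration
    // already sums internal assignments per boundary cell
    return;
  }
  // generic path: variable elimination over the class graph
  std::vector<int> internal;
  for (int v = 0; v < c; ++v)
    if (std::find(gs.boundary.begin(), gs.boundary.end(), v) == gs.boundary.end())
      internal.push_back(v);
  double logscale = 0;
  std::vector<Factor> facs = group_factors(internal, gs.pat, gs.mat, y, q, mu, sd);
  Factor res = eliminate_vars(facs, internal, logscale);
  logoff = logscale;
  vslots.resize(res.vars.size());
  for (size_t i = 0; i < res.vars.size(); ++i)
    vslots[i] = std::find(gs.boundary.begin(), gs.boundary.end(), res.vars[i]) -
      gs.boundary.begin();
  tab = res.tab;
}

// reals: list of K lists(pos, labels); phen_slot: 2 x n_phen 0-based slot
// columns; traits: n_phen x T; blocks: caching-block id per phenotyped
// individual (empty -> heuristic: classes carried by more than
// hub_threshold individuals never glue individuals into one group).
// Individuals of different blocks are never placed in one cache group;
// classes spanning several groups become outer variables, summed out by a
// cheap outer elimination per change-point. Messages are cached across
// realizations and positions; results equal one-shot exact elimination.
// [[Rcpp::export]]
List lod_curves_core(List reals, int n_positions, IntegerMatrix phen_slot,
                     NumericMatrix traits, double q, double mu0, double mu1,
                     double mu2, double sigma2, bool use_cache = true,
                     int class_cap = 22, int hub_threshold = 8,
                     IntegerVector blocks = IntegerVector(0),
                     NumericVector weights = NumericVector(0)) {
  int K = reals.size(), T = traits.ncol(), n_phen = phen_slot.ncol();
  std::vector<double> logw(K, -std::log((double)K));
  if (weights.size() == K)
    for (int k = 0; k < K; ++k) logw[k] = std::log(weights[k]);
  else if (weights.size() != 0) stop("weights must have length K");
  double mu[3] = {mu0, mu1, mu2};
  double sd = std::sqrt(sigma2);
  bool have_blocks = blocks.size() == n_phen;

  std::unordered_map<std::string, int> group_map;
  std::vector<GroupStruct> groups;
  std::vector<std::vector<CpRecord>> recs(K);
  long hits = 0, misses = 0;

  // ---- pass 1: structure extraction and group registry ----
  std::vector<int> pat(n_phen), mat(n_phen);
  for (int k = 0; k < K; ++k) {
    List r = reals[k];
    IntegerVector pos = r["pos"];
    IntegerMatrix lab = r["labels"];
    int ncp = pos.size();
    recs[k].resize(ncp);
    for (int cp = 0; cp < ncp; ++cp) {
      CpRecord& rec = recs[k][cp];
      rec.pos = pos[cp];
      std::unordered_map<int, int> cls;
      for (int i = 0; i < n_phen; ++i) {
        int lp = lab(cp, phen_slot(0, i)), lm = lab(cp, phen_slot(1, i));
        auto ip = cls.find(lp);
        if (ip == cls.end()) { int id = cls.size(); cls[lp] = id; pat[i] = id; }
        else pat[i] = ip->second;
        auto im = cls.find(lm);
        if (im == cls.end()) { int id = cls.size(); cls[lm] = id; mat[i] = id; }
        else mat[i] = im->second;
      }
      int nc = cls.size();
      // carrier degree per class (heuristic mode only)
      std::vector<char> glue(nc, 1);
      if (!have_blocks) {
        std::vector<int> deg(nc, 0);
        for (int i = 0; i < n_phen; ++i) {
          deg[pat[i]]++;
          if (mat[i] != pat[i]) deg[mat[i]]++;
        }
        for (int c2 = 0; c2 < nc; ++c2) glue[c2] = deg[c2] <= hub_threshold;
      }
      // union individuals sharing a glue-able class (within one block)
      std::vector<int> parent(n_phen);
      for (int i = 0; i < n_phen; ++i) parent[i] = i;
      std::function<int(int)> find = [&](int x) {
        while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
        return x;
      };
      // first carrier per (class, block)
      std::unordered_map<long long, int> first;
      auto link = [&](int i, int c2) {
        if (!glue[c2]) return;
        long long key = (long long)c2 * 100003LL + (have_blocks ? blocks[i] : 0);
        auto it = first.find(key);
        if (it == first.end()) { first[key] = i; return; }
        int a = find(i), b = find(it->second);
        if (a != b) parent[a] = b;
      };
      for (int i = 0; i < n_phen; ++i) { link(i, pat[i]); link(i, mat[i]); }
      // groups in order of first member
      std::unordered_map<int, int> root_gid;
      std::vector<std::vector<int>> members;
      std::vector<int> grp_of(n_phen);
      for (int i = 0; i < n_phen; ++i) {
        int rt = find(i);
        auto it = root_gid.find(rt);
        int g;
        if (it == root_gid.end()) { g = members.size(); root_gid[rt] = g; members.push_back({}); }
        else g = it->second;
        members[g].push_back(i);
        grp_of[i] = g;
      }
      // boundary classes: present in more than one group
      std::vector<int> cls_grp(nc, -1);
      std::vector<char> bnd(nc, 0);
      auto see = [&](int c2, int g) {
        if (cls_grp[c2] < 0) cls_grp[c2] = g;
        else if (cls_grp[c2] != g) bnd[c2] = 1;
      };
      for (int i = 0; i < n_phen; ++i) { see(pat[i], grp_of[i]); see(mat[i], grp_of[i]); }
      std::vector<int> outer_id(nc, -1);
      int n_outer = 0;
      for (int c2 = 0; c2 < nc; ++c2) if (bnd[c2]) outer_id[c2] = n_outer++;

      for (auto& mem : members) {
        std::unordered_map<int, int> local;
        std::vector<int> gpat(mem.size()), gmat(mem.size());
        std::vector<int> bnd_local, bnd_outer;
        std::string key;
        key.reserve(mem.size() * 6 + 8);
        auto localize = [&](int c2) {
          auto it2 = local.find(c2);
          if (it2 != local.end()) return it2->second;
          int id = local.size();
          local[c2] = id;
          if (bnd[c2]) { bnd_local.push_back(id); bnd_outer.push_back(outer_id[c2]); }
          return id;
        };
        for (size_t t = 0; t < mem.size(); ++t) {
          int i = mem[t];
          gpat[t] = localize(pat[i]);
          gmat[t] = localize(mat[i]);
          key.push_back((char)(i & 0xff)); key.push_back((char)((i >> 8) & 0xff));
          key.push_back((char)(gpat[t] & 0xff)); key.push_back((char)((gpat[t] >> 8) & 0xff));
          key.push_back((char)(gmat[t] & 0xff)); key.push_back((char)((gmat[t] >> 8) & 0xff));
        }
        key.push_back((char)0xfe);
        for (int b : bnd_local) key.push_back((char)(b & 0xff));
        if ((int)local.size() > class_cap)
          stop("IBD component group has %d classes, above the cap of %d",
               (int)local.size(), class_cap);
        auto it3 = group_map.find(key);
        int gid;
        if (it3 == group_map.end()) {
          gid = groups.size();
          group_map[key] = gid;
          GroupStruct gs;
          gs.members = mem; gs.pat = gpat; gs.mat = gmat;
          gs.n_class = local.size(); gs.boundary = bnd_local;
          groups.push_back(gs);
        } else gid = it3->second;
        rec.gids.push_back(gid);
        rec.bmap.push_back(bnd_outer);
      }
    }
  }

  // ---- pass 2: per-trait message evaluation and curve assembly ----
  int n_groups = groups.size();
  NumericMatrix out(n_positions, T);
  std::vector<double> msg_off(n_groups);
  std::vector<std::vector<double>> msg_tab(n_groups);
  std::vector<std::vector<int>> msg_vars(n_groups);   // boundary-slot indices
  std::vector<char> have(n_groups);
  std::vector<double> ybuf;

  for (int t = 0; t < T; ++t) {
    std::fill(have.begin(), have.end(), 0);
    std::vector<std::vector<double>> totals(K);
    for (int k = 0; k < K; ++k) {
      totals[k].resize(recs[k].size());
      for (size_t cp = 0; cp < recs[k].size(); ++cp) {
        CpRecord& rec = recs[k][cp];
        double tot = 0;
        std::vector<Factor> outer;
        for (size_t gi = 0; gi < rec.gids.size(); ++gi) {
          int gid = rec.gids[gi];
          if (!have[gid] || !use_cache) {
            GroupStruct& gs = groups[gid];
            ybuf.resize(gs.members.size());
            for (size_t i = 0; i < gs.members.size(); ++i)
              ybuf[i] = traits(gs.members[i], t);
            group_message(gs, ybuf, q, mu, sd, msg_tab[gid], msg_vars[gid],
                          msg_off[gid]);
            have[gid] = 1;
            ++misses;
          } else ++hits;
          tot += msg_off[gid];
          if (msg_vars[gid].empty()) {
            double v = msg_tab[gid][0];
            tot += (v > 0) ? std::log(v) : R_NegInf;
          } else {
            Factor f;
            std::vector<size_t> ord(msg_vars[gid].size());
            for (size_t i = 0; i < ord.size(); ++i) {
              f.vars.push_back(rec.bmap[gi][msg_vars[gid][i]]);
              ord[i] = i;
            }
            std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
              return f.vars[a] < f.vars[b]; });
            std::vector<int> sv(ord.size());
            for (size_t i = 0; i < ord.size(); ++i) sv[i] = f.vars[ord[i]];
            std::vector<double> st((size_t)1 << ord.size());
            for (size_t a = 0; a < st.size(); ++a) {
              size_t ia = 0;
              for (size_t i = 0; i < ord.size(); ++i)
                if ((a >> i) & 1) ia |= ((size_t)1 << ord[i]);
              st[a] = msg_tab[gid][ia];
            }
            f.vars = sv; f.tab = st;
            outer.push_back(f);
          }
        }
        if (!outer.empty() && R_FINITE(tot)) {
          std::vector<int> ovars;
          for (auto& f : outer)
            for (int v : f.vars)
              if (std::find(ovars.begin(), ovars.end(), v) == ovars.end()) ovars.push_back(v);
          for (int v : ovars) {
            Factor f; f.vars = {v}; f.tab = {1 - q, q};
            outer.push_back(f);
          }
          double logscale = 0;
          Factor res = eliminate_vars(outer, ovars, logscale);
          double s = 0;
          for (double x : res.tab) s += x;
          tot += (s > 0) ? std::log(s) + logscale : R_NegInf;
        }
        totals[k][cp] = tot;
      }
    }
    std::vector<int> row(K, 0);
    for (int j = 0; j < n_positions; ++j) {
      double mx = R_NegInf;
      std::vector<double> lks(K);
      for (int k = 0; k < K; ++k) {
        while (row[k] + 1 < (int)recs[k].size() && recs[k][row[k] + 1].pos <= j + 1) ++row[k];
        lks[k] = totals[k][row[k]] + logw[k];
        if (lks[k] > mx) mx = lks[k];
      }
      double s = 0;
      for (int k = 0; k < K; ++k) s += std::exp(lks[k] - mx);
      out(j, t) = mx + std::log(s);
    }
  }
  return List::create(_["loglik"] = out, _["hits"] = (double)hits,
                      _["misses"] = (double)misses);
}
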