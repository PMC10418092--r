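// Individual-based Wright-Fisher simulator with tracked mutations.
//
// Infinite-sites, non-recombining, haploid. Each generation: a mutation
// step (Poisson(U) selected + Poisson(Un) neutral mutations per
// individual, selected effects drawn from rho(s)) followed by a
// reproduction step (multinomial resampling with weights e^{X - Xbar}).
// Mutation identities are tracked; fixed mutations are compacted out of
// genotypes into a fixed ledger, lost ones are recorded. Pairwise
// heterozygosity is computed exactly from carrier counts:
// pi = sum_i 2 c_i (N - c_i) / (N (N-1)).
//
// Uses R's RNG throughout so set.seed() gives bit-reproducible runs.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

namespace {

struct MutInfo {
  double effect;
  bool neutral;
  int origin;
};

struct DfeParams {
  int family;        // 0 two_effect, 1 exponential_pair, 2 gamma_pair, 3 tabulated
  double sb, sd, shape_b, shape_d, eta;
  std::vector<double> tab_s;
  std::vector<double> tab_cw;  // cumulative weights
  int epistasis;     // 0 none, 1 dr, 2 ic, 3 dc, 4 dr_plus_ic
  double sb0, sd0, length_scale;
};

// draw one selected effect; X is the acquiring individual's current
// log-fitness (used only under fitness-mediated epistasis)
double draw_effect(const DfeParams &p, double X) {
  if (p.family == 3) {
    double u = unif_rand();
    size_t lo = 0, hi = p.tab_cw.size() - 1;
    while (lo < hi) {
      size_t mid = (lo + hi) / 2;
      if (p.tab_cw[mid] < u) lo = mid + 1; else hi = mid;
    }
    return p.tab_s[lo];
  }
  double sb = p.sb, sd = p.sd;
  if (p.epistasis != 0) {
    // diminishing returns weakens beneficial effects on fit backgrounds;
    // increasing costs strengthens deleterious ones; decreasing costs
    // weakens them; dr_plus_ic does both with sb*sd exactly conserved
    switch (p.epistasis) {
      case 1: sb = p.sb0 * std::exp(-X / p.length_scale); sd = p.sd0; break;
      case 2: sb = p.sb0; sd = p.sd0 * std::exp(X / p.length_scale); break;
      case 3: sb = p.sb0; sd = p.sd0 * std::exp(-X / p.length_scale); break;
      case 4: sb = p.sb0 * std::exp(-X / p.length_scale);
              sd = p.sd0 * std::exp(X / p.length_scale); break;
    }
  }
  bool beneficial = unif_rand() < p.eta / (1.0 + p.eta);
  double mag;
  if (p.family == 0) mag = beneficial ? sb : sd;
  else if (p.family == 1) mag = R::rexp(beneficial ? sb : sd);
  else mag = beneficial ? R::rgamma(p.shape_b, sb / p.shape_b)
                        : R::rgamma(p.shape_d, sd / p.shape_d);
  return beneficial ? mag : -mag;
}

}  // namespace

// [[Rcpp::export(name = ".wf_run_cpp")]]
List wf_run_cpp(List genomes_sel_in, List genomes_neu_in, NumericVector X_in,
                IntegerVector active_id, NumericVector active_effect,
                LogicalVector active_neutral, IntegerVector active_origin,
                int next_id, int generation, List params, int n_generations,
                bool stop_at_first_fixation, int record_every) {
  const int N = X_in.size();
  const double U = as<double>(params["U"]);
  const double Un = as<double>(params["Un"]);
  DfeParams dfe;
  dfe.family = as<int>(params["family"]);
  dfe.sb = as<double>(params["sb"]);
  dfe.sd = as<double>(params["sd"]);
  dfe.shape_b = as<double>(params["shape_b"]);
  dfe.shape_d = as<double>(params["shape_d"]);
  dfe.eta = as<double>(params["eta"]);
  dfe.epistasis = as<int>(params["epistasis"]);
  dfe.sb0 = as<double>(params["sb0"]);
  dfe.sd0 = as<double>(params["sd0"]);
  dfe.length_scale = as<double>(params["length_scale"]);
  if (dfe.family == 3) {
    NumericVector ts = params["tab_s"], tw = params["tab_w"];
    double tot = 0;
    for (double w : tw) tot += w;
    double cum = 0;
    for (int i = 0; i < ts.size(); ++i) {
      dfe.tab_s.push_back(ts[i]);
      cum += tw[i] / tot;
      dfe.tab_cw.push_back(cum);
    }
    dfe.tab_cw.back() = 1.0;
  }

  std::vector<std::vector<int>> gsel(N), gneu(N);
  for (int i = 0; i < N; ++i) {
    IntegerVector v = genomes_sel_in[i];
    gsel[i].assign(v.begin(), v.end());
    IntegerVector w = genomes_neu_in[i];
    gneu[i].assign(w.begin(), w.end());
  }
  std::vector<double> X(X_in.begin(), X_in.end());
  std::unordered_map<int, MutInfo> active;
  for (int i = 0; i < active_id.size(); ++i)
    active[active_id[i]] = MutInfo{active_effect[i],
                                   (bool)active_neutral[i], active_origin[i]};

  // records
  std::vector<int> fix_id, fix_gen, lost_id, lost_gen;
  std::vector<double> fix_effect;
  std::vector<bool> fix_neutral, lost_neutral;
  std::vector<double> traj_gen, traj_meanX, traj_pineu, traj_pisel,
      traj_fsel, traj_fneu;
  int first_fix_gen = -1;
  long long fixed_sel_cum = 0, fixed_neu_cum = 0;
  double pi_neu = 0, pi_sel = 0;

  std::vector<double> cumw(N);
  std::vector<std::vector<int>> nsel(N), nneu(N);
  std::vector<double> nX(N);
  std::unordered_map<int, int> counts;

  int g = 0;
  for (g = 1; g <= n_generations; ++g) {
    // --- mutation step ---
    for (int i = 0; i < N; ++i) {
      int nm = (int)R::rpois(U);
      for (int m = 0; m < nm; ++m) {
        double s = draw_effect(dfe, X[i]);
        gsel[i].push_back(next_id);
        X[i] += s;
        active[next_id] = MutInfo{s, false, generation + g};
        ++next_id;
      }
      int nn = (int)R::rpois(Un);
      for (int m = 0; m < nn; ++m) {
        gneu[i].push_back(next_id);
        active[next_id] = MutInfo{0.0, true, generation + g};
        ++next_id;
      }
    }
    // --- reproduction step: multinomial with weights e^{X - max X} ---
    double xmax = X[0];
    for (int i = 1; i < N; ++i) if (X[i] > xmax) xmax = X[i];
    double tot = 0;
    for (int i = 0; i < N; ++i) {
      tot += std::exp(X[i] - xmax);
      cumw[i] = tot;
    }
    for (int c = 0; c < N; ++c) {
      double u = unif_rand() * tot;
      int lo = 0, hi = N - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (cumw[mid] < u) lo = mid + 1; else hi = mid;
      }
      nsel[c] = gsel[lo];
      nneu[c] = gneu[lo];
      nX[c] = X[lo];
    }
    gsel.swap(nsel);
    gneu.swap(nneu);
    X.swap(nX);

    // --- fixation / loss scan ---
    counts.clear();
    for (int i = 0; i < N; ++i) {
      for (int id : gsel[i]) ++counts[id];
      for (int id : gneu[i]) ++counts[id];
    }
    bool any_fixed = false;
    std::vector<int> to_remove;
    for (auto it = active.begin(); it != active.end();) {
      auto c = counts.find(it->first);
      int cnt = (c == counts.end()) ? 0 : c->second;
      if (cnt == 0) {
        lost_id.push_back(it->first);
        lost_gen.push_back(generation + g);
        lost_neutral.push_back(it->second.neutral);
        it = active.erase(it);
      } else if (cnt == N) {
        fix_id.push_back(it->first);
        fix_gen.push_back(generation + g);
        fix_effect.push_back(it->second.effect);
        fix_neutral.push_back(it->second.neutral);
        if (it->second.neutral) ++fixed_neu_cum; else ++fixed_sel_cum;
        to_remove.push_back(it->first);
        any_fixed = true;
        it = active.erase(it);
      } else {
        ++it;
      }
    }
    if (!to_remove.empty()) {
      // compact fixed mutations out of every genotype
      std::unordered_map<int, bool> rm;
      for (int id : to_remove) rm[id] = true;
      for (int i = 0; i < N; ++i) {
        auto keep = [&](std::vector<int> &v) {
          size_t k = 0;
          for (size_t j = 0; j < v.size(); ++j)
            if (!rm.count(v[j])) v[k++] = v[j];
          v.resize(k);
        };
        keep(gsel[i]);
        keep(gneu[i]);
      }
    }
    // heterozygosity from carrier counts (exact all-pairs average)
    pi_neu = 0; pi_sel = 0;
    if (N > 1) {
      const double denom = (double)N * (N - 1);
      for (auto &kv : active) {
        auto c = counts.find(kv.first);
        if (c == counts.end()) continue;
        double cc = 2.0 * c->second * (N - c->second) / denom;
        if (kv.second.neutral) pi_neu += cc; else pi_sel += cc;
      }
    }
    if (record_every > 0 && (g % record_every == 0 || g == n_generations)) {
      double mx = 0;
      for (int i = 0; i < N; ++i) mx += X[i];
      traj_gen.push_back(generation + g);
      traj_meanX.push_back(mx / N);
      traj_pineu.push_back(pi_neu);
      traj_pisel.push_back(pi_sel);
      traj_fsel.push_back((double)fixed_sel_cum);
      traj_fneu.push_back((double)fixed_neu_cum);
    }
    if (any_fixed && stop_at_first_fixation && first_fix_gen < 0) {
      first_fix_gen = generation + g;
      break;
    }
    if (any_fixed && first_fix_gen < 0) first_fix_gen = generation + g;
    if (g % 64 == 0) Rcpp::checkUserInterrupt();
  }
  int gens_done = std::min(g, n_generations);

  // pack state back
  List out_sel(N), out_neu(N);
  for (int i = 0; i < N; ++i) {
    out_sel[i] = IntegerVector(gsel[i].begin(), gsel[i].end());
    out_neu[i] = IntegerVector(gneu[i].begin(), gneu[i].end());
  }
  int na = active.size();
  IntegerVector aid(na), aorig(na);
  NumericVector aeff(na);
  LogicalVector aneu(na);
  int k = 0;
  for (auto &kv : active) {
    aid[k] = kv.first;
    aeff[k] = kv.second.effect;
    aneu[k] = kv.second.neutral;
    aorig[k] = kv.second.origin;
    ++k;
  }
  double mx = 0;
  for (int i = 0; i < N; ++i) mx += X[i];

  return List::create(
      _["genomes_sel"] = out_sel, _["genomes_neu"] = out_neu,
      _["X"] = NumericVector(X.begin(), X.end()),
      _["next_id"] = next_id, _["generation"] = generation + gens_done,
      _["active_id"] = aid, _["active_effect"] = aeff,
      _["active_neutral"] = aneu, _["active_origin"] = aorig,
      _["fixed"] = DataFrame::create(
          _["id"] = IntegerVector(fix_id.begin(), fix_id.end()),
          _["effect"] = NumericVector(fix_effect.begin(), fix_effect.end()),
          _["neutral"] = LogicalVector(fix_neutral.begin(), fix_neutral.end()),
          _["generation"] = IntegerVector(fix_gen.begin(), fix_gen.end())),
      _["lost"] = DataFrame::create(
          _["id"] = IntegerVector(lost_id.begin(), lost_id.end()),
          _["neutral"] = LogicalVector(lost_neutral.begin(), lost_neutral.end()),
          _["generation"] = IntegerVector(lost_gen.begin(), lost_gen.end())),
      _["trajectory"] = DataFrame::create(
          _["generation"] = NumericVector(traj_gen.begin(), traj_gen.end()),
          _["mean_fitness"] = NumericVector(traj_meanX.begin(), traj_meanX.end()),
          _["pi_neu"] = NumericVector(traj_pineu.begin(), traj_pineu.end()),
          _["pi_sel"] = NumericVector(traj_pisel.begin(), traj_pisel.end()),
          _["fixed_sel"] = NumericVector(traj_fsel.begin(), traj_fsel.end()),
          _["fixed_neu"] = NumericVector(traj_fneu.begin(), traj_fneu.end())),
      _["first_fix_gen"] = first_fix_gen,
      _["mean_fitness"] = mx / N,
      _["pi_neu"] = pi_neu, _["pi_sel"] = pi_sel);
}
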