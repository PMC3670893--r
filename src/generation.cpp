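// Generation kernel: oviposition, brood resolution and in-host mating.
//
// Semantics mirror the documented R-level operations (attractiveness,
// accept_host, host_state_key, choose_egg_sex, resolve_host): at each of
// `lifespan` time steps every female, in random order, is presented one
// uniformly random host, lays one egg if the host's attractiveness
// strictly exceeds the threshold, and picks the egg's sex from her
// strategy keyed by the sensed host state. Hosts over the egg limit die;
// surviving eggs proliferate into clones (truncated-normal sizes, drawn
// from R's RNG so runs are reproducible under set.seed), and a fraction
// of emerging females mates with brood males before dispersal, capped by
// male virility. Dispersal mating happens afterwards, in R.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 0-based column into the sex-choice matrix for a host state.
// info: 0 = none, 1 = relatedness, 2 = sex_and_relatedness.
static inline int key_index(int n_eggs, int n_related, int n_male,
                            int info) {
  if (n_eggs == 0) return 0;
  if (info == 0) return 1;
  int rel = (n_related == n_eggs) ? 0 : (n_related == 0 ? 1 : 2);
  if (info == 1) return 1 + rel;
  int sx = (n_male == n_eggs) ? 0 : (n_male == 0 ? 1 : 2);
  return 1 + rel * 3 + sx;
}

static inline int unif_index(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static inline int clone_size(double mean, double sd) {
  double x = sd > 0 ? mean + sd * norm_rand() : mean;
  if (x < 0) x = 0;
  return (int)Rf_fround(x, 0.0);
}

// [[Rcpp::export(name = ".cpp_generation")]]
List cpp_generation(NumericMatrix f_strat, LogicalVector f_mated,
                    NumericMatrix f_mate, IntegerVector f_lin,
                    int n_hosts, int lifespan, int host_limit,
                    double threshold, double influence, double c_stop,
                    double inherit_w, double mating_ratio,
                    int virility, int virgin_son_virility, int info,
                    NumericVector surv_mean, NumericVector surv_sd,
                    Nullable<IntegerMatrix> presentation) {
  const int n_f = f_strat.nrow();
  const int K = f_strat.ncol();
  const bool have_pres = presentation.isNotNull();
  IntegerMatrix pres;
  if (have_pres) pres = presentation.get();

  // host state
  std::vector<int> cnt(n_hosts, 0), nmale(n_hosts, 0),
      first_lin(n_hosts, 0);
  std::vector<char> same(n_hosts, 1);
  std::vector<std::vector<int> > host_eggs(n_hosts),
      host_egg_lin(n_hosts);

  // egg records
  std::vector<int> e_host, e_lin;
  std::vector<char> e_male, e_vson;
  std::vector<double> e_strat;  // K values per egg
  e_host.reserve(256);

  int n_open = n_hosts;
  std::vector<int> perm(n_f);
  for (int i = 0; i < n_f; ++i) perm[i] = i;

  for (int t = 0; t < lifespan && n_open > 0; ++t) {
    if (!have_pres) {
      for (int i = n_f - 1; i > 0; --i) {  // Fisher-Yates presentation order
        int j = unif_index(i + 1);
        std::swap(perm[i], perm[j]);
      }
    }
    for (int i = 0; i < n_f; ++i) {
      int fi = perm[i];
      int h = have_pres ? pres(fi, t) - 1 : unif_index(n_hosts);
      int c = cnt[h];
      double attr = 1.0 - influence * c;
      if (attr < 0) attr = 0;
      if (!(attr > threshold)) continue;

      int n_rel = 0;
      const std::vector<int>& hl = host_egg_lin[h];
      for (size_t k = 0; k < hl.size(); ++k) {
        if (hl[k] == f_lin[fi]) ++n_rel;
      }
      int key = key_index(c, n_rel, nmale[h], info);
      bool mated = f_mated[fi];
      bool male = !mated || unif_rand() < f_strat(fi, key);

      int ei = (int)e_host.size();
      e_host.push_back(h);
      e_male.push_back(male);
      e_vson.push_back(male && !mated);
      e_lin.push_back(f_lin[fi]);
      for (int k = 0; k < K; ++k) {
        e_strat.push_back(male ? f_strat(fi, k)
                               : inherit_w * f_mate(fi, k) +
                                     (1.0 - inherit_w) * f_strat(fi, k));
      }
      host_eggs[h].push_back(ei);
      host_egg_lin[h].push_back(f_lin[fi]);
      if (male) nmale[h] += 1;
      if (c == 0) {
        first_lin[h] = f_lin[fi];
      } else if (same[h] && first_lin[h] != f_lin[fi]) {
        same[h] = 0;
      }
      cnt[h] = c + 1;
      if (cnt[h] >= c_stop) --n_open;
    }
  }

  const int ne = (int)e_host.size();
  int eggs_male = 0;
  for (int i = 0; i < ne; ++i) eggs_male += e_male[i];

  // brood resolution
  int n_premature = 0;
  for (int h = 0; h < n_hosts; ++h) {
    if (cnt[h] > host_limit) ++n_premature;
  }
  std::vector<int> n_emerge(ne, 0);
  int nF = 0, nM = 0;
  for (int i = 0; i < ne; ++i) {
    int h = e_host[i];
    if (cnt[h] > host_limit) continue;  // premature death: no emergers
    bool mixed = nmale[h] > 0 && nmale[h] < cnt[h];
    int ctx = mixed ? (same[h] ? 2 : 4) : 0;  // + 0 male / + 1 female
    ctx += e_male[i] ? 0 : 1;
    n_emerge[i] = clone_size(surv_mean[ctx], surv_sd[ctx]);
    if (e_male[i]) nM += n_emerge[i]; else nF += n_emerge[i];
  }

  NumericMatrix nf_strat(nF, K), nf_mate(nF, K), nm_strat(nM, K);
  std::fill(nf_mate.begin(), nf_mate.end(), NA_REAL);
  LogicalVector nf_mated(nF);
  IntegerVector nf_lin(nF), nm_lin(nM), nm_cap(nM);
  LogicalVector nm_vson(nM);

  std::vector<std::vector<int> > host_newf(n_hosts), host_newm(n_hosts);
  int fi_out = 0, mi_out = 0;
  for (int i = 0; i < ne; ++i) {
    int h = e_host[i];
    for (int rep = 0; rep < n_emerge[i]; ++rep) {
      if (e_male[i]) {
        for (int k = 0; k < K; ++k) nm_strat(mi_out, k) = e_strat[i * K + k];
        nm_lin[mi_out] = i + 1;  // clone id = egg index
        nm_vson[mi_out] = (bool)e_vson[i];
        nm_cap[mi_out] = e_vson[i] ? virgin_son_virility : virility;
        host_newm[h].push_back(mi_out);
        ++mi_out;
      } else {
        for (int k = 0; k < K; ++k) nf_strat(fi_out, k) = e_strat[i * K + k];
        nf_lin[fi_out] = i + 1;
        host_newf[h].push_back(fi_out);
        ++fi_out;
      }
    }
  }

  // in-host mating before dispersal
  if (mating_ratio > 0 && nF > 0 && nM > 0) {
    std::vector<int> att, slots;
    for (int h = 0; h < n_hosts; ++h) {
      const std::vector<int>& fh = host_newf[h];
      const std::vector<int>& mh = host_newm[h];
      if (fh.empty() || mh.empty()) continue;
      att.clear();
      for (size_t i = 0; i < fh.size(); ++i) {
        if (mating_ratio >= 1 || unif_rand() < mating_ratio) {
          att.push_back(fh[i]);
        }
      }
      if (att.empty()) continue;
      slots.clear();
      for (size_t i = 0; i < mh.size(); ++i) {
        for (int s = 0; s < nm_cap[mh[i]]; ++s) slots.push_back(mh[i]);
      }
      int k = (int)std::min(att.size(), slots.size());
      if (k == 0) continue;
      for (int i = 0; i < k; ++i) {  // draw k distinct of each, uniformly
        int j = i + unif_index((int)att.size() - i);
        std::swap(att[i], att[j]);
        j = i + unif_index((int)slots.size() - i);
        std::swap(slots[i], slots[j]);
      }
      for (int i = 0; i < k; ++i) {
        int f = att[i], m = slots[i];
        nf_mated[f] = true;
        for (int kk = 0; kk < K; ++kk) nf_mate(f, kk) = nm_strat(m, kk);
        nm_cap[m] -= 1;
      }
    }
  }

  return List::create(
      _["eggs_male"] = eggs_male, _["eggs_female"] = ne - eggs_male,
      _["premature_hosts"] = n_premature,
      _["f_strat"] = nf_strat, _["f_mated"] = nf_mated,
      _["f_mate"] = nf_mate, _["f_lin"] = nf_lin,
      _["m_strat"] = nm_strat, _["m_lin"] = nm_lin,
      _["m_vson"] = nm_vson, _["m_cap"] = nm_cap);
}
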