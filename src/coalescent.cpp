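// Equilibrium coalescent sampler for microsatellite mutation models.
//
// Samples the allelic configuration of n genes drawn from a neutral
// Wright-Fisher population at mutation-drift equilibrium with scaled
// mutation rate theta = 4*N*mu, by simulating the n-coalescent and placing
// Poisson mutations on its branches. Models: 0 = IAM (every mutation makes
// a brand-new allele), 1 = SMM (+/-1 repeat step), 2 = TPM (single step
// with probability p_single, otherwise a geometric multistep whose size
// variance is controlled by geom_q: Var = (1-q)/q^2).

#include <Rcpp.h>
using namespace Rcpp;

static void simulate_config(int n, double theta, int model, double p_single,
                            double geom_q, std::vector<int> &leaf_val) {
  int total = 2 * n - 1;
  std::vector<int> parent(total, -1);
  std::vector<double> node_time(total, 0.0);
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;
  double t = 0.0;
  int next_node = n;
  while ((int)active.size() > 1) {
    int i = active.size();
    t += R::rexp(2.0 / ((double)i * (i - 1)));
    int a = (int)(unif_rand() * i);
    int b = (int)(unif_rand() * (i - 1));
    if (b >= a) b += 1;
    int c1 = active[a], c2 = active[b];
    parent[c1] = next_node;
    parent[c2] = next_node;
    node_time[next_node] = t;
    // remove the two children, append the parent
    if (a > b) std::swap(a, b);
    active[a] = next_node;
    active.erase(active.begin() + b);
    ++next_node;
  }
  // values top-down: nodes n..2n-2 were created in increasing time order,
  // so iterate from the root downwards
  std::vector<int> value(total, 0);
  int new_label = 1; // IAM labels
  for (int node = total - 2; node >= 0; --node) {
    double blen = node_time[parent[node]] - node_time[node];
    int nmut = (int)R::rpois(0.5 * theta * blen);
    int v = value[parent[node]];
    if (model == 0) {
      if (nmut > 0) v = new_label++;
    } else {
      for (int m = 0; m < nmut; ++m) {
        int step;
        if (model == 1 || unif_rand() < p_single) {
          step = 1;
        } else {
          step = 1 + (int)R::rgeom(geom_q);
        }
        v += (unif_rand() < 0.5) ? step : -step;
      }
    }
    value[node] = v;
  }
  leaf_val.assign(value.begin(), value.begin() + n);
}

static int count_alleles(const std::vector<int> &v) {
  std::vector<int> s(v);
  std::sort(s.begin(), s.end());
  return std::unique(s.begin(), s.end()) - s.begin();
}

// unbiased expected heterozygosity n/(n-1) * (1 - sum p^2)
static double unbiased_het(const std::vector<int> &v) {
  std::map<int, int> cnt;
  for (int x : v) cnt[x]++;
  double n = v.size(), ss = 0.0;
  for (auto &kv : cnt) {
    double p = kv.second / n;
    ss += p * p;
  }
  return n / (n - 1.0) * (1.0 - ss);
}

// [[Rcpp::export]]
IntegerVector coalescent_config(int n, double theta, int model,
                                double p_single, double geom_q) {
  std::vector<int> leaf;
  simulate_config(n, theta, model, p_single, geom_q, leaf);
  return wrap(leaf);
}

// [[Rcpp::export]]
NumericVector coalescent_mean_k(int n, double theta, int model,
                                double p_single, double geom_q, int reps) {
  std::vector<int> leaf;
  double sum = 0.0;
  for (int r = 0; r < reps; ++r) {
    simulate_config(n, theta, model, p_single, geom_q, leaf);
    sum += count_alleles(leaf);
  }
  return NumericVector::create(sum / reps);
}

// Retain equilibrium replicates conditional on exactly k alleles and return
// their unbiased expected heterozygosities (length <= nreps; shorter only
// if max_tries was exhausted).
// [[Rcpp::export]]
List coalescent_heq(int n, int k, double theta, int model, double p_single,
                    double geom_q, int nreps, int max_tries) {
  std::vector<int> leaf;
  std::vector<double> hets;
  hets.reserve(nreps);
  int tries = 0;
  while ((int)hets.size() < nreps && tries < max_tries) {
    ++tries;
    simulate_config(n, theta, model, p_single, geom_q, leaf);
    if (count_alleles(leaf) == k) hets.push_back(unbiased_het(leaf));
  }
  return List::create(_["het"] = wrap(hets), _["tries"] = tries);
}
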