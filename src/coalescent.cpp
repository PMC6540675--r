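#include <Rcpp.h>
#include <vector>
#include <set>
#include <algorithm>
using namespace Rcpp;

// Coalescent machinery under piecewise-constant demography.
//
// All sizes passed from R are already "haploid-equivalent" numbers of gene
// copies M(t): for an autosomal diploid locus M = 2N, for maternally
// inherited haploid mtDNA with even sex ratio M = N/4.  The pairwise
// coalescence rate while k lineages remain is C(k,2)/M(t) per generation.
// Time is measured in generations, continuously, backward from sampling.
//
// Uses R's RNG throughout (RNGScope via Rcpp attributes) so set.seed() in
// R makes every simulation reproducible.

struct Tree {
  int n;                       // tips
  std::vector<int> parent;     // 2n-1 entries, parent index, -1 for root
  std::vector<double> blen;    // branch length (generations) to parent
};

// Simulate a Kingman coalescent genealogy; epoch starts are strictly
// increasing with ep_start[0] == 0.
static Tree sim_tree(int n, const NumericVector& ep_start,
                     const NumericVector& ep_M) {
  int total = 2 * n - 1;
  Tree tr;
  tr.n = n;
  tr.parent.assign(total, -1);
  tr.blen.assign(total, 0.0);
  if (n == 1) return tr;
  std::vector<int> active(n);
  std::vector<double> node_time(total, 0.0);
  for (int i = 0; i < n; ++i) active[i] = i;
  int next_node = n;
  int k = n, ei = 0, nep = ep_start.size();
  double t = 0.0;
  while (k > 1) {
    double M = ep_M[ei];
    double rate = 0.5 * (double)k * (k - 1) / M;
    double dt = R::exp_rand() / rate;
    double ep_end = (ei + 1 < nep) ? ep_start[ei + 1] : R_PosInf;
    if (t + dt >= ep_end) { t = ep_end; ++ei; continue; }
    t += dt;
    int i = (int)(unif_rand() * k); if (i == k) i = k - 1;
    int j = (int)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
    if (j >= i) ++j;
    int a = active[i], b = active[j];
    int p = next_node++;
    tr.parent[a] = p; tr.parent[b] = p;
    tr.blen[a] = t - node_time[a];
    tr.blen[b] = t - node_time[b];
    node_time[p] = t;
    int lo = std::min(i, j), hi = std::max(i, j);
    active[lo] = p;
    active[hi] = active[k - 1];
    --k;
  }
  return tr;
}

// Reflect an allele state into [1, n_states].
static inline int reflect_state(int x, int n_states) {
  while (x < 1 || x > n_states) {
    if (x < 1) x = 2 - x;
    if (x > n_states) x = 2 * n_states - x;
  }
  return x;
}

// One microsatellite locus under the generalized stepwise model:
// mutations Poisson on branches, geometric step sizes (parameter p_geom,
// support >= 1), symmetric sign, reflecting bounds on a contiguous state
// range 1..n_states.  Returns tip allele states.
// [[Rcpp::export(name = ".sim_msat_locus_cpp")]]
IntegerVector sim_msat_locus_cpp(int n, NumericVector ep_start,
                                 NumericVector ep_M, double mu,
                                 double p_geom, int n_states,
                                 int anc_state) {
  Tree tr = sim_tree(n, ep_start, ep_M);
  int total = 2 * n - 1;
  std::vector<int> state(total);
  state[total - 1] = anc_state;
  for (int idx = total - 2; idx >= 0; --idx) {
    int s = state[tr.parent[idx]];
    int m = (int)R::rpois(mu * tr.blen[idx]);
    for (int e = 0; e < m; ++e) {
      int step = (int)R::rgeom(1.0 - p_geom) + 1;
      if (unif_rand() < 0.5) step = -step;
      s = reflect_state(s + step, n_states);
    }
    state[idx] = s;
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = state[i];
  return out;
}

// One sequence locus under HKY85, simulated as a Poisson mutation-event
// process: events at rate mu (per site per generation) * L on each branch,
// site chosen uniformly, replacement base drawn with probability
// proportional to kappa*pi_j for transitions and pi_j for transversions.
// Bases coded 0=A, 1=C, 2=G, 3=T.  Returns the n x L tip matrix.
// [[Rcpp::export(name = ".sim_seq_locus_cpp")]]
IntegerMatrix sim_seq_locus_cpp(int n, NumericVector ep_start,
                                NumericVector ep_M, double mu, int L,
                                double kappa, NumericVector base_freq) {
  Tree tr = sim_tree(n, ep_start, ep_M);
  int total = 2 * n - 1;
  // transition partner: A<->G, C<->T
  static const int ts_partner[4] = {2, 3, 0, 1};
  std::vector<std::vector<unsigned char> > seq(total);
  // root sequence from stationary frequencies
  seq[total - 1].resize(L);
  for (int s = 0; s < L; ++s) {
    double u = unif_rand(), acc = 0.0;
    int b = 3;
    for (int j = 0; j < 4; ++j) { acc += base_freq[j]; if (u < acc) { b = j; break; } }
    seq[total - 1][s] = (unsigned char)b;
  }
  for (int idx = total - 2; idx >= 0; --idx) {
    seq[idx] = seq[tr.parent[idx]];
    int m = (int)R::rpois(mu * (double)L * tr.blen[idx]);
    for (int e = 0; e < m; ++e) {
      int site = (int)(unif_rand() * L); if (site == L) site = L - 1;
      int cur = seq[idx][site];
      double w[4], tot = 0.0;
      for (int j = 0; j < 4; ++j) {
        if (j == cur) { w[j] = 0.0; continue; }
        w[j] = (j == ts_partner[cur]) ? kappa * base_freq[j] : base_freq[j];
        tot += w[j];
      }
      double u = unif_rand() * tot, acc = 0.0;
      int nb = cur;
      for (int j = 0; j < 4; ++j) { acc += w[j]; if (u < acc && w[j] > 0) { nb = j; break; } }
      seq[idx][site] = (unsigned char)nb;
    }
    // free parent memory early not needed at these sizes
  }
  IntegerMatrix out(n, L);
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < L; ++s) out(i, s) = seq[i][s];
  return out;
}

// Coalescence waiting summary for calibration: returns the time to the
// most recent common ancestor for n_rep independent genealogies.
// [[Rcpp::export(name = ".sim_tmrca_cpp")]]
NumericVector sim_tmrca_cpp(int n, NumericVector ep_start,
                            NumericVector ep_M, int n_rep) {
  NumericVector out(n_rep);
  for (int r = 0; r < n_rep; ++r) {
    Tree tr = sim_tree(n, ep_start, ep_M);
    double tm = 0.0;
    // root time = sum of branch lengths down any path; recover from tip 0
    int idx = 0;
    while (tr.parent[idx] >= 0) { tm += tr.blen[idx]; idx = tr.parent[idx]; }
    out[r] = tm;
  }
  return out;
}

// Constant-size infinite-sites replicates in coalescent units: mutations
// Poisson with rate theta/2 per unit branch length.  For each replicate
// returns S (segregating sites), mean pairwise differences and the
// haplotype count.  Used for neutrality-test null distributions.
// [[Rcpp::export(name = ".sim_infsites_cpp")]]
NumericMatrix sim_infsites_cpp(int n, double theta, int n_rep) {
  NumericMatrix out(n_rep, 3);
  colnames(out) = CharacterVector::create("S", "kbar", "H");
  NumericVector ep_start = NumericVector::create(0.0);
  NumericVector ep_M = NumericVector::create(1.0);
  double npairs = 0.5 * (double)n * (n - 1);
  for (int r = 0; r < n_rep; ++r) {
    Tree tr = sim_tree(n, ep_start, ep_M);
    int total = 2 * n - 1;
    // leaf descendants per node
    std::vector<std::vector<int> > leaves(total);
    for (int i = 0; i < n; ++i) leaves[i].push_back(i);
    for (int idx = 0; idx < total - 1; ++idx) {
      std::vector<int>& par = leaves[tr.parent[idx]];
      par.insert(par.end(), leaves[idx].begin(), leaves[idx].end());
    }
    int S = 0;
    double ksum = 0.0;
    std::vector<std::vector<int> > hap(n);
    for (int idx = 0; idx < total - 1; ++idx) {
      int m = (int)R::rpois(0.5 * theta * tr.blen[idx]);
      if (m <= 0) continue;
      S += m;
      double c = (double)leaves[idx].size();
      ksum += m * c * ((double)n - c);
      for (size_t q = 0; q < leaves[idx].size(); ++q)
        for (int e = 0; e < m; ++e) hap[leaves[idx][q]].push_back(idx * 1000 + e);
    }
    std::set<std::vector<int> > uniq;
    for (int i = 0; i < n; ++i) {
      std::sort(hap[i].begin(), hap[i].end());
      uniq.insert(hap[i]);
    }
    out(r, 0) = S;
    out(r, 1) = ksum / npairs;
    out(r, 2) = (double)uniq.size();
  }
  return out;
}
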