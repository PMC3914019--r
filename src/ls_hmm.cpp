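#include <Rcpp.h>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Diploid Li-Stephens haplotype-copying HMM over ordered template pairs.
//
// Hidden state at a site: an ordered pair (k1, k2) of template haplotypes.
// Transition per interval: each copied haplotype independently switches to
// a uniformly chosen template (including the current one) with probability
// `rec`, so T(j -> k) = (1 - rec) * [j == k] + rec / H.  This factorised
// structure lets the H^2-state forward/backward sums collapse to row and
// column marginals, giving O(S * H^2) total work instead of O(S * H^4).
// Emission at a site depends only on the number of alternate alleles the
// two templates carry (c = a1 + a2); each copied allele is flipped with
// probability `terr` before being combined with the genotype likelihoods.
//
// Returns exact forward-backward genotype posteriors per site, the data
// log-likelihood, and optionally a state path drawn from the joint
// posterior (forward-filter backward-sample) together with a sampled
// haplotype pair, used by the iterative LD-aware caller.  Randomness comes
// from R's RNG so results are reproducible under set.seed().

// [[Rcpp::export(name = ".ls_hmm_cpp")]]
List ls_hmm_cpp(NumericMatrix lik, IntegerMatrix templates, double rec,
                double terr, bool sample_path) {
  const int S = lik.nrow();
  const int H = templates.nrow();
  if (templates.ncol() != S) stop("template site count mismatch");
  const int HH = H * H;
  const double stay = 1.0 - rec;
  const double sw = rec / H;

  // emission weights w_c(g): P(g | templates carry c alt alleles)
  double w[3][3];
  w[0][0] = (1 - terr) * (1 - terr); w[0][1] = 2 * terr * (1 - terr);
  w[0][2] = terr * terr;
  w[1][0] = terr * (1 - terr);
  w[1][1] = (1 - terr) * (1 - terr) + terr * terr;
  w[1][2] = terr * (1 - terr);
  w[2][0] = terr * terr; w[2][1] = 2 * terr * (1 - terr);
  w[2][2] = (1 - terr) * (1 - terr);

  // contiguous per-site buffers: template alleles and class emissions
  std::vector<int> tbuf((size_t)S * H);
  std::vector<double> ec((size_t)S * 3);
  for (int s = 0; s < S; s++) {
    for (int h = 0; h < H; h++) tbuf[(size_t)s * H + h] = templates(h, s);
    for (int c = 0; c < 3; c++)
      ec[(size_t)s * 3 + c] = w[c][0] * lik(s, 0) + w[c][1] * lik(s, 1) +
                              w[c][2] * lik(s, 2);
  }

  // forward pass with per-site normalisation; all scaled alphas kept
  std::vector<double> alpha((size_t)S * HH);
  std::vector<double> prev(HH), cur(HH), row1(H), row2(H), wgt(HH);
  double loglik = 0.0;

  {
    const int* ts = &tbuf[0];
    const double* es = &ec[0];
    for (int k1 = 0; k1 < H; k1++)
      for (int k2 = 0; k2 < H; k2++)
        prev[k1 * H + k2] = es[ts[k1] + ts[k2]] / HH;
  }
  double z = std::accumulate(prev.begin(), prev.end(), 0.0);
  if (z <= 0) stop("zero forward mass (degenerate likelihoods)");
  for (int i = 0; i < HH; i++) prev[i] /= z;
  loglik += std::log(z);
  std::copy(prev.begin(), prev.end(), alpha.begin());

  for (int s = 1; s < S; s++) {
    const int* ts = &tbuf[(size_t)s * H];
    const double* es = &ec[(size_t)s * 3];
    std::fill(row1.begin(), row1.end(), 0.0);
    std::fill(row2.begin(), row2.end(), 0.0);
    for (int k1 = 0; k1 < H; k1++) {
      const double* pr = &prev[k1 * H];
      double acc = 0.0;
      for (int k2 = 0; k2 < H; k2++) {
        acc += pr[k2];
        row2[k2] += pr[k2];
      }
      row1[k1] = acc;
    }
    // total mass is 1 after the previous normalisation
    z = 0.0;
    for (int k1 = 0; k1 < H; k1++) {
      const double* pr = &prev[k1 * H];
      double* cu = &cur[k1 * H];
      const double r1 = stay * sw * row1[k1];
      const double e1base = ts[k1];
      for (int k2 = 0; k2 < H; k2++) {
        double trans = stay * stay * pr[k2] + r1 + stay * sw * row2[k2] +
                       sw * sw;
        cu[k2] = es[(int)e1base + ts[k2]] * trans;
        z += cu[k2];
      }
    }
    if (z <= 0) stop("zero forward mass (degenerate likelihoods)");
    const double inv = 1.0 / z;
    double* as = &alpha[(size_t)s * HH];
    for (int i = 0; i < HH; i++) {
      cur[i] *= inv;
      as[i] = cur[i];
    }
    loglik += std::log(z);
    std::swap(prev, cur);
  }

  // backward pass (on the same scaling), genotype posteriors per site
  NumericMatrix post(S, 3);
  std::vector<double> beta(HH, 1.0), bnext(HH), Bw(HH);
  for (int s = S - 1; s >= 0; s--) {
    const int* ts = &tbuf[(size_t)s * H];
    const double* es = &ec[(size_t)s * 3];
    // gamma = alpha * beta, grouped by template-allele class
    double gcls[3] = {0.0, 0.0, 0.0};
    const double* as = &alpha[(size_t)s * HH];
    for (int k1 = 0; k1 < H; k1++) {
      const int t1 = ts[k1];
      const double* ar = &as[k1 * H];
      const double* br = &beta[k1 * H];
      for (int k2 = 0; k2 < H; k2++)
        gcls[t1 + ts[k2]] += ar[k2] * br[k2];
    }
    double gz = gcls[0] + gcls[1] + gcls[2];
    for (int g = 0; g < 3; g++) {
      double p = 0.0;
      for (int c = 0; c < 3; c++)
        if (es[c] > 0)
          p += (gcls[c] / gz) * (w[c][g] * lik(s, g) / es[c]);
      post(s, g) = p;
    }
    double psum = post(s, 0) + post(s, 1) + post(s, 2);
    for (int g = 0; g < 3; g++) post(s, g) /= psum;

    if (s == 0) break;
    // recurse: beta_{s-1}(j) = sum_k T(j->k) E_k(s) beta_s(k)
    std::fill(row1.begin(), row1.end(), 0.0);
    std::fill(row2.begin(), row2.end(), 0.0);
    double tot = 0.0;
    for (int k1 = 0; k1 < H; k1++) {
      const int t1 = ts[k1];
      double* bw = &Bw[k1 * H];
      const double* br = &beta[k1 * H];
      double acc = 0.0;
      for (int k2 = 0; k2 < H; k2++) {
        double b = es[t1 + ts[k2]] * br[k2];
        bw[k2] = b;
        acc += b;
        row2[k2] += b;
      }
      row1[k1] = acc;
      tot += acc;
    }
    double bz = 0.0;
    for (int j1 = 0; j1 < H; j1++) {
      const double* bw = &Bw[j1 * H];
      double* bn = &bnext[j1 * H];
      const double r1 = stay * sw * row1[j1];
      for (int j2 = 0; j2 < H; j2++) {
        bn[j2] = stay * stay * bw[j2] + r1 + stay * sw * row2[j2] +
                 sw * sw * tot;
        bz += bn[j2];
      }
    }
    // renormalise so products with the scaled alphas stay O(1)
    const double binv = HH / bz;
    for (int i = 0; i < HH; i++) bnext[i] *= binv;
    std::swap(beta, bnext);
  }

  IntegerMatrix path;
  IntegerVector h1, h2;
  if (sample_path) {
    path = IntegerMatrix(S, 2);
    h1 = IntegerVector(S);
    h2 = IntegerVector(S);
    // sample final state from alpha_S
    const double* aS = &alpha[(size_t)(S - 1) * HH];
    double u = R::unif_rand();
    double acc = 0.0;
    int cur_state = HH - 1;
    for (int i = 0; i < HH; i++) {
      acc += aS[i];
      if (u <= acc) { cur_state = i; break; }
    }
    int k1 = cur_state / H, k2 = cur_state % H;
    path(S - 1, 0) = k1 + 1; path(S - 1, 1) = k2 + 1;
    for (int s = S - 2; s >= 0; s--) {
      const double* as = &alpha[(size_t)s * HH];
      // P(state_s = (j1,j2) | rest) propto alpha_s(j1,j2) T(j1->k1) T(j2->k2)
      double tot2 = 0.0;
      for (int j1 = 0; j1 < H; j1++) {
        const double t1w = (j1 == k1 ? stay + sw : sw);
        const double* ar = &as[j1 * H];
        double* wr = &wgt[j1 * H];
        for (int j2 = 0; j2 < H; j2++) {
          double v = ar[j2] * t1w * (j2 == k2 ? stay + sw : sw);
          wr[j2] = v;
          tot2 += v;
        }
      }
      u = R::unif_rand() * tot2;
      acc = 0.0;
      cur_state = HH - 1;
      for (int i = 0; i < HH; i++) {
        acc += wgt[i];
        if (u <= acc) { cur_state = i; break; }
      }
      k1 = cur_state / H; k2 = cur_state % H;
      path(s, 0) = k1 + 1; path(s, 1) = k2 + 1;
    }
    // sample the carried alleles given the path and the data:
    // P(x1, x2) propto P(x1 | a1) P(x2 | a2) L(x1 + x2)
    for (int s = 0; s < S; s++) {
      int a1 = tbuf[(size_t)s * H + (path(s, 0) - 1)];
      int a2 = tbuf[(size_t)s * H + (path(s, 1) - 1)];
      double p1[2] = {a1 ? terr : 1 - terr, a1 ? 1 - terr : terr};
      double p2[2] = {a2 ? terr : 1 - terr, a2 ? 1 - terr : terr};
      double pw[4];
      double tw = 0.0;
      for (int x1 = 0; x1 < 2; x1++)
        for (int x2 = 0; x2 < 2; x2++) {
          double v = p1[x1] * p2[x2] * lik(s, x1 + x2);
          pw[x1 * 2 + x2] = v; tw += v;
        }
      if (tw <= 0) { h1[s] = a1; h2[s] = a2; continue; }
      u = R::unif_rand() * tw;
      acc = 0.0;
      int pick = 3;
      for (int i = 0; i < 4; i++) {
        acc += pw[i];
        if (u <= acc) { pick = i; break; }
      }
      h1[s] = pick / 2; h2[s] = pick % 2;
    }
  }

  List out = List::create(_["post"] = post, _["loglik"] = loglik);
  if (sample_path) {
    out["path"] = path; out["h1"] = h1; out["h2"] = h2;
  }
  return out;
}
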