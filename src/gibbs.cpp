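#include <Rcpp.h>
using namespace Rcpp;

// Palindromic zero-or-one-occupancy Gibbs sampler over a set of regions.
//
// regions: list of integer vectors with base codes 0..3 (A,C,G,T); codes
//   outside that range (ambiguous bases) make a window unusable.
// width: motif width (even when palindromic).
// nIter / burnIn: sweeps per chain and discarded prefix.
// bg: background base probabilities (length 4).
// pseudoTotal: total Dirichlet pseudo-observations per motif column,
//   spread as bg * pseudoTotal.
// logOccOdds: log prior odds of a site starting at any given window
//   versus that window staying empty (site-sampler parameterization:
//   pi/(1-pi) with pi = expected sites / total windows). Under the
//   zero-or-one-per-region truncation, window j is weighted
//   exp(logOccOdds + score_j) against weight 1 for an empty region.
// palindromic: average the count matrix with its reverse complement when
//   computing the predictive distribution.
//
// Returns an integer matrix (nIter - burnIn) x nRegions: 0 = region
// unoccupied in that sweep, otherwise the 1-based window start.
// Uses R's RNG, so results are reproducible under set.seed().

// [[Rcpp::export(name = ".gibbsChain")]]
IntegerMatrix gibbsChain(List regions, int width, int nIter, int burnIn,
                         NumericVector bg, double pseudoTotal,
                         double logOccOdds, bool palindromic) {
  const int nReg = regions.size();
  std::vector<std::vector<int>> seqs(nReg);
  std::vector<int> nWin(nReg);
  for (int i = 0; i < nReg; ++i) {
    IntegerVector v = regions[i];
    seqs[i].assign(v.begin(), v.end());
    nWin[i] = (int)seqs[i].size() - width + 1;
    if (nWin[i] < 1) stop("region shorter than motif width");
  }

  // counts[b + 4*k] over current site assignments
  std::vector<double> counts(4 * width, 0.0);
  std::vector<int> a(nReg, 0); // 0 = none, else 1-based start
  int nPlaced = 0;

  auto addSite = [&](int i, int start1, double sign) {
    const int s0 = start1 - 1;
    for (int k = 0; k < width; ++k) {
      int b = seqs[i][s0 + k];
      if (b >= 0 && b < 4) counts[b + 4 * k] += sign;
    }
  };

  // initialize: every region occupied at a random start
  for (int i = 0; i < nReg; ++i) {
    a[i] = 1 + (int)(unif_rand() * nWin[i]);
    if (a[i] > nWin[i]) a[i] = nWin[i];
    addSite(i, a[i], 1.0);
    ++nPlaced;
  }

  IntegerMatrix samples(nIter - burnIn, nReg);
  std::vector<double> theta(4 * width);
  std::vector<double> logw;

  // Collapsed score of a full site configuration: palindrome-symmetrized
  // Dirichlet-multinomial marginal of the count matrix minus the
  // background likelihood of the covered bases. Used by the phase-shift
  // move to compare whole-register translations of the site set.
  auto configScore = [&](const std::vector<int>& starts) {
    std::vector<double> c(4 * width, 0.0);
    double bgLik = 0.0;
    double nSites = 0.0;
    for (int i = 0; i < nReg; ++i) {
      if (starts[i] <= 0) continue;
      ++nSites;
      for (int k = 0; k < width; ++k) {
        int b = seqs[i][starts[i] - 1 + k];
        if (b >= 0 && b < 4) { c[b + 4 * k] += 1.0; bgLik += std::log(bg[b]); }
      }
    }
    double lp = 0.0;
    for (int k = 0; k < width; ++k) {
      for (int b = 0; b < 4; ++b) {
        double cs = 0.5 * (c[b + 4 * k] + c[(3 - b) + 4 * (width - 1 - k)]);
        if (!palindromic) cs = c[b + 4 * k];
        lp += std::lgamma(cs + bg[b] * pseudoTotal) -
          std::lgamma(bg[b] * pseudoTotal);
      }
      lp -= std::lgamma(nSites + pseudoTotal) - std::lgamma(pseudoTotal);
    }
    return lp - bgLik;
  };

  for (int iter = 0; iter < nIter; ++iter) {
    for (int i = 0; i < nReg; ++i) {
      if (a[i] > 0) { addSite(i, a[i], -1.0); --nPlaced; }

      // predictive motif model from the remaining sites
      double nEff = (double)nPlaced;
      for (int k = 0; k < width; ++k) {
        for (int b = 0; b < 4; ++b) {
          double c = counts[b + 4 * k];
          if (palindromic) {
            // reverse complement: base 3-b, column width-1-k
            c = 0.5 * (c + counts[(3 - b) + 4 * (width - 1 - k)]);
          }
          theta[b + 4 * k] =
            std::log((c + bg[b] * pseudoTotal) / (nEff + pseudoTotal)) -
            std::log(bg[b]);
        }
      }

      const int nw = nWin[i];
      logw.assign(nw + 1, 0.0);
      logw[0] = 0.0;
      for (int j = 0; j < nw; ++j) {
        double s = logOccOdds;
        bool usable = true;
        for (int k = 0; k < width; ++k) {
          int b = seqs[i][j + k];
          if (b < 0 || b > 3) { usable = false; break; }
          s += theta[b + 4 * k];
        }
        logw[j + 1] = usable ? s : -1e300;
      }

      double mx = logw[0];
      for (int j = 1; j <= nw; ++j) if (logw[j] > mx) mx = logw[j];
      double tot = 0.0;
      for (int j = 0; j <= nw; ++j) { logw[j] = std::exp(logw[j] - mx); tot += logw[j]; }
      double u = unif_rand() * tot;
      int pick = 0;
      double acc = 0.0;
      for (int j = 0; j <= nw; ++j) {
        acc += logw[j];
        if (u <= acc) { pick = j; break; }
        if (j == nw) pick = nw;
      }

      a[i] = pick; // 0 = unoccupied
      if (a[i] > 0) { addSite(i, a[i], 1.0); ++nPlaced; }
    }
    // phase-shift move: translate every placed site by k in {-5..5},
    // sampled proportionally to the collapsed configuration score
    // (escapes shifted-register local optima that per-region resampling
    // cannot leave; self-similar palindromes make registers several bp
    // apart locally optimal, so the range exceeds the self-overlap
    // periods seen in 14-bp sites)
    {
      const int kmax = 5;
      std::vector<int> shifts;
      std::vector<double> sc;
      for (int k = -kmax; k <= kmax; ++k) {
        bool ok = true;
        for (int i = 0; i < nReg; ++i)
          if (a[i] > 0 && (a[i] + k < 1 || a[i] + k > nWin[i])) {
            ok = false;
            break;
          }
        if (!ok) continue;
        std::vector<int> cand(a);
        for (int i = 0; i < nReg; ++i) if (cand[i] > 0) cand[i] += k;
        shifts.push_back(k);
        sc.push_back(configScore(cand));
      }
      double mx = sc[0];
      for (double v : sc) if (v > mx) mx = v;
      double tot = 0.0;
      for (double& v : sc) { v = std::exp(v - mx); tot += v; }
      double u = unif_rand() * tot, acc = 0.0;
      int pick = 0;
      for (size_t j = 0; j < sc.size(); ++j) {
        acc += sc[j];
        if (u <= acc) { pick = (int)j; break; }
      }
      const int k = shifts[pick];
      if (k != 0) {
        for (int i = 0; i < nReg; ++i)
          if (a[i] > 0) { addSite(i, a[i], -1.0); a[i] += k; addSite(i, a[i], 1.0); }
      }
    }

    if (iter >= burnIn)
      for (int i = 0; i < nReg; ++i) samples(iter - burnIn, i) = a[i];
  }
  return samples;
}
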