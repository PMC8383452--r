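#include <Rcpp.h>
using namespace Rcpp;

// Single chain of the Metropolis-within-Gibbs sampler for the BYM model:
//   O_i ~ Poisson(E_i * exp(c + beta*x_i + u_i + v_i))
//   u   ~ intrinsic CAR (pairwise-difference prior, sum-to-zero per
//         connected component; isolated areas have u_i fixed at 0)
//   v_i ~ N(0, 1/tauV);  tauU, tauV ~ Gamma(shape, rate) [conjugate]
//   c, beta ~ flat on the real line
// Random-walk Metropolis for c, beta and each u_i, v_i; step sizes adapted
// toward 30-45% acceptance during burn-in only. Uses R's RNG so set.seed()
// in R makes chains reproducible.

static inline double rw_step(double cur) { return cur * R::norm_rand(); }

// [[Rcpp::export(name = ".bymChain")]]
List bymChain(IntegerVector obs, NumericVector expct, NumericVector x,
              bool useBeta, List adj, IntegerVector isIso,
              int rankU, int nIter, int burnIn, int thin,
              double hyperShape, double hyperRate,
              IntegerVector compId, int nComp,
              double c0, double beta0, double tauU0, double tauV0) {
  const int n = obs.size();
  double c = c0, beta = beta0, tauU = tauU0, tauV = tauV0;
  NumericVector u(n, 0.0), v(n, 0.0), eta(n);
  std::vector<std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector a = adj[i];
    nb[i].assign(a.begin(), a.end());
    for (size_t k = 0; k < nb[i].size(); ++k) nb[i][k] -= 1; // 0-based
  }
  for (int i = 0; i < n; ++i)
    eta[i] = c + (useBeta ? beta * x[i] : 0.0) + u[i] + v[i];

  // step sizes + acceptance bookkeeping
  NumericVector su(n, 0.5), sv(n, 0.5);
  double sc = 0.1, sb = 0.05;
  std::vector<int> accU(n, 0), accV(n, 0);
  int accC = 0, accB = 0, winLen = 100;
  long totAccU = 0, totAccV = 0, totAccC = 0, totAccB = 0, nPost = 0;

  const int nKeep = (nIter - burnIn) / thin;
  NumericVector cDraws(nKeep), betaDraws(useBeta ? nKeep : 0),
      tauUDraws(nKeep), tauVDraws(nKeep);
  NumericMatrix uDraws(nKeep, n), vDraws(nKeep, n);
  int keep = 0;

  // per-component member lists for the recentring step
  std::vector<std::vector<int> > compMembers(nComp);
  for (int i = 0; i < n; ++i)
    if (!isIso[i]) compMembers[compId[i] - 1].push_back(i);

  for (int it = 0; it < nIter; ++it) {
    // --- structured effects u_i (non-isolated only) ---
    for (int i = 0; i < n; ++i) {
      if (isIso[i]) continue;
      double prop = u[i] + rw_step(su[i]);
      double du = prop - u[i];
      double dprior = 0.0;
      for (size_t k = 0; k < nb[i].size(); ++k) {
        double dj = u[nb[i][k]];
        dprior += (prop - dj) * (prop - dj) - (u[i] - dj) * (u[i] - dj);
      }
      double etaNew = eta[i] + du;
      double dll = obs[i] * du - expct[i] * (std::exp(etaNew) - std::exp(eta[i]));
      double logA = dll - 0.5 * tauU * dprior;
      if (std::log(R::unif_rand()) < logA) {
        u[i] = prop; eta[i] = etaNew; accU[i]++;
        if (it >= burnIn) totAccU++;
      }
    }
    // recentre u to sum zero within each connected component (GeoBUGS-style
    // identifiability constraint); eta tracks the shift
    for (int g = 0; g < nComp; ++g) {
      double m = 0.0;
      const std::vector<int> &mem = compMembers[g];
      for (size_t k = 0; k < mem.size(); ++k) m += u[mem[k]];
      m /= mem.size();
      for (size_t k = 0; k < mem.size(); ++k) { u[mem[k]] -= m; eta[mem[k]] -= m; }
    }
    // --- unstructured effects v_i ---
    for (int i = 0; i < n; ++i) {
      double prop = v[i] + rw_step(sv[i]);
      double dv = prop - v[i];
      double etaNew = eta[i] + dv;
      double dll = obs[i] * dv - expct[i] * (std::exp(etaNew) - std::exp(eta[i]));
      double logA = dll - 0.5 * tauV * (prop * prop - v[i] * v[i]);
      if (std::log(R::unif_rand()) < logA) {
        v[i] = prop; eta[i] = etaNew; accV[i]++;
        if (it >= burnIn) totAccV++;
      }
    }
    // --- intercept c ---
    {
      double dc = rw_step(sc);
      double sumMu = 0.0, sumObs = 0.0;
      for (int i = 0; i < n; ++i) { sumMu += expct[i] * std::exp(eta[i]); sumObs += obs[i]; }
      double logA = sumObs * dc - (std::exp(dc) - 1.0) * sumMu;
      if (std::log(R::unif_rand()) < logA) {
        c += dc; for (int i = 0; i < n; ++i) eta[i] += dc;
        accC++; if (it >= burnIn) totAccC++;
      }
    }
    // --- covariate coefficient beta ---
    if (useBeta) {
      double db = rw_step(sb);
      double logA = 0.0;
      for (int i = 0; i < n; ++i)
        logA += obs[i] * db * x[i] -
                expct[i] * std::exp(eta[i]) * (std::exp(db * x[i]) - 1.0);
      if (std::log(R::unif_rand()) < logA) {
        beta += db; for (int i = 0; i < n; ++i) eta[i] += db * x[i];
        accB++; if (it >= burnIn) totAccB++;
      }
    }
    // --- conjugate precision updates ---
    {
      double ssPair = 0.0;
      for (int i = 0; i < n; ++i)
        for (size_t k = 0; k < nb[i].size(); ++k) {
          int j = nb[i][k];
          if (j > i) { double d = u[i] - u[j]; ssPair += d * d; }
        }
      tauU = R::rgamma(hyperShape + 0.5 * rankU, 1.0 / (hyperRate + 0.5 * ssPair));
      double ssV = 0.0;
      for (int i = 0; i < n; ++i) ssV += v[i] * v[i];
      tauV = R::rgamma(hyperShape + 0.5 * n, 1.0 / (hyperRate + 0.5 * ssV));
    }
    // --- step-size adaptation (burn-in only, frozen afterwards) ---
    if (it < burnIn && (it + 1) % winLen == 0) {
      for (int i = 0; i < n; ++i) {
        double r = accU[i] / (double)winLen;
        if (r > 0.45) su[i] *= 1.2; else if (r < 0.30) su[i] *= 0.8;
        su[i] = std::min(std::max(su[i], 1e-3), 10.0); accU[i] = 0;
        r = accV[i] / (double)winLen;
        if (r > 0.45) sv[i] *= 1.2; else if (r < 0.30) sv[i] *= 0.8;
        sv[i] = std::min(std::max(sv[i], 1e-3), 10.0); accV[i] = 0;
      }
      double r = accC / (double)winLen;
      if (r > 0.45) sc *= 1.2; else if (r < 0.30) sc *= 0.8;
      sc = std::min(std::max(sc, 1e-3), 10.0); accC = 0;
      r = accB / (double)winLen;
      if (r > 0.45) sb *= 1.2; else if (r < 0.30) sb *= 0.8;
      sb = std::min(std::max(sb, 1e-3), 10.0); accB = 0;
    }
    if (it >= burnIn) {
      nPost++;
      if ((it - burnIn) % thin == 0 && keep < nKeep) {
        cDraws[keep] = c;
        if (useBeta) betaDraws[keep] = beta;
        tauUDraws[keep] = tauU; tauVDraws[keep] = tauV;
        for (int i = 0; i < n; ++i) { uDraws(keep, i) = u[i]; vDraws(keep, i) = v[i]; }
        keep++;
      }
    }
  }
  int nIsoFree = 0;
  for (int i = 0; i < n; ++i) if (!isIso[i]) nIsoFree++;
  double denomU = (double)nPost * std::max(nIsoFree, 1);
  return List::create(
      _["c"] = cDraws, _["beta"] = betaDraws,
      _["u"] = uDraws, _["v"] = vDraws,
      _["tauU"] = tauUDraws, _["tauV"] = tauVDraws,
      _["accept"] = NumericVector::create(
          _["u"] = nIsoFree ? totAccU / denomU : NA_REAL,
          _["v"] = totAccV / ((double)nPost * n),
          _["c"] = totAccC / (double)nPost,
          _["beta"] = useBeta ? totAccB / (double)nPost : NA_REAL));
}
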