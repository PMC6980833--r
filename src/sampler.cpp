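#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// stable log(1 + exp(x))
static inline double log1pexp_c(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double dnorm_log(double x, double m, double s) {
  static const double LN_SQRT_2PI = 0.9189385332046727;
  double z = (x - m) / s;
  return -LN_SQRT_2PI - std::log(s) - 0.5 * z * z;
}

struct Adapt {
  double step;
  int acc, att;
  Adapt() : step(0.5), acc(0), att(0) {}
  void tune() {
    if (att == 0) return;
    double rate = (double)acc / att;
    if (rate < 0.30) step *= 0.8;
    else if (rate > 0.45) step *= 1.25;
    acc = 0; att = 0;
  }
};

// One adaptive Metropolis-within-Gibbs chain for the hierarchical
// Bernoulli-logit detection model. The linear predictor eta is cached and
// updated incrementally: each scalar's proposal touches only the rows it
// enters. Step sizes adapt toward 30-45% acceptance during burn-in, then
// freeze. Hyper-means are updated by conjugate Gibbs draws; SDs by
// random-walk on the log scale with Jacobian, reflected at log(10).
// [[Rcpp::export]]
List run_chain_cpp(IntegerVector y, IntegerVector sp, IntegerVector scat,
                   NumericMatrix PR, NumericVector deg, NumericVector ind,
                   int S, int nScat, int nIter, int nBurn, int thin,
                   List init, bool hierarchical, bool randomEffect,
                   bool monitorAlpha, int adaptInterval) {
  const int n = y.size();
  const double L10 = std::log(10.0);

  // state
  NumericMatrix beta0 = clone(as<NumericMatrix>(init["beta"])); // 5 x S
  double b5 = as<double>(init["beta5"]);
  double b6 = as<double>(init["beta6"]);
  NumericVector alpha = clone(as<NumericVector>(init["alpha"]));
  NumericVector mu = clone(as<NumericVector>(init["mu"]));
  NumericVector sig = clone(as<NumericVector>(init["sigma"]));
  double sigA = as<double>(init["sigma_alpha"]);

  std::vector<std::vector<int> > rowsSp(S), rowsScat(nScat);
  std::vector<int> rowsInd, rowsDeg;
  for (int r = 0; r < n; ++r) {
    rowsSp[sp[r]].push_back(r);
    if (randomEffect) rowsScat[scat[r]].push_back(r);
    if (ind[r] != 0.0) rowsInd.push_back(r);
    if (deg[r] != 0.0) rowsDeg.push_back(r);
  }

  // cached linear predictor
  std::vector<double> eta(n);
  for (int r = 0; r < n; ++r) {
    int s = sp[r];
    double e = beta0(0, s);
    for (int k = 1; k < 5; ++k) e += beta0(k, s) * PR(r, k - 1);
    e += b5 * deg[r] + b6 * ind[r];
    if (randomEffect) e += alpha[scat[r]];
    eta[r] = e;
  }

  // adaptive step sizes
  std::vector<Adapt> adBeta(5 * S), adAlpha(nScat), adSig(5);
  Adapt adB5, adB6, adSigA;

  std::vector<double> etaScratch(n);

  // scalar MH helper: proposes `prop` for a coefficient with covariate
  // column `xcol` over a row set, prior log-density difference supplied by
  // the caller; on acceptance the cached eta rows are updated.
  // xcol: -1 -> covariate 1 (intercept/alpha), 0..3 -> PR column,
  //        4 -> degradation, 5 -> individual
  auto rowCov = [&](int r, int xcol) -> double {
    if (xcol < 0) return 1.0;
    if (xcol < 4) return PR(r, xcol);
    if (xcol == 4) return deg[r];
    return ind[r];
  };

  auto mhUpdate = [&](double cur, double prop,
                      const std::vector<int>& rows, int xcol,
                      double dPrior) -> bool {
    double delta = prop - cur;
    double dll = 0.0;
    for (size_t j = 0; j < rows.size(); ++j) {
      int r = rows[j];
      double x = rowCov(r, xcol);
      double en = eta[r] + delta * x;
      etaScratch[j] = en;
      dll += (y[r] ? delta * x : 0.0) - log1pexp_c(en) + log1pexp_c(eta[r]);
    }
    if (std::log(unif_rand()) < dll + dPrior) {
      for (size_t j = 0; j < rows.size(); ++j) eta[rows[j]] = etaScratch[j];
      return true;
    }
    return false;
  };

  // monitored columns
  int nMon = 5 * S + 2;
  if (hierarchical) nMon += 10;
  if (randomEffect) nMon += 1;
  if (monitorAlpha) nMon += nScat;
  int nSave = 0;
  for (int t = nBurn + 1; t <= nIter; ++t)
    if ((t - nBurn - 1) % thin == 0) ++nSave;
  NumericMatrix draws(nSave, nMon);
  int saveRow = 0;

  long accPost = 0, attPost = 0;

  for (int t = 1; t <= nIter; ++t) {
    bool adapting = (t <= nBurn);

    // species-indexed coefficients
    for (int k = 0; k < 5; ++k) {
      for (int s = 0; s < S; ++s) {
        Adapt& ad = adBeta[k * S + s];
        double cur = beta0(k, s);
        double prop = cur + ad.step * norm_rand();
        double dPrior = hierarchical
          ? dnorm_log(prop, mu[k], sig[k]) - dnorm_log(cur, mu[k], sig[k])
          : dnorm_log(prop, 0.0, 10.0) - dnorm_log(cur, 0.0, 10.0);
        bool ok = mhUpdate(cur, prop, rowsSp[s], k - 1, dPrior);
        if (ok) beta0(k, s) = prop;
        ad.att++; if (ok) ad.acc++;
        if (!adapting) { attPost++; if (ok) accPost++; }
        if (adapting && ad.att >= adaptInterval) ad.tune();
      }
    }

    // degradation coefficient (touches rows with deg != 0)
    {
      double cur = b5, prop = cur + adB5.step * norm_rand();
      double dPrior = dnorm_log(prop, 0.0, 10.0) - dnorm_log(cur, 0.0, 10.0);
      bool ok = mhUpdate(cur, prop, rowsDeg, 4, dPrior);
      if (ok) b5 = prop;
      adB5.att++; if (ok) adB5.acc++;
      if (!adapting) { attPost++; if (ok) accPost++; }
      if (adapting && adB5.att >= adaptInterval) adB5.tune();
    }
    // individual coefficient (touches rows with ind != 0)
    {
      double cur = b6, prop = cur + adB6.step * norm_rand();
      double dPrior = dnorm_log(prop, 0.0, 10.0) - dnorm_log(cur, 0.0, 10.0);
      bool ok = mhUpdate(cur, prop, rowsInd, 5, dPrior);
      if (ok) b6 = prop;
      adB6.att++; if (ok) adB6.acc++;
      if (!adapting) { attPost++; if (ok) accPost++; }
      if (adapting && adB6.att >= adaptInterval) adB6.tune();
    }

    if (randomEffect) {
      // per-scat random effects
      for (int i = 0; i < nScat; ++i) {
        Adapt& ad = adAlpha[i];
        double cur = alpha[i];
        double prop = cur + ad.step * norm_rand();
        double dPrior = dnorm_log(prop, 0.0, sigA) - dnorm_log(cur, 0.0, sigA);
        bool ok = mhUpdate(cur, prop, rowsScat[i], -1, dPrior);
        if (ok) alpha[i] = prop;
        ad.att++; if (ok) ad.acc++;
        if (!adapting) { attPost++; if (ok) accPost++; }
        if (adapting && ad.att >= adaptInterval) ad.tune();
      }
      // sigma_alpha: log-scale RW with Jacobian, reflected at log(10)
      {
        double l = std::log(sigA);
        double lp = l + adSigA.step * norm_rand();
        while (lp > L10) lp = 2.0 * L10 - lp;
        double sigP = std::exp(lp);
        double dlt = lp - l; // Jacobian
        for (int i = 0; i < nScat; ++i)
          dlt += dnorm_log(alpha[i], 0.0, sigP) -
                 dnorm_log(alpha[i], 0.0, sigA);
        bool ok = std::log(unif_rand()) < dlt;
        if (ok) sigA = sigP;
        adSigA.att++; if (ok) adSigA.acc++;
        if (!adapting) { attPost++; if (ok) accPost++; }
        if (adapting && adSigA.att >= adaptInterval) adSigA.tune();
      }
    }

    if (hierarchical) {
      for (int k = 0; k < 5; ++k) {
        // conjugate Gibbs draw for the hyper-mean
        double sig2 = sig[k] * sig[k];
        double postVar = 1.0 / (S / sig2 + 1.0 / 100.0);
        double sum = 0.0;
        for (int s = 0; s < S; ++s) sum += beta0(k, s);
        double postMean = postVar * sum / sig2;
        mu[k] = postMean + std::sqrt(postVar) * norm_rand();

        // hyper-SD: log-scale RW with Jacobian, reflected at log(10)
        double l = std::log(sig[k]);
        double lp = l + adSig[k].step * norm_rand();
        while (lp > L10) lp = 2.0 * L10 - lp;
        double sigP = std::exp(lp);
        double dlt = lp - l;
        for (int s = 0; s < S; ++s)
          dlt += dnorm_log(beta0(k, s), mu[k], sigP) -
                 dnorm_log(beta0(k, s), mu[k], sig[k]);
        bool ok = std::log(unif_rand()) < dlt;
        if (ok) sig[k] = sigP;
        adSig[k].att++; if (ok) adSig[k].acc++;
        if (!adapting) { attPost++; if (ok) accPost++; }
        if (adapting && adSig[k].att >= adaptInterval) adSig[k].tune();
      }
    }

    // store
    if (t > nBurn && (t - nBurn - 1) % thin == 0) {
      int c = 0;
      for (int k = 0; k < 5; ++k)
        for (int s = 0; s < S; ++s) draws(saveRow, c++) = beta0(k, s);
      draws(saveRow, c++) = b5;
      draws(saveRow, c++) = b6;
      if (hierarchical) {
        for (int k = 0; k < 5; ++k) draws(saveRow, c++) = mu[k];
        for (int k = 0; k < 5; ++k) draws(saveRow, c++) = sig[k];
      }
      if (randomEffect) draws(saveRow, c++) = sigA;
      if (monitorAlpha)
        for (int i = 0; i < nScat; ++i) draws(saveRow, c++) = alpha[i];
      ++saveRow;
    }
  }

  return List::create(
    _["draws"] = draws,
    _["acceptance_rate"] = attPost > 0 ? (double)accPost / attPost
                                       : NA_REAL);
}
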