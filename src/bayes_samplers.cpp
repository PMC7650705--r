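#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs samplers for whole-genome marker-effect regression
//   y_i = mu + sum_j w_ij g_j + e_i,  e ~ N(0, I sigma_e^2)
// with the four prior hierarchies of the Bayesian alphabet:
//   model 0 (Bayes A):     g_j ~ N(0, s2_j),  s2_j ~ scaled-inv-chi2(nu, S)
//   model 1 (Bayes B):     as A but effect present with prob 1 - pi (pi fixed)
//   model 2 (Bayes C):     as B with a common s2 across markers and
//                          pi ~ uniform(0, 1) updated from the data
//   model 3 (Bayes Lasso): g_j ~ N(0, tau2_j), tau2_j ~ Exp(lambda2 / 2),
//                          lambda2 ~ Gamma(a, b)
// W columns are centered genotype codes; R's RNG is used throughout so a
// set.seed() in R makes chains bit-reproducible.

static double rinvgauss(double mu, double lambda) {
  double z = norm_rand();
  double v = z * z;
  double x = mu + mu * mu * v / (2.0 * lambda) -
    mu / (2.0 * lambda) * std::sqrt(4.0 * mu * lambda * v + mu * mu * v * v);
  if (x <= 0) x = 1e-12;
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// [[Rcpp::export(name = ".bayes_gibbs_cpp")]]
List bayes_gibbs_cpp(NumericVector y, NumericMatrix W, int model,
                     double nu, double S, double piInit, bool piFixed,
                     double aLasso, double bLasso, double lambda2Init,
                     double nuE, double SE,
                     int chainLength, int burnIn, int thin,
                     double fixMarkerVar, double fixSigmaE) {
  const int n = y.size();
  const int m = W.ncol();
  const bool varFixed = R_finite(fixMarkerVar);
  const bool eFixed = R_finite(fixSigmaE);
  const bool pointMass = (model == 1 || model == 2);

  std::vector<double> xx(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    const double *wj = &W(0, j);
    for (int i = 0; i < n; ++i) s += wj[i] * wj[i];
    xx[j] = s;
  }

  double mu = mean(y);
  std::vector<double> g(m, 0.0);
  std::vector<int> del(m, pointMass ? 0 : 1);
  double priorMeanVar = (nu > 2.0) ? nu * S / (nu - 2.0) : S;
  std::vector<double> s2(m, varFixed ? fixMarkerVar : priorMeanVar);
  double s2common = varFixed ? fixMarkerVar : priorMeanVar; // Bayes C
  double lambda2 = lambda2Init;
  std::vector<double> tau2(m, varFixed ? fixMarkerVar
                                       : (lambda2 > 0 ? 2.0 / lambda2 : 1.0));
  double vy = var(y);
  if (!(vy > 0)) vy = 1e-6;
  double sigmaE2 = eFixed ? fixSigmaE : vy * 0.5;
  double piZero = piInit;

  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  // accumulators over saved samples
  std::vector<double> gSum(m, 0.0), dSum(m, 0.0);
  std::vector<double> gvSum(n, 0.0), gvSq(n, 0.0);
  std::vector<double> gvH1(n, 0.0), gvH2(n, 0.0);
  double muSum = 0, se2Sum = 0, piSum = 0, lamSum = 0;
  int nSave = 0;
  const int totSave = (chainLength - burnIn + thin - 1) / thin;
  const int half1 = totSave / 2;
  int saveIdx = 0;

  for (int it = 0; it < chainLength; ++it) {
    // intercept
    double se_ = 0.0;
    for (int i = 0; i < n; ++i) se_ += e[i];
    double muNew = mu + se_ / n + norm_rand() * std::sqrt(sigmaE2 / n);
    double dmu = muNew - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    mu = muNew;

    int mIn = 0;
    double ssIn = 0.0; // sum g^2 over included (Bayes C)

    for (int j = 0; j < m; ++j) {
      if (xx[j] <= 0) { g[j] = 0; del[j] = 0; continue; }
      const double *wj = &W(0, j);
      double r = 0.0;
      for (int i = 0; i < n; ++i) r += wj[i] * e[i];
      r += xx[j] * g[j]; // g[j] is 0 when currently excluded

      double varj = (model == 2) ? s2common : (model == 3 ? tau2[j] : s2[j]);
      int include = 1;
      if (pointMass) {
        if (piZero >= 1.0) include = 0;
        else if (piZero <= 0.0) include = 1;
        else {
          double v0 = sigmaE2 * xx[j];
          double v1 = v0 + xx[j] * xx[j] * varj;
          double logOdds = std::log(1.0 - piZero) - std::log(piZero) +
            0.5 * (std::log(v0) - std::log(v1)) +
            0.5 * r * r * (1.0 / v0 - 1.0 / v1);
          double pIncl = 1.0 / (1.0 + std::exp(-logOdds));
          include = (unif_rand() < pIncl) ? 1 : 0;
        }
      }

      double gNew = 0.0;
      if (include) {
        double C = xx[j] + sigmaE2 / varj;
        gNew = r / C + norm_rand() * std::sqrt(sigmaE2 / C);
      }
      double diff = g[j] - gNew;
      if (diff != 0.0)
        for (int i = 0; i < n; ++i) e[i] += wj[i] * diff;
      g[j] = gNew;
      del[j] = include;
      if (include) { ++mIn; ssIn += gNew * gNew; }

      // per-marker variance updates
      if (!varFixed) {
        if (model == 0) {
          s2[j] = (g[j] * g[j] + nu * S) / Rf_rchisq(nu + 1.0);
        } else if (model == 1) {
          s2[j] = include ? (g[j] * g[j] + nu * S) / Rf_rchisq(nu + 1.0)
                          : nu * S / Rf_rchisq(nu);
        } else if (model == 3) {
          double g2 = g[j] * g[j];
          if (g2 < 1e-12) {
            tau2[j] = Rf_rexp(2.0 / lambda2); // prior draw, Exp(lambda2/2)
          } else {
            double chi = rinvgauss(std::sqrt(lambda2 / g2), lambda2);
            tau2[j] = 1.0 / chi;
          }
        }
      }
    }

    if (model == 2 && !varFixed)
      s2common = (ssIn + nu * S) / Rf_rchisq(nu + mIn);
    if (model == 2 && !piFixed)
      piZero = Rf_rbeta(m - mIn + 1.0, mIn + 1.0);
    if (model == 3 && !varFixed) {
      double st = 0.0;
      for (int j = 0; j < m; ++j) st += tau2[j];
      lambda2 = Rf_rgamma(aLasso + m, 1.0 / (bLasso + 0.5 * st));
    }

    if (!eFixed) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      sigmaE2 = (sse + nuE * SE) / Rf_rchisq(n + nuE);
    }
    if (!R_finite(sigmaE2) || sigmaE2 <= 0)
      stop("Gibbs chain diverged: non-finite residual variance at iteration %d "
           "(mu=%g, pi=%g)", it + 1, mu, piZero);

    if (it >= burnIn && ((it - burnIn) % thin == 0)) {
      ++nSave;
      muSum += mu; se2Sum += sigmaE2; piSum += piZero;
      lamSum += std::sqrt(lambda2);
      for (int j = 0; j < m; ++j) {
        gSum[j] += g[j];
        dSum[j] += del[j];
      }
      for (int i = 0; i < n; ++i) {
        double gv = y[i] - mu - e[i];
        gvSum[i] += gv; gvSq[i] += gv * gv;
        if (saveIdx < half1) gvH1[i] += gv; else gvH2[i] += gv;
      }
      ++saveIdx;
    }
  }

  NumericVector gMean(m), dMean(m), gvMean(n), gvSD(n), h1(n), h2(n);
  for (int j = 0; j < m; ++j) {
    gMean[j] = gSum[j] / nSave;
    dMean[j] = dSum[j] / nSave;
  }
  int nH2 = nSave - half1;
  for (int i = 0; i < n; ++i) {
    gvMean[i] = gvSum[i] / nSave;
    double v = gvSq[i] / nSave - gvMean[i] * gvMean[i];
    gvSD[i] = v > 0 ? std::sqrt(v) : 0.0;
    h1[i] = half1 > 0 ? gvH1[i] / half1 : NA_REAL;
    h2[i] = nH2 > 0 ? gvH2[i] / nH2 : NA_REAL;
  }

  return List::create(
    _["gMean"] = gMean, _["inclusionProb"] = dMean,
    _["mu"] = muSum / nSave, _["sigmaE2"] = se2Sum / nSave,
    _["pi"] = piSum / nSave, _["lambda"] = lamSum / nSave,
    _["fitted"] = gvMean, _["fittedSD"] = gvSD,
    _["halfFitted1"] = h1, _["halfFitted2"] = h2,
    _["nSaved"] = nSave);
}
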