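// Adaptive random-walk Metropolis-within-Gibbs sampler for the nested family
// LLTM / constrained 2PL / MLTM-D / GMLTM-D.
//
// State: theta (N x M abilities), eta (active feature difficulties),
// alpha (G discrimination groups, optional), c (J guessing floors, optional).
// The likelihood is accumulated through two caches kept in sync with the
// state: Lm(i,j,m) = C_jm * log logistic(alpha_jm (theta_im - b_jm)) and
// S(i,j) = sum_m Lm(i,j,m), so each scalar update touches only the cells it
// can change. Proposal scales adapt during warmup by Robbins-Monro toward a
// 0.44 acceptance rate. Randomness comes from R's RNG, so a set.seed() on the
// R side fully determines a chain.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double log_logistic(double x) {
  // log(1/(1+exp(-x))), stable on both tails
  if (x >= 0.0) return -std::log1p(std::exp(-x));
  return x - std::log1p(std::exp(x));
}

static inline double lg1mexp(double s) {
  // log(1 - exp(s)) for s < 0
  if (s > -M_LN2) return std::log(-std::expm1(s));
  return std::log1p(-std::exp(s));
}

static inline double cell_ll(int y, double S, double c) {
  if (y < 0) return 0.0;  // missing
  if (y == 1) {
    if (c <= 0.0) return S;
    return std::log(c + (1.0 - c) * std::exp(S));
  }
  double l0 = lg1mexp(S);
  if (c <= 0.0) return l0;
  return std::log1p(-c) + l0;
}

// in-place lower Cholesky of a symmetric matrix stored row-major in the lower
// triangle; returns false if not positive definite
static bool cholesky(std::vector<double>& Lmat, int D) {
  for (int p = 0; p < D; ++p) {
    for (int r = 0; r <= p; ++r) {
      double s = Lmat[p * D + r];
      for (int k = 0; k < r; ++k) s -= Lmat[p * D + k] * Lmat[r * D + k];
      if (p == r) {
        if (s <= 0.0) return false;
        Lmat[p * D + p] = std::sqrt(s);
      } else {
        Lmat[p * D + r] = s / Lmat[r * D + r];
      }
    }
  }
  return true;
}

struct Adapt {
  double ls;       // log proposal sd
  double target;
  Adapt(double s = 0.0, double t = 0.44) : ls(std::log(s)), target(t) {}
  double sd() const { return std::exp(ls); }
  void update(double acc_prob, double gamma) {
    ls += gamma * (acc_prob - target);
    if (ls < -10.0) ls = -10.0;
    if (ls > 4.0) ls = 4.0;
  }
};

// [[Rcpp::export(name = ".sample_chain")]]
List sample_chain(IntegerMatrix y, IntegerMatrix Q, IntegerMatrix C,
                  IntegerVector etaK, IntegerVector etaM,
                  IntegerMatrix group, int G,
                  bool estAlpha, bool estGuess,
                  List prior, int warmup, int iter, int thin, int structReps,
                  NumericMatrix theta0, NumericVector eta0,
                  NumericVector alpha0, NumericVector guess0) {
  const int N = y.nrow(), J = y.ncol(), M = C.ncol();
  const int nEta = etaK.size();

  const double thMean = as<double>(prior["theta_mean"]);
  const double thSd   = as<double>(prior["theta_sd"]);
  const double etMean = as<double>(prior["eta_mean"]);
  const double etSd   = as<double>(prior["eta_sd"]);
  const double alMean = as<double>(prior["alpha_mean"]);
  const double alSd   = as<double>(prior["alpha_sd"]);
  const double gA     = as<double>(prior["guess_shape1"]);
  const double gB     = as<double>(prior["guess_shape2"]);

  // state
  NumericMatrix theta = clone(theta0);
  std::vector<double> eta(eta0.begin(), eta0.end());
  std::vector<double> alphaG(alpha0.begin(), alpha0.end());
  std::vector<double> cvec(guess0.begin(), guess0.end());

  // composed difficulty b[j + J*m] and expanded discrimination a[j + J*m]
  std::vector<double> b(J * M, 0.0), a(J * M, 0.0);
  for (int e = 0; e < nEta; ++e)
    for (int j = 0; j < J; ++j)
      if (Q(j, etaK[e])) b[j + J * etaM[e]] += eta[e];
  for (int j = 0; j < J; ++j)
    for (int m = 0; m < M; ++m)
      if (C(j, m)) a[j + J * m] = estAlpha ? alphaG[group(j, m) - 1] : 1.0;

  // index lists
  std::vector<std::vector<int>> itemsOfComp(M), itemsOfEta(nEta);
  for (int m = 0; m < M; ++m)
    for (int j = 0; j < J; ++j)
      if (C(j, m)) itemsOfComp[m].push_back(j);
  for (int e = 0; e < nEta; ++e)
    for (int j = 0; j < J; ++j)
      if (Q(j, etaK[e]) && C(j, etaM[e])) itemsOfEta[e].push_back(j);
  std::vector<std::vector<std::pair<int, int>>> cellsOfGroup(G);
  if (estAlpha)
    for (int j = 0; j < J; ++j)
      for (int m = 0; m < M; ++m)
        if (C(j, m)) cellsOfGroup[group(j, m) - 1].push_back({j, m});

  // caches
  std::vector<double> Lm((size_t)N * J * M, 0.0), S((size_t)N * J, 0.0);
  auto lmIdx = [&](int i, int j, int m) { return (size_t)i + (size_t)N * j + (size_t)N * J * m; };
  auto sIdx  = [&](int i, int j) { return (size_t)i + (size_t)N * j; };
  for (int m = 0; m < M; ++m)
    for (int j = 0; j < J; ++j) {
      if (!C(j, m)) continue;
      const double aj = a[j + J * m], bj = b[j + J * m];
      for (int i = 0; i < N; ++i) {
        double v = log_logistic(aj * (theta(i, m) - bj));
        Lm[lmIdx(i, j, m)] = v;
        S[sIdx(i, j)] += v;
      }
    }

  // proposal scales
  std::vector<Adapt> sTheta(M, Adapt(1.0));
  std::vector<Adapt> sEta(nEta, Adapt(0.25));
  std::vector<Adapt> sAlpha(G, Adapt(0.25));
  std::vector<Adapt> sC(J, Adapt(0.15));

  // draw storage
  NumericVector thDraws((size_t)iter * N * M);
  NumericMatrix etDraws(iter, nEta), alDraws(iter, std::max(G, 1)),
                cDraws(iter, J);
  std::vector<double> accTheta(M, 0.0), accEta(nEta, 0.0),
                      accAlpha(G, 0.0), accC(J, 0.0);
  int nKept = 0;

  std::vector<double> newL(J), newLcols((size_t)N * J);

  // structural vector (eta, alpha, c) for the joint adaptive-Metropolis move
  const int D = nEta + (estAlpha ? G : 0) + (estGuess ? J : 0);
  std::vector<double> xCur(D), xProp(D), z(D), dx(D);
  std::vector<double> covMean(D, 0.0), covM2((size_t)D * D, 0.0),
                      cholL((size_t)D * D, 0.0), cholTmp((size_t)D * D, 0.0);
  double covN = 0.0;
  bool haveChol = false;
  Adapt jointScale(2.38 / std::sqrt((double)(D > 0 ? D : 1)), 0.234);
  double accJoint = 0.0;
  std::vector<double> etaP(nEta), alphaP(alphaG.size()), cP(J);
  std::vector<double> bP(J * M, 0.0), aP(J * M, 0.0);
  std::vector<double> SP((size_t)N * J, 0.0), LmP((size_t)N * J * M, 0.0);

  auto packX = [&](std::vector<double>& x) {
    int p = 0;
    for (int e = 0; e < nEta; ++e) x[p++] = eta[e];
    if (estAlpha) for (int g = 0; g < G; ++g) x[p++] = alphaG[g];
    if (estGuess) for (int j = 0; j < J; ++j) x[p++] = cvec[j];
  };
  auto unpackOk = [&](const std::vector<double>& x, std::vector<double>& et,
                      std::vector<double>& al, std::vector<double>& cc) {
    int p = 0;
    for (int e = 0; e < nEta; ++e) et[e] = x[p++];
    if (estAlpha)
      for (int g = 0; g < G; ++g) { al[g] = x[p++]; if (al[g] < 0.0) return false; }
    if (estGuess)
      for (int j = 0; j < J; ++j) {
        cc[j] = x[p++];
        if (cc[j] <= 0.0 || cc[j] >= 1.0) return false;
      }
    if (!estGuess) std::fill(cc.begin(), cc.end(), 0.0);
    return true;
  };
  auto structPrior = [&](const std::vector<double>& et,
                         const std::vector<double>& al,
                         const std::vector<double>& cc) {
    double lp = 0.0;
    for (int e = 0; e < nEta; ++e)
      lp += -0.5 * (et[e] - etMean) * (et[e] - etMean) / (etSd * etSd);
    if (estAlpha)
      for (int g = 0; g < G; ++g)
        lp += -0.5 * (al[g] - alMean) * (al[g] - alMean) / (alSd * alSd);
    if (estGuess)
      for (int j = 0; j < J; ++j)
        lp += (gA - 1.0) * std::log(cc[j]) + (gB - 1.0) * std::log1p(-cc[j]);
    return lp;
  };

  const int total = warmup + iter * thin;
  RNGScope scope;

  for (int t = 0; t < total; ++t) {
    const bool adapting = t < warmup;
    const double gamma =
      adapting ? 0.75 / std::pow((double)(t + 1), 0.6) : 0.0;

    // --- theta ---
    for (int m = 0; m < M; ++m) {
      const double sd = sTheta[m].sd();
      double accSum = 0.0;
      for (int i = 0; i < N; ++i) {
        const double cur = theta(i, m);
        const double prop = cur + sd * norm_rand();
        double d = -0.5 * ((prop - thMean) * (prop - thMean) -
                           (cur - thMean) * (cur - thMean)) / (thSd * thSd);
        for (size_t u = 0; u < itemsOfComp[m].size(); ++u) {
          const int j = itemsOfComp[m][u];
          const double v = log_logistic(a[j + J * m] * (prop - b[j + J * m]));
          newL[u] = v;
          if (y(i, j) != NA_INTEGER && y(i, j) >= 0) {
            const double Sold = S[sIdx(i, j)];
            const double Snew = Sold - Lm[lmIdx(i, j, m)] + v;
            d += cell_ll(y(i, j), Snew, cvec[j]) -
                 cell_ll(y(i, j), Sold, cvec[j]);
          }
        }
        const double ap = d >= 0 ? 1.0 : std::exp(d);
        accSum += ap;
        if (unif_rand() < ap) {
          theta(i, m) = prop;
          for (size_t u = 0; u < itemsOfComp[m].size(); ++u) {
            const int j = itemsOfComp[m][u];
            S[sIdx(i, j)] += newL[u] - Lm[lmIdx(i, j, m)];
            Lm[lmIdx(i, j, m)] = newL[u];
          }
          if (!adapting) accTheta[m] += 1.0;
        }
      }
      if (adapting) sTheta[m].update(accSum / N, gamma);
    }

    // --- item-level blocks, refreshed structReps times per ability sweep ---
    for (int rep = 0; rep < structReps; ++rep) {
    // --- eta ---
    for (int e = 0; e < nEta; ++e) {
      const int m = etaM[e];
      const double cur = eta[e];
      const double prop = cur + sEta[e].sd() * norm_rand();
      const double shift = prop - cur;
      double d = -0.5 * ((prop - etMean) * (prop - etMean) -
                         (cur - etMean) * (cur - etMean)) / (etSd * etSd);
      for (size_t u = 0; u < itemsOfEta[e].size(); ++u) {
        const int j = itemsOfEta[e][u];
        const double aj = a[j + J * m], bnew = b[j + J * m] + shift;
        for (int i = 0; i < N; ++i) {
          const double v = log_logistic(aj * (theta(i, m) - bnew));
          newLcols[(size_t)N * u + i] = v;
          if (y(i, j) != NA_INTEGER && y(i, j) >= 0) {
            const double Sold = S[sIdx(i, j)];
            const double Snew = Sold - Lm[lmIdx(i, j, m)] + v;
            d += cell_ll(y(i, j), Snew, cvec[j]) -
                 cell_ll(y(i, j), Sold, cvec[j]);
          }
        }
      }
      const double ap = d >= 0 ? 1.0 : std::exp(d);
      if (unif_rand() < ap) {
        eta[e] = prop;
        for (size_t u = 0; u < itemsOfEta[e].size(); ++u) {
          const int j = itemsOfEta[e][u];
          b[j + J * m] += shift;
          for (int i = 0; i < N; ++i) {
            const double v = newLcols[(size_t)N * u + i];
            S[sIdx(i, j)] += v - Lm[lmIdx(i, j, m)];
            Lm[lmIdx(i, j, m)] = v;
          }
        }
        if (!adapting) accEta[e] += 1.0;
      }
      if (adapting) sEta[e].update(ap, gamma);
    }

    // --- alpha ---
    if (estAlpha) {
      for (int g = 0; g < G; ++g) {
        const double cur = alphaG[g];
        const double prop = cur + sAlpha[g].sd() * norm_rand();
        double ap = 0.0;
        if (prop >= 0.0) {
          double d = -0.5 * ((prop - alMean) * (prop - alMean) -
                             (cur - alMean) * (cur - alMean)) / (alSd * alSd);
          for (size_t u = 0; u < cellsOfGroup[g].size(); ++u) {
            const int j = cellsOfGroup[g][u].first;
            const int m = cellsOfGroup[g][u].second;
            const double bj = b[j + J * m];
            for (int i = 0; i < N; ++i) {
              const double v = log_logistic(prop * (theta(i, m) - bj));
              newLcols[(size_t)N * u + i] = v;
              if (y(i, j) != NA_INTEGER && y(i, j) >= 0) {
                const double Sold = S[sIdx(i, j)];
                const double Snew = Sold - Lm[lmIdx(i, j, m)] + v;
                d += cell_ll(y(i, j), Snew, cvec[j]) -
                     cell_ll(y(i, j), Sold, cvec[j]);
              }
            }
          }
          ap = d >= 0 ? 1.0 : std::exp(d);
          if (unif_rand() < ap) {
            alphaG[g] = prop;
            for (size_t u = 0; u < cellsOfGroup[g].size(); ++u) {
              const int j = cellsOfGroup[g][u].first;
              const int m = cellsOfGroup[g][u].second;
              a[j + J * m] = prop;
              for (int i = 0; i < N; ++i) {
                const double v = newLcols[(size_t)N * u + i];
                S[sIdx(i, j)] += v - Lm[lmIdx(i, j, m)];
                Lm[lmIdx(i, j, m)] = v;
              }
            }
            if (!adapting) accAlpha[g] += 1.0;
          }
        }
        if (adapting) sAlpha[g].update(ap, gamma);
      }
    }

    // --- guessing ---
    if (estGuess) {
      for (int j = 0; j < J; ++j) {
        const double cur = cvec[j];
        const double prop = cur + sC[j].sd() * norm_rand();
        double ap = 0.0;
        if (prop > 0.0 && prop < 1.0) {
          double d = (gA - 1.0) * (std::log(prop) - std::log(cur)) +
                     (gB - 1.0) * (std::log1p(-prop) - std::log1p(-cur));
          for (int i = 0; i < N; ++i) {
            if (y(i, j) == NA_INTEGER || y(i, j) < 0) continue;
            const double Sij = S[sIdx(i, j)];
            d += cell_ll(y(i, j), Sij, prop) - cell_ll(y(i, j), Sij, cur);
          }
          ap = d >= 0 ? 1.0 : std::exp(d);
          if (unif_rand() < ap) {
            cvec[j] = prop;
            if (!adapting) accC[j] += 1.0;
          }
        }
        if (adapting) sC[j].update(ap, gamma);
      }
    }

    } // structReps

    // --- joint adaptive-Metropolis update of the structural block ---
    // Scalar moves mix slowly along the correlated ridges that tie feature
    // difficulties, slopes and guessing together; a multivariate random walk
    // with the empirical posterior covariance (learned during warmup) walks
    // the ridge directly.
    if (D > 0) {
      packX(xCur);
      if (adapting) {
        // accumulate running mean / covariance of the structural vector
        covN += 1.0;
        for (int p = 0; p < D; ++p) dx[p] = xCur[p] - covMean[p];
        for (int p = 0; p < D; ++p) covMean[p] += dx[p] / covN;
        for (int p = 0; p < D; ++p)
          for (int r = 0; r <= p; ++r)
            covM2[p * D + r] += dx[p] * (xCur[r] - covMean[r]);
        if (covN >= 2.0 * D && ((t + 1) % 25 == 0 || t == warmup - 1)) {
          for (int p = 0; p < D; ++p)
            for (int r = 0; r <= p; ++r) {
              double v = covM2[p * D + r] / (covN - 1.0);
              cholTmp[p * D + r] = v + (p == r ? 1e-8 : 0.0);
            }
          if (cholesky(cholTmp, D)) {
            cholL = cholTmp;
            haveChol = true;
          }
        }
      }
      if (haveChol) {
        const int nJoint = 4;
        for (int rep = 0; rep < nJoint; ++rep) {
          // current log-likelihood + log-prior
          double llCur = 0.0;
          for (int j = 0; j < J; ++j)
            for (int i = 0; i < N; ++i)
              if (y(i, j) >= 0) llCur += cell_ll(y(i, j), S[sIdx(i, j)], cvec[j]);
          llCur += structPrior(eta, alphaG, cvec);
          for (int p = 0; p < D; ++p) z[p] = norm_rand();
          const double lam = jointScale.sd();
          for (int p = 0; p < D; ++p) {
            double s = 0.0;
            for (int r = 0; r <= p; ++r) s += cholL[p * D + r] * z[r];
            xProp[p] = xCur[p] + lam * s;
          }
          double ap = 0.0;
          if (unpackOk(xProp, etaP, alphaP, cP)) {
            // compose candidate b, a and the full likelihood caches
            std::fill(bP.begin(), bP.end(), 0.0);
            for (int e = 0; e < nEta; ++e)
              for (size_t u = 0; u < itemsOfEta[e].size(); ++u)
                bP[itemsOfEta[e][u] + J * etaM[e]] += etaP[e];
            for (int j = 0; j < J; ++j)
              for (int m = 0; m < M; ++m)
                aP[j + J * m] = C(j, m)
                  ? (estAlpha ? alphaP[group(j, m) - 1] : 1.0) : 0.0;
            std::fill(SP.begin(), SP.end(), 0.0);
            for (int m = 0; m < M; ++m)
              for (int j = 0; j < J; ++j) {
                if (!C(j, m)) { for (int i = 0; i < N; ++i) LmP[lmIdx(i, j, m)] = 0.0; continue; }
                const double aj = aP[j + J * m], bj = bP[j + J * m];
                for (int i = 0; i < N; ++i) {
                  const double v = log_logistic(aj * (theta(i, m) - bj));
                  LmP[lmIdx(i, j, m)] = v;
                  SP[sIdx(i, j)] += v;
                }
              }
            double llProp = 0.0;
            for (int j = 0; j < J; ++j)
              for (int i = 0; i < N; ++i)
                if (y(i, j) >= 0) llProp += cell_ll(y(i, j), SP[sIdx(i, j)], cP[j]);
            llProp += structPrior(etaP, alphaP, cP);
            const double d = llProp - llCur;
            ap = d >= 0 ? 1.0 : std::exp(d);
            if (unif_rand() < ap) {
              eta = etaP; if (estAlpha) alphaG = alphaP; if (estGuess) cvec = cP;
              b = bP; a = aP; S.swap(SP); Lm.swap(LmP);
              std::copy(xProp.begin(), xProp.end(), xCur.begin());
              if (!adapting) accJoint += 1.0;
            }
          }
          if (adapting) jointScale.update(ap, gamma);
        }
      }
    }

    // --- store (every thin-th post-warmup sweep) ---
    if (!adapting && (t - warmup + 1) % thin == 0) {
      for (int m = 0; m < M; ++m)
        for (int i = 0; i < N; ++i)
          thDraws[(size_t)nKept + (size_t)iter * i + (size_t)iter * N * m] =
            theta(i, m);
      for (int e = 0; e < nEta; ++e) etDraws(nKept, e) = eta[e];
      if (estAlpha) for (int g = 0; g < G; ++g) alDraws(nKept, g) = alphaG[g];
      if (estGuess) for (int j = 0; j < J; ++j) cDraws(nKept, j) = cvec[j];
      ++nKept;
    }
  }

  thDraws.attr("dim") = IntegerVector::create(iter, N, M);
  const double denom = iter > 0 ? (double)iter * thin : 1.0;
  NumericVector accT(M), accE(nEta), accA(G), accG(J);
  for (int m = 0; m < M; ++m) accT[m] = accTheta[m] / (denom * N);
  const double sdenom = denom * (structReps > 0 ? structReps : 1);
  for (int e = 0; e < nEta; ++e) accE[e] = accEta[e] / sdenom;
  for (int g = 0; g < G; ++g) accA[g] = accAlpha[g] / sdenom;
  for (int j = 0; j < J; ++j) accG[j] = accC[j] / sdenom;

  return List::create(
    _["theta"] = thDraws, _["eta"] = etDraws,
    _["alpha"] = estAlpha ? alDraws : NumericMatrix(0, 0),
    _["guess"] = estGuess ? cDraws : NumericMatrix(0, 0),
    _["accept"] = List::create(_["theta"] = accT, _["eta"] = accE,
                               _["alpha"] = accA, _["guess"] = accG,
                               _["joint"] = accJoint / (denom * 4.0)));
}
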