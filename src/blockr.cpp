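// Blocked Gibbs sampler cores (single- and multi-trait).
//
// All randomness goes through R's RNG (unif_rand / norm_rand /
// R::rchisq / R::rgamma / R::rbeta) so that chains are reproducible
// from set.seed() and draw-for-draw comparable with plain-R reference
// samplers that consume the same stream.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// smallest k with cumulative normalised weight >= x, weights
// pi_k * exp(-0.5 gbar^2 / v_k) / sqrt(v_k), computed in log space
int draw_component(double gbar, const arma::rowvec& pi,
                   const arma::vec& sigmaK2, double sigmaE2,
                   double djj, bool lsvar) {
  const int K = pi.n_elem;
  arma::vec logp(K);
  double mx = -arma::datum::inf;
  for (int k = 0; k < K; ++k) {
    double v = sigmaK2[k] + (lsvar ? sigmaE2 / djj : sigmaE2);
    if (pi[k] <= 0.0) { logp[k] = -arma::datum::inf; continue; }
    logp[k] = std::log(pi[k]) - 0.5 * gbar * gbar / v - 0.5 * std::log(v);
    if (logp[k] > mx) mx = logp[k];
  }
  double tot = 0.0;
  arma::vec p(K);
  for (int k = 0; k < K; ++k) {
    p[k] = std::isfinite(logp[k]) ? std::exp(logp[k] - mx) : 0.0;
    tot += p[k];
  }
  double x = unif_rand();
  double cum = 0.0;
  for (int k = 0; k < K; ++k) {
    cum += p[k] / tot;
    if (cum >= x) return k;
  }
  return K - 1;
}

// one Dirichlet draw per class: gamma variates normalised row-wise
void draw_mixing(arma::mat& pi, const arma::mat& alpha,
                 const arma::mat& beta) {
  for (arma::uword c = 0; c < pi.n_rows; ++c) {
    double tot = 0.0;
    for (arma::uword k = 0; k < pi.n_cols; ++k) {
      pi(c, k) = R::rgamma(alpha(c, k) + beta(c, k), 1.0);
      tot += pi(c, k);
    }
    pi.row(c) /= tot;
  }
}

void sample_fixed(arma::vec& u, arma::vec& e, const arma::mat& X,
                  const arma::vec& w, const arma::vec& xwx,
                  double sigmaE2) {
  for (arma::uword f = 0; f < u.n_elem; ++f) {
    double rhs = arma::dot(X.col(f), w % e);
    double mean = (rhs + xwx[f] * u[f]) / xwx[f];
    double unew = mean + std::sqrt(sigmaE2 / xwx[f]) * norm_rand();
    e -= X.col(f) * (unew - u[f]);
    u[f] = unew;
  }
}

void sample_poly(arma::vec& a, arma::vec& e, const arma::vec& w,
                 const arma::mat& Ainv, double sigmaE2, double sigmaA2) {
  double lambda = sigmaE2 / sigmaA2;
  for (arma::uword i = 0; i < a.n_elem; ++i) {
    double den = w[i] + Ainv(i, i) * lambda;
    double mean = (w[i] * e[i] - lambda * arma::dot(Ainv.row(i), a)) / den
      + a[i];
    double anew = mean + std::sqrt(sigmaE2 / den) * norm_rand();
    e[i] -= (anew - a[i]);
    a[i] = anew;
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_run_chain(const arma::mat& V, const arma::vec& y,
                   const arma::vec& w, const arma::mat& X,
                   const arma::imat& bounds, int nInner, int nOuter,
                   int sr, const arma::vec& alloc, const arma::mat& alpha,
                   const arma::ivec& snpClass, double h2, double sigmaT2,
                   int burnIn, bool lsvar, bool sigmaGScaled,
                   bool usePoly, const arma::mat& Ainv,
                   bool checkResiduals, bool verbose) {
  const int nR = V.n_rows, nM = V.n_cols;
  const int K = alloc.n_elem, nClass = alpha.n_rows;
  const int nB = bounds.n_rows;
  const int nW = arma::sum(w != 0);
  if (nW <= 2) stop("need more than 2 records with non-zero weight");

  // initialisation: e = y, u = 0, g = 0, all markers in the spike
  arma::vec e = y, u(X.n_cols, arma::fill::zeros),
    g(nM, arma::fill::zeros), a(nR, arma::fill::zeros);
  arma::ivec k(nM, arma::fill::ones); // 1-based component labels
  double sigmaE2 = sigmaT2 * (1.0 - h2);
  double sigmaG2 = sigmaT2 * h2 * (usePoly ? 0.9 : 1.0);
  double sigmaA2 = usePoly ? sigmaT2 * h2 * 0.1 : 0.0;
  arma::vec sigmaK2 = alloc * sigmaG2;
  arma::mat pi(nClass, K);
  pi.fill(1.0 / K);

  arma::vec xwx(X.n_cols);
  for (arma::uword f = 0; f < X.n_cols; ++f) {
    xwx[f] = arma::dot(arma::square(X.col(f)), w);
    if (xwx[f] <= 0)
      stop("fixed-effect column %d has zero weighted sum of squares",
           (int)f + 1);
  }

  arma::vec gSum(nM, arma::fill::zeros), ppCount(nM, arma::fill::zeros);
  arma::mat compCount(nM, K, arma::fill::zeros);
  arma::vec sigmaE2Tr(nOuter), sigmaG2Tr(nOuter);
  arma::ivec nmTr(nOuter);
  arma::cube betaTr(nOuter, nClass, K, arma::fill::zeros);
  std::vector<double> residCheck;
  long blockCounter = 0;
  long nRetained = 0;

  for (int l = 0; l < nOuter; ++l) {
    bool keep = (l >= burnIn);
    for (int b = 0; b < nB; ++b) {
      const int j0 = bounds(b, 0) - 1, j1 = bounds(b, 1) - 1;
      const int bs = j1 - j0 + 1;
      const arma::mat Vb = V.cols(j0, j1);
      // fresh block cross-product each visit (memory O(n^2), no
      // global V'V cache)
      const arma::mat A = Vb.t() * (Vb.each_col() % w);
      arma::vec rb = Vb.t() * (w % e);
      const arma::vec gEntry = g.subvec(j0, j1);

      for (int i = 0; i < nInner; ++i) {
        for (int jj = 0; jj < bs; ++jj) {
          const int j = j0 + jj;
          const double d = A(jj, jj);
          const double gOld = g[j];
          const double gBar = (rb[jj] + d * gOld) / d;
          if (!std::isfinite(gBar))
            stop("non-finite least-squares estimate at marker %d, "
                 "outer cycle %d", j + 1, l + 1);
          const int cls = snpClass[j] - 1;
          const int kj = draw_component(gBar, pi.row(cls), sigmaK2,
                                        sigmaE2, d, lsvar);
          k[j] = kj + 1;
          double gNew;
          if (kj == 0) {
            gNew = 0.0;
          } else {
            const double kappa = sigmaE2 / sigmaK2[kj];
            const double den = d + kappa;
            gNew = (rb[jj] + d * gOld) / den
              + std::sqrt(sigmaE2 / den) * norm_rand();
          }
          if (gNew != gOld) {
            rb += A.col(jj) * (gOld - gNew);
            g[j] = gNew;
          }
          if (keep) {
            gSum[j] += gNew;
            compCount(j, kj) += 1.0;
            if (kj > 0) ppCount[j] += 1.0;
          }
        }
      }
      e -= Vb * (g.subvec(j0, j1) - gEntry);

      if (++blockCounter % sr == 0) {
        sample_fixed(u, e, X, w, xwx, sigmaE2);
        if (usePoly) sample_poly(a, e, w, Ainv, sigmaE2, sigmaA2);
        sigmaE2 = arma::dot(arma::square(e), w) / R::rchisq(nW - 2);
      }
    }

    // outer-cycle end: sigma_a^2, sigma_g^2, mixing proportions
    if (usePoly)
      sigmaA2 = arma::as_scalar(a.t() * Ainv * a) / R::rchisq(nR - 2);
    arma::mat beta(nClass, K, arma::fill::zeros);
    for (int j = 0; j < nM; ++j) beta(snpClass[j] - 1, k[j] - 1) += 1.0;
    const int nm = nM - (int)arma::accu(beta.col(0));
    if (nm > 2) {
      double ss;
      if (!sigmaGScaled) {
        ss = (double)nm * arma::dot(g, g);
      } else {
        ss = 0.0;
        for (int j = 0; j < nM; ++j)
          if (k[j] > 1) ss += g[j] * g[j] / alloc[k[j] - 1];
      }
      sigmaG2 = ss / R::rchisq(nm - 2);
    }
    sigmaK2 = alloc * sigmaG2;
    draw_mixing(pi, alpha, beta);

    if (!std::isfinite(sigmaE2) || !std::isfinite(sigmaG2))
      stop("non-finite variance at outer cycle %d", l + 1);

    sigmaE2Tr[l] = sigmaE2;
    sigmaG2Tr[l] = sigmaG2;
    nmTr[l] = nm;
    betaTr.row(l) = beta;
    if (keep) nRetained += nInner;

    if (checkResiduals) {
      arma::vec ref = y - X * u - V * g;
      if (usePoly) ref -= a;
      residCheck.push_back(arma::abs(e - ref).max());
    }
    if (verbose)
      Rprintf("cycle %d: sigmaE2 %.4f sigmaG2 %.4f nm %d\n",
              l + 1, sigmaE2, sigmaG2, nm);
    Rcpp::checkUserInterrupt();
  }

  arma::vec gMean = nRetained > 0 ? arma::vec(gSum / nRetained)
                                  : arma::vec(nM, arma::fill::zeros);
  arma::vec pp = nRetained > 0 ? arma::vec(ppCount / nRetained)
                               : arma::vec(nM, arma::fill::zeros);
  arma::mat compFreq = compCount;
  if (nRetained > 0) compFreq /= (double)nRetained;

  return List::create(
    _["gMean"] = gMean, _["pp"] = pp, _["compFreq"] = compFreq,
    _["sigmaE2Trace"] = sigmaE2Tr, _["sigmaG2Trace"] = sigmaG2Tr,
    _["nmTrace"] = nmTr, _["betaTrace"] = betaTr,
    _["nRetained"] = (double)nRetained,
    _["u"] = u, _["g"] = g, _["a"] = a, _["e"] = e, _["k"] = k,
    _["pi"] = pi, _["sigmaE2"] = sigmaE2, _["sigmaG2"] = sigmaG2,
    _["sigmaA2"] = sigmaA2,
    _["residCheck"] = residCheck);
}

// [[Rcpp::export]]
List cpp_run_mt_chain(const arma::mat& V, const arma::mat& Y,
                      const arma::mat& W, const arma::mat& X,
                      const arma::imat& bounds, int nInner, int nOuter,
                      int sr, const arma::vec& alloc,
                      const arma::mat& alpha, const arma::ivec& snpClass,
                      const arma::vec& h2, const arma::vec& sigmaT2,
                      int burnIn, bool lsvar, bool sigmaGScaled,
                      const arma::vec& piStarInit,
                      const arma::vec& alphaStar, bool verbose) {
  const int nM = V.n_cols;
  const int T = Y.n_cols;
  const int K = alloc.n_elem, nClass = alpha.n_rows;
  const int nB = bounds.n_rows;

  // per-trait state
  arma::mat E(Y), G(nM, T, arma::fill::zeros),
    U(X.n_cols, T, arma::fill::zeros);
  arma::imat Kmat(nM, T, arma::fill::ones);
  arma::vec sigmaE2(T), sigmaG2(T);
  arma::ivec nWt(T);
  for (int t = 0; t < T; ++t) {
    sigmaE2[t] = sigmaT2[t] * (1.0 - h2[t]);
    sigmaG2[t] = sigmaT2[t] * h2[t];
    nWt[t] = arma::sum(W.col(t) != 0);
    if (nWt[t] <= 2)
      stop("trait %d has fewer than 3 non-zero weights", t + 1);
  }
  arma::mat sigmaK2(K, T);
  for (int t = 0; t < T; ++t) sigmaK2.col(t) = alloc * sigmaG2[t];
  std::vector<arma::mat> piT(T, arma::mat(nClass, K,
                                          arma::fill::value(1.0 / K)));
  arma::vec piStar = piStarInit; // (P(J=0), P(J=1))
  arma::ivec J(nM, arma::fill::zeros);

  arma::mat xwx(X.n_cols, T);
  for (int t = 0; t < T; ++t)
    for (arma::uword f = 0; f < X.n_cols; ++f) {
      xwx(f, t) = arma::dot(arma::square(X.col(f)), W.col(t));
      if (xwx(f, t) <= 0)
        stop("fixed-effect column %d empty under trait %d weights",
             (int)f + 1, t + 1);
    }

  arma::mat gSum(nM, T, arma::fill::zeros);
  arma::vec jCount(nM, arma::fill::zeros);
  std::vector<arma::mat> compCount(T, arma::mat(nM, K, arma::fill::zeros));
  arma::mat sigmaE2Tr(nOuter, T), sigmaG2Tr(nOuter, T);
  arma::imat nmTr(nOuter, T);
  std::vector<arma::cube> betaTr(
    T, arma::cube(nOuter, nClass, K, arma::fill::zeros));
  arma::mat piStarTr(nOuter, 2);
  long blockCounter = 0, nRetained = 0;

  for (int l = 0; l < nOuter; ++l) {
    bool keep = (l >= burnIn);
    for (int b = 0; b < nB; ++b) {
      const int j0 = bounds(b, 0) - 1, j1 = bounds(b, 1) - 1;
      const int bs = j1 - j0 + 1;
      const arma::mat Vb = V.cols(j0, j1);
      std::vector<arma::mat> A(T);
      arma::mat rb(bs, T);
      for (int t = 0; t < T; ++t) {
        A[t] = Vb.t() * (Vb.each_col() % W.col(t));
        rb.col(t) = Vb.t() * (W.col(t) % E.col(t));
      }
      const arma::mat gEntry = G.rows(j0, j1);

      for (int i = 0; i < nInner; ++i) {
        for (int jj = 0; jj < bs; ++jj) {
          const int j = j0 + jj;
          const int cls = snpClass[j] - 1;
          // model-inclusion indicator from all traits' least-squares
          // estimates, in log space
          double p0 = piStar[0] > 0 ? std::log(piStar[0])
                                    : -arma::datum::inf;
          double p1 = piStar[1] > 0 ? std::log(piStar[1])
                                    : -arma::datum::inf;
          arma::vec gBar(T);
          for (int t = 0; t < T; ++t) {
            const double d = A[t](jj, jj);
            gBar[t] = (rb(jj, t) + d * G(j, t)) / d;
            if (!std::isfinite(gBar[t]))
              stop("non-finite least-squares estimate at marker %d, "
                   "trait %d, outer cycle %d", j + 1, t + 1, l + 1);
            double sumL = 0.0, L0 = 0.0;
            for (int kk = 0; kk < K; ++kk) {
              const double v = 1.0 / (sigmaK2(kk, t) + sigmaE2[t]);
              const double L = std::sqrt(v)
                * std::exp(-0.5 * v * gBar[t] * gBar[t]);
              if (kk == 0) L0 = L;
              sumL += L * piT[t](cls, kk);
            }
            p0 += std::log(L0);
            p1 += std::log(sumL);
          }
          double p;
          if (!std::isfinite(p1)) p = 0.0;
          else if (!std::isfinite(p0)) p = 1.0;
          else p = 1.0 / (1.0 + std::exp(p0 - p1));
          const int Jj = (unif_rand() < p) ? 1 : 0;
          J[j] = Jj;
          if (Jj == 0) {
            // marker leaves the model: zero every trait's effect
            for (int t = 0; t < T; ++t) {
              if (G(j, t) != 0.0) {
                rb.col(t) += A[t].col(jj) * G(j, t);
                G(j, t) = 0.0;
              }
              Kmat(j, t) = 1;
            }
          } else {
            for (int t = 0; t < T; ++t) {
              const double d = A[t](jj, jj);
              const double gOld = G(j, t);
              const int kj = draw_component(gBar[t], piT[t].row(cls),
                                            sigmaK2.col(t), sigmaE2[t],
                                            d, lsvar);
              Kmat(j, t) = kj + 1;
              double gNew;
              if (kj == 0) {
                gNew = 0.0;
              } else {
                const double kappa = sigmaE2[t] / sigmaK2(kj, t);
                const double den = d + kappa;
                gNew = (rb(jj, t) + d * gOld) / den
                  + std::sqrt(sigmaE2[t] / den) * norm_rand();
              }
              if (gNew != gOld) {
                rb.col(t) += A[t].col(jj) * (gOld - gNew);
                G(j, t) = gNew;
              }
            }
          }
          if (keep) {
            jCount[j] += Jj;
            for (int t = 0; t < T; ++t) {
              gSum(j, t) += G(j, t);
              compCount[t](j, Kmat(j, t) - 1) += 1.0;
            }
          }
        }
      }
      for (int t = 0; t < T; ++t)
        E.col(t) -= Vb * (G(arma::span(j0, j1), arma::span(t, t))
                          - gEntry.col(t));

      if (++blockCounter % sr == 0) {
        for (int t = 0; t < T; ++t) {
          arma::vec ut = U.col(t), et = E.col(t);
          sample_fixed(ut, et, X, W.col(t), xwx.col(t), sigmaE2[t]);
          U.col(t) = ut; E.col(t) = et;
          sigmaE2[t] = arma::dot(arma::square(E.col(t)), W.col(t))
            / R::rchisq(nWt[t] - 2);
        }
      }
    }

    // outer-cycle end: per-trait variances and mixing, then pi*
    for (int t = 0; t < T; ++t) {
      arma::mat beta(nClass, K, arma::fill::zeros);
      for (int j = 0; j < nM; ++j)
        beta(snpClass[j] - 1, Kmat(j, t) - 1) += 1.0;
      const int nm = nM - (int)arma::accu(beta.col(0));
      if (nm > 2) {
        double ss;
        if (!sigmaGScaled) {
          ss = (double)nm * arma::dot(G.col(t), G.col(t));
        } else {
          ss = 0.0;
          for (int j = 0; j < nM; ++j)
            if (Kmat(j, t) > 1)
              ss += G(j, t) * G(j, t) / alloc[Kmat(j, t) - 1];
        }
        sigmaG2[t] = ss / R::rchisq(nm - 2);
      }
      sigmaK2.col(t) = alloc * sigmaG2[t];
      draw_mixing(piT[t], alpha, beta);
      if (!std::isfinite(sigmaE2[t]) || !std::isfinite(sigmaG2[t]))
        stop("non-finite variance for trait %d at outer cycle %d",
             t + 1, l + 1);
      sigmaE2Tr(l, t) = sigmaE2[t];
      sigmaG2Tr(l, t) = sigmaG2[t];
      nmTr(l, t) = nm;
      betaTr[t].row(l) = beta;
    }
    const int nIn = (int)arma::accu(J);
    piStar[0] = R::rbeta(alphaStar[0] + (nM - nIn), alphaStar[1] + nIn);
    piStar[1] = 1.0 - piStar[0];
    piStarTr(l, 0) = piStar[0];
    piStarTr(l, 1) = piStar[1];
    if (keep) nRetained += nInner;
    if (verbose)
      Rprintf("cycle %d: in-model %d, piStar1 %.4f\n", l + 1, nIn,
              piStar[1]);
    Rcpp::checkUserInterrupt();
  }

  List perTrait(T);
  for (int t = 0; t < T; ++t) {
    arma::vec gm = nRetained > 0
      ? arma::vec(gSum.col(t) / (double)nRetained)
      : arma::vec(nM, arma::fill::zeros);
    arma::mat cf = compCount[t];
    if (nRetained > 0) cf /= (double)nRetained;
    perTrait[t] = List::create(
      _["gMean"] = gm, _["compFreq"] = cf,
      _["sigmaE2Trace"] = arma::vec(sigmaE2Tr.col(t)),
      _["sigmaG2Trace"] = arma::vec(sigmaG2Tr.col(t)),
      _["nmTrace"] = arma::ivec(nmTr.col(t)),
      _["betaTrace"] = betaTr[t],
      _["u"] = arma::vec(U.col(t)), _["g"] = arma::vec(G.col(t)),
      _["e"] = arma::vec(E.col(t)), _["k"] = arma::ivec(Kmat.col(t)),
      _["sigmaE2"] = sigmaE2[t], _["sigmaG2"] = sigmaG2[t]);
  }
  arma::vec jpp = nRetained > 0 ? arma::vec(jCount / (double)nRetained)
                                : arma::vec(nM, arma::fill::zeros);
  return List::create(
    _["perTrait"] = perTrait, _["jpp"] = jpp,
    _["piStarTrace"] = piStarTr, _["J"] = J,
    _["nRetained"] = (double)nRetained);
}
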