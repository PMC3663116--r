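// Slice-sampling Gibbs sweep for the hierarchical Poisson-beta model.
// Uses R's RNG (unif_rand via the R API) so chains are reproducible under
// set.seed from the wrapper.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One slice-sampler update (Neal 2003: step-out then shrinkage).
// f returns the log target; hard support bounds clamp the bracket.
template <typename F>
static double slice1(F f, double x0, double w, int max_steps,
                     double lower, double upper) {
  double lf0 = f(x0);
  if (!std::isfinite(lf0))
    stop("slice sampler: log density not finite at current point");
  double logy = lf0 - R::exp_rand();
  double L = x0 - w * unif_rand();
  double R_ = L + w;
  int J = (int)std::floor(max_steps * unif_rand());
  int K = max_steps - 1 - J;
  while (J > 0 && L > lower && f(L) > logy) { L -= w; --J; }
  while (K > 0 && R_ < upper && f(R_) > logy) { R_ += w; --K; }
  if (L < lower) L = lower;
  if (R_ > upper) R_ = upper;
  for (;;) {
    double x1 = L + unif_rand() * (R_ - L);
    if (f(x1) > logy) return x1;
    if (x1 < x0) L = x1; else R_ = x1;
    if (R_ - L < 1e-300) return x0;
  }
}

// [[Rcpp::export]]
List gibbs_core(NumericMatrix X, NumericVector ti, NumericVector tj,
                NumericVector alpha_s, NumericVector beta_s,
                NumericVector alpha_kon, NumericVector beta_kon,
                NumericVector alpha_koff, NumericVector beta_koff,
                int n_iter, int burn_in,
                double width_p, double width_log, int max_steps,
                NumericMatrix p0, NumericVector kon0,
                NumericVector koff0, NumericVector s0, bool verbose) {
  const int G = X.nrow(), J = X.ncol();
  NumericMatrix p(clone(p0));
  NumericVector kon(clone(kon0)), koff(clone(koff0)), s(clone(s0));

  NumericMatrix kon_tr(n_iter, G), koff_tr(n_iter, G), s_tr(n_iter, G);
  NumericVector logpost(n_iter);
  NumericMatrix p_acc(G, J);
  int n_acc = 0;

  std::vector<double> sum_x(G, 0.0), lgam_x(G, 0.0);
  for (int i = 0; i < G; ++i)
    for (int j = 0; j < J; ++j) {
      sum_x[i] += X(i, j);
      lgam_x[i] += R::lgammafn(X(i, j) + 1.0);
    }

  for (int it = 0; it < n_iter; ++it) {
    // 1) auxiliary variables p_ij on their natural (0,1) scale
    for (int i = 0; i < G; ++i) {
      const double a = kon[i] - 1.0, b = koff[i] - 1.0, si = s[i];
      for (int j = 0; j < J; ++j) {
        const double x = X(i, j), tts = ti[i] * tj[j] * si;
        auto f = [&](double pp) -> double {
          if (pp <= 0.0 || pp >= 1.0) return R_NegInf;
          return a * std::log(pp) + b * std::log1p(-pp) +
                 x * std::log(tts * pp) - tts * pp;
        };
        p(i, j) = slice1(f, p(i, j), width_p, max_steps, 0.0, 1.0);
      }
    }
    // 2) per-gene rates on the log scale (with Jacobian)
    for (int i = 0; i < G; ++i) {
      double slp = 0.0, sl1mp = 0.0, stp = 0.0;
      for (int j = 0; j < J; ++j) {
        slp += std::log(p(i, j));
        sl1mp += std::log1p(-p(i, j));
        stp += ti[i] * tj[j] * p(i, j);
      }
      {
        const double a = alpha_kon[i], bt = beta_kon[i], kf = koff[i];
        auto f = [&](double th) -> double {
          double k = std::exp(th);
          return (a - 1.0) * th - k / bt +
                 J * (R::lgammafn(k + kf) - R::lgammafn(k)) +
                 (k - 1.0) * slp + th;
        };
        kon[i] = std::exp(slice1(f, std::log(kon[i]), width_log, max_steps,
                                 R_NegInf, R_PosInf));
      }
      {
        const double a = alpha_koff[i], bt = beta_koff[i], kn = kon[i];
        auto f = [&](double th) -> double {
          double k = std::exp(th);
          return (a - 1.0) * th - k / bt +
                 J * (R::lgammafn(kn + k) - R::lgammafn(k)) +
                 (k - 1.0) * sl1mp + th;
        };
        koff[i] = std::exp(slice1(f, std::log(koff[i]), width_log, max_steps,
                                  R_NegInf, R_PosInf));
      }
      {
        const double a = alpha_s[i], bt = beta_s[i], sx = sum_x[i];
        auto f = [&](double th) -> double {
          double ss = std::exp(th);
          return (a - 1.0) * th - ss / bt + sx * th - ss * stp + th;
        };
        s[i] = std::exp(slice1(f, std::log(s[i]), width_log, max_steps,
                               R_NegInf, R_PosInf));
      }
    }
    // 3) bookkeeping: traces and the log posterior
    double lp = 0.0;
    for (int i = 0; i < G; ++i) {
      kon_tr(it, i) = kon[i];
      koff_tr(it, i) = koff[i];
      s_tr(it, i) = s[i];
      double slp = 0.0, sl1mp = 0.0;
      for (int j = 0; j < J; ++j) {
        const double rate = ti[i] * tj[j] * s[i] * p(i, j);
        lp += X(i, j) * std::log(rate) - rate;
        slp += std::log(p(i, j));
        sl1mp += std::log1p(-p(i, j));
      }
      lp -= lgam_x[i];
      lp += J * (R::lgammafn(kon[i] + koff[i]) - R::lgammafn(kon[i]) -
                 R::lgammafn(koff[i])) +
            (kon[i] - 1.0) * slp + (koff[i] - 1.0) * sl1mp;
      lp += -s[i] / beta_s[i] + (alpha_s[i] - 1.0) * std::log(s[i]) -
            alpha_s[i] * std::log(beta_s[i]) - R::lgammafn(alpha_s[i]);
      lp += -kon[i] / beta_kon[i] + (alpha_kon[i] - 1.0) * std::log(kon[i]) -
            alpha_kon[i] * std::log(beta_kon[i]) - R::lgammafn(alpha_kon[i]);
      lp += -koff[i] / beta_koff[i] + (alpha_koff[i] - 1.0) * std::log(koff[i]) -
            alpha_koff[i] * std::log(beta_koff[i]) - R::lgammafn(alpha_koff[i]);
    }
    logpost[it] = lp;
    if (it >= burn_in) {
      ++n_acc;
      for (int i = 0; i < G; ++i)
        for (int j = 0; j < J; ++j) p_acc(i, j) += p(i, j);
    }
    if (verbose && ((it + 1) % 1000 == 0))
      Rcout << "iteration " << (it + 1) << "/" << n_iter
            << "  log posterior " << lp << "\n";
    if ((it & 63) == 0) checkUserInterrupt();
  }
  if (n_acc > 0)
    for (int i = 0; i < G; ++i)
      for (int j = 0; j < J; ++j) p_acc(i, j) /= n_acc;

  return List::create(_["kon"] = kon_tr, _["koff"] = koff_tr, _["s"] = s_tr,
                      _["log_posterior"] = logpost, _["p_mean"] = p_acc,
                      _["p_final"] = p, _["kon_final"] = kon,
                      _["koff_final"] = koff, _["s_final"] = s);
}
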