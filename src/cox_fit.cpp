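#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Cox partial-likelihood machinery. Subjects must arrive sorted by
// ascending follow-up time; Xt holds one column per subject (p x n) so the
// backwards risk-set sweep touches contiguous memory. Tied event times are
// handled by the Efron correction (or Breslow when efron = false); censored
// subjects tied with events remain in the risk set at that time.

// Accumulate log partial likelihood, score and observed information in one
// backwards sweep. Only the upper triangle of the information is updated
// subject-by-subject; it is symmetrised at the end.
static double cox_ngh(const arma::mat& Xt, const arma::vec& time,
                      const arma::ivec& event, const arma::vec& beta,
                      bool efron, arma::vec& grad, arma::mat& info) {
  const int n = Xt.n_cols;
  const int p = Xt.n_rows;
  arma::vec eta = Xt.t() * beta;
  double m = eta.max();
  if (!std::isfinite(m)) m = 0.0;   // guard exp() overflow; shift cancels

  double loglik = 0.0;
  grad.zeros(p);
  info.zeros(p, p);

  double r0 = 0.0;
  arma::vec r1(p, arma::fill::zeros);
  arma::mat r2(p, p, arma::fill::zeros);   // upper triangle only
  arma::vec a(p), s1d(p), sum_x(p);
  arma::mat s2d(p, p);

  int i = n - 1;
  while (i >= 0) {
    double t = time[i];
    double s0d = 0.0;
    double sum_eta = 0.0;
    int d = 0;
    int jend = i;
    while (jend >= 0 && time[jend] == t) {
      if (event[jend] == 1) ++d;
      --jend;
    }
    bool needTies = efron && d >= 2;
    if (needTies) { s1d.zeros(); s2d.zeros(); }
    sum_x.zeros();
    for (int j = i; j > jend; --j) {
      const double* x = Xt.colptr(j);
      double wj = std::exp(eta[j] - m);
      r0 += wj;
      bool ev = event[j] == 1;
      if (ev) { s0d += wj; sum_eta += eta[j] - m; }
      for (int b = 0; b < p; ++b) {
        double xb = x[b];
        double wxb = wj * xb;
        r1[b] += wxb;
        if (ev) sum_x[b] += xb;
        double* r2c = r2.colptr(b);
        for (int aa = 0; aa <= b; ++aa) r2c[aa] += wxb * x[aa];
        if (ev && needTies) {
          s1d[b] += wxb;
          double* s2c = s2d.colptr(b);
          for (int aa = 0; aa <= b; ++aa) s2c[aa] += wxb * x[aa];
        }
      }
    }
    if (d > 0) {
      loglik += sum_eta;
      grad += sum_x;
      for (int k = 0; k < d; ++k) {
        double f = needTies ? (double)k / d : 0.0;
        double phi = r0 - f * s0d;
        double iphi = 1.0 / phi;
        for (int b = 0; b < p; ++b)
          a[b] = (r1[b] - (f > 0 ? f * s1d[b] : 0.0)) * iphi;
        loglik -= std::log(phi);
        grad -= a;
        if (f > 0) {
          for (int b = 0; b < p; ++b) {
            double* ic = info.colptr(b);
            const double* r2c = r2.colptr(b);
            const double* s2c = s2d.colptr(b);
            double ab = a[b];
            for (int aa = 0; aa <= b; ++aa)
              ic[aa] += (r2c[aa] - f * s2c[aa]) * iphi - a[aa] * ab;
          }
        } else {
          for (int b = 0; b < p; ++b) {
            double* ic = info.colptr(b);
            const double* r2c = r2.colptr(b);
            double ab = a[b];
            for (int aa = 0; aa <= b; ++aa)
              ic[aa] += r2c[aa] * iphi - a[aa] * ab;
          }
        }
      }
    }
    i = jend;
  }
  info = arma::symmatu(info);
  return loglik;
}

// [[Rcpp::export(name = ".cox_fit_cpp")]]
List cox_fit_cpp(const arma::mat& Xt, const arma::vec& time,
                 const arma::ivec& event, const arma::vec& beta_init,
                 bool efron, double tol, int max_iter, double beta_bound) {
  const int p = Xt.n_rows;
  arma::vec beta = beta_init;
  arma::vec grad(p);
  arma::mat info(p, p);

  double loglik = cox_ngh(Xt, time, event, beta, efron, grad, info);
  double loglik_null = loglik;
  if (arma::norm(beta, "inf") > 0) {
    arma::vec b0(p, arma::fill::zeros), g0(p);
    arma::mat i0(p, p);
    loglik_null = cox_ngh(Xt, time, event, b0, efron, g0, i0);
  }

  bool converged = false;
  bool singular = false;
  int diverged = 0;       // 1-based index of runaway coefficient, 0 if none
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    if (arma::norm(grad, "inf") < tol) { converged = true; break; }
    arma::vec step;
    bool ok = arma::solve(step, info, grad,
                          arma::solve_opts::likely_sympd + arma::solve_opts::no_approx);
    if (!ok) {
      // non-identifiable direction: report singularity so callers can drop
      // the offending column(s); try one pseudo-inverse step
      singular = true;
      arma::mat pinv_i;
      if (!arma::pinv(pinv_i, info)) break;
      step = pinv_i * grad;
    }
    // step halving: accept only likelihood-increasing updates
    double stepsize = 1.0;
    arma::vec cand;
    double ll_new = -arma::datum::inf;
    arma::vec g_new(p);
    arma::mat i_new(p, p);
    for (int h = 0; h < 25; ++h) {
      cand = beta + stepsize * step;
      ll_new = cox_ngh(Xt, time, event, cand, efron, g_new, i_new);
      if (std::isfinite(ll_new) && ll_new >= loglik - 1e-12) break;
      stepsize /= 2.0;
    }
    double stepnorm = stepsize * arma::norm(step, "inf");
    beta = cand;
    loglik = ll_new;
    grad = g_new;
    info = i_new;
    arma::uword imax = arma::abs(beta).index_max();
    if (std::abs(beta[imax]) > beta_bound) { diverged = (int)imax + 1; break; }
    // floating-point floor: once the accepted update is numerically nil the
    // score cannot shrink further; accept if it is already small
    if (stepnorm < 1e-9 && arma::norm(grad, "inf") < 1e-4) {
      converged = true;
      ++iter;
      break;
    }
  }
  if (!converged && arma::norm(grad, "inf") < tol) converged = true;

  // variance from the observed information at the solution
  arma::mat vcov(p, p, arma::fill::value(arma::datum::nan));
  arma::mat vtmp;
  bool vok = arma::inv_sympd(vtmp, info);
  if (!vok) { vok = arma::inv(vtmp, info); }
  if (vok) vcov = vtmp; else singular = true;

  return List::create(
    _["beta"] = beta,
    _["vcov"] = vcov,
    _["loglik"] = loglik,
    _["loglik_null"] = loglik_null,
    _["score_norm"] = arma::norm(grad, "inf"),
    _["iter"] = iter,
    _["converged"] = converged,
    _["singular"] = singular,
    _["diverged"] = diverged);
}

// ---------------------------------------------------------------------------
// Backward elimination and LOOCV engines
// ---------------------------------------------------------------------------

struct SubFit {
  arma::vec beta, se, p;
  bool converged = false, singular = false;
  int diverged = 0;       // 1-based within the active set
};

static SubFit cox_fit_sub(const arma::mat& Xt, const arma::uvec& rows,
                          const arma::uvec& cols, const arma::vec& time,
                          const arma::ivec& event, bool efron,
                          const arma::vec& init, double tol, int max_iter,
                          double beta_bound) {
  const int p = rows.n_elem;
  const int n = cols.n_elem;
  // gather the active submatrix into contiguous storage once per fit; the
  // Newton sweeps then run on cache-friendly, vectorisable memory
  arma::mat Xf(p, n);
  arma::vec tf(n);
  arma::ivec evf(n);
  for (int j = 0; j < n; ++j) {
    const double* src = Xt.colptr(cols[j]);
    double* dst = Xf.colptr(j);
    for (int b = 0; b < p; ++b) dst[b] = src[rows[b]];
    tf[j] = time[cols[j]];
    evf[j] = event[cols[j]];
  }
  SubFit out;
  arma::vec beta = init;
  arma::vec grad(p);
  arma::mat info(p, p);
  double loglik = cox_ngh(Xf, tf, evf, beta, efron, grad, info);
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    if (arma::norm(grad, "inf") < tol) { out.converged = true; break; }
    arma::vec step;
    bool ok = arma::solve(step, info, grad,
                          arma::solve_opts::likely_sympd + arma::solve_opts::no_approx);
    if (!ok) {
      out.singular = true;
      arma::mat pinv_i;
      if (!arma::pinv(pinv_i, info)) break;
      step = pinv_i * grad;
    }
    double stepsize = 1.0;
    arma::vec cand;
    double ll_new = -arma::datum::inf;
    arma::vec g_new(p);
    arma::mat i_new(p, p);
    for (int h = 0; h < 25; ++h) {
      cand = beta + stepsize * step;
      ll_new = cox_ngh(Xf, tf, evf, cand, efron, g_new, i_new);
      if (std::isfinite(ll_new) && ll_new >= loglik - 1e-12) break;
      stepsize /= 2.0;
    }
    double stepnorm = stepsize * arma::norm(step, "inf");
    beta = cand; loglik = ll_new; grad = g_new; info = i_new;
    arma::uword imax = arma::abs(beta).index_max();
    if (std::abs(beta[imax]) > beta_bound) {
      out.diverged = (int)imax + 1;
      break;
    }
    if (stepnorm < 1e-9 && arma::norm(grad, "inf") < 1e-4) {
      out.converged = true;
      break;
    }
  }
  if (!out.converged && arma::norm(grad, "inf") < tol) out.converged = true;
  out.beta = beta;
  arma::mat vtmp;
  bool vok = arma::inv_sympd(vtmp, info);
  if (!vok) vok = arma::inv(vtmp, info);
  if (!vok) { out.singular = true; out.se = arma::vec(p, arma::fill::value(arma::datum::nan)); }
  else {
    arma::vec dg = vtmp.diag();
    out.se = arma::sqrt(arma::clamp(dg, 0.0, arma::datum::inf));
  }
  out.p = arma::vec(p);
  for (int b = 0; b < p; ++b) {
    double se = out.se.is_empty() ? arma::datum::nan : out.se[b];
    if (!std::isfinite(se) || se <= 0) out.p[b] = arma::datum::nan;
    else out.p[b] = 2.0 * R::pnorm(-std::fabs(beta[b] / se), 0.0, 1.0, 1, 0);
  }
  return out;
}

struct BackwardResult {
  arma::uvec selected;        // indices into the full column set (0-based)
  arma::vec beta, se, p;
  std::vector<int> droppedFit;  // columns dropped for non-identifiability
  bool empty = true;
};

// Backward elimination over the subjects listed in cols. eligible and
// lex_rank are aligned with Xt's rows (the full variable set); candidates
// holds the active starting set. Tie rule at the maximal Wald p: remove the
// variable with the largest lexicographic rank.
static BackwardResult cox_backward_engine(
    const arma::mat& Xt, const arma::uvec& candidates,
    const arma::uvec& cols, const arma::vec& time, const arma::ivec& event,
    const LogicalVector& eligible, const IntegerVector& lex_rank,
    double p_remove, bool efron, double tol, int max_iter,
    double beta_bound) {
  BackwardResult out;
  std::vector<arma::uword> sel(candidates.begin(), candidates.end());
  arma::vec init(sel.size(), arma::fill::zeros);
  SubFit fit;
  bool haveFit = false;
  while (!sel.empty()) {
    arma::uvec rows(sel);
    fit = cox_fit_sub(Xt, rows, cols, time, event, efron, init, tol,
                      max_iter, beta_bound);
    haveFit = true;
    if (fit.diverged > 0 || fit.singular || !fit.converged) {
      // drop the offending column, preferring eligible ones
      int bad = -1;
      if (fit.diverged > 0 && eligible[sel[fit.diverged - 1]])
        bad = fit.diverged - 1;
      else {
        double worst = -1.0;
        for (size_t k = 0; k < sel.size(); ++k) {
          if (!eligible[sel[k]]) continue;
          double crit = std::isfinite(fit.se[k]) ? fit.se[k] : arma::datum::inf;
          double ab = std::fabs(fit.beta[k]);
          double score = (crit == arma::datum::inf) ? 1e300 + ab : crit + ab;
          if (score > worst) { worst = score; bad = (int)k; }
        }
      }
      if (bad < 0) break;   // only mandatory columns left; accept as-is
      out.droppedFit.push_back((int)sel[bad] + 1);
      init = arma::vec(sel.size() - 1);
      for (size_t k = 0, q = 0; k < sel.size(); ++k)
        if ((int)k != bad) init[q++] = fit.beta[k];
      sel.erase(sel.begin() + bad);
      haveFit = false;
      continue;
    }
    // find the eligible variable with the largest p
    double pmaxv = -1.0;
    for (size_t k = 0; k < sel.size(); ++k) {
      if (!eligible[sel[k]]) continue;
      double pk = std::isfinite(fit.p[k]) ? fit.p[k] : 1.0;
      if (pk > pmaxv) pmaxv = pk;
    }
    if (pmaxv < 0 || pmaxv <= p_remove) break;
    int worstIdx = -1, worstRank = -1;
    for (size_t k = 0; k < sel.size(); ++k) {
      if (!eligible[sel[k]]) continue;
      double pk = std::isfinite(fit.p[k]) ? fit.p[k] : 1.0;
      if (pk >= pmaxv - 1e-12 && lex_rank[sel[k]] > worstRank) {
        worstRank = lex_rank[sel[k]];
        worstIdx = (int)k;
      }
    }
    if (worstIdx < 0) break;
    init = arma::vec(sel.size() - 1);
    for (size_t k = 0, q = 0; k < sel.size(); ++k)
      if ((int)k != worstIdx) init[q++] = fit.beta[k];
    sel.erase(sel.begin() + worstIdx);
    haveFit = false;
  }
  if (sel.empty()) return out;
  if (!haveFit) {
    arma::uvec rows(sel);
    init.zeros(sel.size());
    fit = cox_fit_sub(Xt, rows, cols, time, event, efron, init, tol,
                      max_iter, beta_bound);
  }
  out.empty = false;
  out.selected = arma::uvec(sel);
  out.beta = fit.beta; out.se = fit.se; out.p = fit.p;
  return out;
}

// [[Rcpp::export(name = ".cox_backward_cpp")]]
List cox_backward_cpp(const arma::mat& Xt, const arma::vec& time,
                      const arma::ivec& event, const LogicalVector& eligible,
                      const IntegerVector& lex_rank, double p_remove,
                      bool efron, double tol, int max_iter,
                      double beta_bound) {
  const int n = Xt.n_cols;
  arma::uvec cols = arma::regspace<arma::uvec>(0, n - 1);
  arma::uvec cand = arma::regspace<arma::uvec>(0, Xt.n_rows - 1);
  BackwardResult r = cox_backward_engine(Xt, cand, cols, time, event,
                                         eligible, lex_rank, p_remove,
                                         efron, tol, max_iter, beta_bound);
  return List::create(
    _["selected"] = IntegerVector(r.selected.begin(), r.selected.end()),
    _["beta"] = r.beta, _["se"] = r.se, _["p"] = r.p,
    _["dropped_fit"] = IntegerVector(r.droppedFit.begin(), r.droppedFit.end()),
    _["empty"] = r.empty);
}

// Full leave-one-out loop. Xt: p x n in *original* subject order; ord:
// 0-based subject indices sorted by ascending time. For each fold, the
// training columns are ord minus the held-out subject; backward elimination
// runs from scratch; the held-out subject is high risk iff its prognostic
// index is >= the median training prognostic index.
// [[Rcpp::export(name = ".cox_loocv_cpp")]]
List cox_loocv_cpp(const arma::mat& Xt, const arma::vec& time,
                   const arma::ivec& event, const arma::uvec& ord,
                   const LogicalVector& eligible,
                   const IntegerVector& lex_rank, double p_remove,
                   bool efron, double tol, int max_iter, double beta_bound,
                   bool collect_models) {
  const int n = Xt.n_cols;
  const int p = Xt.n_rows;
  LogicalVector high(n);
  NumericVector piOut(n);
  List models(collect_models ? n : 0);

  // per-column min/max counts: a column goes constant on a training set only
  // by losing the lone carrier of its minority value. For two-valued
  // columns, also count events within each value group: a binary column
  // with no events in one group has monotone partial likelihood (its
  // coefficient runs away), so such columns are withheld from the fold's
  // candidate set instead of being discovered by divergence.
  arma::vec cmin(p), cmax(p);
  arma::ivec cntMin(p, arma::fill::zeros), cntMax(p, arma::fill::zeros);
  arma::ivec evMin(p, arma::fill::zeros), evMax(p, arma::fill::zeros);
  arma::ivec twoValued(p, arma::fill::ones);
  for (int b = 0; b < p; ++b) {
    double lo = arma::datum::inf, hi = -arma::datum::inf;
    for (int j = 0; j < n; ++j) {
      double v = Xt(b, j);
      if (v < lo) lo = v;
      if (v > hi) hi = v;
    }
    cmin[b] = lo; cmax[b] = hi;
    for (int j = 0; j < n; ++j) {
      double v = Xt(b, j);
      if (v == lo) { ++cntMin[b]; if (event[j] == 1) ++evMin[b]; }
      else if (v == hi) { ++cntMax[b]; if (event[j] == 1) ++evMax[b]; }
      else twoValued[b] = 0;
    }
  }

  arma::uvec cols(n - 1);
  std::vector<double> piTrain(n - 1);
  for (int i = 0; i < n; ++i) {
    int q = 0;
    for (int j = 0; j < n; ++j)
      if ((int)ord[j] != i) cols[q++] = ord[j];
    // usable columns for this fold
    bool iEv = event[i] == 1;
    std::vector<arma::uword> cand;
    for (int b = 0; b < p; ++b) {
      bool atMin = Xt(b, i) == cmin[b];
      bool atMax = !atMin && Xt(b, i) == cmax[b];
      int rm = cntMin[b] - (atMin ? 1 : 0);
      int rM = cntMax[b] - (atMax ? 1 : 0);
      if (rm >= n - 1 || rM >= n - 1) continue;      // constant in training
      if (twoValued[b]) {
        int em = evMin[b] - ((atMin && iEv) ? 1 : 0);
        int eM = evMax[b] - ((atMax && iEv) ? 1 : 0);
        if (em == 0 || eM == 0) continue;            // monotone likelihood
      }
      cand.push_back(b);
    }
    BackwardResult r = cox_backward_engine(Xt, arma::uvec(cand), cols, time,
                                           event, eligible, lex_rank,
                                           p_remove, efron, tol, max_iter,
                                           beta_bound);
    double piHeld = 0.0;
    if (r.empty) {
      std::fill(piTrain.begin(), piTrain.end(), 0.0);
    } else {
      for (int j = 0; j < n - 1; ++j) {
        const double* x = Xt.colptr(cols[j]);
        double s = 0.0;
        for (arma::uword k = 0; k < r.selected.n_elem; ++k)
          s += r.beta[k] * x[r.selected[k]];
        piTrain[j] = s;
      }
      const double* xi = Xt.colptr(i);
      for (arma::uword k = 0; k < r.selected.n_elem; ++k)
        piHeld += r.beta[k] * xi[r.selected[k]];
    }
    // median: mean of the two central order statistics for even counts
    std::vector<double> tmp(piTrain);
    size_t m2 = tmp.size() / 2;
    std::nth_element(tmp.begin(), tmp.begin() + m2, tmp.end());
    double med = tmp[m2];
    if (tmp.size() % 2 == 0) {
      double lower = *std::max_element(tmp.begin(), tmp.begin() + m2);
      med = (med + lower) / 2.0;
    }
    high[i] = piHeld >= med;
    piOut[i] = piHeld;
    if (collect_models) {
      models[i] = List::create(
        _["selected"] = IntegerVector(r.selected.begin(), r.selected.end()),
        _["beta"] = r.beta);
    }
  }
  return List::create(_["high"] = high, _["pi"] = piOut,
                      _["models"] = models);
}
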