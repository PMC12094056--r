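#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for a repeatability animal model
//
//   y = sum_f X_f b_f + Z a + Z_pe pe + e
//
// where each factor f is a partition of the records (one level per record),
// a has prior N(0, A sigma2_a) expressed through the sparse A-inverse, pe is
// iid N(0, sigma2_pe) and e is iid N(0, sigma2_e).  Fixed-factor levels use a
// flat prior (a designated reference level can be held at zero); random
// factors are iid N(0, sigma2_f).  Location effects are updated one at a
// time with on-the-fly residual adjustment: levels of one factor never share
// a record, so a factor's levels are conditionally independent and are
// refreshed in one sweep.  Variances are drawn from scaled-inverse-chi-square
// full conditionals (SS + nu*S2) / chisq(q + nu).
//
// Variance registry order: random environmental factors (in factor order),
// then sigma2_a (if additive present), sigma2_pe (if present), sigma2_e.
// [[Rcpp::export(name = ".gibbs_core")]]
List gibbs_core(NumericVector y,
                List factor_levels, IntegerVector factor_nlev,
                LogicalVector factor_random, IntegerVector factor_skip,
                IntegerVector acow, int n_anim,
                IntegerVector ai_p, IntegerVector ai_j, NumericVector ai_x,
                IntegerVector pecow, int n_pe, IntegerVector pe_to_anim,
                int niter, int burnin, int thin,
                NumericVector nu, NumericVector S2, NumericVector var0,
                bool store_a_samples) {
  const int n = y.size();
  const int nf = factor_levels.size();
  const bool has_a = acow.size() > 0;
  const bool has_pe = pecow.size() > 0;

  // flatten factor structures
  std::vector<const int*> lev(nf);
  std::vector<std::vector<double> > beta(nf), fsum(nf);
  std::vector<std::vector<int> > fcnt(nf);
  std::vector<IntegerVector> lev_keep(nf);
  int n_env = 0;
  for (int f = 0; f < nf; ++f) {
    lev_keep[f] = factor_levels[f];
    lev[f] = INTEGER(lev_keep[f]);
    int K = factor_nlev[f];
    beta[f].assign(K, 0.0);
    fsum[f].assign(K, 0.0);
    fcnt[f].assign(K, 0);
    for (int r = 0; r < n; ++r) fcnt[f][lev[f][r]]++;
    if (factor_random[f]) n_env++;
  }
  const int n_var = n_env + (has_a ? 1 : 0) + (has_pe ? 1 : 0) + 1;
  if (nu.size() != n_var || S2.size() != n_var || var0.size() != n_var)
    stop("prior/start vectors must have length %d (variance registry)", n_var);

  std::vector<double> e(y.begin(), y.end());
  std::vector<double> a(has_a ? n_anim : 0, 0.0), delta_a(has_a ? n_anim : 0);
  std::vector<double> ta(has_a ? n_anim : 0);
  std::vector<int> acnt(has_a ? n_anim : 0, 0);
  const int* ac = has_a ? INTEGER(acow) : 0;
  if (has_a) for (int r = 0; r < n; ++r) acnt[ac[r]]++;

  std::vector<double> pe(has_pe ? n_pe : 0, 0.0), delta_pe(has_pe ? n_pe : 0);
  std::vector<double> tpe(has_pe ? n_pe : 0);
  std::vector<int> pcnt(has_pe ? n_pe : 0, 0);
  const int* pc = has_pe ? INTEGER(pecow) : 0;
  if (has_pe) for (int r = 0; r < n; ++r) pcnt[pc[r]]++;

  const int* aip = INTEGER(ai_p);
  const int* aij = INTEGER(ai_j);
  const double* aix = REAL(ai_x);

  std::vector<double> v(var0.begin(), var0.end());
  const int i_a = n_env;                       // registry indices
  const int i_pe = n_env + (has_a ? 1 : 0);
  const int i_e = n_var - 1;

  const int n_stored = (niter - burnin) / thin;
  if (n_stored <= 0) stop("no samples would be stored (check niter/burnin/thin)");
  NumericMatrix var_samples(n_stored, n_var);
  NumericMatrix a_samples = store_a_samples && has_a
    ? NumericMatrix(n_stored, n_anim) : NumericMatrix(0, 0);
  std::vector<double> a_mean(has_a ? n_anim : 0, 0.0);
  std::vector<double> pe_mean(has_pe ? n_pe : 0, 0.0);
  std::vector<std::vector<double> > beta_mean(nf);
  for (int f = 0; f < nf; ++f) beta_mean[f].assign(factor_nlev[f], 0.0);

  int stored = 0;
  for (int it = 1; it <= niter; ++it) {
    const double var_e = v[i_e];
    if (!R_finite(var_e) || var_e <= 0) stop("non-finite residual variance");

    // --- location effects: factors in given order -------------------------
    int env_k = 0;
    for (int f = 0; f < nf; ++f) {
      const int K = factor_nlev[f];
      double* b = beta[f].data();
      double* s = fsum[f].data();
      const int* l = lev[f];
      std::fill(s, s + K, 0.0);
      for (int r = 0; r < n; ++r) {
        const int li = l[r];
        e[r] += b[li];
        s[li] += e[r];
      }
      double lambda = 0.0;
      if (factor_random[f]) {
        const double vf = v[env_k];
        if (!R_finite(vf) || vf <= 0) stop("non-finite variance for factor %d", f + 1);
        lambda = var_e / vf;
      }
      const int skip = factor_skip[f];
      const int* cnt = fcnt[f].data();
      for (int li = 0; li < K; ++li) {
        if (li == skip) { b[li] = 0.0; continue; }
        const double denom = cnt[li] + lambda;
        if (denom <= 0) stop("empty fixed-effect level in factor %d", f + 1);
        b[li] = s[li] / denom + norm_rand() * std::sqrt(var_e / denom);
      }
      for (int r = 0; r < n; ++r) e[r] -= b[l[r]];
      if (factor_random[f]) env_k++;
    }

    // --- additive genetic effects (pedigree order) ------------------------
    if (has_a) {
      const double var_a = v[i_a];
      if (!R_finite(var_a) || var_a <= 0) stop("non-finite additive variance");
      const double alpha = var_e / var_a;
      std::fill(ta.begin(), ta.end(), 0.0);
      for (int r = 0; r < n; ++r) ta[ac[r]] += e[r];
      for (int i = 0; i < n_anim; ++i) {
        double off = 0.0, dia = 0.0;
        for (int k = aip[i]; k < aip[i + 1]; ++k) {
          const int j = aij[k];
          if (j == i) dia += aix[k]; else off += aix[k] * a[j];
        }
        const double lhs = acnt[i] + alpha * dia;
        const double rhs = ta[i] + acnt[i] * a[i] - alpha * off;
        const double anew = rhs / lhs + norm_rand() * std::sqrt(var_e / lhs);
        delta_a[i] = anew - a[i];
        a[i] = anew;
      }
      for (int r = 0; r < n; ++r) e[r] -= delta_a[ac[r]];
    }

    // --- permanent environmental effects ----------------------------------
    if (has_pe) {
      const double var_pe = v[i_pe];
      if (!R_finite(var_pe) || var_pe <= 0) stop("non-finite pe variance");
      const double lambda = var_e / var_pe;
      std::fill(tpe.begin(), tpe.end(), 0.0);
      for (int r = 0; r < n; ++r) tpe[pc[r]] += e[r];
      for (int i = 0; i < n_pe; ++i) {
        const double denom = pcnt[i] + lambda;
        const double penew = (tpe[i] + pcnt[i] * pe[i]) / denom +
          norm_rand() * std::sqrt(var_e / denom);
        delta_pe[i] = penew - pe[i];
        pe[i] = penew;
      }
      for (int r = 0; r < n; ++r) e[r] -= delta_pe[pc[r]];
    }

    // --- a/pe transfer update ---------------------------------------------
    // For each phenotyped cow, a scalar Gibbs draw on delta in
    // (a_i + delta, pe_i - delta): the likelihood depends on a_i + pe_i
    // only, so the full conditional of delta involves just the two priors,
    //   delta ~ N( (pe_i/var_pe - (Ainv a)_i/var_a) / P, 1/P ),
    //   P = Ainv_ii/var_a + 1/var_pe.
    // This breaks the near-nonidentifiability of the cow-level split that
    // otherwise makes sigma2_a/sigma2_pe mix at a crawl with many records
    // per cow; it is exact (an ordinary Gibbs update on a linear
    // reparameterization) and costs one sparse row product per cow.
    if (has_a && has_pe && pe_to_anim.size() == n_pe) {
      const double var_a = v[i_a], var_pe = v[i_pe];
      const int* p2a = INTEGER(pe_to_anim);
      for (int c = 0; c < n_pe; ++c) {
        const int i = p2a[c];
        double rowdot = 0.0, dia = 0.0;
        for (int k = aip[i]; k < aip[i + 1]; ++k) {
          rowdot += aix[k] * a[aij[k]];
          if (aij[k] == i) dia += aix[k];
        }
        const double P = dia / var_a + 1.0 / var_pe;
        const double m = (pe[c] / var_pe - rowdot / var_a) / P;
        const double d = m + norm_rand() / std::sqrt(P);
        a[i] += d;
        pe[c] -= d;
      }
    }

    // --- variance components ----------------------------------------------
    env_k = 0;
    for (int f = 0; f < nf; ++f) {
      if (!factor_random[f]) continue;
      double ss = 0.0;
      const int K = factor_nlev[f];
      for (int li = 0; li < K; ++li) ss += beta[f][li] * beta[f][li];
      const double df = K + nu[env_k];
      if (df <= 0) stop("non-positive degrees of freedom for a random factor");
      v[env_k] = (ss + nu[env_k] * S2[env_k]) / R::rchisq(df);
      env_k++;
    }
    if (has_a) {
      double ss = 0.0;
      for (int i = 0; i < n_anim; ++i) {
        double rowdot = 0.0;
        for (int k = aip[i]; k < aip[i + 1]; ++k) rowdot += aix[k] * a[aij[k]];
        ss += a[i] * rowdot;
      }
      const double df = n_anim + nu[i_a];
      v[i_a] = (ss + nu[i_a] * S2[i_a]) / R::rchisq(df);
    }
    if (has_pe) {
      double ss = 0.0;
      for (int i = 0; i < n_pe; ++i) ss += pe[i] * pe[i];
      const double df = n_pe + nu[i_pe];
      v[i_pe] = (ss + nu[i_pe] * S2[i_pe]) / R::rchisq(df);
    }
    {
      double ss = 0.0;
      for (int r = 0; r < n; ++r) ss += e[r] * e[r];
      const double df = n + nu[i_e];
      v[i_e] = (ss + nu[i_e] * S2[i_e]) / R::rchisq(df);
    }

    // --- storage ----------------------------------------------------------
    if (it > burnin && (it - burnin) % thin == 0 && stored < n_stored) {
      for (int k = 0; k < n_var; ++k) var_samples(stored, k) = v[k];
      if (store_a_samples && has_a)
        for (int i = 0; i < n_anim; ++i) a_samples(stored, i) = a[i];
      if (has_a) for (int i = 0; i < n_anim; ++i) a_mean[i] += a[i];
      if (has_pe) for (int i = 0; i < n_pe; ++i) pe_mean[i] += pe[i];
      for (int f = 0; f < nf; ++f)
        for (int li = 0; li < factor_nlev[f]; ++li) beta_mean[f][li] += beta[f][li];
      stored++;
    }
    if (it % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  List bm(nf);
  for (int f = 0; f < nf; ++f) {
    NumericVector x(factor_nlev[f]);
    for (int li = 0; li < factor_nlev[f]; ++li) x[li] = beta_mean[f][li] / stored;
    bm[f] = x;
  }
  NumericVector am(has_a ? n_anim : 0), pm(has_pe ? n_pe : 0);
  for (int i = 0; i < (int)a_mean.size(); ++i) am[i] = a_mean[i] / stored;
  for (int i = 0; i < (int)pe_mean.size(); ++i) pm[i] = pe_mean[i] / stored;

  return List::create(
    _["var_samples"] = var_samples,
    _["a_samples"] = a_samples,
    _["a_mean"] = am,
    _["pe_mean"] = pm,
    _["beta_mean"] = bm,
    _["n_stored"] = stored);
}
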