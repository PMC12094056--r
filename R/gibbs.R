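#' Gibbs sampler configuration
#'
#' Chain-length defaults follow the package's reference protocol: 50,000
#' iterations, 10,000 burn-in, storing 1 sample in 10.  Variance priors are
#' scaled-inverse-chi-square with degrees of belief `nu` and scale `s2`;
#' the default `nu = -2, s2 = 0` is flat on the variance (the usual
#' GIBBSF90-style improper default), `nu = 0, s2 = 0` gives the Jeffreys
#' prior `1/sigma2`.  `nu`/`s2` may be scalars or vectors over the variance
#' registry of the system being fitted.
#'
#' @param n_iterations total Gibbs iterations.
#' @param burn_in iterations discarded before storage.
#' @param thin store 1 in `thin` post-burn-in samples.
#' @param seed integer seed (`NULL` = leave the RNG stream alone).
#' @param nu,s2 prior degrees of belief and scale per variance component.
#' @return Object of class `gibbs_config`.
#' @export
gibbs_config <- function(n_iterations = 50000L, burn_in = 10000L, thin = 10L,
                         seed = NULL, nu = -2, s2 = 0) {
  if (!(burn_in < n_iterations)) stop("burn_in must be smaller than n_iterations")
  if (thin < 1L) stop("thin must be >= 1")
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = seed, nu = nu, s2 = s2),
            class = "gibbs_config")
}

#' Run the Gibbs sampler
#'
#' Single-site Gibbs sampling of all location effects and variance
#' components of an [assemble_system()] system.  Location effects are drawn
#' from their full conditional normals (fixed effects under flat priors with
#' corner-point constraints, random environmental levels iid
#' `N(0, sigma2_factor)`, additive effects `N(0, A sigma2_a)` through the
#' sparse A-inverse, pe iid `N(0, sigma2_pe)`); variances from their
#' scaled-inverse-chi-square full conditionals, the additive one using
#' `a' A^{-1} a`.  Deterministic given `config$seed`.
#'
#' @param system an `assembled_system`.
#' @param config a [gibbs_config()].
#' @param store_effects store the additive-effect samples (needed for sire
#'   PTA/PEV; default `TRUE`).
#' @return Object of class `posterior_chains`: stored variance samples
#'   (`$var`, one column per registry entry), additive samples (`$a`, one
#'   column per pedigree animal), posterior-mean location effects, and run
#'   metadata.
#' @export
run_gibbs <- function(system, config = gibbs_config(), store_effects = TRUE) {
  stopifnot(inherits(system, "assembled_system"), inherits(config, "gibbs_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  n_var <- length(system$var_names)
  nu <- rep_len(config$nu, n_var)
  s2 <- rep_len(config$s2, n_var)
  var0 <- rep_len(stats::var(system$y) / n_var, n_var)

  Ainv <- methods::as(methods::as(system$Ainv, "generalMatrix"), "RsparseMatrix")
  res <- .gibbs_core(
    y = as.numeric(system$y),
    factor_levels = lapply(system$factors, function(f) f$codes - 1L),
    factor_nlev = vapply(system$factors, function(f) f$nlev, integer(1)),
    factor_random = vapply(system$factors, function(f) f$random, logical(1)),
    factor_skip = vapply(system$factors, function(f)
      if (is.na(f$skip)) -1L else f$skip - 1L, integer(1)),
    acow = system$acow - 1L,
    n_anim = system$ped$n,
    ai_p = Ainv@p, ai_j = Ainv@j, ai_x = Ainv@x,
    pecow = if (system$n_pe > 0) system$pe_idx - 1L else integer(),
    n_pe = system$n_pe,
    pe_to_anim = if (system$n_pe > 0) match(system$cow_ids, system$ped$id) - 1L else integer(),
    niter = config$n_iterations, burnin = config$burn_in, thin = config$thin,
    nu = nu, S2 = s2, var0 = var0,
    store_a_samples = store_effects)

  vs <- res$var_samples
  colnames(vs) <- system$var_names
  a <- res$a_samples
  if (length(a)) colnames(a) <- system$ped$id
  chains <- structure(list(
    var = vs,
    a = a,
    a_mean = stats::setNames(res$a_mean, system$ped$id),
    pe_mean = if (system$n_pe > 0) stats::setNames(res$pe_mean, system$cow_ids) else NULL,
    beta_mean = stats::setNames(res$beta_mean, names(system$factors)),
    n_stored = res$n_stored,
    var_names = system$var_names,
    cow_ids = system$cow_ids,
    ped_ids = system$ped$id,
    spec = system$spec,
    config = config
  ), class = "posterior_chains")

  low <- vapply(seq_len(ncol(vs)), function(k) {
    e <- .ess(vs[, k])
    !is.na(e) && e < 50
  }, logical(1))
  if (any(low))
    warning("effective sample size < 50 for: ",
            paste(system$var_names[low], collapse = ", "))
  chains
}

#' @export
print.posterior_chains <- function(x, ...) {
  cat("posterior_chains: ", x$n_stored, " stored samples of ",
      length(x$var_names), " variance components",
      if (length(x$a)) paste0(" and ", ncol(x$a), " additive effects"),
      "\n", sep = "")
  s <- summarize_chains(x)
  print(s)
  invisible(x)
}

#' Posterior summaries of the variance components
#'
#' Posterior mean and standard deviation of every stored variance parameter.
#'
#' @param chains a `posterior_chains`.
#' @return Object of class `variance_components`: list with named vectors
#'   `mean` and `sd` over the variance registry; components not in the
#'   fitted model are absent (not zero).
#' @export
summarize_chains <- function(chains) {
  stopifnot(inherits(chains, "posterior_chains"), chains$n_stored > 0L)
  structure(list(
    mean = colMeans(chains$var),
    sd = apply(chains$var, 2L, stats::sd),
    n_stored = chains$n_stored
  ), class = "variance_components")
}

#' Construct variance components directly
#'
#' For feeding externally reported posterior means (e.g. published tables)
#' into [heritability()] / [repeatability()].  Use `NULL` for components a
#' model does not include.
#'
#' @param sigma2_cg,sigma2_a,sigma2_pe,sigma2_e component values (kg^2).
#' @return A `variance_components` object (with `sd` absent).
#' @export
variance_components <- function(sigma2_cg = NULL, sigma2_a, sigma2_pe = NULL,
                                sigma2_e) {
  m <- c(if (!is.null(sigma2_cg)) c(sigma2_cg = sigma2_cg),
         sigma2_a = sigma2_a,
         if (!is.null(sigma2_pe)) c(sigma2_pe = sigma2_pe),
         sigma2_e = sigma2_e)
  if (any(m < 0)) stop("variance components must be nonnegative")
  structure(list(mean = m, sd = NULL), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  df <- data.frame(component = names(x$mean), mean = unname(x$mean))
  if (!is.null(x$sd)) df$sd <- unname(x$sd)
  print(df, row.names = FALSE)
  invisible(x)
}

# effective sample size by Geyer's initial positive sequence
.ess <- function(x) {
  n <- length(x)
  if (n < 4L || stats::sd(x) == 0) return(NA_real_)
  rho <- stats::acf(x, lag.max = min(n - 2L, 500L), plot = FALSE,
                    demean = TRUE)$acf[, 1L, 1L]
  # pair sums Gamma_m = rho_{2m} + rho_{2m+1}, truncate at first negative
  tau <- 0
  m <- 1L
  while (m + 1L <= length(rho)) {
    g <- rho[m] + rho[m + 1L]
    if (g < 0) break
    tau <- tau + g
    m <- m + 2L
  }
  tau <- max(2 * tau - 1, 1 / n)
  n / tau
}

# Geweke-style comparison of the first 10% and last 50% of a chain, with
# ESS-adjusted standard errors instead of spectral densities
.geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[seq_len(max(2L, floor(frac1 * n)))]
  b <- x[seq.int(n - max(2L, floor(frac2 * n)) + 1L, n)]
  va <- stats::var(a) / max(.ess(a), 1, na.rm = TRUE)
  vb <- stats::var(b) / max(.ess(b), 1, na.rm = TRUE)
  if (!is.finite(va + vb) || va + vb == 0) return(NA_real_)
  (mean(a) - mean(b)) / sqrt(va + vb)
}

#' Chain diagnostics
#'
#' Effective sample size and a Geweke-style early-versus-late z statistic
#' for every stored variance parameter; |z| > 3 is flagged.  Constant chains
#' report `NA` diagnostics rather than failing.
#'
#' @param chains a `posterior_chains`.
#' @return `data.frame` with `param`, `ess`, `geweke_z`, `flagged`.
#' @export
gibbs_diagnostics <- function(chains) {
  stopifnot(inherits(chains, "posterior_chains"), chains$n_stored > 0L)
  out <- data.frame(
    param = chains$var_names,
    ess = vapply(seq_along(chains$var_names),
                 function(k) .ess(chains$var[, k]), numeric(1)),
    geweke_z = vapply(seq_along(chains$var_names),
                      function(k) .geweke_z(chains$var[, k]), numeric(1))
  )
  out$flagged <- !is.na(out$geweke_z) & abs(out$geweke_z) > 3
  out
}
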