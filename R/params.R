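.cg_names <- function(vc_names) setdiff(vc_names, c("sigma2_a", "sigma2_pe", "sigma2_e"))

#' Heritability from variance components
#'
#' `h2 = sigma2_a / (sigma2_cg + sigma2_a + sigma2_pe + sigma2_e)` with
#' absent components dropped.  With `include_cg = FALSE` the contemporary-
#' group variance is left out of the denominator (the `h2*` definition used
#' when the contemporary group is random).
#'
#' @param vc a `variance_components` (fitted via [summarize_chains()] or
#'   constructed via [variance_components()]).
#' @param include_cg include the contemporary-group variance in the
#'   denominator (default `TRUE`).
#' @return Heritability ratio in `[0, 1]`.
#' @export
heritability <- function(vc, include_cg = TRUE) {
  stopifnot(inherits(vc, "variance_components"))
  m <- vc$mean
  if (!"sigma2_a" %in% names(m)) stop("sigma2_a is required")
  keep <- if (include_cg) names(m) else setdiff(names(m), .cg_names(names(m)))
  denom <- sum(m[keep])
  if (denom == 0) stop("zero phenotypic variance")
  unname(m[["sigma2_a"]] / denom)
}

#' Repeatability from variance components
#'
#' `r2 = (sigma2_a + sigma2_pe) / (sigma2_cg + sigma2_a + sigma2_pe +
#' sigma2_e)`, the contemporary-group variance included whenever the model
#' has one.  Only defined for repeated-records models (pe present).
#'
#' @param vc a `variance_components`.
#' @return Repeatability ratio in `[0, 1]`.
#' @export
repeatability <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  m <- vc$mean
  if (!"sigma2_pe" %in% names(m))
    stop("repeatability requires a permanent environmental component (daily-record models)")
  denom <- sum(m)
  if (denom == 0) stop("zero phenotypic variance")
  unname((m[["sigma2_a"]] + m[["sigma2_pe"]]) / denom)
}

#' Posterior ratio estimates from stored chains
#'
#' Computes `h2`, `h2*` or `r2` per stored sample and reports the mean and
#' SD of those per-sample ratios, alongside the plug-in ratio of the
#' posterior-mean components.  The two estimators differ (Jensen gap) and
#' both are first-class outputs.
#'
#' @param chains a `posterior_chains`.
#' @param ratio one of `"h2"`, `"h2_star"`, `"r2"`.
#' @return List with `mean`, `sd` (per-sample estimator) and `plugin`.
#' @export
posterior_ratio <- function(chains, ratio = c("h2", "h2_star", "r2")) {
  stopifnot(inherits(chains, "posterior_chains"))
  ratio <- match.arg(ratio)
  v <- chains$var
  nm <- colnames(v)
  cg <- .cg_names(nm)
  if (ratio == "r2" && !"sigma2_pe" %in% nm)
    stop("r2 requires a permanent environmental component")
  num <- if (ratio == "r2") v[, "sigma2_a"] + v[, "sigma2_pe"] else v[, "sigma2_a"]
  den_cols <- if (ratio == "h2_star") setdiff(nm, cg) else nm
  den <- rowSums(v[, den_cols, drop = FALSE])
  per_sample <- num / den
  vc <- summarize_chains(chains)
  plugin <- switch(ratio,
    h2 = heritability(vc, include_cg = TRUE),
    h2_star = heritability(vc, include_cg = FALSE),
    r2 = repeatability(vc))
  list(mean = mean(per_sample), sd = stats::sd(per_sample), plugin = plugin)
}

#' Sire PTA, PEV and reliability
#'
#' For every sire with at least `min_daughters` phenotyped daughters:
#' predicted transmitting ability = half the sire's posterior-mean additive
#' effect; prediction error variance = squared posterior SD of the PTA
#' samples; reliability `REL = 1 - PEV / sigma2_a` with the posterior-mean
#' additive variance from the same run.  Monte-Carlo noise can push REL
#' outside `[0, 1]` for poorly connected sires; values are clipped with a
#' warning.
#'
#' @param chains a `posterior_chains` with stored additive samples.
#' @param ped the [pedigree] used in the fit.
#' @param min_daughters minimum phenotyped daughters (default 10).
#' @return `data.table` with `sire`, `n_daughters`, `pta_kg`, `pev`, `rel`,
#'   ordered by decreasing daughter count.
#' @export
sire_pta <- function(chains, ped, min_daughters = 10L) {
  stopifnot(inherits(chains, "posterior_chains"), inherits(ped, "pedigree"))
  if (!length(chains$a))
    stop("run_gibbs must be called with store_effects = TRUE for sire PTA")
  cow_idx <- match(chains$cow_ids, ped$id)
  sire_idx <- ped$sire[cow_idx]
  tab <- table(sire_idx[!is.na(sire_idx)])
  keep <- as.integer(names(tab))[tab >= min_daughters]
  if (!length(keep)) {
    return(data.table::data.table(sire = character(), n_daughters = integer(),
                                  pta_kg = numeric(), pev = numeric(),
                                  rel = numeric()))
  }
  sigma2_a <- mean(chains$var[, "sigma2_a"])
  pta_samples <- chains$a[, keep, drop = FALSE] / 2
  pta <- colMeans(pta_samples)
  pev <- apply(pta_samples, 2L, stats::var)
  rel <- 1 - pev / sigma2_a
  n_clip <- sum(rel < 0 | rel > 1)
  if (n_clip > 0)
    warning(n_clip, " sire reliability value(s) clipped to [0, 1]")
  rel <- pmin(pmax(rel, 0), 1)
  out <- data.table::data.table(
    sire = ped$id[keep],
    n_daughters = as.integer(tab[as.character(keep)]),
    pta_kg = unname(pta),
    pev = unname(pev),
    rel = unname(rel))
  data.table::setorder(out, -n_daughters, sire)
  out[]
}

#' Reliability histogram counts
#'
#' Bins sire reliabilities for export (counts per bin; no plotting).
#'
#' @param pta output of [sire_pta()].
#' @param breaks bin boundaries over `[0, 1]`.
#' @return `data.table` with `bin_lo`, `bin_hi`, `count`.
#' @export
rel_histogram <- function(pta, breaks = seq(0, 1, by = 0.05)) {
  cl <- cut(pta$rel, breaks = breaks, include.lowest = TRUE, right = TRUE)
  data.table::data.table(bin_lo = utils::head(breaks, -1L),
                         bin_hi = utils::tail(breaks, -1L),
                         count = as.integer(table(cl)))
}

#' Genetic summary of a fitted model
#'
#' One-stop summary: variance components with posterior SDs, `h2`, `h2*`
#' and (for repeated-records models) `r2`, each as the per-sample posterior
#' estimator with SD and as the plug-in ratio of posterior means.
#'
#' @param chains a `posterior_chains`.
#' @return Object of class `genetic_summary`.
#' @export
genetic_summary <- function(chains) {
  vc <- summarize_chains(chains)
  has_cg <- length(.cg_names(names(vc$mean))) > 0
  has_pe <- "sigma2_pe" %in% names(vc$mean)
  out <- list(
    vc = vc,
    h2 = posterior_ratio(chains, "h2"),
    h2_star = if (has_cg) posterior_ratio(chains, "h2_star"),
    r2 = if (has_pe) posterior_ratio(chains, "r2"))
  structure(out, class = "genetic_summary")
}

#' @export
print.genetic_summary <- function(x, ...) {
  print(x$vc)
  fmt <- function(nm, r) {
    if (is.null(r)) return(invisible())
    cat(sprintf("%-8s %.3f (SD %.3f; plug-in %.3f)\n", nm, r$mean, r$sd, r$plugin))
  }
  fmt("h2", x$h2); fmt("h2*", x$h2_star); fmt("r2", x$r2)
  invisible(x)
}
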