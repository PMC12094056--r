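# Internal: true AFC class effects (kg per milking), classes <=22 .. 31+.
# Older first calvers yield somewhat more; magnitudes modest relative to the
# variance components, as in field data.
.afc_effects <- c(0, 0.3, 0.5, 0.65, 0.75, 0.8)

#' Simulation configuration
#'
#' Parameters of the synthetic multi-herd daily-milk-weight generator.  The
#' default variance components are sized like the daily-milk-weight scale of
#' the repeatability-model literature for primiparous Holsteins milked 3x/day
#' (additive ~ 10.85, permanent environment ~ 15.01, residual ~ 14.60,
#' herd-year-season ~ 10.34, pen-day ~ 4.96 kg^2 per milking).
#'
#' @param n_herds number of herds.
#' @param cows_per_herd phenotyped (primiparous) cows per herd.
#' @param n_sires number of founder sires; if `NULL`, derived from
#'   `daughters_per_sire`.
#' @param daughters_per_sire expected daughters per sire (used only when
#'   `n_sires` is `NULL`).
#' @param years span of calving dates in years.
#' @param seasons_per_year must be 4 (seasons are calendar quarters
#'   throughout the package).
#' @param pens_per_herd pens per herd.
#' @param pen_reassign_interval_days days between pen reassignments.
#' @param reassign_on_phenotype if `TRUE`, cows are re-penned by quantile of
#'   their trailing 7-day mean daily yield (top yielders to pen 1) and pens
#'   carry a persistent production-rank effect; if `FALSE`, re-penning is
#'   random.
#' @param milkings_per_day milking sessions per day (1-3, default 3).
#' @param lactation_length_days recorded lactation length (default 300).
#' @param true_sigma2_a,true_sigma2_pe,true_sigma2_e,true_sigma2_hys,true_sigma2_pen_day
#'   true variance components, kg^2 on the per-milking scale.
#' @param pen_day_autocorr lag-1 autocorrelation of the AR(1) pen-day
#'   process, in `[0, 1)`.
#' @param pen_rank_share under phenotype-driven reassignment, the share of
#'   `true_sigma2_pen_day` carried by a persistent production-rank (ration)
#'   component attached to the pen ordering, in `[0, 1)`.  This is the
#'   channel that correlates breeding values with experienced pen effects;
#'   kept minor by default so that a model with HYS groups remains
#'   essentially unbiased, as observed in field analyses.  Ignored (treated
#'   as 0) under random reassignment.
#' @param afc_distribution probabilities over the 6 age-at-first-calving
#'   classes (must sum to 1).
#' @param dim_curve mean yield (kg per milking) for each of the 10 days-in-
#'   milk classes; the lactation-curve shape is carried entirely by these
#'   class means, matching the class structure of the fitted models.
#' @param seed integer seed driving all randomness of the simulation.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_herds = 10L,
                       cows_per_herd = 150L,
                       n_sires = 40L,
                       daughters_per_sire = NULL,
                       years = 5L,
                       seasons_per_year = 4L,
                       pens_per_herd = 4L,
                       pen_reassign_interval_days = 14L,
                       reassign_on_phenotype = FALSE,
                       milkings_per_day = 3L,
                       lactation_length_days = 300L,
                       true_sigma2_a = 10.85,
                       true_sigma2_pe = 15.01,
                       true_sigma2_e = 14.60,
                       true_sigma2_hys = 10.34,
                       true_sigma2_pen_day = 4.96,
                       pen_day_autocorr = 0.9,
                       pen_rank_share = 0.25,
                       afc_distribution = c(0.15, 0.30, 0.25, 0.15, 0.10, 0.05),
                       dim_curve = c(11.5, 13.5, 13.8, 13.4, 12.9,
                                     12.3, 11.7, 11.1, 10.5, 9.9),
                       seed = 1L) {
  cfg <- list(
    n_herds = as.integer(n_herds), cows_per_herd = as.integer(cows_per_herd),
    n_sires = if (is.null(n_sires)) NULL else as.integer(n_sires),
    daughters_per_sire = daughters_per_sire,
    years = as.integer(years), seasons_per_year = as.integer(seasons_per_year),
    pens_per_herd = as.integer(pens_per_herd),
    pen_reassign_interval_days = as.integer(pen_reassign_interval_days),
    reassign_on_phenotype = isTRUE(reassign_on_phenotype),
    milkings_per_day = as.integer(milkings_per_day),
    lactation_length_days = as.integer(lactation_length_days),
    true_sigma2_a = true_sigma2_a, true_sigma2_pe = true_sigma2_pe,
    true_sigma2_e = true_sigma2_e, true_sigma2_hys = true_sigma2_hys,
    true_sigma2_pen_day = true_sigma2_pen_day,
    pen_day_autocorr = pen_day_autocorr,
    pen_rank_share = pen_rank_share,
    afc_distribution = afc_distribution,
    dim_curve = dim_curve,
    seed = as.integer(seed)
  )
  vars <- c("true_sigma2_a", "true_sigma2_pe", "true_sigma2_e",
            "true_sigma2_hys", "true_sigma2_pen_day")
  for (v in vars) if (cfg[[v]] < 0) stop("invariant violated: ", v, " must be >= 0")
  if (cfg$pen_day_autocorr < 0 || cfg$pen_day_autocorr >= 1)
    stop("invariant violated: pen_day_autocorr must be in [0, 1)")
  if (cfg$pen_rank_share < 0 || cfg$pen_rank_share >= 1)
    stop("invariant violated: pen_rank_share must be in [0, 1)")
  if (abs(sum(cfg$afc_distribution) - 1) > 1e-8 || any(cfg$afc_distribution < 0))
    stop("invariant violated: afc_distribution must be probabilities summing to 1")
  if (length(cfg$dim_curve) != 10L)
    stop("invariant violated: dim_curve must have exactly 10 entries")
  if (!cfg$milkings_per_day %in% 1:3)
    stop("invariant violated: milkings_per_day must be in 1..3")
  if (cfg$seasons_per_year != 4L)
    stop("invariant violated: seasons_per_year must be 4 (calendar quarters)")
  if (is.null(cfg$n_sires)) {
    if (is.null(cfg$daughters_per_sire))
      stop("provide n_sires or daughters_per_sire")
    cfg$n_sires <- max(1L, as.integer(round(
      cfg$n_herds * cfg$cows_per_herd / cfg$daughters_per_sire)))
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a multi-herd daily milk-weight dataset
#'
#' Phenotype for cow i, milking m, day t:
#' `y = DIM_class_mean + AFC_effect + HYS + pen_day + a_i + pe_i + e`,
#' with breeding values drawn jointly over a two-generation pedigree
#' (unrelated founder sires/dams, each cow one sire and one dam, sires with
#' daughters across herds), `pe` and `e` iid normal, HYS effects iid normal
#' per herd-year-quarter, and pen-day effects following a stationary AR(1)
#' across days within each pen.  Under `reassign_on_phenotype = TRUE` pens
#' are production-ranked groups: half of the pen-day variance is a persistent
#' rank (ration) component and cows are re-penned every
#' `pen_reassign_interval_days` by quantile of their trailing 7-day mean
#' daily yield, which induces a positive correlation between breeding value
#' and experienced pen effect; under random reassignment the process is pure
#' AR(1) and that correlation is zero in expectation.
#'
#' @param config a [sim_config()].
#' @return Object of class `sim_output`: list with `records`, `cows`,
#'   `pedigree` (data.tables in the package's csv dialects) and `truth`
#'   (true components, per-animal breeding values and pe effects, HYS and
#'   pen-day effect tables).
#' @export
simulate_herds <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  cfg <- config
  set.seed(cfg$seed)

  N <- cfg$n_herds * cfg$cows_per_herd
  L <- cfg$lactation_length_days
  S <- cfg$milkings_per_day
  date0 <- as.IDate("2019-01-01")

  if (N == 0L) {
    empty_rec <- data.table::data.table(
      cow_id = character(), herd = character(), pen = integer(),
      date = as.IDate(character()), milking = integer(), dim = integer(),
      milk_kg = numeric())
    empty_cow <- data.table::data.table(
      cow_id = character(), herd = character(),
      calving_date = as.IDate(character()), afc_months = integer())
    empty_ped <- data.table::data.table(
      animal = character(), sire = character(), dam = character())
    truth <- list(components = .truth_components(cfg),
                  bv = numeric(), pe = numeric(),
                  hys = data.table::data.table(hys = character(), effect = numeric()),
                  pen_day = data.table::data.table(
                    herd = character(), pen = integer(),
                    date = as.IDate(character()), effect = numeric()))
    return(structure(list(records = empty_rec, cows = empty_cow,
                          pedigree = empty_ped, truth = truth),
                     class = "sim_output"))
  }

  cow_id <- sprintf("C%04d", seq_len(N))
  herd_of <- rep(sprintf("H%02d", seq_len(cfg$n_herds)), each = cfg$cows_per_herd)
  sire_of <- sample.int(cfg$n_sires, N, replace = TRUE)
  sire_id <- sprintf("S%03d", seq_len(cfg$n_sires))
  dam_id <- sprintf("D%04d", seq_len(N))  # one unique dam per cow

  # breeding values over the two-generation pedigree
  a_sire <- stats::rnorm(cfg$n_sires, 0, sqrt(cfg$true_sigma2_a))
  a_dam <- stats::rnorm(N, 0, sqrt(cfg$true_sigma2_a))
  a_cow <- 0.5 * (a_sire[sire_of] + a_dam) +
    stats::rnorm(N, 0, sqrt(0.5 * cfg$true_sigma2_a))
  pe_cow <- stats::rnorm(N, 0, sqrt(cfg$true_sigma2_pe))

  calving <- date0 + sample.int(cfg$years * 365L, N, replace = TRUE) - 1L
  afc_cl <- sample.int(6L, N, replace = TRUE, prob = cfg$afc_distribution)
  afc_lo <- c(20L, 23L, 25L, 27L, 29L, 31L)
  afc_hi <- c(22L, 24L, 26L, 28L, 30L, 34L)
  afc_months <- afc_lo[afc_cl] +
    floor(stats::runif(N) * (afc_hi[afc_cl] - afc_lo[afc_cl] + 1L))

  # HYS effects over all herd x year x quarter combinations
  hys_lab_cow <- assign_hys(herd_of, calving)
  yrs <- sort(unique(data.table::year(calving)))
  hys_all <- as.vector(outer(
    sprintf("H%02d", seq_len(cfg$n_herds)),
    as.vector(outer(yrs, 1:4, function(y, q) paste0(y, "-Q", q))),
    function(h, yq) paste0(h, "-", yq)))
  hys_eff <- stats::setNames(
    stats::rnorm(length(hys_all), 0, sqrt(cfg$true_sigma2_hys)), hys_all)

  # pen-day effects: [herd x pen, day] matrix over the full calendar span
  n_days <- as.integer(max(calving) - date0) + L + 1L
  K <- cfg$pens_per_herd
  rho <- cfg$pen_day_autocorr
  s2pd <- cfg$true_sigma2_pen_day
  phi <- if (cfg$reassign_on_phenotype) cfg$pen_rank_share else 0
  s2ar <- (1 - phi) * s2pd
  pen_rank_eff <- if (phi > 0 && K > 1) {
    cr <- (K:1) - (K + 1) / 2  # pen 1 = top production group
    cr * sqrt(phi * s2pd / mean(cr^2))
  } else rep(0, K)
  np <- cfg$n_herds * K
  pd <- matrix(0, np, n_days)
  if (s2ar > 0) {
    pd[, 1L] <- stats::rnorm(np, 0, sqrt(s2ar))
    innov_sd <- sqrt(s2ar * (1 - rho^2))
    for (t in 2:n_days) pd[, t] <- rho * pd[, t - 1L] + stats::rnorm(np, 0, innov_sd)
  }
  pd <- pd + rep(pen_rank_eff, times = cfg$n_herds)
  herd_idx <- match(herd_of, sprintf("H%02d", seq_len(cfg$n_herds)))
  row_of <- function(h_idx, pen) (h_idx - 1L) * K + pen

  # day-by-day simulation with pen dynamics
  calv_off <- as.integer(calving - date0)   # calving at day offset (0-based)
  pen_cur <- sample.int(K, N, replace = TRUE)
  buf <- matrix(NA_real_, N, 7L)            # trailing daily totals
  se <- sqrt(cfg$true_sigma2_e)
  base_cow <- a_cow + pe_cow + .afc_effects[afc_cl] + hys_eff[hys_lab_cow]

  out_cow <- out_pen <- out_day <- out_dim <- vector("list", n_days)
  out_y <- vector("list", n_days)
  for (t in seq_len(n_days) - 1L) {
    dim_t <- t - calv_off + 1L
    act <- which(dim_t >= 1L & dim_t <= L)
    if (t %% cfg$pen_reassign_interval_days == 0L && length(act)) {
      tm <- rowMeans(buf[act, , drop = FALSE], na.rm = TRUE)
      for (h in unique(herd_idx[act])) {
        ih <- act[herd_idx[act] == h]
        n_h <- length(ih)
        ord <- if (cfg$reassign_on_phenotype) {
          order(-tm[match(ih, act)], stats::runif(n_h))
        } else sample.int(n_h)
        # equal-size quantile groups: first n_h/K of ord -> pen 1, etc.
        pen_cur[ih[ord]] <- rep(seq_len(K), each = ceiling(n_h / K))[seq_len(n_h)]
      }
    }
    if (!length(act)) next
    d <- dim_t[act]
    dcl <- ceiling(pmin(d, 300L) / 30)
    mu <- cfg$dim_curve[dcl] + base_cow[act] +
      pd[row_of(herd_idx[act], pen_cur[act]), t + 1L]
    yday <- matrix(mu, length(act), S) +
      matrix(stats::rnorm(length(act) * S, 0, se), length(act), S)
    buf[act, (d - 1L) %% 7L + 1L] <- rowSums(yday)
    out_cow[[t + 1L]] <- rep(act, S)
    out_pen[[t + 1L]] <- rep(pen_cur[act], S)
    out_day[[t + 1L]] <- rep.int(t, length(act) * S)
    out_dim[[t + 1L]] <- rep(d, S)
    out_y[[t + 1L]] <- as.vector(yday)
  }

  ci <- unlist(out_cow, use.names = FALSE)
  ns <- lengths(out_cow) / S
  records <- data.table::data.table(
    cow_id = cow_id[ci],
    herd = herd_of[ci],
    pen = unlist(out_pen, use.names = FALSE),
    date = date0 + unlist(out_day, use.names = FALSE),
    milking = unlist(lapply(ns[ns > 0], function(k) rep(seq_len(S), each = k)),
                     use.names = FALSE),
    dim = unlist(out_dim, use.names = FALSE),
    milk_kg = unlist(out_y, use.names = FALSE)
  )
  data.table::setkey(records, cow_id, date, milking)

  cows <- data.table::data.table(cow_id = cow_id, herd = herd_of,
                                 calving_date = calving,
                                 afc_months = as.integer(afc_months))
  pedigree <- data.table::data.table(
    animal = c(sire_id, dam_id, cow_id),
    sire = c(rep("0", cfg$n_sires + N), sire_id[sire_of]),
    dam = c(rep("0", cfg$n_sires + N), dam_id))

  pd_dt <- data.table::data.table(
    herd = rep(sprintf("H%02d", rep(seq_len(cfg$n_herds), each = K)), n_days),
    pen = rep(rep(seq_len(K), cfg$n_herds), n_days),
    date = rep(date0 + seq_len(n_days) - 1L, each = np),
    effect = as.vector(pd))
  truth <- list(
    components = .truth_components(cfg),
    bv = stats::setNames(c(a_sire, a_dam, a_cow), c(sire_id, dam_id, cow_id)),
    pe = stats::setNames(pe_cow, cow_id),
    hys = data.table::data.table(hys = hys_all, effect = unname(hys_eff)),
    pen_day = pd_dt,
    afc_effects = .afc_effects)
  structure(list(records = records, cows = cows, pedigree = pedigree,
                 truth = truth), class = "sim_output")
}

.truth_components <- function(cfg) {
  c(sigma2_a = cfg$true_sigma2_a, sigma2_pe = cfg$true_sigma2_pe,
    sigma2_e = cfg$true_sigma2_e, sigma2_hys = cfg$true_sigma2_hys,
    sigma2_pen_day = cfg$true_sigma2_pen_day)
}

#' @export
print.sim_output <- function(x, ...) {
  cat("sim_output: ", nrow(x$records), " records, ", nrow(x$cows), " cows, ",
      nrow(x$pedigree), " pedigree animals\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to csv files
#'
#' Writes `records.csv`, `cows.csv`, `pedigree.csv` (0 = unknown parent) and
#' `truth.csv` (long `name,value` format: variance components, then one row
#' per animal for breeding values and permanent environmental effects) into
#' `directory`.  Round-trips losslessly through [read_records()],
#' [read_cows()] and [read_pedigree()].
#'
#' @param output a `sim_output`.
#' @param directory output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_sim <- function(output, directory) {
  stopifnot(inherits(output, "sim_output"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(directory, c("records.csv", "cows.csv", "pedigree.csv",
                                  "truth.csv"))
  data.table::fwrite(output$records, paths[1L])
  data.table::fwrite(output$cows, paths[2L])
  data.table::fwrite(output$pedigree, paths[3L])
  tr <- output$truth
  truth_long <- data.table::data.table(
    name = c(names(tr$components),
             if (length(tr$bv)) paste0("bv.", names(tr$bv)),
             if (length(tr$pe)) paste0("pe.", names(tr$pe))),
    value = c(unname(tr$components), unname(tr$bv), unname(tr$pe)))
  data.table::fwrite(truth_long, paths[4L])
  invisible(paths)
}
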