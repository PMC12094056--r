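test_that("sim_config validates its invariants by name", {
  expect_error(sim_config(true_sigma2_a = -1), "true_sigma2_a")
  expect_error(sim_config(pen_day_autocorr = 1), "pen_day_autocorr")
  expect_error(sim_config(afc_distribution = rep(0.2, 6)), "afc_distribution")
  expect_error(sim_config(dim_curve = 1:9), "dim_curve")
  expect_error(sim_config(milkings_per_day = 4), "milkings_per_day")
  # n_sires derivable from expected daughters per sire
  cfg <- sim_config(n_herds = 2, cows_per_herd = 100, n_sires = NULL,
                    daughters_per_sire = 40)
  expect_equal(cfg$n_sires, 5L)
})

test_that("simulation is seed-deterministic and seed-sensitive", {
  a <- quick_sim(seed = 3)
  b <- quick_sim(seed = 3)
  d <- quick_sim(seed = 4)
  expect_identical(a, b)
  expect_false(identical(a$records$milk_kg, d$records$milk_kg))
})

test_that("zero additive variance yields exactly constant breeding values", {
  out <- quick_sim(seed = 2, true_sigma2_a = 0)
  expect_equal(stats::var(out$truth$bv), 0)
})

test_that("every phenotyped cow appears in cows and pedigree; truth is complete", {
  out <- quick_sim(seed = 6)
  expect_true(all(out$records$cow_id %in% out$cows$cow_id))
  expect_true(all(out$cows$cow_id %in% out$pedigree$animal))
  expect_setequal(names(out$truth$pe), out$cows$cow_id)
  expect_true(all(out$cows$cow_id %in% names(out$truth$bv)))
  # one truth entry per HYS level and per herd-pen-day level
  expect_false(anyDuplicated(out$truth$hys$hys) > 0)
  expect_false(any(duplicated(out$truth$pen_day[, c("herd", "pen", "date")])))
})

test_that("breeding-value moments match the pedigree design", {
  cfg <- sim_config(n_herds = 10, cows_per_herd = 300, n_sires = 30, years = 1,
                    pens_per_herd = 1, milkings_per_day = 1,
                    lactation_length_days = 30,
                    true_sigma2_a = 11, true_sigma2_hys = 0,
                    true_sigma2_pen_day = 0, seed = 8)
  out <- simulate_herds(cfg)
  bv_cows <- out$truth$bv[out$cows$cow_id]
  expect_lt(abs(stats::var(bv_cows) - 11) / 11, 0.10)

  # paternal half-sib phenotypic covariance ~ sigma2_a / 4 via the
  # between-sire variance component of per-cow mean yields
  rec <- data.table::as.data.table(out$records)
  m <- rec[, .(my = mean(milk_kg)), by = cow_id]
  sire_of <- out$pedigree$sire[match(m$cow_id, out$pedigree$animal)]
  fit <- stats::aov(my ~ sire, data = data.frame(my = m$my, sire = sire_of))
  ms <- summary(fit)[[1]][["Mean Sq"]]
  n0 <- nrow(m) / length(unique(sire_of))
  sb <- (ms[1] - ms[2]) / n0
  s <- length(unique(sire_of))
  se_sb <- sqrt(2 / (s - 1)) * (sb + ms[2] / n0)
  expect_lt(abs(sb - 11 / 4), 3 * se_sb)
})

test_that("total phenotypic variance decomposes into the stated components", {
  cfg <- sim_config(n_herds = 5, cows_per_herd = 200, n_sires = 20, years = 1,
                    pens_per_herd = 2, milkings_per_day = 1,
                    lactation_length_days = 100, seed = 12)
  out <- simulate_herds(cfg)
  expect_gte(nrow(out$records), 1e5)
  fixed_mean <- cfg$dim_curve[ceiling(out$records$dim / 30)] +
    out$truth$afc_effects[afc_class(
      out$cows$afc_months[match(out$records$cow_id, out$cows$cow_id)])]
  expected <- cfg$true_sigma2_a + cfg$true_sigma2_pe + cfg$true_sigma2_e +
    cfg$true_sigma2_hys + cfg$true_sigma2_pen_day + stats::var(fixed_mean)
  expect_lt(abs(stats::var(out$records$milk_kg) - expected) / expected, 0.10)
})

test_that("pen-day effects are AR(1) with the configured autocorrelation", {
  cfg <- sim_config(n_herds = 3, cows_per_herd = 30, n_sires = 5, years = 1,
                    pens_per_herd = 2, milkings_per_day = 1,
                    lactation_length_days = 300, pen_day_autocorr = 0.9,
                    seed = 13)
  out <- simulate_herds(cfg)
  pd <- out$truth$pen_day
  ac1 <- pd[, .(r = stats::cor(effect[-1], effect[-.N])), by = .(herd, pen)]
  expect_gte(min(table(paste(pd$herd, pd$pen))), 300)
  expect_lt(abs(mean(ac1$r) - 0.9), 0.05)
})

test_that("pen assignment policy controls the breeding-value / pen-effect link", {
  experienced_cor <- function(out) {
    rec <- data.table::as.data.table(out$records)[milking == 1]
    rec <- merge(rec, out$truth$pen_day, by = c("herd", "pen", "date"))
    percow <- rec[, .(pen_eff = mean(effect)), by = cow_id]
    stats::cor(out$truth$bv[percow$cow_id], percow$pen_eff)
  }
  base <- list(n_herds = 4, cows_per_herd = 150, n_sires = 20, years = 1,
               pens_per_herd = 4, milkings_per_day = 1,
               lactation_length_days = 150, pen_day_autocorr = 0.95)
  r_random <- experienced_cor(simulate_herds(do.call(sim_config,
    c(base, list(reassign_on_phenotype = FALSE, seed = 14)))))
  r_pheno <- experienced_cor(simulate_herds(do.call(sim_config,
    c(base, list(reassign_on_phenotype = TRUE, seed = 14)))))
  expect_lt(abs(r_random), 0.12)   # zero up to Monte-Carlo error
  expect_gt(r_pheno, 0)            # sign only, per the grouping mechanism
})

test_that("write_sim round-trips through the readers", {
  out <- quick_sim(seed = 9, cows_per_herd = 20, lactation_length_days = 20)
  dir <- tempfile()
  write_sim(out, dir)
  rec <- suppressWarnings(read_records(file.path(dir, "records.csv")))
  cows <- read_cows(file.path(dir, "cows.csv"))
  ped <- read_pedigree(file.path(dir, "pedigree.csv"))
  expect_equal(nrow(rec), nrow(out$records))
  expect_equal(cows$calving_date, out$cows$calving_date)
  back <- data.frame(animal = ped$id,
                     sire = ifelse(is.na(ped$sire), "0", ped$id[ped$sire]),
                     dam = ifelse(is.na(ped$dam), "0", ped$id[ped$dam]))
  orig <- out$pedigree[match(back$animal, out$pedigree$animal)]
  expect_identical(back$sire, orig$sire)
  expect_identical(back$dam, orig$dam)
  truth <- data.table::fread(file.path(dir, "truth.csv"))
  expect_equal(nrow(truth), 5L + length(out$truth$bv) + length(out$truth$pe))
})

test_that("an empty simulation writes valid header-only files", {
  out <- simulate_herds(sim_config(n_herds = 0, cows_per_herd = 0, n_sires = 1))
  dir <- tempfile()
  write_sim(out, dir)
  rec <- read_records(file.path(dir, "records.csv"))
  expect_equal(nrow(rec), 0L)
  expect_true(all(c("cow_id", "milk_kg") %in% names(rec)))
  expect_equal(nrow(data.table::fread(file.path(dir, "truth.csv"))), 5L)
})
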