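#' @import data.table
#' @importFrom Rcpp sourceCpp
#' @useDynLib penmodel, .registration = TRUE
NULL

# quiet R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  "cow_id", "herd", "pen", "date", "milking", "dim", "milk_kg",
  "calving_date", "afc_months", "hys", "hpm", "dimc", "daily", "n_days",
  "y305", "phen", "afc", "flagged", ".N", "."
))

#' Age-at-first-calving class
#'
#' Six classes: `<=22`, `23-24`, `25-26`, `27-28`, `29-30`, `31+` months.
#' Age 30 falls in class 5; class 6 starts at 31.
#'
#' @param afc_months age at first calving in months (positive).
#' @return Integer class 1..6.
#' @export
afc_class <- function(afc_months) {
  if (any(afc_months <= 0, na.rm = TRUE) || anyNA(afc_months))
    stop("afc_months must be positive")
  findInterval(afc_months, c(0, 23, 25, 27, 29, 31))
}

#' Days-in-milk class
#'
#' Ten 30-day classes covering days 1-300; `class = ceiling(dim / 30)`.
#' Records beyond day 300 fall outside the class system and are returned as
#' `NA` (callers drop them).
#'
#' @param dim_days days in milk (>= 1).
#' @return Integer class 1..10, or `NA` for `dim_days > 300`.
#' @export
dim_class <- function(dim_days) {
  if (any(dim_days < 1, na.rm = TRUE)) stop("dim_days must be >= 1")
  cl <- as.integer(ceiling(dim_days / 30))
  cl[dim_days > 300] <- NA_integer_
  cl
}

#' Herd-year-season label
#'
#' Contemporary group of calving: herd x calving year x calendar quarter
#' (Q1 = Jan-Mar, ..., Q4 = Oct-Dec).
#'
#' @param herd herd id vector.
#' @param calving_date `Date`/`IDate` vector.
#' @return Character labels like `"H7-2021-Q1"`.
#' @export
assign_hys <- function(herd, calving_date) {
  calving_date <- as.Date(calving_date)
  yr <- data.table::year(calving_date)
  q <- (data.table::month(calving_date) - 1L) %/% 3L + 1L
  paste0(herd, "-", yr, "-Q", q)
}

#' Herd-pen-milking-date label
#'
#' Contemporary group of a daily record: herd x pen x milking date.  All
#' milking sessions of one day share the label.
#'
#' @param herd,pen id vectors.
#' @param date milking date (`Date`/`IDate`).
#' @return Character labels like `"H7-P2-2021-04-03"`.
#' @export
assign_hpm <- function(herd, pen, date) {
  paste0(herd, "-P", pen, "-", as.character(as.Date(date)))
}

#' Read daily milk records
#'
#' Expects columns `cow_id,herd,pen,date,milking,dim,milk_kg` with ISO-8601
#' dates, as written by [write_sim()].
#'
#' @param path csv path.
#' @return `data.table` of records.
#' @export
read_records <- function(path) {
  dt <- data.table::fread(path)
  need <- c("cow_id", "herd", "pen", "date", "milking", "dim", "milk_kg")
  if (!all(need %in% names(dt)))
    stop("records file missing columns: ", paste(setdiff(need, names(dt)), collapse = ", "))
  dt[, date := as.IDate(date)]
  n_neg <- dt[milk_kg < 0, .N]
  if (n_neg > 0)
    warning(n_neg, " record(s) with negative milk weight")
  dt[]
}

#' Read cow attributes
#'
#' Expects columns `cow_id,herd,calving_date,afc_months`.  Ages outside the
#' plausible 18-40 month range raise a warning (not an error).
#'
#' @param path csv path.
#' @return `data.table` of cow attributes.
#' @export
read_cows <- function(path) {
  dt <- data.table::fread(path)
  need <- c("cow_id", "herd", "calving_date", "afc_months")
  if (!all(need %in% names(dt)))
    stop("cows file missing columns: ", paste(setdiff(need, names(dt)), collapse = ", "))
  dt[, calving_date := as.IDate(calving_date)]
  n_odd <- dt[afc_months < 18 | afc_months > 40, .N]
  if (n_odd > 0)
    warning(n_odd, " cow(s) with age at first calving outside 18-40 months")
  dt[]
}

#' Apply contemporary-group edits and build the prepared dataset
#'
#' Drops records beyond day 300 of lactation, then iteratively removes
#' records belonging to herd-pen-milking-date (HPM) groups with fewer than
#' `min_group` distinct cows and cows whose herd-year-season (HYS) group has
#' fewer than `min_group` cows with surviving records, until both minima hold
#' (removals shrink other groups, so one pass is not enough).  Factor levels
#' are then recoded to dense ids with label dictionaries retained.
#'
#' @param records daily records (`data.table` as from [read_records()]).
#' @param cows cow attributes (`data.table` as from [read_cows()]).
#' @param min_group minimum distinct cows per HYS and per HPM group
#'   (default 25).
#' @return An object of class `prepared_data`: list with `rec` (a
#'   `data.table` of `phen`, `cow`, `afc`, `dim`, `hys`, `hpm` integer codes,
#'   1-based), `levels` (label dictionaries per factor), `cows` (surviving
#'   cow attributes incl. `hys` label), and `removed` (edit log).
#' @export
apply_edits <- function(records, cows, min_group = 25L) {
  stopifnot(is.data.frame(records), is.data.frame(cows))
  rec <- data.table::as.data.table(records)
  cw <- data.table::as.data.table(cows)
  if (anyNA(match(rec$cow_id, cw$cow_id)))
    stop("records reference cow ids absent from the cow table")
  if (rec[, any(!milking %in% 1:3)]) stop("milking session must be in 1..3")
  if (rec[, any(dim < 1)]) stop("dim must be >= 1")

  n0 <- nrow(rec)
  rec[, dimc := dim_class(dim)]
  rec <- rec[!is.na(dimc)]
  n_dim_dropped <- n0 - nrow(rec)

  cw[, hys := assign_hys(herd, calving_date)]
  rec[, hpm := assign_hpm(herd, pen, date)]
  rec[, hys := cw$hys[match(cow_id, cw$cow_id)]]

  it <- 0L
  n_hpm_dropped <- 0L
  n_hys_cows_dropped <- 0L
  repeat {
    it <- it + 1L
    small_hpm <- rec[, .(k = data.table::uniqueN(cow_id)), by = hpm][k < min_group, hpm]
    n_before <- nrow(rec)
    if (length(small_hpm)) rec <- rec[!hpm %in% small_hpm]
    n_hpm_dropped <- n_hpm_dropped + (n_before - nrow(rec))

    small_hys <- rec[, .(k = data.table::uniqueN(cow_id)), by = hys][k < min_group, hys]
    changed_hys <- FALSE
    if (length(small_hys)) {
      drop_cows <- unique(rec[hys %in% small_hys, cow_id])
      n_hys_cows_dropped <- n_hys_cows_dropped + length(drop_cows)
      rec <- rec[!cow_id %in% drop_cows]
      changed_hys <- TRUE
    }
    if (!length(small_hpm) && !changed_hys) break
    if (nrow(rec) == 0L) stop("no records survive the contemporary-group edits")
  }

  cw <- cw[cow_id %in% unique(rec$cow_id)]
  afc_cl <- afc_class(cw$afc_months)
  rec[, afc := afc_cl[match(cow_id, cw$cow_id)]]

  lev <- list(
    cow = sort(unique(rec$cow_id)),
    afc = sort(unique(rec$afc)),
    dim = sort(unique(rec$dimc)),
    hys = sort(unique(rec$hys)),
    hpm = sort(unique(rec$hpm))
  )
  out_rec <- data.table::data.table(
    phen = rec$milk_kg,
    cow = match(rec$cow_id, lev$cow),
    afc = match(rec$afc, lev$afc),
    dim = match(rec$dimc, lev$dim),
    hys = match(rec$hys, lev$hys),
    hpm = match(rec$hpm, lev$hpm)
  )
  structure(list(
    rec = out_rec,
    levels = lev,
    cows = cw,
    records = rec,  # post-edit raw records (needed for 305-d projection)
    removed = list(dim_records = n_dim_dropped, hpm_records = n_hpm_dropped,
                   hys_cows = n_hys_cows_dropped, sweeps = it)
  ), class = "prepared_data")
}

#' @export
print.prepared_data <- function(x, ...) {
  cat("prepared_data: ", nrow(x$rec), " records, ",
      length(x$levels$cow), " cows, ",
      length(x$levels$hys), " HYS levels, ",
      length(x$levels$hpm), " HPM levels\n", sep = "")
  cat("edits removed: ", x$removed$dim_records, " records past day 300, ",
      x$removed$hpm_records, " records in small HPM groups, ",
      x$removed$hys_cows, " cows in small HYS groups (",
      x$removed$sweeps, " sweeps)\n", sep = "")
  invisible(x)
}

#' 305-day milk yield per cow
#'
#' Projects daily records to a single 305-d lactation yield: the sum of daily
#' totals (milking sessions summed) over days 1-300, scaled by 305/300.
#' Cows with fewer than 250 recorded days are flagged; cows with no records
#' are excluded.
#'
#' @param records daily records.
#' @param cows cow attributes.
#' @return `data.table` with `cow_id`, `herd`, `y305`, `n_days`, `flagged`.
#' @export
make_305d <- function(records, cows) {
  rec <- data.table::as.data.table(records)[dim >= 1 & dim <= 300]
  daily <- rec[, .(daily = sum(milk_kg)), by = .(cow_id, herd, dim)]
  out <- daily[, .(y305 = sum(daily) * 305 / 300, n_days = .N), by = .(cow_id, herd)]
  out[, flagged := n_days < 250]
  out[]
}
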