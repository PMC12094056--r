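#' Model presets
#'
#' The four repeatability-model layouts for milk production with either
#' herd-year-season (HYS) or herd-pen-milking-date (HPM) contemporary
#' groups:
#'
#' * model 1: `305-d milk = AFC + HYS + animal + e` (single record per cow)
#' * model 2: `daily milk = AFC + DIM + HYS + animal + pe + e`
#' * model 3: `daily milk = AFC + DIM + HPM + animal + pe + e`
#' * model 4: `daily milk = AFC + DIM + HYS(fixed) + HPM(random) + animal + pe + e`
#'
#' For models 1-3 the contemporary group is fitted fixed or random via
#' `cg_mode`; model 4 is HYS fixed + HPM random by definition and ignores
#' `cg_mode`.
#'
#' @param model_id 1..4.
#' @param cg_mode `"fixed"` or `"random"` treatment of the contemporary
#'   group (ignored for model 4).
#' @param include_pe override the preset's permanent-environment flag; the
#'   only legal override is leaving it alone.  Requesting pe for model 1 is
#'   an error (one record per cow).
#' @return Object of class `model_spec`.
#' @export
model_preset <- function(model_id, cg_mode = c("fixed", "random"),
                         include_pe = NULL) {
  stopifnot(model_id %in% 1:4)
  cg_mode <- match.arg(cg_mode)
  spec <- switch(as.character(model_id),
    "1" = list(phenotype = "y305", fixed = "AFC", cg = "HYS", pe = FALSE),
    "2" = list(phenotype = "daily", fixed = c("AFC", "DIM"), cg = "HYS", pe = TRUE),
    "3" = list(phenotype = "daily", fixed = c("AFC", "DIM"), cg = "HPM", pe = TRUE),
    "4" = list(phenotype = "daily", fixed = c("AFC", "DIM", "HYS"),
               cg = "HPM", pe = TRUE))
  if (model_id == 4L) cg_mode <- "random"
  if (cg_mode == "fixed") {
    spec$fixed <- c(spec$fixed, spec$cg)
    spec$random_env <- character()
  } else {
    spec$random_env <- spec$cg
  }
  if (!is.null(include_pe)) {
    if (model_id == 1L && isTRUE(include_pe))
      stop("model 1 has one record per cow; a permanent environmental effect is not estimable")
    spec$pe <- isTRUE(include_pe)
  }
  structure(list(
    model_id = as.integer(model_id),
    phenotype = spec$phenotype,
    fixed = spec$fixed,
    random_env = spec$random_env,
    includes_pe = spec$pe,
    includes_additive = TRUE,
    cg_mode = cg_mode
  ), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  rhs <- c(x$fixed,
           if (length(x$random_env)) paste0(x$random_env, "(random)"),
           "animal", if (x$includes_pe) "pe", "e")
  cat("model ", x$model_id, ": ",
      if (x$phenotype == "y305") "305-d milk (kg)" else "daily milk weight (kg)",
      " = ", paste(rhs, collapse = " + "), "\n", sep = "")
  invisible(x)
}

# factor name -> prepared_data column
.factor_col <- c(AFC = "afc", DIM = "dim", HYS = "hys", HPM = "hpm")

#' Assemble a model system for the sampler
#'
#' Builds the phenotype vector, record-to-level incidence maps, the variance
#' registry and the sparse A-inverse for a given model spec and prepared
#' dataset.  Animals in the pedigree without records (sires, dams) still
#' receive additive-effect slots, which is what makes sire PTA available
#' from the chains.  Identifiability: the first fixed factor absorbs the
#' intercept (all levels free); each later fixed factor has its first level
#' constrained to zero.
#'
#' @param spec a [model_preset()] spec.
#' @param prepared a `prepared_data` from [apply_edits()].
#' @param ped a [pedigree] covering every phenotyped cow.
#' @return Object of class `assembled_system`.
#' @export
assemble_system <- function(spec, prepared, ped) {
  stopifnot(inherits(spec, "model_spec"), inherits(prepared, "prepared_data"),
            inherits(ped, "pedigree"))
  missing_cows <- setdiff(prepared$levels$cow, ped$id)
  if (length(missing_cows))
    stop("phenotyped cows missing from pedigree: ",
         paste(utils::head(missing_cows, 10L), collapse = ", "),
         if (length(missing_cows) > 10L) " ...")

  if (spec$phenotype == "daily") {
    rec <- prepared$rec
    y <- rec$phen
    codes <- function(f) rec[[.factor_col[[f]]]]
    cow_of_rec <- rec$cow
    levels_of <- function(f) prepared$levels[[.factor_col[[f]]]]
  } else {
    y305 <- make_305d(prepared$records, prepared$cows)
    cw <- prepared$cows[match(y305$cow_id, prepared$cows$cow_id)]
    afc_codes_all <- afc_class(cw$afc_months)
    hys_all <- cw$hys
    afc_lev <- sort(unique(afc_codes_all))
    hys_lev <- sort(unique(hys_all))
    y <- y305$y305
    codes <- function(f) switch(f,
      AFC = match(afc_codes_all, afc_lev),
      HYS = match(hys_all, hys_lev),
      stop("factor ", f, " not available for the 305-d phenotype"))
    cow_of_rec <- match(y305$cow_id, prepared$levels$cow)
    levels_of <- function(f) switch(f, AFC = afc_lev, HYS = hys_lev)
  }

  fac_names <- c(spec$fixed, spec$random_env)
  factors <- lapply(seq_along(fac_names), function(k) {
    f <- fac_names[k]
    cd <- codes(f)
    is_fixed <- f %in% spec$fixed
    list(name = f, codes = cd, nlev = max(cd), random = !is_fixed,
         labels = levels_of(f),
         # first fixed factor absorbs the intercept; later fixed factors get
         # a corner-point constraint on their first level
         skip = if (is_fixed && match(f, spec$fixed) > 1L) 1L else NA_integer_)
  })
  names(factors) <- fac_names

  f_inb <- inbreeding(ped)
  Ainv <- build_A_inverse(ped, f_inb)
  acow <- match(prepared$levels$cow, ped$id)[cow_of_rec]

  var_names <- c(
    if (length(spec$random_env)) paste0("sigma2_", tolower(spec$random_env)),
    "sigma2_a",
    if (spec$includes_pe) "sigma2_pe",
    "sigma2_e")

  structure(list(
    spec = spec,
    y = y,
    factors = factors,
    acow = acow,
    ped = ped,
    Ainv = Ainv,
    inbreeding = f_inb,
    pe_idx = if (spec$includes_pe) cow_of_rec else integer(),
    n_pe = if (spec$includes_pe) length(prepared$levels$cow) else 0L,
    cow_ids = prepared$levels$cow,
    var_names = var_names
  ), class = "assembled_system")
}

#' @export
print.assembled_system <- function(x, ...) {
  print(x$spec)
  cat(length(x$y), " records, ", x$ped$n, " pedigree animals, factors: ",
      paste(vapply(x$factors, function(f)
        paste0(f$name, "[", f$nlev, if (f$random) ", random" else "", "]"),
        character(1)), collapse = " "),
      "\nvariance registry: ", paste(x$var_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}
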