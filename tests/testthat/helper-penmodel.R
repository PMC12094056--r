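# shared fixtures, all generated in code

# random multi-generation pedigree; parents always precede offspring
random_pedigree <- function(n, seed, p_parent = 0.7) {
  set.seed(seed)
  sire <- dam <- rep("0", n)
  for (i in seq_len(n)) {
    if (i > 2 && stats::runif(1) < p_parent) {
      pair <- sample(i - 1L, 2L)
      sire[i] <- paste0("A", pair[1L])
      dam[i] <- paste0("A", pair[2L])
    }
  }
  pedigree(paste0("A", seq_len(n)), sire, dam)
}

# independent reference implementation of the contemporary-group edits:
# dumb repeated full rescans on plain data frames, dropping one offending
# group class at a time until a full pass changes nothing
edits_oracle <- function(records, cows, min_group) {
  rec <- as.data.frame(records)
  cw <- as.data.frame(cows)
  rec <- rec[rec$dim >= 1 & rec$dim <= 300, , drop = FALSE]
  mo <- as.integer(format(as.Date(cw$calving_date), "%m"))
  hys_of <- stats::setNames(
    paste(cw$herd, format(as.Date(cw$calving_date), "%Y"), (mo - 1) %/% 3 + 1),
    cw$cow_id)
  repeat {
    changed <- FALSE
    hpm <- paste(rec$herd, rec$pen, as.character(rec$date))
    for (g in unique(hpm)) {
      in_g <- hpm == g
      if (length(unique(rec$cow_id[in_g])) < min_group) {
        rec <- rec[!in_g, , drop = FALSE]
        hpm <- hpm[!in_g]
        changed <- TRUE
      }
    }
    hys <- hys_of[as.character(rec$cow_id)]
    for (g in unique(hys)) {
      ids <- unique(rec$cow_id[hys == g])
      if (length(ids) < min_group) {
        keep <- !(rec$cow_id %in% ids)
        rec <- rec[keep, , drop = FALSE]
        hys <- hys[keep]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  rec
}

# small random daily datasets for exercising the edit fixed point
random_edit_dataset <- function(seed) {
  set.seed(seed)
  n_herds <- sample(2:3, 1L)
  cows <- do.call(rbind, lapply(seq_len(n_herds), function(h) {
    k <- sample(8:16, 1L)
    data.frame(cow_id = paste0("h", h, "c", seq_len(k)),
               herd = paste0("H", h),
               calving_date = as.Date("2021-01-01") + sample(0:240, k, TRUE),
               afc_months = sample(20:34, k, TRUE))
  }))
  rec <- do.call(rbind, lapply(seq_len(nrow(cows)), function(i) {
    len <- sample(5:20, 1L)
    data.frame(cow_id = cows$cow_id[i], herd = cows$herd[i],
               pen = sample(1:2, len, TRUE),
               date = cows$calving_date[i] + seq_len(len) - 1L,
               milking = 1L, dim = seq_len(len),
               milk_kg = round(stats::rnorm(len, 12, 3), 2))
  }))
  list(records = rec, cows = cows, min_group = sample(3:6, 1L))
}

# record-identity key for comparing surviving record sets
rec_key <- function(df) {
  sort(paste(df$cow_id, as.character(df$date), df$milking, df$pen, sep = "|"))
}

# small, fast full-pipeline simulation shared by several tests
quick_sim <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_herds = 3, cows_per_herd = 60, n_sires = 8, years = 1,
         pens_per_herd = 2, milkings_per_day = 1,
         lactation_length_days = 100, seed = seed),
    list(...))
  simulate_herds(do.call(sim_config, args))
}

# fake posterior_chains object for params-level unit tests
fake_chains <- function(var, a = NULL, cow_ids = character()) {
  structure(list(var = var, a = a,
                 n_stored = nrow(var), var_names = colnames(var),
                 cow_ids = cow_ids, ped_ids = colnames(a)),
            class = "posterior_chains")
}
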