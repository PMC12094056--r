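test_that("afc_class bins ages as printed, with 30 in the 29-30 class", {
  expect_identical(afc_class(c(22, 24, 28)), c(1L, 2L, 4L))
  expect_identical(afc_class(30), 5L)
  expect_identical(afc_class(31), 6L)
  expect_identical(afc_class(c(18, 23, 25, 27, 29, 40)), c(1L, 2L, 3L, 4L, 5L, 6L))
  expect_error(afc_class(0), "positive")
  expect_error(afc_class(-3), "positive")
})

test_that("dim_class covers days 1-300 in 30-day bins and drops beyond", {
  expect_identical(dim_class(c(1, 30, 31)), c(1L, 1L, 2L))
  expect_identical(dim_class(300), 10L)
  expect_identical(dim_class(301), NA_integer_)
  expect_identical(dim_class(c(60, 61, 299)), c(2L, 3L, 10L))
  expect_error(dim_class(0), ">= 1")
})

test_that("contemporary-group labels follow herd/date structure", {
  expect_identical(assign_hys("H7", as.Date("2021-02-10")), "H7-2021-Q1")
  expect_identical(assign_hys("H7", as.Date("2021-12-31")), "H7-2021-Q4")
  # quarter boundary separates two same-herd cows
  labs <- assign_hys(c("H1", "H1"), as.Date(c("2020-03-31", "2020-04-01")))
  expect_false(labs[1] == labs[2])

  d <- as.Date("2021-04-03")
  # sessions of one day share a label; dates and pens split labels
  expect_length(unique(assign_hpm(rep("H7", 3), rep(2, 3), rep(d, 3))), 1L)
  expect_false(assign_hpm("H7", 2, d) == assign_hpm("H7", 2, d + 1))
  expect_false(assign_hpm("H7", 1, d) == assign_hpm("H7", 2, d))
})

test_that("apply_edits keeps only groups meeting the 25-cow minima", {
  # one 30-cow HYS cohort and one 24-cow cohort in the same herd, with
  # non-overlapping record dates so HPM groups coincide with cohorts
  mk <- function(k, calv, tag) {
    cows <- data.frame(cow_id = paste0(tag, seq_len(k)), herd = "H1",
                       calving_date = as.Date(calv), afc_months = 24)
    rec <- do.call(rbind, lapply(cows$cow_id, function(id)
      data.frame(cow_id = id, herd = "H1", pen = 1L,
                 date = as.Date(calv) + 0:9, milking = 1L, dim = 1:10,
                 milk_kg = 10)))
    list(cows = cows, rec = rec)
  }
  big <- mk(30, "2021-02-01", "b")
  small <- mk(24, "2021-05-01", "s")
  prep <- apply_edits(rbind(big$rec, small$rec), rbind(big$cows, small$cows),
                      min_group = 25)
  expect_setequal(prep$cows$cow_id, big$cows$cow_id)
  expect_equal(nrow(prep$rec), 300L)

  # dataset already satisfying both minima is unchanged
  prep2 <- apply_edits(prep$records, prep$cows, min_group = 25)
  expect_identical(rec_key(prep2$records), rec_key(prep$records))
  expect_error(apply_edits(small$rec, small$cows, min_group = 25),
               "no records survive")
})

test_that("apply_edits matches the brute-force fixed point and is idempotent", {
  for (s in 1:12) {
    d <- random_edit_dataset(s)
    oracle <- edits_oracle(d$records, d$cows, d$min_group)
    got <- try(apply_edits(d$records, d$cows, min_group = d$min_group),
               silent = TRUE)
    if (nrow(oracle) == 0L) {
      expect_s3_class(got, "try-error")
      next
    }
    expect_identical(rec_key(got$records), rec_key(oracle))
    # idempotence
    again <- apply_edits(got$records, got$cows, min_group = d$min_group)
    expect_identical(rec_key(again$records), rec_key(got$records))
  }
})

test_that("prepared factor codes are dense and dictionaries round-trip", {
  d <- random_edit_dataset(99)
  d$min_group <- 2
  prep <- apply_edits(d$records, d$cows, min_group = 2)
  for (col in c("cow", "afc", "dim", "hys", "hpm")) {
    codes <- prep$rec[[col]]
    expect_identical(sort(unique(codes)), seq_along(prep$levels[[col]]))
  }
  # label -> id -> label identity
  expect_identical(prep$levels$hys[match(prep$levels$hys, prep$levels$hys)],
                   prep$levels$hys)
  # every record maps to exactly one HYS and one HPM
  expect_false(anyNA(prep$rec$hys))
  expect_false(anyNA(prep$rec$hpm))
  expect_lte(length(prep$levels$hpm),
             nrow(unique(prep$records[, c("herd", "pen", "date")])))
})

test_that("make_305d projects daily records onto a 305-d yield", {
  # constant 10 kg per session, 3 sessions, 300 days
  rec <- data.frame(cow_id = "c1", herd = "H1", pen = 1,
                    date = rep(as.Date("2021-01-01") + 0:299, each = 3),
                    milking = rep(1:3, 300), dim = rep(1:300, each = 3),
                    milk_kg = 10)
  cows <- data.frame(cow_id = "c1", herd = "H1",
                     calving_date = as.Date("2021-01-01"), afc_months = 24)
  out <- make_305d(rec, cows)
  expect_equal(out$y305, 30 * 300 * 305 / 300)
  expect_false(out$flagged)

  # cow with zero records is absent; cow with few days is flagged
  rec2 <- rec[rec$dim <= 100, ]
  out2 <- make_305d(rec2, cows)
  expect_true(out2$flagged)
  expect_false("ghost" %in% make_305d(rec, cows)$cow_id)
})

test_that("make_305d tracks the simulator's truth closely", {
  out <- quick_sim(seed = 5, lactation_length_days = 300, cows_per_herd = 40,
                   milkings_per_day = 2)
  y <- make_305d(out$records, out$cows)
  tr <- out$truth
  cw <- out$cows[match(y$cow_id, out$cows$cow_id)]
  # predicted lactation total from the truth tables
  dimsum <- sum(sim_config()$dim_curve[ceiling((1:300) / 30)])
  hys_eff <- tr$hys$effect[match(assign_hys(cw$herd, cw$calving_date), tr$hys$hys)]
  pend <- data.table::as.data.table(out$records)[milking == 1]
  pend <- merge(pend, tr$pen_day, by = c("herd", "pen", "date"))
  pen_sum <- pend[, .(ps = sum(effect)), by = cow_id]
  base <- tr$bv[y$cow_id] + tr$pe[y$cow_id] + hys_eff +
    tr$afc_effects[afc_class(cw$afc_months)]
  pred <- 2 * (dimsum + 300 * base + pen_sum$ps[match(y$cow_id, pen_sum$cow_id)]) *
    305 / 300
  expect_gt(stats::cor(y$y305, pred), 0.99)
})
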