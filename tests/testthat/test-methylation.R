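test_that("band types map the four digest patterns and miss on NA", {
  expect_equal(as.character(classify_band_type(c(1, 1, 0, 0),
                                               c(1, 0, 1, 0))),
               c("I", "II", "III", "IV"))
  expect_true(is.na(classify_band_type(NA, 1)))
  expect_true(is.na(classify_band_type(0, NA)))
  expect_error(classify_band_type(2, 1), "0, 1 or NA")
})

test_that("band-type counting pools complete pairs and is additive", {
  m <- toy_matrix()
  whole <- count_band_types(m, "treatment_class")
  # toy matrix has 11 complete (sample, locus) pairs (one NA pair dropped)
  expect_equal(sum(whole$total), 11)

  by_group <- count_band_types(m, "treatment_group")
  for (col in c("n_I", "n_II", "n_III", "n_IV"))
    expect_equal(sum(by_group[[col]]), sum(whole[[col]]))

  # invariant to sample and locus permutation
  perm <- band_matrix(m$calls_M[c(3, 1, 4, 2), c(2, 3, 1)],
                      m$calls_H[c(3, 1, 4, 2), c(2, 3, 1)],
                      m$samples[c(3, 1, 4, 2), ], "MSAP",
                      m$locus_ids[c(2, 3, 1)])
  cp <- count_band_types(perm, "treatment_class")
  expect_equal(cp[order(cp$group), ], whole[order(whole$group), ],
               ignore_attr = TRUE)

  # one sample holding each pattern once
  s1 <- band_matrix(matrix(c(1, 1, 0, 0), 1), matrix(c(1, 0, 1, 0), 1),
                    sample_meta("only", "Control"))
  expect_equal(unlist(count_band_types(s1)[c("n_I", "n_II", "n_III",
                                             "n_IV")]),
               c(n_I = 1L, n_II = 1L, n_III = 1L, n_IV = 1L))
})

test_that("simulated band-type counts equal the truth-record tallies", {
  sim <- simulate_band_matrix(sim_config("MSAP", seed = 11))
  cnt <- count_band_types(sim$matrix, "treatment_group")
  tal <- sim$truth$group_tallies[cnt$group, ]
  expect_equal(as.matrix(cnt[c("n_I", "n_II", "n_III", "n_IV")]),
               unname(tal), ignore_attr = TRUE)
})

test_that("methylation rates reproduce the published control columns", {
  msap <- methylation_rates(published_counts("msap"))
  ctl <- msap[msap$group == "Control", ]
  expect_equal(round_half_up(ctl$total_pct), 58.69)
  expect_equal(round_half_up(ctl$full_pct), 13.08)
  expect_equal(round_half_up(ctl$hemi_pct), 19.07)
  expect_equal(round_half_up(ctl$non_pct), 41.31)

  tmd <- methylation_rates(published_counts("tmd"))
  ctl2 <- tmd[tmd$group == "Control", ]
  expect_equal(round_half_up(c(ctl2$total_pct, ctl2$full_pct,
                               ctl2$hemi_pct, ctl2$non_pct)),
               c(57.27, 23.35, 7.05, 42.73))
})

test_that("rate identities hold at full precision for arbitrary counts", {
  set.seed(42)
  for (i in 1:50) {
    cnt <- band_type_counts_table("g", sample(0:500, 1), sample(0:500, 1),
                                  sample(0:500, 1), sample(1:500, 1))
    r <- methylation_rates(cnt)
    expect_equal(r$total_pct + r$non_pct, 100, tolerance = 1e-12)
    expect_equal(r$full_pct + r$hemi_pct + r$typeIV_pct, r$total_pct,
                 tolerance = 1e-12)
    expect_true(all(unlist(r[2:6]) >= 0 & unlist(r[2:6]) <= 100))
  }
  # all-unmethylated limit and zero-total error
  lim <- methylation_rates(band_type_counts_table("g", 7, 0, 0, 0))
  expect_equal(c(lim$total_pct, lim$non_pct), c(0, 100))
  expect_error(methylation_rates(band_type_counts_table("g", 0, 0, 0, 0)),
               "zero total")
})

test_that("class contrasts reproduce the published treatment averages", {
  classes <- design_classes()
  msap <- rate_contrasts(methylation_rates(published_counts("msap")),
                         classes, reference = "Control")
  comb_total <- msap[msap$class == "DNMTi+GR" & msap$rate == "total_pct", ]
  expect_equal(round_half_up(comb_total$delta), -4.87)

  tmd <- rate_contrasts(methylation_rates(published_counts("tmd")),
                        classes, reference = "Control")
  gr_full <- tmd[tmd$class == "GR" & tmd$rate == "full_pct", ]
  expect_equal(round_half_up(gr_full$mean), 14.06)

  # a group contrasted with itself is zero for every rate
  self <- rate_contrasts(methylation_rates(published_counts("msap")),
                         reference = "Control")
  expect_true(all(self$delta[self$class == "Control"] == 0))
  expect_error(rate_contrasts(methylation_rates(published_counts("msap")),
                              reference = "nope"), "unknown reference")
})
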