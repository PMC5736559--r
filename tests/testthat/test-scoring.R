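test_that("euclidean distance matches hand values and the loop oracle", {
  u <- rep(0.5, 10)
  expect_equal(euclidean_distance(u, u), 0)
  expect_equal(euclidean_distance(u + 0.1, u), sqrt(10 * 0.01))

  set.seed(41)
  for (i in 1:100) {
    a <- runif(10); b <- runif(10)
    expect_lt(abs(euclidean_distance(a, b) - naive_euclidean(a, b)), 1e-12)
    perm <- sample(10)
    expect_equal(euclidean_distance(a[perm], b[perm]),
                 euclidean_distance(a, b))
  }
  expect_error(euclidean_distance(u, u[-1]), "equal length")
  expect_error(euclidean_distance(c(u[-1], NA), u), "finite")
})

test_that("plateau filters apply the published cutoffs to control curves", {
  melter <- unit_curve(10, 0.05, 50)       # first3 high, last3 low
  high_bottom <- unit_curve(10, 0.45, 50)  # last3 avg > 0.3
  early <- unit_curve(12, 0.05, 39)        # first3 avg < 0.85
  ds <- make_dataset(function(cond, rep) rbind(melter, high_bottom, early),
                     ids = c("M", "HB", "E"))
  pf <- plateau_filter(ds)
  expect_equal(pf$retained, c(TRUE, FALSE, FALSE))
  expect_false(pf$pass_bottom[2]); expect_true(pf$pass_top[2])
  expect_false(pf$pass_top[3]); expect_true(pf$pass_bottom[3])
  expect_equal(pf$avg_first3[1], mean(melter[1:3]))
  expect_equal(pf$avg_last3[1], mean(melter[8:10]))

  # averages pool control replicates
  ds$values["M", "vehicle_r2", ] <- melter * 0.9
  pf2 <- plateau_filter(ds)
  expect_equal(pf2$avg_first3[1], mean(c(melter[1:3], 0.9 * melter[1:3])))

  # incomplete control series is excluded, not an error
  ds$values["M", "vehicle_r1", 2] <- NA
  pf3 <- plateau_filter(ds)
  expect_false(pf3$complete_control[1])
  expect_false(pf3$retained[1])
})

test_that("shift scores follow the ED-score equation", {
  curve <- unit_curve(10, 0.05, 50)
  four_same <- shift_scores(rbind(curve, curve), rbind(curve, curve),
                            c(50, 50), c(50, 50))
  expect_equal(four_same$sum_ed_inter_treatment, 0)
  expect_equal(four_same$sum_ed_inter_replicate, 0)
  expect_equal(four_same$ed_score, 0)
  expect_equal(four_same$delta_tm, 0)

  # direct formula: ED score = sum_T / 10^sum_R on random curve sets
  set.seed(43)
  for (i in 1:50) {
    v <- matrix(runif(20), nrow = 2)
    cpd <- matrix(runif(20), nrow = 2)
    ss <- shift_scores(v, cpd, c(50, 50), c(52, 51))
    sum_t <- naive_euclidean(cpd[1, ], v[1, ]) +
      naive_euclidean(cpd[1, ], v[2, ]) +
      naive_euclidean(cpd[2, ], v[1, ]) +
      naive_euclidean(cpd[2, ], v[2, ])
    sum_r <- naive_euclidean(v[1, ], v[2, ]) +
      naive_euclidean(cpd[1, ], cpd[2, ])
    expect_equal(ss$sum_ed_inter_treatment, sum_t, tolerance = 1e-12)
    expect_equal(ss$sum_ed_inter_replicate, sum_r, tolerance = 1e-12)
    expect_equal(ss$ed_score, sum_t / 10^sum_r, tolerance = 1e-12)
    expect_equal(ss$delta_tm, mean(c(52 - 50, 51 - 50)))
  }

  # matched pairing uses replicate-matched treated-control terms only
  v <- matrix(runif(20), nrow = 2); cpd <- matrix(runif(20), nrow = 2)
  ssm <- shift_scores(v, cpd, c(50, 50), c(51, 51),
                      analysis_config(ed_pairing = "matched_pairs"))
  expect_equal(ssm$sum_ed_inter_treatment,
               naive_euclidean(cpd[1, ], v[1, ]) +
                 naive_euclidean(cpd[2, ], v[2, ]), tolerance = 1e-12)

  # undefined Tm anywhere leaves delta Tm undefined but keeps the ED score
  ssna <- shift_scores(v, cpd, c(50, NA), c(51, 51))
  expect_true(is.na(ssna$delta_tm))
  expect_false(is.na(ssna$ed_score))

  # incomplete curves: no scores
  v[1, 3] <- NA
  expect_false(shift_scores(v, cpd, c(50, 50), c(51, 51))$complete)
})

test_that("inter-treatment ED grows with the injected shift, noise-free", {
  base <- unit_curve(10, 0.05, 50)
  prev <- 0
  for (delta in c(1, 2, 4, 6)) {
    shifted <- unit_curve(10, 0.05, 50 + delta)
    ss <- shift_scores(rbind(base, base), rbind(shifted, shifted),
                       c(50, 50), c(50 + delta, 50 + delta))
    expect_equal(ss$sum_ed_inter_replicate, 0)
    expect_gt(ss$sum_ed_inter_treatment, prev)
    prev <- ss$sum_ed_inter_treatment
  }
})

test_that("replicate-independent noise raises the replicate penalty", {
  base <- unit_curve(10, 0.05, 50)
  set.seed(47)
  noisy_scores <- replicate(200, {
    v <- rbind(base + rnorm(10, 0, 0.05), base + rnorm(10, 0, 0.05))
    cpd <- rbind(base + rnorm(10, 0, 0.05), base + rnorm(10, 0, 0.05))
    unlist(shift_scores(pmax(v, 0), pmax(cpd, 0), c(50, 50), c(50, 50))[
      c("sum_ed_inter_replicate", "ed_score")])
  })
  expect_true(all(noisy_scores["sum_ed_inter_replicate", ] > 0))
  # the exponential penalty keeps the null ED score below the raw signal
  clean <- shift_scores(rbind(base, base), rbind(base, base),
                        c(50, 50), c(50, 50))$ed_score
  expect_gt(mean(noisy_scores["ed_score", ]), clean)  # noise adds signal
  # but the penalty bounds it: score < sum_T always when sum_R > 0
  expect_true(all(noisy_scores["ed_score", ] >= 0))
})

test_that("score_dataset funnels proteins with recorded exclusion reasons", {
  sim <- generate_dataset(generator_config(n_proteins = 60, n_targets = 3,
                                           noise_sd = 0,
                                           run_baseline_distortion = 0,
                                           seed = 19))
  out <- score_dataset(sim$dataset)
  sc <- out$scores
  cls <- sim$truth$class
  expect_true(all(is.na(sc$ed_score[!sc$retained])))
  expect_match(sc$exclusion_reason[cls == "non_melter"],
               "high bottom plateau")
  expect_match(sc$exclusion_reason[cls == "early_melter"], "top plateau")
  expect_true(all(!is.na(sc$ed_score[sc$retained])))
  # zero-noise targets carry the injected shift; nulls are exactly null
  targ <- sim$truth$is_target
  expect_true(all(sc$ed_score[sc$retained & !targ] == 0))
  expect_true(all(sc$delta_tm[sc$retained & !targ] == 0))
  tshift <- sim$truth$true_tm05_compound - sim$truth$true_tm05_vehicle
  expect_equal(sc$delta_tm[targ], tshift[targ], tolerance = 1e-4)
})

test_that("fitted-curve basis scores on the fitted grid values", {
  sim <- generate_dataset(generator_config(n_proteins = 40, n_targets = 2,
                                           noise_sd = 0,
                                           run_baseline_distortion = 0,
                                           seed = 29))
  raw <- score_dataset(sim$dataset)
  fitted <- score_dataset(sim$dataset,
                          analysis_config(curve_basis = "fitted_curves"))
  # noise-free: fitted curves reproduce the data, so the bases agree
  keep <- !is.na(raw$scores$ed_score)
  expect_equal(fitted$scores$ed_score[keep], raw$scores$ed_score[keep],
               tolerance = 1e-4)
})

test_that("analysis_config rejects out-of-range constants", {
  expect_error(analysis_config(bottom_plateau_cutoff = 0), "bottom")
  expect_error(analysis_config(tm_level = 1.2), "tm_level")
  expect_error(analysis_config(mad_multiplier = -1), "mad_multiplier")
  expect_error(analysis_config(ed_pairing = "something"))
})
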