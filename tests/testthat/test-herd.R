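test_that("herd generation is deterministic given (config, seed) and has the configured structure", {
  cfg <- herd_config()
  h1 <- generate_herd(cfg, seed = 11)
  h2 <- generate_herd(cfg, seed = 11)
  expect_identical(h1, h2)
  expect_false(identical(h1, generate_herd(cfg, seed = 12)))

  # litter count = groups x litters_per_group; sizes within the range
  expect_equal(length(unique(h1$litter_id)),
               length(cfg$groups) * cfg$litters_per_group)
  sizes <- table(h1$litter_id)
  expect_true(all(sizes >= cfg$litter_size_range[1] &
                  sizes <= cfg$litter_size_range[2]))
  # every pig in exactly one litter and one regime
  expect_equal(anyDuplicated(h1$pig_id), 0L)
  expect_true(all(h1$regime %in% c("conventional", "welfare_friendly")))

  # dead => no slaughter weight and flagged weak-or-dead
  expect_true(all(is.na(h1$slaughter_weight[h1$dead])))
  expect_true(all(h1$weak_or_dead[h1$dead]))
  # surviving weights positive
  expect_true(all(h1$slaughter_weight[!h1$dead] > 0))
})

test_that("adding a group does not perturb earlier groups' records", {
  base <- herd_config()
  extended <- herd_config(groups = 1:5,
                          group_regime = c(`1` = "conventional",
                                           `2` = "conventional",
                                           `3` = "welfare_friendly",
                                           `4` = "welfare_friendly",
                                           `5` = "welfare_friendly"))
  h4 <- generate_herd(base, seed = 21)
  h5 <- generate_herd(extended, seed = 21)
  expect_identical(h4, h5[h5$group <= 4, ])
})

test_that("moments and rates are recovered at large n (4 SE bound)", {
  cfg <- big_herd_config(1e5)
  herd <- generate_herd(cfg, seed = 31)
  for (r in c("conventional", "welfare_friendly")) {
    sub <- herd[herd$regime == r, ]
    n <- nrow(sub)
    expect_gte(n, 1e5 * 0.8)
    p <- cfg$mortality_prob[[r]]
    expect_lt(abs(mean(sub$dead) - p), 4 * sqrt(p * (1 - p) / n))
    w <- sub$slaughter_weight[!sub$dead]
    expect_lt(abs(mean(w) - cfg$slaughter_weight_mean[[r]]),
              4 * cfg$slaughter_weight_sd[[r]] / sqrt(length(w)))
  }
})

test_that("degenerate sd = 0 puts every survivor exactly at the regime mean", {
  cfg <- herd_config(slaughter_weight_sd = c(conventional = 0,
                                             welfare_friendly = 0))
  herd <- generate_herd(cfg, seed = 41)
  for (r in c("conventional", "welfare_friendly")) {
    w <- herd$slaughter_weight[herd$regime == r & !herd$dead]
    expect_true(all(w == cfg$slaughter_weight_mean[[r]]))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(herd_config(mortality_prob = c(conventional = 1.4,
                                              welfare_friendly = 0.05)),
               "probability")
  expect_error(herd_config(slaughter_weight_sd = c(conventional = -1,
                                                   welfare_friendly = 14)),
               "non-negative")
  expect_error(herd_config(litter_size_range = c(0, 40)), "litter_size_range")
  expect_error(herd_config(groups = 1:5), "regime")
  # weak-or-dead odds below the mortality rate are impossible
  expect_error(herd_config(weak_or_dead_odds = c(conventional = 0.01,
                                                 welfare_friendly = 0.01)),
               "weak_or_dead")
})

test_that("herd CSV round-trips with empty fields for missing weights", {
  herd <- generate_herd(herd_config(), seed = 51)
  path <- withr::local_tempfile(fileext = ".csv")
  write_herd_csv(herd, path)
  expect_true(any(grepl(",,", readLines(path)[-1], fixed = TRUE)))
  back <- read_herd_csv(path)
  expect_equal(back, herd, tolerance = 1e-12)
})

test_that("litter effect preserves the marginal variance and induces within-litter correlation", {
  cfg <- big_herd_config(4e4, litter_effect_fraction = 0.5)
  herd <- generate_herd(cfg, seed = 61)
  sub <- herd[herd$regime == "conventional" & !herd$dead, ]
  s <- sd(sub$slaughter_weight)
  expect_lt(abs(s / cfg$slaughter_weight_sd[["conventional"]] - 1), 0.05)
  litter_means <- tapply(sub$slaughter_weight, sub$litter_id, mean)
  # between-litter spread must far exceed the no-effect expectation sd/sqrt(m)
  expect_gt(sd(litter_means), 2 * s / sqrt(11))
})
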