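test_that("availability resolution separates used and skipped with reasons", {
  crit <- template_criteria_22()
  rec <- as.data.frame(template_record())
  av <- resolve_availability(rec, crit)

  expect_equal(sum(av$status == "used"), 20)
  expect_equal(av$status[av$parameter == "total_hardness"], "excluded_override")
  expect_equal(av$status[av$parameter == "ammonium"], "no_data")

  # all 13 default parameters present, no overrides -> all used
  full <- as.data.frame(as.list(setNames(rep(1, 13),
                                         default_criteria()$parameter[1:13])))
  full$ph <- 7
  av13 <- resolve_availability(full, default_criteria())
  expect_equal(sum(av13$status == "used"), 13)
  expect_equal(av13$status[av13$parameter == "total_hardness"],
               "excluded_globally")

  # a record with every value missing has no usable parameter
  empty <- as.data.frame(as.list(setNames(rep(NA_real_, 13),
                                          default_criteria()$parameter[1:13])))
  expect_error(compute_wqi(empty, default_criteria()), "no usable parameters")
})

test_that("per-record codes beat inclusion but cannot re-enable exclusions", {
  crit <- wq_criteria(data.frame(
    parameter = c("a", "b", "c"), weight = c(1, 1, 1), limit = c(1, 1, 1),
    included = c(TRUE, TRUE, FALSE)
  ))
  d <- data.frame(a = 1, b = 2, c = 3, a_code = 0, c_code = 1)
  av <- resolve_availability(d, crit)
  expect_equal(av$status[av$parameter == "a"], "no_data")
  expect_equal(av$status[av$parameter == "b"], "used")
  expect_equal(av$status[av$parameter == "c"], "excluded_globally")
  expect_error(resolve_availability(data.frame(a = 1, a_code = 5), crit),
               "selection codes")
})

test_that("dynamic weights renormalize proportionally and sum to one", {
  crit <- default_criteria()
  all13 <- crit$parameter[crit$included]

  expect_equal(dynamic_weights(crit, "nitrate"), c(nitrate = 1.0))
  expect_equal(dynamic_weights(crit, all13)[["nitrate"]], 5 / 46)
  expect_equal(dynamic_weights(crit, c("ph", "nitrate")),
               c(ph = 4 / 9, nitrate = 5 / 9))

  expect_error(dynamic_weights(crit, character(0)), "no usable")
  expect_error(dynamic_weights(crit, "uranium"), "not in the criteria")

  # property: weights over any availability pattern sum to exactly one
  set.seed(42)
  for (i in 1:200) {
    used <- sample(all13, sample(1:13, 1))
    w <- dynamic_weights(crit, used)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w > 0 & w <= 1))
  }
})

test_that("quality values follow the band and ratio formulas", {
  # inside the band, any weight: zero
  expect_equal(quality_value_ph(7.0, 0.8), 0)
  expect_equal(quality_value_ph(6.5, 1), 0)
  expect_equal(quality_value_ph(8.5, 1), 0)
  # below / above the band
  expect_equal(quality_value_ph(6.0, 0.5), 6.5 / 6.0 * 100 * 0.5)
  expect_equal(quality_value_ph(9.0, 1.0), 9.0 / 8.5 * 100)
  expect_error(quality_value_ph(0, 1), "pH")
  expect_error(quality_value_ph(15, 1), "pH")
  expect_error(quality_value_ph(7, 1.5), "weights")

  expect_equal(quality_value_generic(250, 250, 1), 100)
  expect_equal(quality_value_generic(0, 50, 1), 0)
  expect_equal(quality_value_generic(25, 50, 0.5), 25)
  expect_error(quality_value_generic(-1, 50, 1), "non-negative")
  expect_error(quality_value_generic(1, 0, 1), "positive")
})

test_that("WQI is the sum of quality values and anchors at 100 at the limits", {
  crit <- default_criteria()
  at_limit <- as.data.frame(as.list(setNames(
    crit$limit[crit$included], crit$parameter[crit$included])))
  at_limit$ph <- 7.2  # in band

  r <- compute_wqi(at_limit, crit)
  w_ph <- 4 / 46
  expect_equal(r$wqi, 100 * (1 - w_ph), tolerance = 1e-12)

  # drop pH from the record: every used parameter at its limit scores 100
  no_ph <- at_limit[setdiff(names(at_limit), "ph")]
  expect_equal(compute_wqi(no_ph, crit)$wqi, 100, tolerance = 1e-12)

  # single-parameter record
  single <- compute_wqi(data.frame(nitrate = 10), crit)
  expect_equal(single$wqi, 20)
  expect_equal(as.character(single$class), "Excellent water quality")

  # audit invariants: dynamic weights sum to 1, quality values sum to wqi
  det <- wqi_details(r)
  expect_equal(sum(det$dynamic_weight), 1, tolerance = 1e-9)
  expect_equal(sum(det$quality_value), r$wqi, tolerance = 1e-9)
})

test_that("the engine matches the one-shot weighted-mean oracle", {
  crit <- default_criteria()
  set.seed(7)
  for (i in 1:100) {
    rec <- random_record(crit)
    if (all(is.na(rec))) next
    r <- compute_wqi(rec, crit)
    vals <- unlist(rec)
    expect_equal(r$wqi, naive_wqi(vals, crit), tolerance = 1e-9)
    det <- wqi_details(r)
    expect_equal(sum(det$dynamic_weight), 1, tolerance = 1e-9)
    expect_equal(sum(det$quality_value), r$wqi, tolerance = 1e-9)
  }
})

test_that("WQI is non-decreasing in each non-pH concentration", {
  crit <- default_criteria()
  set.seed(11)
  base <- random_record(crit, missing_rate = 0)
  params <- setdiff(names(base), "ph")
  for (p in params) {
    bumped <- base
    bumped[[p]] <- base[[p]] * 1.5 + 0.01
    expect_gt(compute_wqi(bumped, crit)$wqi, compute_wqi(base, crit)$wqi)
  }
})

test_that("removing a parameter at the weighted-mean ratio leaves WQI fixed", {
  # algebraic identity of proportional renormalization: if one parameter's
  # concentration/limit ratio equals the weighted mean ratio of the others,
  # deleting it does not move the index
  crit <- wq_criteria(data.frame(
    parameter = c("a", "b", "c"), weight = c(2, 3, 5), limit = c(10, 20, 40)
  ))
  rec <- data.frame(a = 4, b = 12)  # ratios 0.4, 0.6; weighted mean 0.52
  mean_ratio <- (2 * 0.4 + 3 * 0.6) / 5
  with_c <- data.frame(a = 4, b = 12, c = 40 * mean_ratio)
  expect_equal(compute_wqi(with_c, crit)$wqi, compute_wqi(rec, crit)$wqi,
               tolerance = 1e-12)
})

test_that("classification is total, exhaustive and half-open at band edges", {
  expect_equal(as.character(classify_wqi(49.99)), "Excellent water quality")
  expect_equal(as.character(classify_wqi(162.08)), "Poor water quality")
  expect_equal(as.character(classify_wqi(0)), "Excellent water quality")
  # shared endpoints go to the upper band
  expect_equal(as.character(classify_wqi(c(50, 100, 200, 300))),
               c("Good water quality", "Poor water quality",
                 "Very poor water quality", "Unsuitable for drinking"))
  expect_error(classify_wqi(-1), "non-negative")
  # every non-negative value receives exactly one of the five labels
  set.seed(3)
  grid <- c(stats::runif(500, 0, 400), 1e6)
  cls <- classify_wqi(grid)
  expect_false(anyNA(cls))
  expect_setequal(levels(cls), wqi_classes()$class)
})

test_that("pH-only records score zero with a warning", {
  crit <- default_criteria()
  expect_warning(r <- compute_wqi(data.frame(ph = 7.0), crit), "in-band")
  expect_equal(r$wqi, 0)
  expect_equal(as.character(r$class), "Excellent water quality")

  # errors carry the sample id
  expect_error(
    compute_wqi(data.frame(sample_id = "X9", nitrate = NA_real_), crit),
    "X9"
  )
  expect_error(
    compute_wqi(data.frame(sample_id = "N1", nitrate = -5), crit),
    "N1"
  )
})
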