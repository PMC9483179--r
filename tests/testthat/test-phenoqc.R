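test_that("somatic cell score transform and its inverse", {
  expect_equal(compute_scs(100), 3)
  expect_equal(compute_scs(200), 4)
  expect_equal(compute_scs(50), 2)
  expect_error(compute_scs(0), "positive")
  expect_error(compute_scs(-5), "positive")
  # round trip on a grid of positive counts
  scc <- c(0.5, 10, 100, 999, 1999)
  expect_equal(rrmgwas:::.scs_to_scc(compute_scs(scc)), scc)
})

test_that("component yields follow the percentage product formulas", {
  expect_equal(compute_component_yields(0, 4.0, 3.0)$fy, 0)
  expect_equal(compute_component_yields(40, 4.0, 3.0)$fy, 1.6)
  expect_equal(compute_component_yields(30, 4.0, 3.0)$py, 0.9)
  expect_error(compute_component_yields(-1, 4, 3), "non-negative")
})

test_that("record filters enforce the inclusion bounds, inclusively", {
  base <- toy_records()[1, ]
  variants <- list(
    list(dim = 4L, rule = "dim_range"),
    list(dim = 306L, rule = "dim_range"),
    list(my = 0.5, rule = "my_range"),
    list(my = 66, rule = "my_range"),
    list(fp = 0.4, rule = "fp_range"),
    list(pp = 7.6, rule = "pp_range"),
    list(scc = 2000, rule = "scc_cap"),
    list(birth_date = as.Date("2017-06-01"), rule = "afc_range"))  # afc < 19
  for (v in variants) {
    rec <- base
    for (f in setdiff(names(v), "rule")) rec[[f]] <- v[[f]]
    out <- apply_record_filters(rec)
    expect_equal(nrow(out$records), 0L)
    expect_equal(unname(out$report$per_rule_rejections[v$rule]), 1L,
                 label = v$rule)
  }
  # exactly at the inclusive limits: retained
  rec <- base
  rec$dim <- 5L; rec$my <- 1.0; rec$fp <- 0.5; rec$pp <- 0.5
  rec$scc <- 1999.999
  expect_equal(nrow(apply_record_filters(rec)$records), 1L)
  # missing field goes to its own rule, not a crash
  rec <- base; rec$my <- NA
  out <- apply_record_filters(rec)
  expect_equal(unname(out$report$per_rule_rejections["missing_field"]), 1L)
})

test_that("cow filters require 3 records, an early test and the calving cutoff", {
  rec <- toy_records()
  out <- apply_cow_filters(rec)
  # c1 keeps (3 records incl. dim 10); c2 has 2 records; c3 has none < 45
  expect_setequal(unique(out$records$cow_id), "c1")
  expect_equal(unname(out$report$per_rule_rejections["min_records"]), 2L)
  expect_equal(unname(out$report$per_rule_rejections["no_early_test"]), 4L)
  # calving after the cutoff removes everything
  late <- rec
  late$calving_date <- as.Date("2019-12-15")
  expect_equal(nrow(apply_cow_filters(late)$records), 0L)
})

test_that("filtering is idempotent and counts reconcile", {
  cfg <- sim_config(n_founders = 30, n_generations = 1, seed = 5,
                    p_out_of_range = 0.15)
  ped <- simulate_pedigree(cfg)
  tr <- simulate_rr_coefficients(ped, cfg)
  rec <- derive_traits(simulate_test_day_records(tr, ped, cfg))
  o1 <- apply_record_filters(rec)
  expect_equal(o1$report$records_in - o1$report$records_out +
                 nrow(o1$records), nrow(rec))
  expect_gte(sum(o1$report$per_rule_rejections),
             o1$report$records_in - o1$report$records_out)
  o2 <- apply_record_filters(o1$records)
  expect_identical(o2$records, o1$records)
  c1 <- apply_cow_filters(o1$records)
  c2 <- apply_cow_filters(c1$records)
  expect_identical(c2$records, c1$records)
})

test_that("factor levels cross herd, date, age and season as specified", {
  rec <- data.frame(
    cow_id = c("a", "b", "c", "d"),
    herd = c("H1", "H1", "H1", "H2"),
    test_date = as.Date(c("2018-05-01", "2018-05-01", "2018-06-01",
                          "2018-05-01")),
    calving_date = as.Date(c("2018-01-15", "2018-02-10", "2018-04-01",
                             "2019-01-15")),
    birth_date = as.Date("2016-01-01"),
    dim = 50L, my = 30, fp = 4, pp = 3, scc = 100)
  out <- assign_factor_levels(rec)
  expect_equal(out$htd[1], out$htd[2])          # same herd and test date
  expect_false(out$htd[1] == out$htd[3])
  expect_false(out$htd[1] == out$htd[4])
  # Jan and Feb calvings share the quarter, April does not
  q <- sub(".*_", "", out$season_class)
  expect_equal(q[1], q[2])
  expect_false(q[1] == q[3])
  # different calving years differ regardless of quarter
  expect_false(out$season_class[1] == out$season_class[4])
  expect_error(assign_factor_levels(transform(rec, test_date = NA)),
               "dates")
})

test_that("trait summaries report the coefficient of variation", {
  expect_equal(round(coef_variation(mean = 27.80, sd = 8.35), 2), 0.30)
  expect_equal(round(coef_variation(mean = 3.64, sd = 0.88), 2), 0.24)
  expect_equal(coef_variation(rep(5, 10)), 0)
  rec <- toy_records()
  rec$test_date <- rec$calving_date + rec$dim
  rec <- derive_traits(rec)
  s <- summarize_traits(rec)
  expect_setequal(s$trait, c("my", "fy", "py", "fp", "pp", "scs"))
  expect_equal(s$cv, s$sd / s$mean)
  expect_equal(s$n_records[s$trait == "my"], nrow(rec))
  rec$scs <- NA_real_
  expect_warning(summarize_traits(rec), "omitted")
})
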