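test_that("TVR derivation follows the same-vessel two-year window rule", {
  r <- derive_tvr("2011-01-01", "2012-02-05", "2013-01-01")
  expect_true(r$tvr_event)
  expect_equal(r$followup_days, 400)
  # repeat on a different vessel never reaches this episode
  r2 <- derive_tvr("2011-01-01", character(0), "2013-01-01")
  expect_false(r2$tvr_event)
  expect_equal(r2$followup_days, 730)
  # repeat beyond the window: censored at the window, not at last contact
  r3 <- derive_tvr("2011-01-01", "2013-03-11", "2013-06-19")  # days 800, 900
  expect_false(r3$tvr_event)
  expect_equal(r3$followup_days, 730)
  # last contact inside the window drives censoring
  r4 <- derive_tvr("2011-01-01", character(0), "2011-07-20")  # day 200
  expect_equal(r4$followup_days, 200)
  expect_error(derive_tvr("2011-01-01", "2010-12-01", "2012-01-01"),
               "data-integrity")
})

test_that("hypertension and diabetes covariates use the code-or-drug rules", {
  cfg <- warehouse_config()
  dx_i10 <- data.frame(patient_id = "p", code = "I10", date = "2010-06-01")
  no_dx <- dx_i10[0, ]
  rx_ah <- data.frame(patient_id = "p", drug_class = "arb",
                      start = "2010-06-01", end = "2011-06-01")
  no_rx <- rx_ah[0, ]
  expect_true(derive_hypertension(dx_i10, no_rx, "2011-01-01", cfg))
  expect_true(derive_hypertension(no_dx, rx_ah, "2011-01-01", cfg))
  expect_false(derive_hypertension(no_dx, no_rx, "2011-01-01", cfg))
  # only history up to the index counts
  expect_false(derive_hypertension(dx_i10, no_rx, "2010-01-01", cfg))
  dx_dm <- data.frame(patient_id = "p", code = "E11.9", date = "2010-06-01")
  rx_dm <- data.frame(patient_id = "p", drug_class = "metformin",
                      start = "2010-06-01", end = "2011-06-01")
  expect_true(derive_diabetes(dx_dm, no_rx, "2011-01-01", cfg))
  expect_true(derive_diabetes(no_dx, rx_dm, "2011-01-01", cfg))
  expect_false(derive_diabetes(dx_i10, rx_ah, "2011-01-01", cfg))
})

test_that("DAPT duration is the overlap of aspirin and P2Y12 coverage", {
  mk <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r)
      data.frame(patient_id = "p", drug_class = r[1], start = r[2], end = r[3],
                 stringsAsFactors = FALSE)))
  }
  idx <- as.Date("2011-01-01")
  both400 <- mk(c("aspirin", "2011-01-01", "2012-02-05"),
                c("clopidogrel", "2011-01-01", "2012-02-05"))
  d <- derive_dapt(both400, idx)
  expect_equal(d$dapt_days, 400)
  expect_true(d$over_12mo)
  uneven <- mk(c("aspirin", "2011-01-01", "2012-02-05"),
               c("ticagrelor", "2011-01-01", "2011-07-20"))
  d2 <- derive_dapt(uneven, idx)
  expect_equal(d2$dapt_days, 200)
  expect_false(d2$over_12mo)
  no_p2y12 <- mk(c("aspirin", "2011-01-01", "2012-02-05"))
  expect_equal(derive_dapt(no_p2y12, idx)$dapt_days, 0)
  # coverage before the index does not count; split intervals merge
  split <- mk(c("aspirin", "2010-06-01", "2011-04-11"),   # 100 post-index days
              c("aspirin", "2011-04-11", "2011-08-01"),
              c("clopidogrel", "2010-12-01", "2011-05-01"))
  expect_equal(derive_dapt(split, idx)$dapt_days, 120)
})

test_that("warehouse assembly reproduces the hand-checked toy fixture", {
  w <- build_warehouse(toy_extraction(), toy_patients())
  expect_identical(nrow(w), 3L)
  lad1 <- w[w$patient_id == "p1" & w$vessel == "LAD", ]
  expect_identical(lad1$n_stents, 2L)
  expect_equal(lad1$total_length_mm, 38)
  expect_equal(lad1$mean_diameter_mm, 2.75)
  expect_true(lad1$balloon_used)
  expect_identical(lad1$stent_class, "DES2-DP")
  expect_identical(lad1$approach, "radial")
  expect_true(lad1$tvr_event)
  expect_equal(lad1$followup_days, 400)
  expect_identical(lad1$age, 60)           # born 1951-01-01, index 2011-01-01
  expect_true(lad1$hypertension)           # I10 before index
  expect_false(lad1$diabetes)
  expect_equal(lad1$dapt_days, 304)        # clopidogrel ends 2011-11-01
  expect_false(lad1$dapt_over_12mo)
  rca1 <- w[w$patient_id == "p1" & w$vessel == "RCA", ]
  expect_false(rca1$tvr_event)
  expect_equal(rca1$followup_days, 500)    # last contact inside window
  lad2 <- w[w$patient_id == "p2", ]
  expect_identical(lad2$stent_class, "DES1")
  expect_true(lad2$diabetes)               # E11 code
  expect_true(lad2$emergent)
  expect_equal(lad2$followup_days, 730)    # contact beyond window
  # aggregation conservation
  expect_identical(sum(w$n_stents), nrow(toy_extraction()))
})

test_that("warehouse drops orphan reports, tolerates empty input, and is idempotent", {
  ex <- toy_extraction()
  ex$patient_id[4] <- "ghost"
  w <- build_warehouse(ex, toy_patients())
  expect_identical(nrow(w), 2L)
  expect_identical(attr(w, "orphans"), 1L)
  w0 <- build_warehouse(toy_extraction()[0, ], toy_patients())
  expect_identical(nrow(w0), 0L)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  full <- build_warehouse(toy_extraction(), toy_patients())
  write_warehouse(full, p1)
  write_warehouse(build_warehouse(toy_extraction(), toy_patients()), p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_warehouse(p1)
  expect_equal(back$followup_days, full$followup_days)
  expect_identical(back$stent_class, full$stent_class)
})

test_that("mixed-category exclusion is specific to the comparison granularity", {
  mix <- function(brands, classes, polymers, gens) {
    ex <- toy_extraction()[1:2, ]
    ex$brand_family <- brands; ex$stent_class <- classes
    ex$polymer <- polymers; ex$generation <- gens
    ex
  }
  # Xience + Nobori in one vessel: excluded from the polymer comparison
  ex1 <- mix(c("Xience family", "Nobori"), c("DES2-DP", "DES2-BP"),
             c("durable", "biodegradable"), c("second", "second"))
  w1 <- apply_exclusions(build_warehouse(ex1, toy_patients()), "polymer")
  expect_true(w1$excluded[w1$vessel == "LAD"])
  expect_identical(w1$exclude_reason[w1$vessel == "LAD"], "mixed-category")
  # Xience + Promus (both durable-polymer second generation): retained
  ex2 <- mix(c("Xience family", "Promus family"), c("DES2-DP", "DES2-DP"),
             c("durable", "durable"), c("second", "second"))
  w2 <- apply_exclusions(build_warehouse(ex2, toy_patients()), "polymer")
  expect_false(w2$excluded[w2$vessel == "LAD"])
  # but the same vessel IS mixed at brand granularity
  w2b <- apply_exclusions(build_warehouse(ex2, toy_patients()), "brand")
  expect_true(w2b$excluded[w2b$vessel == "LAD"])
  # Cypher + Xience: excluded from the generation comparison
  ex3 <- mix(c("Cypher", "Xience family"), c("DES1", "DES2-DP"),
             c("none", "durable"), c("first", "second"))
  w3 <- apply_exclusions(build_warehouse(ex3, toy_patients()), "generation")
  expect_true(w3$excluded[w3$vessel == "LAD"])
})

test_that("warehouse agrees with generator truth on every derived field", {
  cfg <- generator_config(n_patients = 120, seed = 17)
  truth <- generate_cohort(cfg)
  w <- build_warehouse(truth_extraction(truth), truth$patients)
  m <- merge(as.data.frame(w), truth$episodes, by = c("patient_id", "vessel"))
  expect_identical(nrow(m), nrow(truth$episodes))
  expect_equal(m$followup_days, m$time_days)
  expect_identical(m$tvr_event.x, m$tvr_event.y)
  expect_identical(m$hypertension.x, m$hypertension.y)
  expect_identical(m$diabetes.x, m$diabetes.y)
  expect_equal(m$dapt_days.x, m$dapt_days.y)
  expect_identical(m$age.x, m$age.y)
  expect_identical(m$n_stents.x, m$n_stents.y)
  expect_equal(m$total_length_mm.x, m$total_length_mm.y)
  expect_equal(m$mean_diameter_mm.x, m$mean_diameter_mm.y)
  # derived invariant: no event beyond the window
  expect_true(all(w$followup_days[w$tvr_event] <= 730))
  expect_true(all(w$followup_days > 0))
})
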