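test_that("gravimetric water content follows the oven-dry definition", {
  expect_equal(soil_water_content(125, 100), 0.25)
  expect_equal(soil_water_content(100, 100), 0)
  expect_error(soil_water_content(100, 0), "dry_mass")
  expect_error(soil_water_content(90, 100), "wet_mass")
})

test_that("design irrigation depth is 10*gamma*H*P*deficit, clamped at 0", {
  expect_equal(irrigation_volume(1.48, 60, 1, target = 0.192,
                                 measured = 0.172), 17.76)
  expect_equal(irrigation_volume(1.48, 60, 1, target = 0.192,
                                 measured = 0.192), 0)
  # profile wetter than target: no irrigation due, never negative
  expect_equal(irrigation_volume(1.48, 60, 1, target = 0.192,
                                 measured = 0.25), 0)
  expect_error(irrigation_volume(1.48, 60, 1.2, 0.19, 0.17),
               "wetting_ratio")
})

test_that("stage water balance matches hand arithmetic", {
  rec <- stage_water_record(
    data.frame(bulk_density = 1.48, thickness = 20,
               content_start = 0.20, content_end = 0.18),
    irrigation = 30, rainfall = 10)
  expect_equal(stage_water_consumption(rec), 45.92)
  # no storage change and no inputs: nothing consumed
  flat <- stage_water_record(
    data.frame(bulk_density = 1.48, thickness = 20,
               content_start = 0.2, content_end = 0.2))
  expect_equal(stage_water_consumption(flat), 0)
  expect_error(stage_water_record(data.frame()), "non-empty")
})

test_that("ET is linear in each water-balance input", {
  layers <- data.frame(bulk_density = c(1.4, 1.5, 1.6), thickness = 20,
                       content_start = c(0.22, 0.21, 0.20),
                       content_end = c(0.18, 0.19, 0.185))
  base <- stage_water_consumption(stage_water_record(layers, 25, 5))
  for (delta in c(1, 7.5, 30)) {
    shifted <- stage_water_consumption(stage_water_record(layers,
                                                          25 + delta, 5))
    expect_equal(shifted - base, delta)
  }
  withK <- stage_water_consumption(stage_water_record(layers, 25, 5,
                                                      recharge = 12))
  withC <- stage_water_consumption(stage_water_record(layers, 25, 5,
                                                      percolation = 12))
  expect_equal(withK - base, 12)
  expect_equal(withC - base, -12)
})

test_that("splitting a layer into contiguous sub-layers leaves ET unchanged", {
  one <- stage_water_record(
    data.frame(bulk_density = 1.48, thickness = 40,
               content_start = 0.21, content_end = 0.185),
    irrigation = 20)
  two <- stage_water_record(
    data.frame(bulk_density = 1.48, thickness = c(20, 20),
               content_start = 0.21, content_end = 0.185),
    irrigation = 20)
  expect_equal(stage_water_consumption(one), stage_water_consumption(two))
})

test_that("stage totals sum to the season", {
  expect_equal(total_water_consumption(c(50, 80, 120, 90)), 340)
  expect_equal(total_water_consumption(42), 42)
  expect_error(total_water_consumption(numeric()), "no stages")
})

test_that("layered moisture CSVs round-trip through the balance", {
  mo <- withr::local_tempfile(fileext = ".csv")
  ev <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "stage,layer_top_cm,layer_bottom_cm,bulk_density,content_start,content_end",
    "seedling,0,20,1.48,0.200,0.190",
    "seedling,20,40,1.48,0.195,0.192",
    "seedling,40,60,1.48,0.193,0.193",
    "flowering,0,20,1.48,0.190,0.170",
    "flowering,20,40,1.48,0.192,0.180",
    "flowering,40,60,1.48,0.193,0.188"), mo)
  writeLines(c("stage,irrigation_mm,rainfall_mm",
               "seedling,20,5", "flowering,45,12"), ev)
  recs <- read_moisture_records(mo, ev)
  expect_named(recs, c("seedling", "flowering"))
  res <- season_water_consumption(recs)
  s1 <- 10 * 1.48 * 20 * (0.010 + 0.003 + 0.000) + 25
  s2 <- 10 * 1.48 * 20 * (0.020 + 0.012 + 0.005) + 57
  expect_equal(unname(res$stage_et), c(s1, s2))
  expect_equal(res$total, s1 + s2)
})
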