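test_that("default quota population matches the case-study structure", {
  pop <- generate_farm_population()
  expect_equal(nrow(pop), 355)
  expect_equal(sum(pop$sector == "dairy"), 284)
  expect_equal(sum(pop$sector == "fruit"), 71)
  for (sec in c("dairy", "fruit")) {
    sub <- pop[pop$sector == sec, ]
    n <- nrow(sub)
    expect_equal(sum(sub$innovative == "yes"), round(0.10 * n))
    m <- sector_marginals(sec)
    obs <- list(
      intrinsic_attitude = sub$intrinsic_attitude,
      age_class = sub$age_class,
      innovative = sub$innovative,
      successor = ifelse(sub$successor, "yes", "no"),
      size_class = sub$size_class,
      location_class = sub$location_class
    )
    for (att in names(m)) {
      for (cl in names(m[[att]])) {
        expect_lte(abs(mean(obs[[att]] == cl) - m[[att]][[cl]]), 1 / n + 1e-12)
      }
    }
  }
})

test_that("population generation is deterministic given the seed", {
  p1 <- generate_farm_population(population_config(seed = 7))
  p2 <- generate_farm_population(population_config(seed = 7))
  expect_identical(p1, p2)
  p3 <- generate_farm_population(population_config(seed = 8))
  expect_false(identical(p1$x, p3$x))
})

test_that("empty and invalid configurations are handled", {
  pop <- generate_farm_population(population_config(n_dairy = 0, n_fruit = 0))
  expect_equal(nrow(pop), 0)
  expect_error(population_config(n_dairy = -1), "negative")
  expect_error(
    population_config(marginals = list(
      dairy = modifyList(sector_marginals("dairy"),
                         list(age_class = c(y = 0, m = 0, o = 0))),
      fruit = sector_marginals("fruit"))),
    "zero probability")
})

test_that("bernoulli sampling is unbiased for the successor marginal", {
  # Monte-Carlo over seeds; mean fraction within 3 binomial standard errors
  p <- 0.29
  n <- 284
  seeds <- 1:200
  fracs <- vapply(seeds, function(s) {
    cfg <- population_config(n_dairy = n, n_fruit = 0, seed = s,
                             sampling_mode = "bernoulli")
    mean(generate_farm_population(cfg)$successor)
  }, numeric(1))
  se <- sqrt(p * (1 - p) / (n * length(seeds)))
  expect_lt(abs(mean(fracs) - p), 3 * se)
})

test_that("location classes come from natural breaks on village distance", {
  cfg <- population_config()
  pop <- generate_farm_population(cfg)
  centers <- attr(pop, "village_centers")
  d <- apply(cbind(pop$x, pop$y), 1, function(p) {
    min(sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2))
  })
  b <- jenks_breaks(d, 3)
  expect_equal(pop$location_class,
               c("close", "medium", "remote")[jenks_class(d, b)])
  # classes ordered by distance
  expect_lt(max(d[pop$location_class == "close"]),
            min(d[pop$location_class == "medium"]))
  expect_lt(max(d[pop$location_class == "medium"]),
            min(d[pop$location_class == "remote"]))
})

test_that("classify_locations handles clustered and degenerate inputs", {
  farms <- data.frame(farm_id = sprintf("f%d", 1:9),
                      x = c(1, 1.2, 0.8, 10, 10.3, 9.7, 50, 50.5, 49.5),
                      y = 0)
  out <- classify_locations(farms, rbind(c(0, 0)))
  expect_equal(out$location_class,
               rep(c("close", "medium", "remote"), each = 3))
  co <- data.frame(farm_id = "f", x = c(0, 0, 0), y = c(0, 0, 0))
  expect_error(classify_locations(co, rbind(c(0, 0))), "infeasible")
  expect_error(classify_locations(farms, matrix(numeric(0), ncol = 2)),
               "village center")
})

test_that("farm size converts linearly from the basic payment", {
  expect_equal(farm_size_from_payment(26000), 100)
  expect_equal(farm_size_from_payment(0), 0)
  expect_equal(farm_size_from_payment(5200), 20)
  expect_error(farm_size_from_payment(-1), "non-negative")
  # linear and invertible
  ha <- farm_size_from_payment(c(1300, 3900))
  expect_equal(ha * 260, c(1300, 3900))
})

test_that("direct sales concentrate close to villages", {
  cfg <- population_config(direct_sales_odds = 4)
  pop <- generate_farm_population(cfg)
  ds_rate_close <- mean(pop$has_direct_sales[pop$location_class == "close"])
  ds_rate_far <- mean(pop$has_direct_sales[pop$location_class != "close"])
  expect_gt(ds_rate_close, ds_rate_far)
})

test_that("farm population round-trips through CSV and GeoJSON", {
  pop <- generate_farm_population(population_config(n_dairy = 10, n_fruit = 5))
  csv <- tempfile(fileext = ".csv")
  write_farms_csv(pop, csv)
  back <- read_farms_csv(csv)
  expect_equal(back$farm_id, pop$farm_id)
  expect_equal(back$size_ha, pop$size_ha, tolerance = 1e-9)
  gj <- tempfile(fileext = ".geojson")
  write_farms_geojson(pop, gj)
  doc <- jsonlite::read_json(gj)
  expect_equal(doc$type, "FeatureCollection")
  expect_length(doc$features, nrow(pop))
  expect_equal(doc$features[[1]]$properties$farm_id, pop$farm_id[1])
})

test_that("config round-trips through a key-value file", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("n_dairy: 12", "n_fruit: 3", "seed: 5",
               "sampling_mode: quota"), path)
  cfg <- read_population_config(path)
  expect_equal(cfg$n_dairy, 12L)
  expect_equal(cfg$seed, 5L)
  writeLines("bogus_key: 1", path)
  expect_error(read_population_config(path), "unknown config keys")
})
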