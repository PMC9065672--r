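test_that("the sensitivity suite has the fourteen documented scenarios", {
  suite <- make_scenario_suite()
  expect_length(suite, 14)
  names14 <- vapply(suite, `[[`, character(1), "name")
  expect_true(all(c("All actors supportive", "All actors unsupportive",
                    "I supportive, F neutral",
                    "G supportive, M unsupportive") %in% names14))
  all_sup <- suite[[which(names14 == "All actors supportive")]]
  expect_true(all(all_sup$actors == "supportive"))
  # informal supportive, formal neutral: group resolution on the roster
  ifn <- suite[[which(names14 == "I supportive, F neutral")]]
  expect_equal(ifn$actors[c("Network", "Consumers", "Labels", "NGOs")],
               setNames(rep("supportive", 4),
                        c("Network", "Consumers", "Labels", "NGOs")))
  expect_equal(ifn$actors[c("Retail", "Province", "NLEU")],
               setNames(rep("neutral", 3), c("Retail", "Province", "NLEU")))
})

test_that("conflicting group assignments are rejected", {
  expect_error(scenario_spec("bad", list(all = "supportive",
                                         market = "unsupportive")),
               "conflicting")
  expect_error(scenario_spec("bad", list(nonsense = "supportive")),
               "unknown actor groups")
})

test_that("the trade-off classifier agrees with a sign-pattern oracle", {
  oracle <- function(d) {
    s <- sign(d)
    if (all(s == 1)) "S_plus"
    else if (all(s == -1)) "S_minus"
    else if (all(s == 0)) "none"
    else "T"
  }
  signs <- expand.grid(a = c(-1, 0, 1), b = c(-1, 0, 1), c = c(-1, 0, 1))
  for (i in seq_len(nrow(signs))) {
    d <- as.numeric(signs[i, ]) * c(17, 8, 3)
    expect_equal(classify_tradeoff(d), oracle(d))
  }
  # reported rows supplied verbatim
  expect_equal(classify_tradeoff(c(17, 11, -5)), "T")
  expect_equal(classify_tradeoff(c(-39, -13, -20)), "S_minus")
  expect_equal(classify_tradeoff(c(33, 23, 55)), "S_plus")
  expect_equal(classify_tradeoff(c(-31, 25, 0)), "T")
  expect_equal(classify_tradeoff(c(0, 0, 0)), "none")
})

test_that("scenario runs respond as classified for the all-actor runs", {
  for (sector in c("dairy", "fruit")) {
    cal <- get_calibrated(sector)
    sup <- run_scenario(cal$net, scenario_spec("all sup", list(all = "supportive")))
    expect_equal(attr(sup, "class_label"), "S_plus")
    expect_true(all(sup$pct_change > 0))
  }
  cal <- get_calibrated("dairy")
  uns <- run_scenario(cal$net, scenario_spec("all uns", list(all = "unsupportive")))
  expect_equal(attr(uns, "class_label"), "S_minus")
  expect_true(all(uns$pct_change < 0))
  # the all-neutral scenario leaves the baseline untouched
  neu <- run_scenario(cal$net, scenario_spec("null", list(all = "neutral")))
  expect_equal(neu$pct_change, rep(0, 3), tolerance = 1e-9)
  expect_equal(attr(neu, "class_label"), "none")
})

test_that("percent changes can reference an external observed baseline", {
  cal <- get_calibrated("dairy")
  observed <- c(FoA1_3 = 0.29, FoA2 = 0.45, FoA4 = 0.11)
  sup <- run_scenario(cal$net,
                      scenario_spec("all sup", list(all = "supportive")),
                      baseline = observed)
  p <- sup$uptake[sup$measure == "FoA2"]
  expect_equal(sup$pct_change[sup$measure == "FoA2"],
               100 * (p - 0.45) / 0.45)
  expect_error(run_scenario(cal$net,
                            scenario_spec("all sup", list(all = "supportive")),
                            baseline = c(FoA1_3 = 0, FoA2 = 0.4, FoA4 = 0.1)),
               "positive")
})

test_that("scenario suites are deterministic and exportable", {
  cal <- get_calibrated("dairy")
  suite <- make_scenario_suite()[c(13, 14)]
  r1 <- run_scenario_suite(cal$net, suite, sector = "dairy")
  r2 <- run_scenario_suite(cal$net, suite, sector = "dairy")
  expect_identical(r1, r2)
  path <- tempfile(fileext = ".csv")
  write_scenario_csv(r1, path)
  back <- read.csv(path)
  expect_equal(back$scenario, r1$scenario)
  expect_equal(back$dFoA4, r1$dFoA4, tolerance = 1e-6)
})

test_that("per-farm supportive-minus-unsupportive impacts are non-negative", {
  cal <- get_calibrated("fruit")
  cfg <- population_config(n_dairy = 0, n_fruit = 60, seed = 3)
  farms <- generate_farm_population(cfg)
  out <- spatial_impact(farms, cal$net, "FoA4")
  expect_equal(nrow(out), nrow(farms))
  expect_true(all(out$impact >= -1e-12))
  # favourable farms move more: close/large/young vs remote/small/old
  ev_hi <- list(FarmLocation = "close", FarmSize = "l", Age = "y",
                Successor = "y", Innovative = "yes")
  ev_lo <- list(FarmLocation = "remote", FarmSize = "s", Age = "o",
                Successor = "n", Innovative = "no")
  diff_for <- function(ev) {
    sup <- setNames(as.list(rep("s", 6)),
                    c("Retail", "NGOs", "Network", "Province", "NLEU", "Consumers"))
    sup$Labels <- "s"
    uns <- setNames(as.list(rep("u", 6)),
                    c("Retail", "NGOs", "Network", "Province", "NLEU", "Consumers"))
    unname(infer_marginal(cal$net, "Uptake_FoA4", c(ev, sup))["yes"]) -
      unname(infer_marginal(cal$net, "Uptake_FoA4", c(ev, uns))["yes"])
  }
  expect_gt(diff_for(ev_hi), diff_for(ev_lo))
  gj <- tempfile(fileext = ".geojson")
  spatial_impact(farms[1:5, ], cal$net, "FoA1_3", geojson = gj)
  doc <- jsonlite::read_json(gj)
  expect_length(doc$features, 5)
  expect_true(!is.null(doc$features[[1]]$properties$impact))
})
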