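test_that("the rank-based elicitation follows the baseline-plus-modifier rule", {
  params <- elicitation_params(baseline = c(FoA2 = 0.5), baseline_spread = 0.3,
                               delta = 0.1, gamma = 0.5)
  two <- list(
    P1 = list(states = c("s", "n", "u"), rank = 1),
    P2 = list(states = c("s", "n", "u"), rank = 2)
  )
  el <- elicit_actor_cpt(two, params, "FoA2")
  grid <- expand.grid(P1 = c("s", "n", "u"), P2 = c("s", "n", "u"),
                      stringsAsFactors = FALSE)
  # b=(0.8, 0.5, 0.2), rank-2 modifier +/-0.1: hand values
  want <- ifelse(grid$P1 == "s", 0.8, ifelse(grid$P1 == "n", 0.5, 0.2)) +
    0.1 * ifelse(grid$P2 == "s", 1, ifelse(grid$P2 == "n", 0, -1))
  expect_equal(unname(el$cpt[, "positive"]), want)
  expect_equal(rowSums(el$cpt), rep(1, 9))
  # rank1=s, rank2=s gives exactly 0.9
  expect_equal(unname(el$cpt[grid$P1 == "s" & grid$P2 == "s", "positive"]), 0.9)
  # all actors neutral collapses to the neutral baseline
  expect_equal(unname(el$cpt[grid$P1 == "n" & grid$P2 == "n", "positive"]), 0.5)
})

test_that("large supportive stacks are clamped", {
  params <- elicitation_params(baseline = c(FoA2 = 0.8), baseline_spread = 0.15,
                               delta = 0.3, gamma = 1, clamp = 0.02)
  actors <- c(list(P1 = list(states = c("s", "n", "u"), rank = 1)),
              lapply(2:6, function(k) list(states = c("s", "n", "u"), rank = k)))
  names(actors) <- paste0("P", 1:6)
  el <- elicit_actor_cpt(actors, params, "FoA2")
  all_s <- el$cpt[1, "positive"]  # first row: every parent at its first state "s"
  expect_equal(unname(all_s), 0.98)
  dup <- list(P1 = list(states = c("s", "n", "u"), rank = 1),
              P2 = list(states = c("s", "n", "u"), rank = 1))
  expect_error(elicit_actor_cpt(dup, params), "duplicate rank-1")
})

test_that("advice-positive marginals are monotone in every actor's attitude", {
  cal <- get_calibrated("dairy")
  for (m in si_measures()) {
    node <- paste0("Advice_", m)
    parents <- cal$net$nodes[[node]]$parents
    for (a in parents) {
      states <- intersect(c("u", "n", "s"), cal$net$nodes[[a]]$states)
      ps <- vapply(states, function(st) {
        unname(infer_marginal(cal$net, node, setNames(list(st), a))["positive"])
      }, numeric(1))
      expect_true(all(diff(ps) >= -1e-12))
    }
  }
})

test_that("the assembled network has the documented 24-node structure", {
  net <- assemble_si_network("dairy")
  expect_length(net$nodes, 24)
  expect_length(validate_network(net, strict = FALSE), 0)
  # advice parents are the ranked actors in rank order
  expect_equal(net$nodes$Advice_FoA4$parents,
               c("Network", "Consumers", "Retail", "Province", "Labels"))
  expect_equal(net$nodes$Advice_FoA1_3$parents,
               c("Province", "NLEU", "Retail", "Labels", "Network"))
  # policy context enters landscape/efficiency intentions, location only FoA4
  expect_true(all(c("Subsidies", "Regulations") %in%
                    net$nodes$Intention_FoA2$parents))
  expect_false("FarmLocation" %in% net$nodes$Intention_FoA2$parents)
  expect_true("FarmLocation" %in% net$nodes$Intention_FoA4$parents)
  expect_false("Subsidies" %in% net$nodes$Intention_FoA4$parents)
})

test_that("null actors and zero characteristic weights collapse to baseline", {
  params <- elicitation_params(
    char_weights = c(intrinsic = 0, innovative = 0, age = 0, successor = 0,
                     size = 0, location = 0),
    policy_weights = c(subsidies = 0, regulations = 0),
    advice_weight = 0,
    intercept = c(FoA1_3 = 0, FoA2 = 0, FoA4 = 0))
  net <- assemble_si_network("dairy", params)
  all_n <- list(Retail = "n", NGOs = "n", Network = "n", Labels = "n",
                Province = "n", NLEU = "n", Consumers = "n")
  for (m in si_measures()) {
    adv <- infer_marginal(net, paste0("Advice_", m), all_n)
    expect_equal(unname(adv["positive"]), params$baseline[[m]],
                 tolerance = 1e-12)
    # with zero weights intention sits at plogis(0) = 0.5 regardless of advice
    int <- infer_marginal(net, paste0("Intention_", m))
    expect_equal(unname(int["positive"]), 0.5, tolerance = 1e-12)
  }
})

test_that("farmer characteristics shift intention in the expected direction", {
  cal <- get_calibrated("dairy")
  pairs <- list(
    list(var = "Age", hi = "y", lo = "o"),
    list(var = "Successor", hi = "y", lo = "n"),
    list(var = "Innovative", hi = "yes", lo = "no"),
    list(var = "FarmSize", hi = "l", lo = "s")
  )
  for (m in si_measures()) {
    node <- paste0("Intention_", m)
    for (p in pairs) {
      hi <- unname(infer_marginal(cal$net, node,
                                  setNames(list(p$hi), p$var))["positive"])
      lo <- unname(infer_marginal(cal$net, node,
                                  setNames(list(p$lo), p$var))["positive"])
      expect_gt(hi, lo)
    }
  }
  # close beats remote for direct sales only
  hi <- unname(infer_marginal(cal$net, "Intention_FoA4",
                              list(FarmLocation = "close"))["positive"])
  lo <- unname(infer_marginal(cal$net, "Intention_FoA4",
                              list(FarmLocation = "remote"))["positive"])
  expect_gt(hi, lo)
})

test_that("calibration reproduces its targets and recovers known parameters", {
  for (sector in c("dairy", "fruit")) {
    cal <- get_calibrated(sector)
    targets <- baseline_targets(sector)
    for (m in si_measures()) {
      expect_lt(abs(cal$achieved[[m]]["advice"] - targets$advice[[m]]), 0.01)
      expect_lt(abs(cal$achieved[[m]]["intention"] - targets$intention[[m]]), 0.01)
      expect_lt(abs(cal$achieved[[m]]["uptake"] - targets$uptake[[m]]), 0.01)
    }
    expect_lte(cal$loss, cal$initial_loss)
  }
  # self-consistency: targets generated from a known parameter vector are
  # recovered at the marginal level
  gen <- elicitation_params(baseline = c(FoA1_3 = 0.46, FoA2 = 0.61, FoA4 = 0.37),
                            intercept = c(FoA1_3 = 0.3, FoA2 = -0.2, FoA4 = -0.6))
  net_gen <- assemble_si_network("dairy", gen)
  bm <- lapply(si_measures(), function(m) {
    c(advice = unname(infer_marginal(net_gen, paste0("Advice_", m))["positive"]),
      intention = unname(infer_marginal(net_gen, paste0("Intention_", m))["positive"]),
      uptake = unname(infer_marginal(net_gen, paste0("Uptake_", m))["yes"]))
  })
  names(bm) <- si_measures()
  targets <- list(
    advice = vapply(bm, `[[`, numeric(1), "advice"),
    intention = vapply(bm, `[[`, numeric(1), "intention"),
    uptake = vapply(bm, `[[`, numeric(1), "uptake")
  )
  cal2 <- calibrate_si_network("dairy", targets)
  for (m in si_measures()) {
    expect_lt(abs(cal2$achieved[[m]]["advice"] - bm[[m]]["advice"]), 0.005)
    expect_lt(abs(cal2$achieved[[m]]["intention"] - bm[[m]]["intention"]), 0.005)
    expect_lt(abs(cal2$achieved[[m]]["uptake"] - bm[[m]]["uptake"]), 0.005)
  }
})

test_that("targets already met return the initial parameters unchanged", {
  cal <- get_calibrated("dairy")
  targets <- list(
    advice = vapply(cal$achieved, `[[`, numeric(1), "advice"),
    intention = vapply(cal$achieved, `[[`, numeric(1), "intention"),
    uptake = vapply(cal$achieved, `[[`, numeric(1), "uptake")
  )
  again <- calibrate_si_network("dairy", targets, params = cal$params)
  expect_identical(again$params, cal$params)
  expect_lt(again$loss, 1e-12)
  expect_error(calibrate_si_network("dairy", list(advice = c(FoA1_3 = 1.2,
                                                             FoA2 = 0.5,
                                                             FoA4 = 0.5),
                                                  intention = targets$intention,
                                                  uptake = targets$uptake)),
               "\\[0, 1\\]")
})

test_that("uptake is the stated convex combination of the intention marginal", {
  cal <- get_calibrated("dairy")
  for (m in si_measures()) {
    p_int <- unname(infer_marginal(cal$net, paste0("Intention_", m))["positive"])
    up <- cal$params$uptake[[m]]
    want <- up[["pi0"]] + (up[["pi1"]] - up[["pi0"]]) * p_int
    expect_equal(unname(infer_marginal(cal$net, paste0("Uptake_", m))["yes"]),
                 want, tolerance = 1e-10)
  }
})

test_that("baseline reports are deterministic and echo the marginals", {
  cal <- get_calibrated("dairy")
  r1 <- baseline_report(cal$net)
  r2 <- baseline_report(cal$net)
  expect_identical(r1, r2)
  up <- r1[r1$node == "Uptake_FoA4" & r1$state == "yes", "probability"]
  expect_lt(abs(up - 0.20), 0.01)
  lab <- r1[r1$node == "Labels", "probability"]
  expect_equal(lab, c(0.5, 0.5))
})
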