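#' Measure labels
#'
#' The three sustainable-intensification output measures: small landscape
#' elements (FoA1_3), farm-level efficiency (FoA2), direct sales (FoA4).
#' @return character vector.
#' @export
si_measures <- function() c("FoA1_3", "FoA2", "FoA4")

#' Actor roster with groups, baseline priors and per-measure ranks
#'
#' The seven actor nodes of the belief network, with the actor-group
#' memberships used by the sensitivity suites (local/external,
#' market/government, formal/informal), baseline attitude priors and the
#' rank-order of importance per measure (rank 1 = most important; ties share a
#' rank). The "Farmers" ranking is carried by the Network node (the farmers'
#' peer network) and "Farmer organizations" by NGOs; NGOs default to the
#' external/informal groups. Labels has no unsupportive state and a 50/50
#' supportive/neutral prior; the Consumers prior is sector-specific.
#'
#' @param sector `"dairy"` or `"fruit"` (affects the Consumers prior).
#' @return named list of actor profiles (states, prior, groups, ranks).
#' @export
actor_roster <- function(sector = c("dairy", "fruit")) {
  sector <- match.arg(sector)
  u3 <- normalize_marginal(c(s = 1, n = 1, u = 1), warn_tol = Inf)
  consumers_prior <- if (sector == "dairy") {
    c(s = 0.19, n = 0.28, u = 0.53)
  } else {
    suppressWarnings(normalize_marginal(c(s = 0.28, n = 0.37, u = 0.38),
                                        "Consumers fruit prior"))
  }
  list(
    Retail    = list(states = c("s", "n", "u"), prior = u3,
                     groups = c("external", "market", "formal"),
                     ranks = c(FoA1_3 = 3, FoA2 = 2, FoA4 = 3)),
    NGOs      = list(states = c("s", "n", "u"), prior = u3,
                     groups = c("external", "informal"),
                     ranks = c(FoA2 = 3)),
    Network   = list(states = c("s", "n", "u"), prior = u3,
                     groups = c("local", "informal"),
                     ranks = c(FoA1_3 = 4, FoA2 = 3, FoA4 = 1)),
    Labels    = list(states = c("s", "n"), prior = c(s = 0.5, n = 0.5),
                     groups = c("external", "market", "informal"),
                     ranks = c(FoA1_3 = 3, FoA2 = 2, FoA4 = 5)),
    Province  = list(states = c("s", "n", "u"), prior = u3,
                     groups = c("local", "government", "formal"),
                     ranks = c(FoA1_3 = 1, FoA4 = 4)),
    NLEU      = list(states = c("s", "n", "u"), prior = u3,
                     groups = c("external", "government", "formal"),
                     ranks = c(FoA1_3 = 2, FoA2 = 1)),
    Consumers = list(states = c("s", "n", "u"), prior = consumers_prior,
                     groups = c("local", "market", "informal"),
                     ranks = c(FoA2 = 4, FoA4 = 2))
  )
}

# attitude sign: supportive +1, neutral 0, unsupportive -1
state_sign <- function(states) {
  signs <- c(s = 1, n = 0, u = -1,
             positive = 1, negative = -1,
             yes = 1, neutral = 0, no = -1,
             y = 1, m = 0, o = -1,
             high = 1, medium = 0, low = -1, none = -1,
             close = 1, remote = -1,
             l = 1)
  # context-dependent labels handled by callers (size, successor)
  unname(signs[states])
}

#' Free parameters of the CPT elicitation scheme
#'
#' Advice nodes use a baseline-plus-rank-ordered-modifier rule: the
#' highest-ranked actor's attitude sets a baseline probability of positive
#' advice and every lower-ranked actor adds or subtracts a geometrically
#' decaying modifier. Intention nodes combine advice, policy context and
#' farmer/farm characteristics through an additive log-odds rule. Uptake is a
#' two-probability link per measure (probability of uptake given positive /
#' negative intention).
#'
#' @param baseline named per-measure baseline probability of positive advice
#'   when the top-ranked actor is neutral.
#' @param baseline_spread added (subtracted) from the baseline when the
#'   top-ranked actor is supportive (unsupportive).
#' @param delta modifier magnitude of the rank-2 actor (probability units).
#' @param gamma geometric rank decay in (0, 1]; an actor at rank k >= 2
#'   contributes `sign * delta * gamma^(k - 2)`.
#' @param clamp probabilities are clamped to `[clamp, 1 - clamp]`.
#' @param advice_weight log-odds weight of advice on intention.
#' @param policy_weights log-odds weights of the Subsidies and Regulations
#'   context (FoA1_3 and FoA2 intentions only).
#' @param char_weights log-odds weights of the farmer/farm characteristics:
#'   intrinsic attitude, innovativeness, age (young positive), successor,
#'   farm size (large positive), location (close positive; FoA4 only).
#' @param intercept named per-measure log-odds intercept of the intention rule.
#' @param uptake named list per measure with elements `pi1` (P(uptake |
#'   intention positive)) and `pi0` (< pi1).
#' @param pi_ratio fixed ratio pi0/pi1 used when calibration derives the
#'   uptake link from targets.
#' @return object of class `elicitation_params`.
#' @export
elicitation_params <- function(baseline = c(FoA1_3 = 0.52, FoA2 = 0.57, FoA4 = 0.40),
                               baseline_spread = 0.30,
                               delta = 0.08,
                               gamma = 0.7,
                               clamp = 0.02,
                               advice_weight = 0.9,
                               policy_weights = c(subsidies = 0.35, regulations = 0.35),
                               char_weights = c(intrinsic = 1.0, innovative = 0.5,
                                                age = 0.4, successor = 0.2,
                                                size = 0.3, location = 0.5),
                               intercept = c(FoA1_3 = 0, FoA2 = 0, FoA4 = -0.8),
                               uptake = list(
                                 FoA1_3 = c(pi1 = 0.55, pi0 = 0.14),
                                 FoA2 = c(pi1 = 0.85, pi0 = 0.21),
                                 FoA4 = c(pi1 = 0.45, pi0 = 0.11)
                               ),
                               pi_ratio = 0.25) {
  stopifnot(delta > 0, gamma > 0, gamma <= 1, clamp > 0, clamp < 0.5,
            all(char_weights >= 0))
  for (m in names(uptake)) {
    if (uptake[[m]]["pi1"] <= uptake[[m]]["pi0"]) {
      stop("uptake link requires pi1 > pi0 for measure ", m)
    }
  }
  structure(list(baseline = baseline, baseline_spread = baseline_spread,
                 delta = delta, gamma = gamma, clamp = clamp,
                 advice_weight = advice_weight, policy_weights = policy_weights,
                 char_weights = char_weights, intercept = intercept,
                 uptake = uptake, pi_ratio = pi_ratio),
            class = "elicitation_params")
}

#' Elicit an advice-node CPT from ranked actor attitudes
#'
#' Implements the baseline-plus-modifier scheme: with actors ordered by rank,
#' `P(positive | attitudes) = clamp(b(state of rank-1 actor) +
#' sum_{k>=2} sign(state_k) * delta * gamma^(rank_k - 2), clamp, 1 - clamp)`,
#' where sign is +1/0/-1 for supportive/neutral/unsupportive. Tied ranks (the
#' elicited importance ranking contains ties) contribute with the decay weight
#' of the shared rank; two actors may not both hold rank 1.
#'
#' @param ranked_actors named list: per actor, a list with `states` and `rank`.
#' @param params [elicitation_params()].
#' @param measure measure label selecting the baseline.
#' @return list with `parents` (actor names ordered by rank) and `cpt`
#'   (matrix over positive/negative with the first parent varying fastest).
#' @export
elicit_actor_cpt <- function(ranked_actors, params, measure = "FoA2") {
  stopifnot(length(ranked_actors) >= 1)
  ranks <- vapply(ranked_actors, function(a) a$rank, numeric(1))
  ord <- order(ranks)  # ties keep roster order
  ranked_actors <- ranked_actors[ord]
  ranks <- ranks[ord]
  if (sum(ranks == min(ranks)) > 1) {
    stop("duplicate rank-1 actors: the baseline actor must be unique")
  }
  b_n <- params$baseline[[measure]]
  b <- clamp(c(s = b_n + params$baseline_spread, n = b_n,
               u = b_n - params$baseline_spread),
             params$clamp, 1 - params$clamp)
  grid <- expand.grid(lapply(ranked_actors, `[[`, "states"),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  p <- b[grid[[1]]]
  if (length(ranked_actors) > 1) {
    for (k in 2:length(ranked_actors)) {
      p <- p + state_sign(grid[[k]]) * params$delta * params$gamma^(ranks[k] - 2)
    }
  }
  p <- clamp(p, params$clamp, 1 - params$clamp)
  list(parents = names(ranked_actors),
       cpt = cbind(positive = unname(p), negative = unname(1 - p)))
}

# characteristic state scores used by the intention log-odds rule
char_scores <- function() {
  list(
    IntrinsicAttitude = c(s = 1, n = 0, u = -1),
    Innovative = c(yes = 1, neutral = 0, no = -1),
    Age = c(y = 1, m = 0, o = -1),
    Successor = c(y = 1, n = -1),
    FarmSize = c(s = -1, m = 0, l = 1),
    FarmLocation = c(close = 1, medium = 0, remote = -1),
    Subsidies = c(high = 1, medium = 0, low = -1),
    Regulations = c(high = 1, medium = 0, none = -1)
  )
}

char_states <- function(sector) {
  m <- sector_marginals(sector)
  list(
    IntrinsicAttitude = setNames(m$intrinsic_attitude,
                                 c("s", "n", "u")),
    Age = m$age_class,
    Innovative = m$innovative,
    Successor = setNames(m$successor, c("y", "n")),
    FarmSize = m$size_class,
    FarmLocation = m$location_class
  )
}

# target (renormalized) distributions for the policy-context nodes
policy_targets <- function(sector) {
  subsidies <- suppressWarnings(normalize_marginal(
    c(high = 0.64, medium = 0.16, low = 0.17), "Subsidies"))
  reg <- if (sector == "dairy") {
    rowMeans(cbind(
      suppressWarnings(normalize_marginal(c(high = 0.62, medium = 0.28, none = 0.11))),
      suppressWarnings(normalize_marginal(c(high = 0.61, medium = 0.28, none = 0.11)))))
  } else {
    rowMeans(cbind(
      suppressWarnings(normalize_marginal(c(high = 0.60, medium = 0.29, none = 0.11))),
      suppressWarnings(normalize_marginal(c(high = 0.61, medium = 0.28, none = 0.10)))))
  }
  list(Subsidies = subsidies, Regulations = setNames(reg, c("high", "medium", "none")))
}

# CPT of a policy node given Province and NLEU: the target distribution tilted
# toward its favorable end by the mean parental attitude
policy_cpt <- function(target, eta = 0.8) {
  z <- state_sign(names(target))  # high 1, medium 0, low/none -1
  grid <- expand.grid(prov = c("s", "n", "u"), nleu = c("s", "n", "u"),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  score <- (state_sign(grid$prov) + state_sign(grid$nleu)) / 2
  cpt <- t(vapply(score, function(sc) {
    w <- target * exp(eta * z * sc)
    w / sum(w)
  }, numeric(length(target))))
  colnames(cpt) <- names(target)
  cpt
}

intention_cpt <- function(measure, sector, params) {
  scores <- char_scores()
  parents <- c(paste0("Advice_", measure),
               if (measure != "FoA4") c("Subsidies", "Regulations"),
               "IntrinsicAttitude", "Innovative", "Age", "Successor",
               "FarmSize",
               if (measure == "FoA4") "FarmLocation")
  state_sets <- lapply(parents, function(p) {
    if (startsWith(p, "Advice_")) c("positive", "negative") else names(scores[[p]])
  })
  names(state_sets) <- parents
  grid <- expand.grid(state_sets, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  eta <- rep(params$intercept[[measure]], nrow(grid))
  for (p in parents) {
    if (startsWith(p, "Advice_")) {
      eta <- eta + params$advice_weight * ifelse(grid[[p]] == "positive", 1, -1)
    } else if (p == "Subsidies") {
      eta <- eta + params$policy_weights[["subsidies"]] * scores[[p]][grid[[p]]]
    } else if (p == "Regulations") {
      eta <- eta + params$policy_weights[["regulations"]] * scores[[p]][grid[[p]]]
    } else {
      w <- switch(p,
                  IntrinsicAttitude = params$char_weights[["intrinsic"]],
                  Innovative = params$char_weights[["innovative"]],
                  Age = params$char_weights[["age"]],
                  Successor = params$char_weights[["successor"]],
                  FarmSize = params$char_weights[["size"]],
                  FarmLocation = params$char_weights[["location"]])
      eta <- eta + w * scores[[p]][grid[[p]]]
    }
  }
  p_pos <- clamp(plogis(eta), params$clamp, 1 - params$clamp)
  list(parents = parents,
       cpt = cbind(positive = unname(p_pos), negative = unname(1 - p_pos)))
}

#' Assemble the sector belief network
#'
#' Builds the 24-node network for one sector: seven actor root nodes with
#' their baseline priors, six farmer/farm characteristic root nodes with the
#' sector's printed marginals, Subsidies and Regulations policy nodes (children
#' of Province and NL&EU), and per measure an advice node (parents: the
#' measure's ranked actors, CPT from [elicit_actor_cpt()]), an intention node
#' (parents: advice, policy context for landscape-element and efficiency
#' measures, the characteristics, and location for direct sales; additive
#' log-odds CPT) and an uptake node (two-probability link on intention).
#'
#' @param sector `"dairy"` or `"fruit"`.
#' @param params [elicitation_params()].
#' @param roster actor roster, see [actor_roster()].
#' @return a validated `bbn`.
#' @export
assemble_si_network <- function(sector = c("dairy", "fruit"),
                                params = elicitation_params(),
                                roster = NULL) {
  sector <- match.arg(sector)
  if (is.null(roster)) roster <- actor_roster(sector)
  nodes <- list()
  for (a in names(roster)) {
    nodes[[a]] <- bbn_node(a, roster[[a]]$states, character(0),
                           matrix(roster[[a]]$prior, nrow = 1))
  }
  cs <- char_states(sector)
  for (v in names(cs)) {
    nodes[[v]] <- bbn_node(v, names(cs[[v]]), character(0),
                           matrix(unname(cs[[v]]), nrow = 1))
  }
  pt <- policy_targets(sector)
  nodes$Subsidies <- bbn_node("Subsidies", names(pt$Subsidies),
                              c("Province", "NLEU"), policy_cpt(pt$Subsidies))
  nodes$Regulations <- bbn_node("Regulations", names(pt$Regulations),
                                c("Province", "NLEU"),
                                policy_cpt(pt$Regulations))
  for (m in si_measures()) {
    ranked <- Filter(function(a) m %in% names(a$ranks), roster)
    if (!length(ranked)) stop("no ranked actors for measure ", m)
    ranked <- lapply(ranked, function(a) list(states = a$states,
                                              rank = a$ranks[[m]]))
    adv <- elicit_actor_cpt(ranked, params, m)
    nodes[[paste0("Advice_", m)]] <-
      bbn_node(paste0("Advice_", m), c("positive", "negative"), adv$parents,
               adv$cpt)
    int <- intention_cpt(m, sector, params)
    nodes[[paste0("Intention_", m)]] <-
      bbn_node(paste0("Intention_", m), c("positive", "negative"),
               int$parents, int$cpt)
    up <- params$uptake[[m]]
    nodes[[paste0("Uptake_", m)]] <-
      bbn_node(paste0("Uptake_", m), c("yes", "no"),
               paste0("Intention_", m),
               rbind(c(up[["pi1"]], 1 - up[["pi1"]]),
                     c(up[["pi0"]], 1 - up[["pi0"]])))
  }
  bbn(nodes)
}

#' Printed baseline calibration targets
#'
#' The baseline advice-positive, intention-positive and uptake-yes
#' probabilities per measure and sector from the reported baseline table.
#'
#' @param sector `"dairy"` or `"fruit"`.
#' @return list with numeric vectors `advice`, `intention`, `uptake` named by
#'   measure.
#' @export
baseline_targets <- function(sector = c("dairy", "fruit")) {
  sector <- match.arg(sector)
  if (sector == "dairy") {
    list(advice = c(FoA1_3 = 0.52, FoA2 = 0.57, FoA4 = 0.40),
         intention = c(FoA1_3 = 0.52, FoA2 = 0.49, FoA4 = 0.29),
         uptake = c(FoA1_3 = 0.36, FoA2 = 0.53, FoA4 = 0.20))
  } else {
    list(advice = c(FoA1_3 = 0.52, FoA2 = 0.56, FoA4 = 0.41),
         intention = c(FoA1_3 = 0.51, FoA2 = 0.45, FoA4 = 0.30),
         uptake = c(FoA1_3 = 0.35, FoA2 = 0.40, FoA4 = 0.22))
  }
}

#' Baseline marginal report
#'
#' Exact baseline marginals (no evidence) of every advice, intention and
#' uptake node, plus the root priors, mirroring the reported baseline table.
#'
#' @param net a calibrated `bbn`.
#' @return data frame: node, state, probability.
#' @export
baseline_report <- function(net) {
  rows <- lapply(names(net$nodes), function(v) {
    p <- infer_marginal(net, v)
    data.frame(node = v, state = names(p), probability = unname(p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

baseline_marginals <- function(net) {
  out <- list()
  for (m in si_measures()) {
    out[[m]] <- c(
      advice = unname(infer_marginal(net, paste0("Advice_", m))["positive"]),
      intention = unname(infer_marginal(net, paste0("Intention_", m))["positive"]),
      uptake = unname(infer_marginal(net, paste0("Uptake_", m))["yes"])
    )
  }
  out
}

#' Calibrate the elicitation parameters to baseline targets
#'
#' Coordinate search with local refinement, measure by measure: the advice
#' baseline is solved by bracketing on a coarse grid followed by root-finding
#' (the advice marginal is monotone in the baseline), then the intention
#' intercept the same way, and the uptake link is derived from the achieved
#' intention marginal with the fixed `pi_ratio` (`pi0 = pi_ratio * pi1`), which
#' matches the uptake target exactly. If the initial parameters already
#' reproduce every target (max deviation < 1e-9) they are returned unchanged.
#' Deterministic.
#'
#' @param sector `"dairy"` or `"fruit"`.
#' @param targets list as from [baseline_targets()].
#' @param params starting [elicitation_params()].
#' @param tol root-finding tolerance on the marginals.
#' @return list of class `si_calibration`: `params`, `net` (the calibrated
#'   network), `achieved` (marginals), `max_abs_dev`, `loss` (sum of squared
#'   deviations), `initial_loss`.
#' @export
calibrate_si_network <- function(sector = c("dairy", "fruit"),
                                 targets = baseline_targets(sector),
                                 params = elicitation_params(),
                                 tol = 1e-7) {
  sector <- match.arg(sector)
  for (blk in c("advice", "intention", "uptake")) {
    if (any(targets[[blk]] < 0 | targets[[blk]] > 1)) {
      stop("calibration targets must lie in [0, 1]")
    }
  }
  roster <- actor_roster(sector)

  dev <- function(net) {
    bm <- baseline_marginals(net)
    unlist(lapply(si_measures(), function(m) {
      c(bm[[m]]["advice"] - targets$advice[[m]],
        bm[[m]]["intention"] - targets$intention[[m]],
        bm[[m]]["uptake"] - targets$uptake[[m]])
    }))
  }
  initial_net <- assemble_si_network(sector, params, roster)
  d0 <- dev(initial_net)
  initial_loss <- sum(d0^2)
  if (max(abs(d0)) < 1e-9) {
    return(structure(list(params = params, net = initial_net,
                          achieved = baseline_marginals(initial_net),
                          max_abs_dev = max(abs(d0)), loss = initial_loss,
                          initial_loss = initial_loss),
                     class = "si_calibration"))
  }

  lo <- params$clamp
  hi <- 1 - params$clamp
  solve_mono <- function(f, target) {
    # coarse grid to bracket, then refine with uniroot
    xs <- seq(lo, hi, length.out = 25)
    ys <- vapply(xs, f, numeric(1)) - target
    if (all(ys < 0)) return(xs[which.max(ys)])
    if (all(ys > 0)) return(xs[which.min(ys)])
    i <- which(ys[-1] * ys[-length(ys)] <= 0)[1]
    uniroot(function(x) f(x) - target, c(xs[i], xs[i + 1]), tol = tol)$root
  }

  for (m in si_measures()) {
    # 1. advice baseline: exact expectation over the (independent) actor priors
    ranked <- Filter(function(a) m %in% names(a$ranks), roster)
    ranked <- lapply(ranked, function(a) list(states = a$states,
                                              rank = a$ranks[[m]],
                                              prior = a$prior))
    # same rank order (ties by roster order) as inside elicit_actor_cpt
    ranked <- ranked[order(vapply(ranked, `[[`, numeric(1), "rank"))]
    advice_marg <- function(b) {
      p2 <- params; p2$baseline[[m]] <- b
      el <- elicit_actor_cpt(ranked, p2, m)
      wgrid <- expand.grid(lapply(ranked, `[[`, "prior"),
                           KEEP.OUT.ATTRS = FALSE)
      sum(el$cpt[, "positive"] * apply(as.matrix(wgrid), 1, prod))
    }
    params$baseline[[m]] <- solve_mono(advice_marg, targets$advice[[m]])

    # 2. intention intercept: exact inference on the assembled network
    net_m <- assemble_si_network(sector, params, roster)
    int_name <- paste0("Intention_", m)
    int_marg <- function(alpha) {
      p2 <- params; p2$intercept[[m]] <- qlogis(alpha)
      ic <- intention_cpt(m, sector, p2)
      net_m$nodes[[int_name]]$cpt <- ic$cpt
      unname(infer_marginal(net_m, int_name)["positive"])
    }
    # parameterized through plogis so the grid stays in (0, 1)
    a_star <- solve_mono(int_marg, targets$intention[[m]])
    params$intercept[[m]] <- qlogis(a_star)

    # 3. uptake link from the achieved intention marginal
    net_m <- assemble_si_network(sector, params, roster)
    p_int <- unname(infer_marginal(net_m, int_name)["positive"])
    r <- params$pi_ratio
    pi1 <- targets$uptake[[m]] / (r + (1 - r) * p_int)
    pi1 <- clamp(pi1, params$clamp, 1 - params$clamp)
    params$uptake[[m]] <- c(pi1 = pi1, pi0 = r * pi1)
  }

  net <- assemble_si_network(sector, params, roster)
  d <- dev(net)
  structure(list(params = params, net = net,
                 achieved = baseline_marginals(net),
                 max_abs_dev = max(abs(d)), loss = sum(d^2),
                 initial_loss = initial_loss),
            class = "si_calibration")
}

#' @export
print.si_calibration <- function(x, ...) {
  cat(sprintf("Calibrated SI network: loss %.3g (initial %.3g), max |dev| %.4f\n",
              x$loss, x$initial_loss, x$max_abs_dev))
  invisible(x)
}
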