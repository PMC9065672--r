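#' Actor-group membership
#'
#' Maps each group used in the sensitivity suites to the actor nodes belonging
#' to it, derived from the roster's group labels. `"all"` covers every actor.
#'
#' @param roster actor roster, see [actor_roster()].
#' @return named list of actor-name vectors.
#' @export
actor_groups <- function(roster = actor_roster("dairy")) {
  groups <- c("local", "external", "market", "government", "formal", "informal")
  out <- lapply(groups, function(g) {
    names(Filter(function(a) g %in% a$groups, roster))
  })
  names(out) <- groups
  out$all <- names(roster)
  out
}

#' Build one scenario specification
#'
#' @param name scenario label.
#' @param assignments named list mapping group names (see [actor_groups()]) to
#'   `"supportive"`, `"neutral"` or `"unsupportive"`. Actors in no assigned
#'   group default to neutral (their baseline prior is kept).
#' @param roster actor roster.
#' @return object of class `scenario_spec` with the resolved per-actor states.
#' @export
scenario_spec <- function(name, assignments, roster = actor_roster("dairy")) {
  groups <- actor_groups(roster)
  bad <- setdiff(names(assignments), names(groups))
  if (length(bad)) stop("unknown actor groups: ", paste(bad, collapse = ", "))
  actors <- setNames(rep("neutral", length(roster)), names(roster))
  for (g in names(assignments)) {
    state <- match.arg(assignments[[g]],
                       c("supportive", "neutral", "unsupportive"))
    for (a in groups[[g]]) {
      if (actors[[a]] != "neutral" && actors[[a]] != state) {
        stop(sprintf("actor %s receives conflicting states in scenario '%s'",
                     a, name))
      }
      actors[[a]] <- state
    }
  }
  structure(list(name = name, assignments = assignments, actors = actors),
            class = "scenario_spec")
}

#' The fourteen-scenario sensitivity suite
#'
#' The four scenario groupings of the sensitivity analysis: external vs local
#' actors, government vs market actors, informal vs formal actors (four
#' combinations each), plus the two all-actor runs.
#'
#' @param roster actor roster.
#' @return list of [scenario_spec()] objects.
#' @export
make_scenario_suite <- function(roster = actor_roster("dairy")) {
  sp <- function(name, ...) scenario_spec(name, list(...), roster)
  list(
    sp("E unsupportive, L neutral", external = "unsupportive", local = "neutral"),
    sp("E unsupportive, L supportive", external = "unsupportive", local = "supportive"),
    sp("E supportive, L unsupportive", external = "supportive", local = "unsupportive"),
    sp("E supportive, L neutral", external = "supportive", local = "neutral"),
    sp("G unsupportive, M neutral", government = "unsupportive", market = "neutral"),
    sp("G unsupportive, M supportive", government = "unsupportive", market = "supportive"),
    sp("G supportive, M unsupportive", government = "supportive", market = "unsupportive"),
    sp("G supportive, M neutral", government = "supportive", market = "neutral"),
    sp("I unsupportive, F neutral", informal = "unsupportive", formal = "neutral"),
    sp("I unsupportive, F supportive", informal = "unsupportive", formal = "supportive"),
    sp("I supportive, F unsupportive", informal = "supportive", formal = "unsupportive"),
    sp("I supportive, F neutral", informal = "supportive", formal = "neutral"),
    sp("All actors unsupportive", all = "unsupportive"),
    sp("All actors supportive", all = "supportive")
  )
}

# evidence list for a scenario: hard state for supportive/unsupportive actors
# (attitude states s/u; an actor without an unsupportive state, i.e. Labels,
# falls back to neutral), nothing for neutral (baseline prior kept)
scenario_evidence <- function(spec, net) {
  ev <- list()
  for (a in names(spec$actors)) {
    st <- spec$actors[[a]]
    if (st == "neutral") next
    target <- if (st == "supportive") "s" else "u"
    if (!target %in% net$nodes[[a]]$states) next  # no such attitude state
    ev[[a]] <- target
  }
  ev
}

#' Classify a scenario's change vector as synergy or trade-off
#'
#' All three indicator changes positive: synergy `S_plus`; all negative:
#' `S_minus`; all exactly zero: `none`; anything else (including zeros inside a
#' mixed vector): trade-off `T`.
#'
#' @param deltas numeric vector of three finite signed (percent) changes.
#' @return one of `"S_plus"`, `"S_minus"`, `"T"`, `"none"`.
#' @export
classify_tradeoff <- function(deltas) {
  stopifnot(length(deltas) == 3, all(is.finite(deltas)))
  if (all(deltas > 0)) return("S_plus")
  if (all(deltas < 0)) return("S_minus")
  if (all(deltas == 0)) return("none")
  "T"
}

#' Run one scenario on a calibrated network
#'
#' Actor attitudes are fixed per the scenario (neutral actors keep their
#' baseline prior), the three uptake marginals are inferred exactly, and the
#' percent change versus the baseline adoption level is computed as
#' `100 * (p_scenario - p_baseline) / p_baseline`.
#'
#' @param net calibrated `bbn`.
#' @param spec a [scenario_spec()].
#' @param baseline named per-measure baseline adoption probabilities in
#'   (0, 1]; defaults to the network's own baseline uptake marginals.
#' @return data frame of class `scenario_result`: measure, uptake,
#'   baseline, pct_change, plus attributes `scenario` and `class`.
#' @export
run_scenario <- function(net, spec, baseline = NULL) {
  if (is.null(baseline)) {
    baseline <- vapply(si_measures(), function(m) {
      unname(infer_marginal(net, paste0("Uptake_", m))["yes"])
    }, numeric(1))
  }
  if (any(baseline <= 0)) {
    stop("baseline adoption must be positive to express percent change")
  }
  ev <- scenario_evidence(spec, net)
  uptake <- vapply(si_measures(), function(m) {
    unname(infer_marginal(net, paste0("Uptake_", m), ev)["yes"])
  }, numeric(1))
  pct <- 100 * (uptake - baseline[si_measures()]) / baseline[si_measures()]
  out <- data.frame(measure = si_measures(), uptake = unname(uptake),
                    baseline = unname(baseline[si_measures()]),
                    pct_change = unname(pct), stringsAsFactors = FALSE)
  attr(out, "scenario") <- spec$name
  attr(out, "class_label") <- classify_tradeoff(pct)
  class(out) <- c("scenario_result", "data.frame")
  out
}

#' Run the full sensitivity suite
#'
#' @param net calibrated `bbn`.
#' @param suite list of scenario specs (default [make_scenario_suite()]).
#' @param baseline see [run_scenario()].
#' @param sector label echoed in the output.
#' @return data frame mirroring the reported layout: scenario, sector, class,
#'   one percent-change column per measure.
#' @export
run_scenario_suite <- function(net, suite = NULL, baseline = NULL,
                               sector = NA_character_) {
  if (is.null(suite)) suite <- make_scenario_suite()
  rows <- lapply(suite, function(spec) {
    r <- run_scenario(net, spec, baseline)
    data.frame(scenario = spec$name, sector = sector,
               class = attr(r, "class_label"),
               dFoA1_3 = r$pct_change[r$measure == "FoA1_3"],
               dFoA2 = r$pct_change[r$measure == "FoA2"],
               dFoA4 = r$pct_change[r$measure == "FoA4"],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-farm supportive-minus-unsupportive impact
#'
#' For each farm, its observable characteristics (location, size, age,
#' successor, innovativeness) are entered as evidence and the uptake marginal
#' of the measure is inferred under the all-actors-supportive and
#' all-actors-unsupportive scenarios; the difference (supportive minus
#' unsupportive) quantifies how much the actor context can move that farm.
#' Computed once per unique characteristic combination for speed. Optionally
#' written as GeoJSON for mapping on the synthetic coordinates.
#'
#' @param farms `farm_population` data frame.
#' @param net calibrated `bbn` for the farms' sector.
#' @param measure one of [si_measures()].
#' @param geojson optional output path for point features.
#' @return `farms` with columns `p_supportive`, `p_unsupportive`, `impact`.
#' @export
spatial_impact <- function(farms, net, measure = "FoA4", geojson = NULL) {
  stopifnot(measure %in% si_measures())
  sup <- scenario_evidence(scenario_spec("all sup", list(all = "supportive")), net)
  uns <- scenario_evidence(scenario_spec("all uns", list(all = "unsupportive")), net)
  key <- paste(farms$location_class, farms$size_class, farms$age_class,
               farms$successor, farms$innovative)
  uk <- !duplicated(key)
  node <- paste0("Uptake_", measure)
  res <- lapply(which(uk), function(i) {
    ev <- list(
      FarmLocation = farms$location_class[i],
      FarmSize = farms$size_class[i],
      Age = farms$age_class[i],
      Successor = if (farms$successor[i]) "y" else "n",
      Innovative = farms$innovative[i]
    )
    c(sup = unname(infer_marginal(net, node, c(ev, sup))["yes"]),
      uns = unname(infer_marginal(net, node, c(ev, uns))["yes"]))
  })
  res <- do.call(rbind, res)
  rownames(res) <- key[uk]
  farms$p_supportive <- res[key, "sup"]
  farms$p_unsupportive <- res[key, "uns"]
  farms$impact <- farms$p_supportive - farms$p_unsupportive
  if (!is.null(geojson)) write_farms_geojson(farms, geojson)
  farms
}

#' Write suite results as CSV
#'
#' @param results data frame from [run_scenario_suite()].
#' @param path output file.
#' @export
write_scenario_csv <- function(results, path) {
  write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
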