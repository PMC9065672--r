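#' Default per-sector characteristic marginals
#'
#' Baseline distributions of farm/farmer characteristics for the dairy and
#' fruit sectors of the peri-urban case-study area: intrinsic attitude
#' (supportive/neutral/unsupportive), age class (young/medium/old),
#' innovativeness (yes/neutral/no), successor (yes/no), farm-size class
#' (small/medium/large) and location class (close/medium/remote). Printed rows
#' that do not sum to exactly 100% are renormalized ratio-preserving.
#'
#' @param sector `"dairy"` or `"fruit"`.
#' @return named list of normalized probability vectors.
#' @export
sector_marginals <- function(sector = c("dairy", "fruit")) {
  sector <- match.arg(sector)
  raw <- if (sector == "dairy") {
    list(
      intrinsic_attitude = c(supportive = 0.45, neutral = 0.27, unsupportive = 0.28),
      age_class          = c(y = 0.21, m = 0.53, o = 0.26),
      innovative         = c(yes = 0.10, neutral = 0.75, no = 0.15),
      successor          = c(yes = 0.29, no = 0.71),
      size_class         = c(s = 0.26, m = 0.58, l = 0.17),
      location_class     = c(close = 0.24, medium = 0.42, remote = 0.34)
    )
  } else {
    list(
      intrinsic_attitude = c(supportive = 0.42, neutral = 0.29, unsupportive = 0.29),
      age_class          = c(y = 0.29, m = 0.37, o = 0.34),
      innovative         = c(yes = 0.10, neutral = 0.80, no = 0.10),
      successor          = c(yes = 0.07, no = 0.93),
      size_class         = c(s = 0.36, m = 0.37, l = 0.27),
      location_class     = c(close = 0.30, medium = 0.57, remote = 0.34)
    )
  }
  out <- lapply(names(raw), function(nm) {
    suppressWarnings(normalize_marginal(raw[[nm]], paste(sector, nm)))
  })
  names(out) <- names(raw)
  out
}

#' Population generator configuration
#'
#' Defaults encode the case-study area: 284 dairy farms and 71 fruit growers
#' (arable farms are excluded from all analyses), per-sector characteristic
#' marginals, a 10% intrinsically innovative fraction, and initial uptake of
#' direct sales and small landscape elements per sector (the observed adoption
#' levels: dairy 29% landscape elements / 11% direct sales, fruit 14% / 9%).
#'
#' @param n_dairy,n_fruit sector farm counts (non-negative integers).
#' @param seed integer seed driving all randomness of the generator.
#' @param sampling_mode `"quota"` (largest-remainder apportionment; printed
#'   marginals are hit exactly up to 1/n) or `"bernoulli"` (independent draws).
#' @param marginals per-sector characteristic marginals; see
#'   [sector_marginals()].
#' @param innovative_fraction fraction of farms classified intrinsically
#'   innovative (exactly `round(fraction * n)` farms per sector in quota mode).
#' @param initial_uptake per-sector list with elements `direct_sales` and
#'   `landscape_elements` in `[0, 1]`.
#' @param direct_sales_odds odds multiplier favouring close-to-village farms
#'   when assigning initial direct-sales status (farms with direct sales tend
#'   to be located closer to villages).
#' @param village_centers two-column matrix of village-center coordinates
#'   (arbitrary planar units). Default centers are mutually distant so each
#'   farm's nearest center is the one it was scattered around.
#' @param size_bounds per-sector list of `c(lo, hi)` hectare bounds for the
#'   s/m/l size classes (uniform within class).
#' @param distance_bands `c(lo, hi)` distance-to-village bands for the
#'   close/medium/remote location classes.
#' @return object of class `population_config`.
#' @export
population_config <- function(n_dairy = 284L,
                              n_fruit = 71L,
                              seed = 1L,
                              sampling_mode = c("quota", "bernoulli"),
                              marginals = list(dairy = sector_marginals("dairy"),
                                               fruit = sector_marginals("fruit")),
                              innovative_fraction = 0.10,
                              initial_uptake = list(
                                dairy = list(direct_sales = 0.11, landscape_elements = 0.29),
                                fruit = list(direct_sales = 0.09, landscape_elements = 0.14)
                              ),
                              direct_sales_odds = 2.0,
                              village_centers = rbind(c(0, 0), c(100, 0), c(50, 80)),
                              size_bounds = list(
                                dairy = list(s = c(5, 25), m = c(25, 60), l = c(60, 120)),
                                fruit = list(s = c(1, 10), m = c(10, 25), l = c(25, 60))
                              ),
                              distance_bands = list(close = c(0.5, 2.5),
                                                    medium = c(6, 9),
                                                    remote = c(13, 17))) {
  sampling_mode <- match.arg(sampling_mode)
  if (n_dairy < 0 || n_fruit < 0) stop("invalid config: negative farm counts")
  for (sec in c("dairy", "fruit")) {
    for (nm in names(marginals[[sec]])) {
      marginals[[sec]][[nm]] <-
        normalize_marginal(marginals[[sec]][[nm]], paste(sec, nm))
    }
  }
  if (innovative_fraction < 0 || innovative_fraction > 1) {
    stop("invalid config: innovative_fraction outside [0, 1]")
  }
  for (sec in c("dairy", "fruit")) {
    for (nm in c("direct_sales", "landscape_elements")) {
      p <- initial_uptake[[sec]][[nm]]
      if (is.null(p) || p < 0 || p > 1) {
        stop("invalid config: initial_uptake proportions must lie in [0, 1]")
      }
    }
  }
  village_centers <- as.matrix(village_centers)
  if (ncol(village_centers) != 2 || nrow(village_centers) < 1) {
    stop("invalid config: village_centers must be an n x 2 matrix with n >= 1")
  }
  structure(list(
    n_dairy = as.integer(n_dairy), n_fruit = as.integer(n_fruit),
    seed = as.integer(seed), sampling_mode = sampling_mode,
    marginals = marginals, innovative_fraction = innovative_fraction,
    initial_uptake = initial_uptake, direct_sales_odds = direct_sales_odds,
    village_centers = village_centers, size_bounds = size_bounds,
    distance_bands = distance_bands
  ), class = "population_config")
}

#' Read a population configuration from a key-value (YAML) file
#'
#' Only keys present in the file override [population_config()] defaults.
#'
#' @param path file path.
#' @return `population_config` object.
#' @export
read_population_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(population_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$village_centers)) {
    raw$village_centers <- do.call(rbind, raw$village_centers)
  }
  do.call(population_config, raw)
}

# quota assignment of one categorical attribute: counts by largest remainder,
# then a seeded permutation over farms
quota_assign <- function(p, n) {
  counts <- largest_remainder(p, n)
  sample(rep(names(counts), counts))
}

bernoulli_assign <- function(p, n) {
  sample(names(p), n, replace = TRUE, prob = p)
}

generate_sector <- function(sector, n, cfg) {
  m <- cfg$marginals[[sector]]
  quota <- cfg$sampling_mode == "quota"
  assign1 <- function(p) if (quota) quota_assign(p, n) else bernoulli_assign(p, n)

  if (n == 0) {
    return(data.frame(farm_id = character(0), sector = character(0),
                      age_class = character(0), size_class = character(0),
                      size_ha = numeric(0), location_class = character(0),
                      successor = logical(0), innovative = character(0),
                      intrinsic_attitude = character(0),
                      has_direct_sales = logical(0), has_sle = logical(0),
                      x = numeric(0), y = numeric(0),
                      stringsAsFactors = FALSE))
  }

  age <- assign1(m$age_class)
  size_class <- assign1(m$size_class)
  location <- assign1(m$location_class)
  successor <- assign1(m$successor) == "yes"
  attitude <- assign1(m$intrinsic_attitude)

  # innovators: exactly round(f * n) in quota mode; the rest split
  # neutral/no per the innovativeness marginal
  rest_p <- m$innovative[c("neutral", "no")]
  if (quota) {
    n_innov <- round(cfg$innovative_fraction * n)
    innovative <- rep(NA_character_, n)
    idx <- sample.int(n, n_innov)
    innovative[idx] <- "yes"
    rest <- setdiff(seq_len(n), idx)
    if (length(rest)) {
      innovative[rest] <- quota_assign(rest_p, length(rest))
    }
  } else {
    innov <- runif(n) < cfg$innovative_fraction
    innovative <- ifelse(innov, "yes", bernoulli_assign(rest_p, n))
  }

  # hectares uniform within the size-class band
  sb <- cfg$size_bounds[[sector]]
  size_ha <- vapply(size_class, function(cl) runif(1, sb[[cl]][1], sb[[cl]][2]),
                    numeric(1))

  # coordinates: each farm scattered around a random village center at a
  # distance drawn from its location class's band
  centers <- cfg$village_centers
  ci <- sample.int(nrow(centers), n, replace = TRUE)
  d <- vapply(location, function(cl) {
    b <- cfg$distance_bands[[cl]]
    runif(1, b[1], b[2])
  }, numeric(1))
  theta <- runif(n, 0, 2 * pi)
  x <- centers[ci, 1] + d * cos(theta)
  y <- centers[ci, 2] + d * sin(theta)

  # initial uptake: direct sales preferentially close to villages
  p_ds <- cfg$initial_uptake[[sector]]$direct_sales
  w <- ifelse(location == "close", cfg$direct_sales_odds, 1)
  has_ds <- rep(FALSE, n)
  if (quota) {
    k <- round(p_ds * n)
    if (k > 0) has_ds[sample.int(n, k, prob = w)] <- TRUE
  } else {
    has_ds <- runif(n) < clamp(p_ds * n * w / sum(w), 0, 1)
  }
  p_sle <- cfg$initial_uptake[[sector]]$landscape_elements
  has_sle <- rep(FALSE, n)
  if (quota) {
    k <- round(p_sle * n)
    if (k > 0) has_sle[sample.int(n, k)] <- TRUE
  } else {
    has_sle <- runif(n) < p_sle
  }

  data.frame(
    farm_id = sprintf("%s_%03d", sector, seq_len(n)),
    sector = sector, age_class = age, size_class = size_class,
    size_ha = size_ha, location_class = location, successor = successor,
    innovative = innovative, intrinsic_attitude = attitude,
    has_direct_sales = has_ds, has_sle = has_sle, x = x, y = y,
    stringsAsFactors = FALSE
  )
}

#' Generate the synthetic farm population
#'
#' Produces one row per farm with sector, characteristic classes, hectares,
#' location class, initial uptake status and planar coordinates. In quota mode
#' every per-sector categorical marginal of the output matches the
#' configuration to within 1/n; in Bernoulli mode classes are drawn
#' independently per farm. Deterministic given the config seed. When the
#' population is large enough, location classes are re-derived from the
#' generated coordinates with [classify_locations()] (Jenks natural breaks on
#' distance to the nearest village center), which reproduces the quota
#' assignment because the distance bands are well separated.
#'
#' @param config a [population_config()].
#' @return data frame of class `farm_population` with attributes
#'   `village_centers` and `seed`.
#' @export
generate_farm_population <- function(config = population_config()) {
  stopifnot(inherits(config, "population_config"))
  pop <- with_local_seed(config$seed, {
    rbind(generate_sector("dairy", config$n_dairy, config),
          generate_sector("fruit", config$n_fruit, config))
  })
  attr(pop, "village_centers") <- config$village_centers
  attr(pop, "seed") <- config$seed
  class(pop) <- c("farm_population", "data.frame")
  if (nrow(pop) >= 3 &&
      length(unique(nearest_center_distance(pop, config$village_centers))) >= 3) {
    pop <- classify_locations(pop, config$village_centers)
  }
  pop
}

nearest_center_distance <- function(farms, centers) {
  apply(cbind(farms$x, farms$y), 1, function(p) {
    min(sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2))
  })
}

#' Classify farm locations by natural breaks on distance to villages
#'
#' Computes each farm's distance to the nearest village center, splits the
#' distances into three classes with Jenks natural breaks, and labels the
#' classes close/medium/remote in increasing distance order.
#'
#' @param farms a `farm_population` data frame.
#' @param village_centers two-column coordinate matrix (>= 1 center).
#' @return `farms` with `location_class` replaced by the Jenks classification.
#' @export
classify_locations <- function(farms, village_centers) {
  village_centers <- as.matrix(village_centers)
  if (nrow(village_centers) < 1) stop("at least one village center required")
  d <- nearest_center_distance(farms, village_centers)
  breaks <- jenks_breaks(d, 3)  # errors when < 3 distinct distances
  cls <- c("close", "medium", "remote")[jenks_class(d, breaks)]
  farms$location_class <- cls
  farms
}

#' Farm size from the basic CAP payment
#'
#' Farm size in hectares is derived from the farm's basic payment at a flat
#' rate of 260 euro per hectare.
#'
#' @param basic_payment payment in euros (>= 0), vectorized.
#' @param rate euro per hectare.
#' @return hectares.
#' @export
farm_size_from_payment <- function(basic_payment, rate = 260) {
  if (any(basic_payment < 0)) stop("basic payment must be non-negative")
  basic_payment / rate
}

#' Write a farm population to CSV
#'
#' Fixed header: farm_id,sector,age_class,size_class,size_ha,location_class,
#' successor,innovative,intrinsic_attitude,has_direct_sales,has_sle,x,y.
#'
#' @param farms farm population data frame.
#' @param path output file.
#' @export
write_farms_csv <- function(farms, path) {
  cols <- c("farm_id", "sector", "age_class", "size_class", "size_ha",
            "location_class", "successor", "innovative", "intrinsic_attitude",
            "has_direct_sales", "has_sle", "x", "y")
  write.csv(as.data.frame(farms)[, cols], path, row.names = FALSE, quote = FALSE)
}

#' Read a farm population from CSV
#' @param path file written by [write_farms_csv()].
#' @return `farm_population` data frame.
#' @export
read_farms_csv <- function(path) {
  pop <- read.csv(path, stringsAsFactors = FALSE)
  class(pop) <- c("farm_population", "data.frame")
  pop
}

#' Write a farm population as GeoJSON point features
#'
#' Each farm becomes a Point feature with its attributes (including any extra
#' columns such as scenario impact differences) as properties.
#'
#' @param farms farm population data frame with `x`, `y` columns.
#' @param path output file.
#' @export
write_farms_geojson <- function(farms, path) {
  farms <- as.data.frame(farms)
  props <- setdiff(names(farms), c("x", "y"))
  features <- lapply(seq_len(nrow(farms)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(farms$x[i], farms$y[i])),
      properties = as.list(farms[i, props, drop = FALSE])
    )
  })
  doc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
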