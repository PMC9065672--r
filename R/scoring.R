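#' Adoption threshold for one efficiency measure
#'
#' The threshold is the empirical lower 10% quantile of the measure's values
#' across all farms in the reference (country-level) table, computed on the
#' favorable scale: values are negated first when small values indicate
#' adoption, so the bottom decile on the favorable scale marks non-adopters
#' either way. The quantile uses linear interpolation between order statistics
#' (type 7, the common statistical-software default).
#'
#' @param values numeric vector of at least 10 values.
#' @param orientation `"higher_is_adoption"` or `"lower_is_adoption"`.
#' @param prob quantile level (default 0.10).
#' @return threshold on the favorable scale.
#' @export
adoption_threshold <- function(values,
                               orientation = c("higher_is_adoption",
                                               "lower_is_adoption"),
                               prob = 0.10) {
  orientation <- match.arg(orientation)
  if (length(values) < 10) stop("at least 10 values required for a threshold")
  v <- if (orientation == "lower_is_adoption") -values else values
  unname(quantile(v, prob, type = 7))
}

#' Thresholds for every measure of an accounting table
#'
#' @param accounts an `accounting_table`.
#' @param measures the measure set defining orientations.
#' @param prob quantile level.
#' @return named numeric vector of thresholds (favorable scale).
#' @export
adoption_thresholds <- function(accounts, measures = default_measures(),
                                prob = 0.10) {
  th <- vapply(seq_len(nrow(measures)), function(j) {
    adoption_threshold(accounts[[measures$name[j]]], measures$orientation[j],
                       prob)
  }, numeric(1))
  names(th) <- measures$name
  th
}

#' Score farms against per-measure adoption thresholds
#'
#' A farm adopts a measure when its value, on the favorable scale, is at or
#' beyond the threshold (boundary counts as adoption). The per-farm count is
#' the number of adopted measures (0-12).
#'
#' @param accounts an `accounting_table`.
#' @param thresholds named thresholds on the favorable scale, as from
#'   [adoption_thresholds()] (or externally supplied, e.g. mixture midpoints).
#' @param measures measure set defining orientations.
#' @return data frame of class `adoption_result`: farm_id, sector, one 0/1
#'   column per measure, and `count`.
#' @export
score_farms <- function(accounts, thresholds, measures = default_measures()) {
  missing <- setdiff(measures$name, names(accounts))
  if (length(missing)) {
    stop("accounting table lacks measures: ", paste(missing, collapse = ", "))
  }
  missing_th <- setdiff(measures$name, names(thresholds))
  if (length(missing_th)) {
    stop("thresholds lack measures: ", paste(missing_th, collapse = ", "))
  }
  ind <- vapply(seq_len(nrow(measures)), function(j) {
    v <- accounts[[measures$name[j]]]
    if (measures$orientation[j] == "lower_is_adoption") v <- -v
    as.integer(v >= thresholds[[measures$name[j]]])
  }, integer(nrow(accounts)))
  ind <- matrix(ind, nrow = nrow(accounts),
                dimnames = list(NULL, measures$name))
  out <- cbind(data.frame(farm_id = accounts$farm_id, sector = accounts$sector,
                          stringsAsFactors = FALSE),
               as.data.frame(ind))
  out$count <- rowSums(ind)
  class(out) <- c("adoption_result", "data.frame")
  out
}

#' Mean adoption count for one sector
#'
#' @param results an `adoption_result`.
#' @param sector sector label present in the results.
#' @return arithmetic mean of per-farm adoption counts.
#' @export
sector_average <- function(results, sector) {
  counts <- results$count[results$sector == sector]
  if (!length(counts)) stop(sprintf("no farms in sector '%s'", sector))
  mean(counts)
}
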