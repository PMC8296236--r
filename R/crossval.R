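#' Leave-one-year-out split
#'
#' Validation rows are every in-season day of the held-out year; training
#' rows are all other days (e.g. hold out 1995, train on 1996-2015; hold
#' out 1996, train on 1995 and 1997-2015).
#'
#' @param panel a [city_panel()].
#' @param year the year to hold out.
#' @return list of logical masks `train` and `valid` over the panel rows.
#' @export
loyo_split <- function(panel, year) {
  stopifnot(inherits(panel, "city_panel"))
  if (!year %in% panel$data$year)
    stop("year ", year, " is absent from the panel")
  valid <- panel$data$year == year
  list(train = !valid, valid = valid)
}

#' Score predictions against observed counts
#'
#' `r2` is the coefficient of determination 1 - SS_res/SS_tot with SS_tot
#' taken about the observed mean of the scored set (it may be negative);
#' `rmse` the root mean squared error. The squared Pearson correlation is
#' reported alongside for transparency but plays no role in selection.
#'
#' @param observed,predicted equal-length numeric vectors (length >= 2).
#' @return list: `r2`, `rmse`, `r2_pearson`, `n`, `flat` (TRUE when the
#'   observed series has zero variance, leaving r2 undefined as `NA`).
#' @export
score_predictions <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2L)
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  flat <- ss_tot == 0
  r2p <- if (flat || stats::var(predicted) == 0) NA_real_
         else stats::cor(observed, predicted)^2
  list(r2 = if (flat) NA_real_ else 1 - ss_res / ss_tot,
       rmse = sqrt(mean((observed - predicted)^2)),
       r2_pearson = r2p, n = length(observed), flat = flat)
}

#' Leave-one-year-out cross-validation of one metric in one city
#'
#' For each baseline year: the exposure knots are re-estimated from the
#' training rows only (no leakage), the DLNM is fitted on the training
#' rows, and expected daily deaths are predicted for the held-out year.
#' The seasonal block follows `config$cv_seasonal_model` (day-of-season
#' spline plus smooth trend by default: the per-year time spline has no
#' support inside a held-out year and cannot predict it).
#' Per-year R2/RMSE are recorded, and the overall scores are computed on
#' the concatenation of all validation-day (observed, predicted) pairs --
#' pooled residuals, not a mean of per-year scores.
#'
#' @param panel a [city_panel()].
#' @param metric metric name present in the panel.
#' @param config a [study_config()].
#' @return object of class `cv_result`: `city_id`, `metric`, `per_year`
#'   data.frame, `overall_r2`, `overall_rmse`, `pairs` (all validation
#'   observations with predictions), `failed_years`.
#' @export
cross_validate <- function(panel, metric, config) {
  stopifnot(inherits(panel, "city_panel"))
  if (!metric %in% names(panel$data))
    stop("metric ", metric, " absent from panel")
  x <- panel$data[[metric]]
  years <- sort(unique(panel$data$year))
  blocks <- season_blocks(panel)

  per_year <- list(); pairs <- list(); failed <- integer(0)
  for (y in years) {
    split <- loyo_split(panel, y)
    res <- tryCatch({
      spec <- default_cross_basis_spec(x[split$train], config)
      cb <- build_cross_basis(x, spec, groups = blocks,
                              pad = config$season_pad == "repeat_first")
      design <- build_design(panel, cb, config, fit_rows = split$train,
                             seasonal_model = config$cv_seasonal_model)
      fit <- fit_quasipoisson(panel$data$deaths, design)
      predictable <- split$valid & !is.na(panel$data$deaths) &
        stats::complete.cases(cb$values)
      obs <- panel$data$deaths[predictable]
      pred <- predict_deaths(fit, design$X[predictable, , drop = FALSE])
      list(obs = obs, pred = pred)
    }, error = function(e) e)
    if (inherits(res, "error") || length(res$obs) < 2L) {
      failed <- c(failed, y)
      next
    }
    sc <- score_predictions(res$obs, res$pred)
    per_year[[as.character(y)]] <-
      data.frame(year = y, r2 = sc$r2, rmse = sc$rmse, n_days = sc$n)
    pairs[[as.character(y)]] <-
      data.frame(year = y, observed = res$obs, predicted = res$pred)
  }
  if (!length(pairs)) stop("all cross-validation folds failed")
  pairs <- do.call(rbind, pairs)
  rownames(pairs) <- NULL
  overall <- score_predictions(pairs$observed, pairs$predicted)
  structure(list(city_id = panel$city_id, metric = metric,
                 per_year = do.call(rbind, per_year),
                 overall_r2 = overall$r2, overall_rmse = overall$rmse,
                 overall_r2_pearson = overall$r2_pearson,
                 pairs = pairs, failed_years = failed),
            class = "cv_result")
}

# Deterministic argmax over metrics: max r2, ties by min rmse, then by the
# canonical metric ordering.
pick_best_metric <- function(scores) {
  scores$ord <- match(scores$metric, metric_names())
  scores <- scores[order(-scores$r2, scores$rmse, scores$ord), ]
  scores$metric[1]
}

#' Select the best temperature metric from cross-validation results
#'
#' The country-level winner maximizes the overall R2 computed on the
#' country-pooled validation days (all cities' held-out observations
#' concatenated per metric); the per-city winner maximizes each city's own
#' pooled R2. Ties break by lower RMSE, then by the canonical metric order.
#'
#' @param cv_results list of [cross_validate()] results covering one
#'   country's cities and the candidate metrics.
#' @return object of class `metric_selection`: `overall_best`, `city_best`
#'   (named character), `country_scores` and `city_scores` data.frames.
#' @export
select_best <- function(cv_results) {
  stopifnot(length(cv_results) >= 1L,
            all(vapply(cv_results, inherits, logical(1), "cv_result")))
  metrics <- unique(vapply(cv_results, function(r) r$metric, character(1)))
  cities <- unique(vapply(cv_results, function(r) r$city_id, character(1)))

  country_scores <- do.call(rbind, lapply(metrics, function(m) {
    rs <- Filter(function(r) r$metric == m, cv_results)
    pooled <- do.call(rbind, lapply(rs, function(r) r$pairs))
    sc <- score_predictions(pooled$observed, pooled$predicted)
    data.frame(metric = m, r2 = sc$r2, rmse = sc$rmse, n_days = sc$n)
  }))

  city_scores <- do.call(rbind, lapply(cv_results, function(r)
    data.frame(city_id = r$city_id, metric = r$metric,
               r2 = r$overall_r2, rmse = r$overall_rmse)))

  city_best <- vapply(cities, function(ct)
    pick_best_metric(city_scores[city_scores$city_id == ct,
                                 c("metric", "r2", "rmse")]),
    character(1))

  structure(list(overall_best = pick_best_metric(country_scores),
                 city_best = city_best,
                 country_scores = country_scores,
                 city_scores = city_scores),
            class = "metric_selection")
}
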