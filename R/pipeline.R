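#' Run the full two-stage analysis over a set of city panels
#'
#' For every country and every configured metric: place exposure knots on
#' the country-pooled warm-season distribution, fit the city-level DLNMs,
#' reduce to lag-cumulated curves, pool them by multivariate meta-analysis
#' with BLUP, locate the country MMT/MMP on the pooled curve and each
#' city's MMT on its BLUP curve, and compute attributable fractions (city
#' BLUP curves; country values pool numerators and denominators across
#' cities). Optionally runs leave-one-year-out cross-validation per city
#' and metric, selects the overall-best and city-specific-best metrics,
#' and adds the "Average" and "City-specific best model" summary rows.
#'
#' A metric missing (all-`NA`) in any of a country's cities is flagged and
#' skipped for that country. The run is a pure function of
#' `(config, panels)`: identical inputs give identical reports.
#'
#' @param config a [study_config()].
#' @param panels list of [city_panel()]s (one or more countries).
#' @param with_cv run cross-validation and metric selection (default TRUE;
#'   the expensive stage).
#' @param verbose log per-stage timing to stderr.
#' @return named list (one element per country) of class `heatattr_report`
#'   elements, each with `mmt_table`, `haf_table`, `cv_table`, `selection`,
#'   `skipped_metrics`, and a `details` list of the underlying objects.
#' @export
run_pipeline <- function(config, panels, with_cv = TRUE, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"), length(panels) >= 1L,
            all(vapply(panels, inherits, logical(1), "city_panel")))
  yearsets <- lapply(panels, function(p) sort(unique(p$data$year)))
  if (length(unique(yearsets)) != 1L)
    stop("all panels must cover the same baseline years")
  set.seed(config$rng_seed)
  say <- function(...) if (verbose) {
    message(sprintf("[%s] ", format(Sys.time(), "%H:%M:%S")), sprintf(...))
  }

  countries <- unique(vapply(panels, function(p) p$country_id, character(1)))
  out <- lapply(countries, function(ctry) {
    cps <- Filter(function(p) p$country_id == ctry, panels)
    run_country(config, cps, ctry, with_cv, say)
  })
  names(out) <- countries
  out
}

run_country <- function(config, cps, ctry, with_cv, say) {
  cities <- vapply(cps, function(p) p$city_id, character(1))
  skipped <- character(0)
  per_metric <- list()

  for (m in config$metrics) {
    present <- vapply(cps, function(p)
      m %in% names(p$data) && any(is.finite(p$data[[m]])), logical(1))
    if (!all(present)) {
      skipped <- c(skipped, m)
      next
    }
    t0 <- proc.time()[3]
    pooled_vals <- unlist(lapply(cps, function(p) p$data[[m]]))
    fits <- lapply(cps, function(p) {
      vals <- if (config$knot_scope == "country") pooled_vals else p$data[[m]]
      spec <- default_cross_basis_spec(vals, config)
      cb <- build_cross_basis(p$data[[m]], spec, groups = season_blocks(p),
                              pad = config$season_pad == "repeat_first")
      design <- build_design(p, cb, config)
      fit <- fit_quasipoisson(p$data$deaths, design)
      list(curve = reduce_fit(fit, spec, p$city_id, m), spec = spec)
    })
    pooled <- meta_fit(lapply(fits, `[[`, "curve"))
    cmmt <- find_mmt(pooled_as_curve(pooled), pooled_vals,
                     search = config$mmt_search_percentiles)
    city_res <- lapply(seq_along(cps), function(i) {
      p <- cps[[i]]
      bl <- pooled$blups[[p$city_id]]
      mmt_i <- find_mmt(bl, p$data[[m]],
                        search = config$mmt_search_percentiles)
      af <- attributable_fractions(p, m, bl, mmt_i$mmt)
      list(mmt = mmt_i, af = af)
    })
    names(city_res) <- cities
    per_metric[[m]] <- list(pooled = pooled, country_mmt = cmmt,
                            city = city_res)
    say("%s / %s fitted in %.1fs", ctry, m, proc.time()[3] - t0)
  }
  if (!length(per_metric)) stop("no usable metric for country ", ctry)
  metrics_used <- names(per_metric)

  mmt_table <- do.call(rbind, lapply(metrics_used, function(m)
    data.frame(metric = m,
               mmp = per_metric[[m]]$country_mmt$mmp,
               mmt = per_metric[[m]]$country_mmt$mmt)))

  country_af <- function(afs) {
    num <- colSums(do.call(rbind, lapply(afs, function(a)
      unlist(a$numerators))))
    den <- sum(vapply(afs, function(a) a$denom, numeric(1)))
    100 * num / den
  }
  haf_rows <- lapply(metrics_used, function(m) {
    v <- country_af(lapply(per_metric[[m]]$city, `[[`, "af"))
    data.frame(metric = m, haf = v[["num_haf"]], ehaf = v[["num_ehaf"]],
               mhaf = v[["num_mhaf"]])
  })
  haf_table <- do.call(rbind, haf_rows)
  haf_table <- rbind(haf_table,
                     data.frame(metric = "Average",
                                haf = mean(haf_table$haf),
                                ehaf = mean(haf_table$ehaf),
                                mhaf = mean(haf_table$mhaf)))

  selection <- NULL
  cv_table <- NULL
  if (with_cv) {
    t0 <- proc.time()[3]
    cvs <- list()
    for (m in metrics_used) for (p in cps)
      cvs[[paste(p$city_id, m, sep = ".")]] <- cross_validate(p, m, config)
    selection <- select_best(unname(cvs))
    cv_table <- selection$country_scores[, c("metric", "r2", "rmse")]
    cv_table <- rbind(cv_table,
                      data.frame(metric = "Average",
                                 r2 = mean(cv_table$r2),
                                 rmse = mean(cv_table$rmse)))
    # city-specific best model: each city contributes its own winner
    best_pairs <- do.call(rbind, lapply(cities, function(ct) {
      cvs[[paste(ct, selection$city_best[[ct]], sep = ".")]]$pairs
    }))
    sc <- score_predictions(best_pairs$observed, best_pairs$predicted)
    cv_table <- rbind(cv_table,
                      data.frame(metric = "City-specific best model",
                                 r2 = sc$r2, rmse = sc$rmse))
    best_afs <- lapply(cities, function(ct)
      per_metric[[selection$city_best[[ct]]]]$city[[ct]]$af)
    v <- country_af(best_afs)
    haf_table <- rbind(haf_table,
                       data.frame(metric = "City-specific best model",
                                  haf = v[["num_haf"]], ehaf = v[["num_ehaf"]],
                                  mhaf = v[["num_mhaf"]]))
    say("%s cross-validation in %.1fs", ctry, proc.time()[3] - t0)
  }

  structure(list(country_id = ctry, cities = cities,
                 mmt_table = mmt_table, haf_table = haf_table,
                 cv_table = cv_table, selection = selection,
                 skipped_metrics = skipped,
                 details = per_metric),
            class = "heatattr_report")
}

#' @export
print.heatattr_report <- function(x, ...) {
  cat("<heatattr_report> country", x$country_id, "-",
      length(x$cities), "cities\n")
  cat("\nMMP / MMT by metric:\n"); print(x$mmt_table, row.names = FALSE)
  cat("\nAttributable fractions (%):\n"); print(x$haf_table, row.names = FALSE)
  if (!is.null(x$cv_table)) {
    cat("\nCross-validated fit:\n"); print(x$cv_table, row.names = FALSE)
    cat("\nOverall best metric:", x$selection$overall_best, "\n")
    cat("City-specific best:",
        paste(names(x$selection$city_best), x$selection$city_best,
              sep = "=", collapse = ", "), "\n")
  }
  if (length(x$skipped_metrics))
    cat("skipped metrics:", paste(x$skipped_metrics, collapse = ", "), "\n")
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' One subdirectory per country with `mmt.csv`, `haf.csv`, `cv.csv` (when
#' cross-validation ran) and a `report.json` summary.
#'
#' @param report the [run_pipeline()] result.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (ctry in names(report)) {
    r <- report[[ctry]]
    d <- file.path(out_dir, ctry)
    dir.create(d, showWarnings = FALSE)
    utils::write.csv(r$mmt_table, file.path(d, "mmt.csv"), row.names = FALSE)
    utils::write.csv(r$haf_table, file.path(d, "haf.csv"), row.names = FALSE)
    if (!is.null(r$cv_table))
      utils::write.csv(r$cv_table, file.path(d, "cv.csv"), row.names = FALSE)
    js <- list(country = ctry, cities = r$cities,
               skipped_metrics = r$skipped_metrics,
               overall_best = if (!is.null(r$selection)) r$selection$overall_best,
               city_best = if (!is.null(r$selection)) as.list(r$selection$city_best),
               mmt = r$mmt_table, haf = r$haf_table)
    jsonlite::write_json(js, file.path(d, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out_dir)
}
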