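test_that("leave-one-year-out splits follow the round structure", {
  truth <- generator_truth(seed = 71, n_years = 21, baseline = 10)
  p <- generate_panel(truth, "c")
  s95 <- loyo_split(p, 1995)
  expect_setequal(unique(p$data$year[s95$train]), 1996:2015)
  expect_setequal(unique(p$data$year[s95$valid]), 1995)
  s96 <- loyo_split(p, 1996)
  expect_setequal(unique(p$data$year[s96$train]), c(1995, 1997:2015))
  # partition: union is everything, intersection empty
  expect_true(all(xor(s96$train, s96$valid)))
  expect_error(loyo_split(p, 1990), "absent")
})

test_that("score_predictions matches hand-computed values", {
  perfect <- score_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  mean_pred <- score_predictions(c(1, 2, 3), rep(2, 3))
  expect_equal(mean_pred$r2, 0)
  hand <- score_predictions(c(1, 2, 3), c(1, 2, 5))
  expect_equal(hand$r2, -1)           # SS_res 4, SS_tot 2
  expect_equal(hand$rmse, sqrt(4 / 3))
  flat <- score_predictions(c(2, 2, 2), c(1, 2, 3))
  expect_true(flat$flat)
  expect_true(is.na(flat$r2))
})

test_that("pooled scoring is not the mean of per-year scores", {
  # two years with different mortality levels: pooling raw residuals must
  # differ from averaging per-year r2 (the between-year level difference
  # enters the pooled SS_tot only)
  obs1 <- c(1, 2, 3); pred1 <- obs1 + 0.5
  obs2 <- c(101, 102, 103); pred2 <- obs2 + 0.5
  pooled <- score_predictions(c(obs1, obs2), c(pred1, pred2))
  mean_r2 <- mean(c(score_predictions(obs1, pred1)$r2,
                    score_predictions(obs2, pred2)$r2))
  expect_gt(abs(pooled$r2 - mean_r2), 0.3)
})

test_that("a 21-season panel yields exactly 21 folds with pooled overall scores", {
  truth <- generator_truth(seed = 72, n_years = 21, baseline = 10)
  p <- generate_panel(truth, "c")
  cfg <- study_config()
  cv <- cross_validate(p, "tmean", cfg)
  expect_equal(nrow(cv$per_year), 21L)
  expect_equal(cv$per_year$year, 1995:2015)
  expect_equal(length(cv$failed_years), 0L)
  # overall = recompute from the stored pairs, not the per-year mean
  sc <- score_predictions(cv$pairs$observed, cv$pairs$predicted)
  expect_equal(cv$overall_r2, sc$r2)
  expect_equal(cv$overall_rmse, sc$rmse)
  expect_false(isTRUE(all.equal(cv$overall_r2, mean(cv$per_year$r2))))
})

test_that("held-out deaths cannot influence fold predictions", {
  truth <- quick_truth(seed = 73, n_years = 4)
  p <- generate_panel(truth, "c")
  cfg <- study_config(baseline_years = 1995:1998)
  cv <- cross_validate(p, "tmean", cfg)
  # corrupt the held-out year's deaths wildly and re-run
  p2 <- p
  y <- 1996
  p2$data$deaths[p2$data$year == y] <-
    p2$data$deaths[p2$data$year == y] + 500L
  cv2 <- cross_validate(p2, "tmean", cfg)
  expect_equal(cv$pairs$predicted[cv$pairs$year == y],
               cv2$pairs$predicted[cv2$pairs$year == y], tolerance = 1e-10)
})

test_that("select_best applies argmax with deterministic tie-breaks", {
  mk <- function(metric, r2, rmse, city = "a") {
    structure(list(city_id = city, metric = metric,
                   per_year = NULL, overall_r2 = r2, overall_rmse = rmse,
                   pairs = data.frame(year = 2000,
                                      observed = c(1, 2, 4),
                                      predicted = c(1, 2, 4) +
                                        (1 - r2) * c(1, -1, 1)),
                   failed_years = integer(0)),
              class = "cv_result")
  }
  one <- select_best(list(mk("tmax", 0.3, 1)))
  expect_equal(one$overall_best, "tmax")
  expect_equal(unname(one$city_best["a"]), "tmax")
  two <- select_best(list(mk("tmean", 0.30, 1), mk("tmax", 0.28, 1)))
  expect_equal(unname(two$city_best["a"]), "tmean")
  # exact city-level tie: rmse equal too -> canonical metric order wins
  tie <- select_best(list(mk("tmax", 0.3, 1), mk("tmean", 0.3, 1)))
  expect_equal(unname(tie$city_best["a"]), "tmean")
})

test_that("temperature-independent mortality gives the CB no edge over a null", {
  cfg <- study_config(baseline_years = 1995:1998)
  diffs <- sapply(1:3, function(s) {
    truth <- quick_truth(seed = 80 + s, slope = 0)
    p <- generate_panel(truth, "c", seed = 80 + s)
    cv <- cross_validate(p, "tmean", cfg)
    # null oracle: same folds via stats::glm with DOW + day-of-season only
    d <- p$data
    doy <- as.integer(format(d$date, "%j"))
    pairs <- NULL
    for (y in sort(unique(d$year))) {
      tr <- d$year != y
      g <- stats::glm(deaths ~ factor(dow) + splines::ns(doy, 4) + year,
                      data = cbind(d, doy = doy), subset = tr,
                      family = stats::quasipoisson())
      pred <- stats::predict(g, newdata = cbind(d, doy = doy)[!tr, ],
                             type = "response")
      pairs <- rbind(pairs, cbind(d$deaths[!tr], pred))
    }
    null_r2 <- score_predictions(pairs[, 1], pairs[, 2])$r2
    cv$overall_r2 - null_r2
  })
  # no out-of-sample advantage for the cross-basis when there is no signal;
  # at this reduced scale its 16 extra parameters cost a little overfitting,
  # so the difference is small-negative, never positive
  expect_lt(max(diffs), 0.05)
  expect_gt(min(diffs), -0.6)
})

test_that("a strong temperature signal beats the null model out of sample", {
  cfg <- study_config(baseline_years = 1995:1998)
  wins <- sapply(1:3, function(s) {
    truth <- quick_truth(seed = 90 + s, slope = 0.15, baseline = 30)
    p <- generate_panel(truth, "c", seed = 90 + s)
    cv <- cross_validate(p, "tmean", cfg)
    d <- p$data
    doy <- as.integer(format(d$date, "%j"))
    pairs <- NULL
    for (y in sort(unique(d$year))) {
      tr <- d$year != y
      g <- stats::glm(deaths ~ factor(dow) + splines::ns(doy, 4) + year,
                      data = cbind(d, doy = doy), subset = tr,
                      family = stats::quasipoisson())
      pred <- stats::predict(g, newdata = cbind(d, doy = doy)[!tr, ],
                             type = "response")
      pairs <- rbind(pairs, cbind(d$deaths[!tr], pred))
    }
    cv$overall_r2 > score_predictions(pairs[, 1], pairs[, 2])$r2
  })
  expect_true(all(wins))
})
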