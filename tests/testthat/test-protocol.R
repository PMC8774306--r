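test_that("case splits are disjoint, exhaustive and correctly sized", {
  d <- generate_cohort(cohort_config(preset = "published", seed = 71))
  parts <- split_cases(d, seed = 72)
  expect_equal(as.numeric(table(parts$part)), c(229, 29, 28))
  expect_equal(sort(parts$case_id), sort(unique(d$case_id)))
  expect_equal(anyDuplicated(parts$case_id), 0L)
})

test_that("degenerate and mis-sized splits are handled", {
  d <- generate_cohort(tiny_cohort_config(n_cancer = 2, n_normal = 1,
                                          seed = 73))
  # three cases into three singleton parts: always valid
  p <- split_cases(d, 1, 1, 1, seed = 74)
  expect_equal(as.numeric(table(p$part)), c(1, 1, 1))
  expect_equal(anyDuplicated(p$case_id), 0L)

  expect_error(split_cases(d, 2, 2, 2), class = "fluordx_value_error")

  # parts of size >= 2 must contain both classes (redraw until they do)
  d2 <- generate_cohort(tiny_cohort_config(n_cancer = 3, n_normal = 3,
                                           seed = 75))
  for (s in 1:10) {
    p2 <- split_cases(d2, 2, 2, 2, seed = s)
    classes_per_part <- tapply(p2$label, p2$part, function(x)
      length(unique(x)))
    expect_true(all(classes_per_part == 2))
  }
})

test_that("spectra of one case never leak across partitions", {
  d <- generate_cohort(tiny_cohort_config(n_cancer = 6, n_normal = 6,
                                          seed = 76))
  for (s in 1:20) {
    parts <- split_cases(d, 8, 2, 2, seed = s)
    by_part <- split(parts$case_id, parts$part)
    expect_length(intersect(by_part$train, by_part$test), 0)
    expect_length(intersect(by_part$train, by_part$validation), 0)
    expect_length(intersect(by_part$test, by_part$validation), 0)
  }
})

test_that("a single experiment recovers a strong synthetic effect", {
  d <- generate_cohort(tiny_strong_config(n_cancer = 12, n_normal = 12,
                                          seed = 81))
  r <- run_experiment(d, n_train = 16, n_test = 4, n_validation = 4,
                      net_spec = tiny_net_spec(),
                      config = tiny_train_config(max_epochs = 300,
                                                 patience = 100),
                      seed = 82)
  expect_equal(r$tp + r$fn + r$tn + r$fp, 4)
  expect_gte(r$sensitivity, 0.95)
  expect_gte(r$specificity, 0.95)
  expect_true(r$auc >= 0 && r$auc <= 1)
  expect_lte(r$best_epoch, r$stopped_epoch)
})

test_that("cross-validation is reproducible and reduces to a single run", {
  d <- generate_cohort(tiny_strong_config(seed = 83))
  cfg <- tiny_train_config(max_epochs = 10, patience = 5)
  cv1 <- cross_validate(d, n_runs = 2, n_train = 14, n_test = 3,
                        n_validation = 3, net_spec = tiny_net_spec(),
                        config = cfg, master_seed = 84)
  cv2 <- cross_validate(d, n_runs = 2, n_train = 14, n_test = 3,
                        n_validation = 3, net_spec = tiny_net_spec(),
                        config = cfg, master_seed = 84)
  expect_identical(tibble::as_tibble(cv1), tibble::as_tibble(cv2))
  expect_equal(nrow(cv1), 2)

  single <- cross_validate(d, n_runs = 1, n_train = 14, n_test = 3,
                           n_validation = 3, net_spec = tiny_net_spec(),
                           config = cfg, master_seed = 84)
  direct <- run_experiment(d, n_train = 14, n_test = 3, n_validation = 3,
                           net_spec = tiny_net_spec(), config = cfg,
                           seed = (84 + 104729) %% 2147483647)
  expect_equal(tibble::as_tibble(single)[, -1], direct, ignore_attr = TRUE)
})

test_that("run summaries match textbook order statistics", {
  set.seed(91)
  fake <- tibble::tibble(sensitivity = runif(50), specificity = runif(50))
  s <- summarize_runs(fake)
  for (m in c("specificity", "sensitivity")) {
    o <- stats_oracle(fake[[m]])
    row <- s[s$metric == m, ]
    expect_equal(row$n, o$n)
    for (col in c("min", "max", "mean", "median", "sd", "p25", "p75")) {
      expect_equal(row[[col]], o[[col]], tolerance = 1e-12)
    }
  }

  two <- summarize_runs(tibble::tibble(sensitivity = c(0.5, 1.0),
                                       specificity = c(0.5, 1.0)))
  expect_equal(two$mean, c(0.75, 0.75))
  expect_equal(two$min, c(0.5, 0.5))
  expect_equal(two$max, c(1, 1))

  one <- summarize_runs(tibble::tibble(sensitivity = 0.7,
                                       specificity = 0.7))
  expect_equal(one$sd, c(0, 0))
  expect_true(all(one$mean == 0.7) && all(one$median == 0.7))

  expect_error(summarize_runs(fake[0, ]), class = "fluordx_value_error")

  # quartile ordering invariant
  expect_true(all(s$min <= s$p25 & s$p25 <= s$median &
                    s$median <= s$p75 & s$p75 <= s$max))
})

test_that("broom accessors summarise fits and run tables", {
  d <- generate_cohort(tiny_strong_config(seed = 95))
  cfg <- tiny_train_config(max_epochs = 8, patience = 4)
  cv <- cross_validate(d, n_runs = 2, n_train = 14, n_test = 3,
                       n_validation = 3, net_spec = tiny_net_spec(),
                       config = cfg, master_seed = 96)
  g <- glance(cv)
  expect_equal(g$n_runs, 2)
  expect_equal(g$mean_sensitivity, mean(cv$sensitivity))
  expect_equal(tidy(cv), summarize_runs(cv))

  parts <- split_cases(d, 14, 3, 3, seed = 97)
  tr <- d[d$case_id %in% parts$case_id[parts$part == "train"], ]
  mo <- d[d$case_id %in% parts$case_id[parts$part == "test"], ]
  fit <- fit_dense_net(tr, mo, spec = tiny_net_spec(),
                       config = tiny_train_config(max_epochs = 6, seed = 98))
  td <- tidy(fit)
  expect_equal(nrow(td), 4)
  expect_equal(sum(td$n_parameters), n_parameters(tiny_net_spec()))
  gf <- glance(fit)
  expect_equal(gf$best_monitor_loss,
               fit$history$monitor_loss[fit$best_epoch])

  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  expect_s3_class(ggplot2::autoplot(cv), "ggplot")
  rc <- roc_curve(runif(10), rep(c("cancer", "normal"), 5))
  expect_s3_class(ggplot2::autoplot(rc), "ggplot")
  expect_s3_class(plot_spectra(d), "ggplot")
})
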