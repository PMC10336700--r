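make_toy_dataset <- function() {
  set.seed(401)
  n <- c(8, 9, 7)
  arms <- c("ref", "x", "y")
  df <- data.frame(
    patient_id = sprintf("P%02d", 1:sum(n)),
    arm = rep(arms, n),
    cost = round(runif(sum(n), 100, 5000), 2),
    qaly = round(runif(sum(n), 0.3, 1.0), 4)
  )
  trial_dataset(df, arms = arms, reference = "ref")
}

test_that("trial_dataset validates its schema and arm structure", {
  d <- make_toy_dataset()
  expect_s3_class(d, "trial_dataset")
  r <- d$records
  expect_error(trial_dataset(r[, c("patient_id", "arm", "cost")]),
               class = "unli2d_validation_error")
  expect_error(trial_dataset(r, arms = c("ref", "x")),
               class = "unli2d_validation_error")
  expect_error(trial_dataset(r, arms = c("ref", "x", "z")),
               class = "unli2d_validation_error")  # 'y' undeclared
  expect_error(trial_dataset(r, arms = c("ref", "x", "y"), reference = "q"),
               class = "unli2d_validation_error")
  r2 <- r
  r2$cost[3] <- -5
  expect_error(trial_dataset(r2), class = "unli2d_validation_error")
})

test_that("patient_nb computes qaly * wtp - cost and flags missing cells", {
  expect_identical(patient_nb(list(cost = 2678, qaly = 0.7092), 50000), 32782)
  expect_identical(patient_nb(list(cost = 4042, qaly = 0.7217), 50000), 32043)
  expect_identical(patient_nb(list(cost = 0, qaly = 0), 123), 0)
  err <- tryCatch(patient_nb(list(patient_id = "P99", cost = NA, qaly = 1), 1),
                  error = identity)
  expect_s3_class(err, "unli2d_validation_error")
  expect_match(conditionMessage(err), "P99")
  expect_error(patient_nb(list(cost = 1, qaly = 1), -10),
               class = "unli2d_validation_error")
})

test_that("trial CSV io round-trips, reports schema violations by column", {
  d <- make_toy_dataset()
  d$records$cost[2] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(trial_dataset(d$records, d$arms, d$reference), path)
  back <- read_trial_csv(path, arms = d$arms, reference = d$reference)
  expect_equal(back$records, d$records)
  expect_identical(back$reference, "ref")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,arm,cost", "P1,a,1"), bad)
  err <- tryCatch(read_trial_csv(bad), error = identity)
  expect_s3_class(err, "unli2d_validation_error")
  expect_match(conditionMessage(err), "qaly")
  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,arm,cost,qaly", "P1,a,oops,0.5"), bad2)
  err2 <- tryCatch(read_trial_csv(bad2), error = identity)
  expect_s3_class(err2, "unli2d_validation_error")
  expect_match(conditionMessage(err2), "cost")
})

test_that("handle_missing implements the three policies", {
  d <- make_toy_dataset()
  d$records$cost[2] <- NA
  d$records$qaly[10] <- NA
  d <- trial_dataset(d$records, d$arms, d$reference)
  err <- tryCatch(handle_missing(d), error = identity)
  expect_s3_class(err, "unli2d_validation_error")
  expect_match(conditionMessage(err), d$records$patient_id[2])
  cc <- handle_missing(d, "complete_cases")
  expect_identical(nrow(cc$records), nrow(d$records) - 2L)
  mi <- handle_missing(d, "mean_impute")
  expect_identical(nrow(mi$records), nrow(d$records))
  in_arm <- d$records$arm == d$records$arm[2]
  expect_equal(mi$records$cost[2],
               mean(d$records$cost[in_arm], na.rm = TRUE))
  # analyses refuse incomplete data, naming offenders
  expect_error(evpi_unli(d, 50000), class = "unli2d_validation_error")
})

test_that("incremental_nb_params implements the shared-reference covariance", {
  d <- make_toy_dataset()
  wtp <- 30000
  nb <- d$records$qaly * wtp - d$records$cost
  arm <- factor(d$records$arm, levels = d$arms)
  v <- as.numeric(tapply(nb, arm, var)) / as.integer(table(arm))
  m <- as.numeric(tapply(nb, arm, mean))
  p <- incremental_nb_params(d, wtp)
  expect_equal(p$mu1, m[2] - m[1], tolerance = 1e-12)
  expect_equal(p$mu2, m[3] - m[1], tolerance = 1e-12)
  expect_equal(p$sigma1, sqrt(v[2] + v[1]), tolerance = 1e-12)
  expect_equal(p$sigma2, sqrt(v[3] + v[1]), tolerance = 1e-12)
  expect_equal(p$rho, v[1] / (p$sigma1 * p$sigma2), tolerance = 1e-12)
  # constant reference arm: no shared variance, rho = 0
  r <- d$records
  r$cost[r$arm == "ref"] <- 1000
  r$qaly[r$arm == "ref"] <- 0.5
  p0 <- incremental_nb_params(trial_dataset(r, d$arms, "ref"), wtp)
  expect_identical(p0$rho, 0)
})

test_that("exchangeable arms give near-zero incremental means", {
  cfg <- synth_config(
    n_per_arm = rep(5000, 3), arms = c("a", "b", "c"), reference = "a",
    mean_cost = rep(3000, 3), sd_cost = rep(1500, 3),
    mean_qaly = rep(0.7, 3), sd_qaly = rep(0.12, 3),
    cost_qaly_cor = -0.1, missingness = 0, seed = 17
  )
  d <- generate_trial(cfg)
  p <- incremental_nb_params(d, 50000)
  expect_lt(abs(p$mu1), 3 * p$sigma1)
  expect_lt(abs(p$mu2), 3 * p$sigma2)
})

test_that("parameter recovery against the generator's analytic ground truth", {
  cfg <- recovery_config(n = 1e4, seed = 7)
  d <- generate_trial(cfg)
  wtp <- 50000
  truth <- induced_bvn_params(cfg, wtp)
  est <- incremental_nb_params(d, wtp)
  se <- recovery_ses(d, wtp)
  expect_lt(abs(est$mu1 - truth$mu1), 3 * se$mu[1])
  expect_lt(abs(est$mu2 - truth$mu2), 3 * se$mu[2])
  expect_lt(abs(est$sigma1 - truth$sigma1), 3 * se$sigma[1])
  expect_lt(abs(est$sigma2 - truth$sigma2), 3 * se$sigma[2])
  expect_lt(abs(est$rho - truth$rho), 3 * se$rho)
})

test_that("closed-form EVPI from data: dominance and reference invariance", {
  # one arm better by far more than 10 SE: no decision uncertainty
  cfg <- synth_config(
    n_per_arm = rep(300, 3), arms = c("a", "b", "c"), reference = "a",
    mean_cost = c(3000, 3000, 3000), sd_cost = rep(800, 3),
    mean_qaly = c(1.0, 0.45, 0.45), sd_qaly = rep(0.05, 3),
    cost_qaly_cor = 0, missingness = 0, seed = 19
  )
  d <- generate_trial(cfg)
  expect_lt(evpi_unli(d, 50000), 1e-6)
  # relabeling the reference arm leaves EVPI unchanged
  d2 <- generate_trial(recovery_config(n = 400, seed = 23))
  for (wtp in c(25000, 75000)) {
    e <- vapply(d2$arms, function(a) {
      evpi_unli(trial_dataset(d2$records, d2$arms, reference = a), wtp)
    }, numeric(1))
    expect_equal(unname(e[1]), unname(e[2]), tolerance = 1e-6)
    expect_equal(unname(e[1]), unname(e[3]), tolerance = 1e-6)
  }
})

test_that("bootstrap EVPI: determinism, degenerate data, non-negativity", {
  d <- generate_trial(recovery_config(n = 200, seed = 29))
  b1 <- evpi_bootstrap(d, 50000, B = 300, seed = 11)
  b2 <- evpi_bootstrap(d, 50000, B = 300, seed = 11)
  expect_identical(b1$evpi, b2$evpi)
  expect_identical(b1$se, b2$se)
  expect_gte(b1$evpi, 0)
  expect_error(evpi_bootstrap(d, 50000, B = 50, seed = 1),
               class = "unli2d_validation_error")
  # all patients identical: degenerate bootstrap distribution
  df <- data.frame(patient_id = sprintf("P%02d", 1:30),
                   arm = rep(c("a", "b", "c"), each = 10),
                   cost = 1000, qaly = 0.5)
  b0 <- evpi_bootstrap(trial_dataset(df), 50000, B = 100, seed = 1)
  expect_identical(b0$evpi, 0)
  expect_identical(b0$se, 0)
})

test_that("bootstrap and closed-form EVPI agree at large n", {
  d <- generate_trial(recovery_config(n = 2000, seed = 37))
  for (wtp in c(30000, 60000)) {
    b <- evpi_bootstrap(d, wtp, B = 1000, seed = 13)
    expect_lt(abs(evpi_unli(d, wtp) - b$evpi), 3 * b$se)
  }
})

test_that("rubin_pool implements Rubin's rules", {
  C <- matrix(c(2, 0.5, 0.5, 1), 2)
  est <- list(mean = c(1, -1), cov = C)
  pooled <- rubin_pool(list(est, est, est))
  expect_equal(pooled$mean, c(1, -1))
  expect_equal(pooled$cov, C, tolerance = 1e-12)   # B = 0
  # m = 2 worked example: means (0,0) and (2,2), equal within-covariances
  p2 <- rubin_pool(list(list(mean = c(0, 0), cov = C),
                        list(mean = c(2, 2), cov = C)))
  expect_equal(p2$mean, c(1, 1))
  B <- cov(rbind(c(0, 0), c(2, 2)))
  expect_equal(p2$cov, C + 1.5 * B, tolerance = 1e-12)
  # pooled covariance dominates the within component on the diagonal
  set.seed(41)
  ests <- lapply(1:10, function(i) {
    a <- matrix(rnorm(4), 2)
    list(mean = rnorm(2), cov = crossprod(a))
  })
  p10 <- rubin_pool(ests)
  expect_true(all(diag(p10$cov) >= diag(p10$within) - 1e-12))
  expect_error(rubin_pool(list(est)), class = "unli2d_validation_error")
  expect_error(rubin_pool(list(est, list(mean = 1, cov = C))),
               class = "unli2d_validation_error")
})

test_that("evpi_from_pooled matches evpi_from_bvn on the induced parameters", {
  pooled <- structure(
    list(mean = c(-4734, -2668),
         cov = matrix(c(4678^2, 0.5 * 4678 * 4645,
                        0.5 * 4678 * 4645, 4645^2), 2),
         m = 10),
    class = "pooled_estimate"
  )
  expect_equal(evpi_from_pooled(pooled),
               evpi_from_bvn(bvn_params(-4734, -2668, 4678, 4645, 0.5)),
               tolerance = 1e-12)
})

test_that("wtp_sweep produces a consistent curve", {
  d <- generate_trial(recovery_config(n = 300, seed = 43))
  one <- wtp_sweep(d, 50000, B = 200, seed = 3)
  expect_identical(nrow(one), 1L)
  grid <- c(20000, 40000, 60000, 80000)
  cv <- wtp_sweep(d, grid, B = 1000, seed = 3)
  expect_identical(names(cv), c("wtp", "evpi_unli", "evpi_boot", "boot_se"))
  expect_true(all(cv$evpi_unli >= 0) && all(cv$evpi_boot >= 0))
  # cross-method consistency band on an uncertain-decision world
  rel <- abs(cv$evpi_unli - cv$evpi_boot) / pmax(cv$evpi_boot, 1)
  expect_lt(max(rel), 0.15)
  expect_error(wtp_sweep(d, c(2, 1)), class = "unli2d_validation_error")
  expect_error(wtp_sweep(d, numeric(0)), class = "unli2d_validation_error")
  # JSON serialization carries the per-point parameterization
  js <- jsonlite::fromJSON(write_evpi_json(cv))
  expect_identical(nrow(js), 4L)
  expect_equal(js$evpi_unli, cv$evpi_unli, tolerance = 1e-12)
  expect_equal(js$bvn_params$rho,
               vapply(attr(cv, "params"), `[[`, numeric(1), "rho"),
               tolerance = 1e-12)
})

test_that("an everywhere-dominant arm yields a flat zero EVPI curve", {
  cfg <- synth_config(
    n_per_arm = rep(250, 3), arms = c("a", "b", "c"), reference = "a",
    mean_cost = c(2000, 2000, 2000), sd_cost = rep(500, 3),
    mean_qaly = c(1.1, 0.4, 0.4), sd_qaly = rep(0.04, 3),
    cost_qaly_cor = 0, missingness = 0, seed = 47
  )
  d <- generate_trial(cfg)
  cv <- wtp_sweep(d, c(10000, 50000, 100000), B = 200, seed = 5)
  expect_true(all(cv$evpi_unli < 1e-6))
  expect_true(all(cv$evpi_boot < 1e-6))
})
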