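#' Patient-level dataset of a parallel three-arm trial
#'
#' Container for analysis-ready patient records: one row per patient with
#' identifier, arm label, total cost and QALYs. Three arm names are
#' declared in order, one of them designated as the reference strategy for
#' incremental comparisons. Costs must be non-negative (or missing);
#' missing cost/qaly cells are allowed at construction and resolved later
#' via [handle_missing()].
#'
#' @param records Data frame with columns `patient_id`, `arm`, `cost`,
#'   `qaly`.
#' @param arms Character vector of the 3 arm names, in display order.
#'   Defaults to the arms in order of first appearance.
#' @param reference The reference arm name; defaults to `arms[1]`.
#' @return An object of class `"trial_dataset"`: list with `records`,
#'   `arms`, `reference`.
#' @export
trial_dataset <- function(records, arms = NULL, reference = NULL) {
  need <- c("patient_id", "arm", "cost", "qaly")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    fail_validation("records must be a data frame with columns ",
                    paste(need, collapse = ", "))
  records <- records[, need]
  records$patient_id <- as.character(records$patient_id)
  records$arm <- as.character(records$arm)
  if (!is.numeric(records$cost) || !is.numeric(records$qaly))
    fail_validation("cost and qaly must be numeric")
  bad_cost <- which(!is.na(records$cost) & records$cost < 0)
  if (length(bad_cost))
    fail_validation("negative cost for patient(s): ",
                    paste(head(records$patient_id[bad_cost], 5), collapse = ", "))
  if (is.null(arms)) arms <- unique(records$arm)
  arms <- as.character(arms)
  if (length(arms) != 3L || anyDuplicated(arms))
    fail_validation("exactly 3 distinct arm names are required, got: ",
                    paste(arms, collapse = ", "))
  if (is.null(reference)) reference <- arms[1]
  if (!reference %in% arms)
    fail_validation("reference arm '", reference, "' is not one of: ",
                    paste(arms, collapse = ", "))
  unknown <- setdiff(unique(records$arm), arms)
  if (length(unknown))
    fail_validation("records contain undeclared arm label(s): ",
                    paste(unknown, collapse = ", "))
  counts <- table(factor(records$arm, levels = arms))
  if (any(counts == 0))
    fail_validation("empty arm(s): ",
                    paste(names(counts)[counts == 0], collapse = ", "))
  structure(list(records = records, arms = arms, reference = reference),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  counts <- table(factor(x$records$arm, levels = x$arms))
  cat(sprintf("Three-arm trial dataset: %d patients\n", nrow(x$records)))
  for (a in x$arms)
    cat(sprintf("  %s%s: n = %d\n", a,
                if (a == x$reference) " (reference)" else "", counts[[a]]))
  nmiss <- sum(is.na(x$records$cost)) + sum(is.na(x$records$qaly))
  cat(sprintf("  missing cells: %d\n", nmiss))
  invisible(x)
}

#' Read / write the trial CSV schema
#'
#' The on-disk schema is a plain CSV with header
#' `patient_id,arm,cost,qaly`; empty cells denote missing values.
#'
#' @param path File path.
#' @param arms,reference Passed to [trial_dataset()].
#' @return `read_trial_csv`: a `trial_dataset`; `write_trial_csv`: `path`,
#'   invisibly.
#' @export
read_trial_csv <- function(path, arms = NULL, reference = NULL) {
  if (!file.exists(path)) fail_validation("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "arm", "cost", "qaly")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    fail_validation("CSV ", path, " lacks required column(s): ",
                    paste(missing_cols, collapse = ", "))
  for (col in c("cost", "qaly")) {
    v <- df[[col]]
    if (is.character(v)) v[v == ""] <- NA
    v2 <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(v2))
    if (length(bad))
      fail_validation("non-numeric ", col, " at data row(s): ",
                      paste(head(bad, 5), collapse = ", "))
    df[[col]] <- v2
  }
  trial_dataset(df, arms = arms, reference = reference)
}

#' @rdname read_trial_csv
#' @param d A `trial_dataset`.
#' @export
write_trial_csv <- function(d, path) {
  write.csv(d$records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Resolve missing cost/qaly cells
#'
#' The analysis operations require complete data. `policy = "error"`
#' (default) refuses any missing cell; `"complete_cases"` drops patients
#' with a missing cost or qaly; `"mean_impute"` replaces missing cells by
#' the within-arm mean of the observed values (a deliberately simple
#' stand-in -- proper multiple imputation is performed outside the package,
#' whose per-imputation estimates can then be pooled with [rubin_pool()]).
#'
#' @param d A [trial_dataset()].
#' @param policy One of `"error"`, `"complete_cases"`, `"mean_impute"`.
#' @return A complete `trial_dataset`.
#' @export
handle_missing <- function(d, policy = c("error", "complete_cases", "mean_impute")) {
  policy <- match.arg(policy)
  r <- d$records
  incomplete <- is.na(r$cost) | is.na(r$qaly)
  if (!any(incomplete)) return(d)
  if (policy == "error")
    fail_validation("missing cost/qaly for patient(s): ",
                    paste(head(r$patient_id[incomplete], 5), collapse = ", "),
                    if (sum(incomplete) > 5) ", ..." else "",
                    " (choose a missing-data policy)")
  if (policy == "complete_cases") {
    r <- r[!incomplete, , drop = FALSE]
  } else {
    for (a in d$arms) {
      in_arm <- r$arm == a
      for (col in c("cost", "qaly")) {
        v <- r[[col]][in_arm]
        v[is.na(v)] <- mean(v, na.rm = TRUE)
        r[[col]][in_arm] <- v
      }
    }
  }
  trial_dataset(r, arms = d$arms, reference = d$reference)
}

#' Per-patient net benefit
#'
#' NB = QALY x willingness-to-pay - cost.
#'
#' @param record A single patient record (one-row data frame or list with
#'   `cost`, `qaly` and optionally `patient_id`).
#' @param wtp Willingness-to-pay per QALY (>= 0).
#' @return The net benefit, a scalar.
#' @examples
#' patient_nb(list(patient_id = "P1", cost = 2678, qaly = 0.7092), 50000)
#' @export
patient_nb <- function(record, wtp) {
  wtp <- check_number(wtp, "wtp")
  if (wtp < 0) fail_validation("wtp must be >= 0")
  cost <- record$cost
  qaly <- record$qaly
  if (is.null(cost) || is.null(qaly) || length(cost) != 1L || length(qaly) != 1L)
    fail_validation("record must carry scalar cost and qaly fields")
  if (is.na(cost) || is.na(qaly))
    fail_validation("missing cost or qaly for patient '",
                    if (!is.null(record$patient_id)) record$patient_id else "?",
                    "'")
  qaly * wtp - cost
}

# Vector of per-patient NBs for a complete dataset; errors (naming
# offenders) if any cell is missing.
.nb_vector <- function(d, wtp) {
  r <- d$records
  incomplete <- is.na(r$cost) | is.na(r$qaly)
  if (any(incomplete))
    fail_validation("missing cost/qaly for patient(s): ",
                    paste(head(r$patient_id[incomplete], 5), collapse = ", "),
                    if (sum(incomplete) > 5) ", ..." else "",
                    " (resolve with handle_missing())")
  r$qaly * wtp - r$cost
}

#' Per-arm net-benefit summaries
#'
#' For each arm: sample size, mean net benefit, and the variance of that
#' mean (sample variance of per-patient NB divided by n).
#'
#' @param d A complete [trial_dataset()].
#' @param wtp Willingness-to-pay per QALY.
#' @return Data frame with columns `arm`, `n`, `mean_nb`, `var_of_mean`,
#'   one row per declared arm (reference first is *not* imposed; rows
#'   follow the declared arm order).
#' @export
arm_summaries <- function(d, wtp) {
  nb <- .nb_vector(d, wtp)
  arm <- factor(d$records$arm, levels = d$arms)
  n <- as.integer(table(arm))
  if (any(n < 2))
    fail_validation("every arm needs n >= 2 to estimate the variance")
  data.frame(
    arm = d$arms,
    n = n,
    mean_nb = as.numeric(tapply(nb, arm, mean)),
    var_of_mean = as.numeric(tapply(nb, arm, var)) / n
  )
}

#' Bivariate-normal parameters of the incremental net benefits
#'
#' Parameterises the joint uncertainty of the two incremental mean net
#' benefits (each alternative arm minus the reference arm) as a bivariate
#' normal. Arms of a parallel randomized trial are independent, so the two
#' incremental means share variance only through the common reference arm:
#' `mu_i = mean_nb_i - mean_nb_ref`,
#' `sigma_i^2 = var_of_mean_i + var_of_mean_ref`, and
#' `rho = var_of_mean_ref / (sigma_1 * sigma_2)`.
#'
#' @param d A complete [trial_dataset()].
#' @param wtp Willingness-to-pay per QALY.
#' @return A [bvn_params()] object; component 1 is the first non-reference
#'   arm in declared order, component 2 the second (see attribute
#'   `"comparison"`).
#' @export
incremental_nb_params <- function(d, wtp) {
  s <- arm_summaries(d, wtp)
  ref <- s[s$arm == d$reference, ]
  alt <- s[s$arm != d$reference, ]
  sigma1 <- sqrt(alt$var_of_mean[1] + ref$var_of_mean)
  sigma2 <- sqrt(alt$var_of_mean[2] + ref$var_of_mean)
  p <- bvn_params(
    mu1 = alt$mean_nb[1] - ref$mean_nb,
    mu2 = alt$mean_nb[2] - ref$mean_nb,
    sigma1 = sigma1,
    sigma2 = sigma2,
    rho = ref$var_of_mean / (sigma1 * sigma2)
  )
  attr(p, "comparison") <- paste(alt$arm, "vs", ref$arm)
  p
}

#' Closed-form EVPI from trial data
#'
#' [evpi_from_bvn()] applied to [incremental_nb_params()]: the closed-form
#' (UNLI) estimate of the expected value of perfect information at a given
#' willingness-to-pay. Invariant (up to numerical noise) to which arm is
#' designated as reference.
#'
#' @inheritParams incremental_nb_params
#' @return EVPI, a non-negative scalar.
#' @export
evpi_unli <- function(d, wtp) {
  evpi_from_bvn(incremental_nb_params(d, wtp))
}

#' Bootstrap EVPI from trial data
#'
#' The conventional data-driven estimator: draw `B` stratified bootstrap
#' resamples (within arm, with replacement, preserving arm sizes), compute
#' each arm's mean net benefit per resample, and form
#' `EVPI = mean_b[max_k NB_k(b)] - max_k[mean_b NB_k(b)]`. The reported
#' standard error is the Monte-Carlo SE of the first term.
#'
#' @inheritParams incremental_nb_params
#' @param B Number of bootstrap resamples (>= 100).
#' @param seed Integer seed (private stream; global RNG state untouched).
#' @return List with `evpi`, `se`, `B`, `seed`.
#' @export
evpi_bootstrap <- function(d, wtp, B = 1000, seed = 1) {
  B <- check_count(B, "B", min = 100L)
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  nb <- .nb_vector(d, wtp)
  arm <- factor(d$records$arm, levels = d$arms)
  nb_by_arm <- split(nb, arm)
  means <- withr::with_seed(seed, {
    vapply(nb_by_arm, function(v) {
      n <- length(v)
      idx <- sample.int(n, n * B, replace = TRUE)
      rowMeans(matrix(v[idx], nrow = B))
    }, numeric(B))
  })
  max_b <- do.call(pmax, as.data.frame(means))
  list(
    evpi = mean(max_b) - max(colMeans(means)),
    se = sd(max_b) / sqrt(B),
    B = B,
    seed = seed
  )
}

#' Pool multiply-imputed estimates with Rubin's rules
#'
#' Given per-imputation estimates of a mean vector and its covariance
#' matrix, returns the pooled mean (element-wise average) and total
#' covariance `W + (1 + 1/m) B`, where `W` is the average within-imputation
#' covariance and `B` the between-imputation sample covariance of the mean
#' vectors.
#'
#' @param estimates List of `m >= 2` elements, each a list with `mean`
#'   (numeric vector) and `cov` (matching square matrix).
#' @return Object of class `"pooled_estimate"`: list with `mean`, `cov`,
#'   `m`, `within`, `between`.
#' @export
rubin_pool <- function(estimates) {
  if (!is.list(estimates) || length(estimates) < 2L)
    fail_validation("estimates must be a list of at least 2 elements")
  m <- length(estimates)
  d <- length(estimates[[1]]$mean)
  if (d < 1L) fail_validation("estimates must carry a 'mean' vector")
  for (e in estimates) {
    if (length(e$mean) != d || !is.matrix(e$cov) || !all(dim(e$cov) == d))
      fail_validation("all estimates must have a length-", d,
                      " mean and a ", d, "x", d, " covariance")
  }
  qmat <- do.call(rbind, lapply(estimates, function(e) as.numeric(e$mean)))
  within <- Reduce(`+`, lapply(estimates, `[[`, "cov")) / m
  between <- cov(qmat)
  structure(
    list(
      mean = colMeans(qmat),
      cov = within + (1 + 1 / m) * between,
      m = m,
      within = within,
      between = between
    ),
    class = "pooled_estimate"
  )
}

#' EVPI from a pooled two-dimensional estimate
#'
#' Convenience bridge from [rubin_pool()] output (or any mean vector plus
#' covariance of the two incremental net benefits) to [evpi_from_bvn()].
#'
#' @param pooled A `"pooled_estimate"` with a length-2 mean.
#' @return EVPI, a non-negative scalar.
#' @export
evpi_from_pooled <- function(pooled) {
  if (!inherits(pooled, "pooled_estimate") || length(pooled$mean) != 2L)
    fail_validation("pooled must be a 2-dimensional pooled_estimate")
  s1 <- sqrt(pooled$cov[1, 1])
  s2 <- sqrt(pooled$cov[2, 2])
  evpi_from_bvn(bvn_params(pooled$mean[1], pooled$mean[2], s1, s2,
                           pooled$cov[1, 2] / (s1 * s2)))
}

#' EVPI curve over a willingness-to-pay grid
#'
#' Computes both the closed-form (UNLI) and stratified-bootstrap EVPI at
#' each willingness-to-pay value. Bootstrap seeds are derived
#' deterministically per grid point (`seed + index - 1`).
#'
#' @inheritParams evpi_bootstrap
#' @param wtp_grid Non-empty, strictly increasing vector of WTP values
#'   (>= 0).
#' @return Data frame of class `"evpi_curve"` with columns `wtp`,
#'   `evpi_unli`, `evpi_boot`, `boot_se`; attribute `"params"` is the list
#'   of per-point [bvn_params()].
#' @export
wtp_sweep <- function(d, wtp_grid, B = 1000, seed = 1) {
  if (!is.numeric(wtp_grid) || length(wtp_grid) < 1L || anyNA(wtp_grid) ||
      any(wtp_grid < 0) || is.unsorted(wtp_grid, strictly = TRUE))
    fail_validation("wtp_grid must be a strictly increasing vector of non-negative values")
  params <- vector("list", length(wtp_grid))
  unli <- boot <- se <- numeric(length(wtp_grid))
  for (i in seq_along(wtp_grid)) {
    params[[i]] <- incremental_nb_params(d, wtp_grid[i])
    unli[i] <- evpi_from_bvn(params[[i]])
    bs <- evpi_bootstrap(d, wtp_grid[i], B = B, seed = seed + i - 1)
    boot[i] <- bs$evpi
    se[i] <- bs$se
  }
  out <- data.frame(wtp = wtp_grid, evpi_unli = unli,
                    evpi_boot = boot, boot_se = se)
  attr(out, "params") <- params
  class(out) <- c("evpi_curve", "data.frame")
  out
}

#' Plot an EVPI curve
#'
#' Closed-form (solid) and bootstrap (dashed) EVPI against
#' willingness-to-pay.
#'
#' @param x An `"evpi_curve"`.
#' @param ... Further arguments passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.evpi_curve <- function(x, ...) {
  graphics::matplot(x$wtp, cbind(x$evpi_unli, x$evpi_boot),
                    type = "l", lty = c(1, 2), col = 1,
                    xlab = "Willingness-to-pay per QALY",
                    ylab = "EVPI", ...)
  graphics::legend("topleft", legend = c("closed-form UNLI", "bootstrap"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Serialize an EVPI curve to JSON
#'
#' One object per grid point with fields `wtp`, `evpi_unli`, `evpi_boot`,
#' `boot_se` and the underlying `bvn_params`.
#'
#' @param curve An `"evpi_curve"`.
#' @param path Output path; `NULL` returns the JSON string.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
write_evpi_json <- function(curve, path = NULL) {
  if (!inherits(curve, "evpi_curve"))
    fail_validation("curve must be an 'evpi_curve'")
  params <- attr(curve, "params")
  pts <- lapply(seq_len(nrow(curve)), function(i) {
    p <- params[[i]]
    list(
      wtp = curve$wtp[i],
      evpi_unli = curve$evpi_unli[i],
      evpi_boot = curve$evpi_boot[i],
      boot_se = curve$boot_se[i],
      bvn_params = list(mu1 = p$mu1, mu2 = p$mu2, sigma1 = p$sigma1,
                        sigma2 = p$sigma2, rho = p$rho)
    )
  })
  json <- jsonlite::toJSON(pts, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}
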