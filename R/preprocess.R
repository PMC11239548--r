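#' Z-score normalization of cohort records
#'
#' Standardizes the numeric features (age, ecg, bp) and encodes gender as
#' male = 1, female = 0. Standard deviations use the n denominator
#' (population convention), so the two-point feature {0, 10} maps to
#' {-1, 1}. When `stats` is supplied (a previous fit's statistics) it is
#' applied unchanged — held-out records never update it.
#'
#' @param records cohort record data.frame with imputed (complete) numeric
#'   fields.
#' @param stats optional statistics from a previous call.
#' @return list with `records` (normalized, gender numeric) and `stats`
#'   (per-feature mean/sd).
#' @export
normalize_cohort <- function(records, stats = NULL) {
  feats <- c("age", "ecg", "bp")
  for (f in feats)
    if (any(is.na(records[[f]])))
      stop_numeric("normalize_cohort: missing values in ", f,
                   " (impute first)")
  if (is.null(stats)) {
    sd_n <- function(x) sqrt(mean((x - mean(x))^2))
    stats <- lapply(records[feats], function(x)
      list(mean = mean(x), sd = sd_n(x)))
    if (any(vapply(stats, function(s) s$sd == 0, logical(1))))
      stop_numeric("normalize_cohort: zero-variance feature")
  }
  for (f in feats)
    records[[f]] <- (records[[f]] - stats[[f]]$mean) / stats[[f]]$sd
  records$gender <- ifelse(records$gender %in% c("Male", "male", 1), 1, 0)
  list(records = records, stats = stats)
}

# Fit the auxiliary regression target ~ covariates on complete cases and
# return predictions plus externally studentized residuals for the fitted
# rows. Leave-one-out (externally) studentized residuals come from
# stats::rstudent on the lm fit.
aux_regression <- function(df, target, covariates) {
  fml <- stats::as.formula(paste(target, "~", paste(covariates, collapse = "+")))
  fit <- stats::lm(fml, data = df)
  fit
}

#' Studentized-residual imputation of cohort records
#'
#' Fills missing ECG values with predictions of the auxiliary regression
#' `ecg ~ bp + age` fitted on complete cases, and symmetrically
#' `bp ~ ecg + age` for missing BP. Complete records whose externally
#' (leave-one-out) studentized residual exceeds `cutoff` in absolute value
#' are treated as non-meaningful sensor noise and their value replaced by
#' the regression prediction; flags come from the initial complete-case fit,
#' while the predictions used for filling and replacement come from a refit
#' that excludes the flagged rows, so gross outliers cannot distort their
#' own replacement. Records missing both sensors fall back to age-only
#' regressions.
#'
#' @param records cohort record data.frame (NA marks missing).
#' @param cutoff absolute studentized-residual threshold (default 2.5).
#' @return the completed records; attribute `"imputation_log"` counts
#'   filled and replaced entries per feature.
#' @export
impute_studentized <- function(records, cutoff = 2.5) {
  complete <- !is.na(records$ecg) & !is.na(records$bp)
  if (sum(complete) < 10)
    stop_numeric("impute_studentized: need at least 10 complete records")
  cc <- records[complete, ]
  fit_ecg0 <- aux_regression(cc, "ecg", c("bp", "age"))
  fit_bp0 <- aux_regression(cc, "bp", c("ecg", "age"))
  # flag non-meaningful rows first, then refit on the clean rows so the
  # predictions used for filling and replacement are not outlier-distorted
  out_e <- which(abs(stats::rstudent(fit_ecg0)) > cutoff)
  out_b <- which(abs(stats::rstudent(fit_bp0)) > cutoff)
  clean_e <- if (length(out_e) && nrow(cc) - length(out_e) >= 10)
    cc[-out_e, ] else cc
  clean_b <- if (length(out_b) && nrow(cc) - length(out_b) >= 10)
    cc[-out_b, ] else cc
  fit_ecg <- aux_regression(clean_e, "ecg", c("bp", "age"))
  fit_bp <- aux_regression(clean_b, "bp", c("ecg", "age"))
  log <- c(ecg_filled = 0L, bp_filled = 0L,
           ecg_replaced = 0L, bp_replaced = 0L)

  miss_ecg <- is.na(records$ecg) & !is.na(records$bp)
  if (any(miss_ecg)) {
    records$ecg[miss_ecg] <- stats::predict(fit_ecg, records[miss_ecg, ])
    log["ecg_filled"] <- sum(miss_ecg)
  }
  miss_bp <- is.na(records$bp) & !is.na(records$ecg)
  if (any(miss_bp)) {
    records$bp[miss_bp] <- stats::predict(fit_bp, records[miss_bp, ])
    log["bp_filled"] <- sum(miss_bp)
  }
  both <- is.na(records$ecg) & is.na(records$bp)
  if (any(both)) {
    fe <- aux_regression(clean_e, "ecg", "age")
    fb <- aux_regression(clean_b, "bp", "age")
    records$ecg[both] <- stats::predict(fe, records[both, ])
    records$bp[both] <- stats::predict(fb, records[both, ])
    log["ecg_filled"] <- log["ecg_filled"] + sum(both)
    log["bp_filled"] <- log["bp_filled"] + sum(both)
  }

  # replace the flagged values with clean-refit predictions
  if (length(out_e)) {
    rows <- which(complete)[out_e]
    records$ecg[rows] <- stats::predict(fit_ecg, records[rows, ])
    log["ecg_replaced"] <- length(out_e)
  }
  if (length(out_b)) {
    rows <- which(complete)[out_b]
    records$bp[rows] <- stats::predict(fit_bp, records[rows, ])
    log["bp_replaced"] <- length(out_b)
  }
  attr(records, "imputation_log") <- log
  attr(records, "imputation_fits") <- list(
    ecg = stats::coef(fit_ecg), bp = stats::coef(fit_bp))
  records
}

#' Expand records into fixed-length feature sequences
#'
#' Each record becomes a `window x 4` sequence of (age, gender, ecg_t, bp):
#' age, gender and bp are constant over time, while the ecg channel follows
#' the per-record sample stream when one is supplied (normalized with the
#' ecg statistics) and is otherwise the replicated ecg summary. Records and
#' streams are matched by patient id.
#'
#' @param normalized list from [normalize_cohort()].
#' @param window sequence length (must not exceed the stream length when
#'   streams are present).
#' @param streams optional matrix of raw per-record samples (rownames =
#'   patient ids).
#' @return list with `x` (an `n x window x 4` array) and `labels`
#'   (character, NA for unlabeled records).
#' @export
build_sequences <- function(normalized, window = 16L, streams = NULL) {
  if (window < 1) stop_config("window must be at least 1")
  rec <- normalized$records
  st <- normalized$stats
  n <- nrow(rec)
  x <- array(0, c(n, window, 4L))
  x[, , 1] <- rec$age
  x[, , 2] <- rec$gender
  x[, , 4] <- rec$bp
  if (is.null(streams)) {
    x[, , 3] <- rec$ecg
  } else {
    if (ncol(streams) < window)
      stop_config("window exceeds available stream samples")
    idx <- match(rec$patient_id, rownames(streams))
    if (any(is.na(idx))) stop_io("streams missing for some patient ids")
    z <- (streams[idx, seq_len(window), drop = FALSE] - st$ecg$mean) /
      st$ecg$sd
    x[, , 3] <- z
  }
  list(x = x, labels = rec$label)
}
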