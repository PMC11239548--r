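#' Specification of a synthetic BAN-IoT cardiac cohort
#'
#' Describes the class-conditional structure the generator emulates:
#' diseased subjects have elevated systolic blood pressure (mostly above
#' 130 mmHg), healthy subjects show a leptokurtic (heavy-peaked) heart-rate
#' distribution capped near 160 bpm while diseased heart rates are capped
#' near 150 bpm and shifted upward at rest, ages are uniform on 22-65, and
#' each record carries a short per-record heart-rate sample stream whose
#' noisy mean is the tabulated ECG value.
#'
#' @param n_total cohort size (default mirrors the 1,672-subject study
#'   composition).
#' @param n_healthy number of healthy records (default 887).
#' @param age_range inclusive age range in years.
#' @param healthy_bp,diseased_bp `c(mean, sd)` of systolic BP in mmHg.
#' @param diseased_bp_floor,diseased_bp_floor_prob diseased BP is drawn
#'   truncated above the floor with this probability (default > 130 with
#'   probability 0.8).
#' @param healthy_hr list `location, scale, df, cap`: scaled shifted
#'   Student-t (leptokurtic) truncated at `cap` (bpm).
#' @param diseased_hr list `location, scale, cap`: Gaussian truncated at
#'   `cap` (bpm).
#' @param hr_bp_coupling within-class coupling between blood pressure and
#'   heart rate, in bpm per BP standard score (sympathetic activation raises
#'   both; this also makes missing sensor values mutually recoverable by
#'   regression, as the preprocessing stage assumes).
#' @param ecg_noise_sd sd of the noise added to the stream mean to form the
#'   ECG column.
#' @param missing_rate fraction of ecg/bp entries marked missing by
#'   [inject_missing()] pipelines (stored for provenance; generation itself
#'   emits complete records).
#' @param stream_length samples per record stream.
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_total = 1672L, n_healthy = 887L,
                        age_range = c(22L, 65L),
                        healthy_bp = c(115, 10), diseased_bp = c(140, 12),
                        diseased_bp_floor = 130, diseased_bp_floor_prob = 0.8,
                        healthy_hr = list(location = 75, scale = 10, df = 5,
                                          cap = 160),
                        diseased_hr = list(location = 100, scale = 12,
                                           cap = 150),
                        hr_bp_coupling = 4,
                        ecg_noise_sd = 3, missing_rate = 0,
                        stream_length = 16L, seed = 1L) {
  if (n_healthy > n_total) stop_config("n_healthy cannot exceed n_total")
  if (missing_rate < 0 || missing_rate >= 1) stop_config("missing_rate in [0,1)")
  if (healthy_bp[2] <= 0 || diseased_bp[2] <= 0 || healthy_hr$scale <= 0 ||
      diseased_hr$scale <= 0 || ecg_noise_sd < 0)
    stop_config("scale parameters must be positive")
  if (stream_length < 1) stop_config("stream_length must be at least 1")
  structure(list(n_total = as.integer(n_total),
                 n_healthy = as.integer(n_healthy),
                 age_range = as.integer(age_range),
                 healthy_bp = healthy_bp, diseased_bp = diseased_bp,
                 diseased_bp_floor = diseased_bp_floor,
                 diseased_bp_floor_prob = diseased_bp_floor_prob,
                 healthy_hr = healthy_hr, diseased_hr = diseased_hr,
                 hr_bp_coupling = hr_bp_coupling,
                 ecg_noise_sd = ecg_noise_sd, missing_rate = missing_rate,
                 stream_length = as.integer(stream_length),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Rejection-truncated draws; the caps sit far in the tails for the default
# parameters so rejection is cheap.
rtrunc_above <- function(n, draw, cap) {
  x <- draw(n)
  bad <- which(x > cap)
  while (length(bad)) {
    x[bad] <- draw(length(bad))
    bad <- bad[x[bad] > cap]
  }
  x
}
rtrunc_below <- function(n, draw, floor) {
  x <- draw(n)
  bad <- which(x < floor)
  while (length(bad)) {
    x[bad] <- draw(length(bad))
    bad <- bad[x[bad] < floor]
  }
  x
}

#' Generate a synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @return list with `records` (data.frame: patient_id, age, gender, ecg,
#'   bp, label) and `streams` (`n_total x stream_length` matrix of
#'   heart-rate samples, rownames = patient ids).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_total = 20, n_healthy = 10))
#' table(cohort$records$label)
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_total
    healthy <- rep(FALSE, n)
    healthy[seq_len(spec$n_healthy)] <- TRUE
    healthy <- sample(healthy)       # interleave classes
    age <- sample(seq(spec$age_range[1], spec$age_range[2]), n, replace = TRUE)
    gender <- sample(c("Male", "Female"), n, replace = TRUE)

    bp <- numeric(n)
    nh <- sum(healthy); nd <- n - nh
    bp[healthy] <- stats::rnorm(nh, spec$healthy_bp[1], spec$healthy_bp[2])
    floored <- stats::runif(nd) < spec$diseased_bp_floor_prob
    d_bp <- numeric(nd)
    d_draw <- function(k) stats::rnorm(k, spec$diseased_bp[1], spec$diseased_bp[2])
    d_bp[floored] <- rtrunc_below(sum(floored), d_draw, spec$diseased_bp_floor)
    d_bp[!floored] <- d_draw(sum(!floored))
    bp[!healthy] <- d_bp

    Tn <- spec$stream_length
    streams <- matrix(0, n, Tn)
    hh <- spec$healthy_hr; dh <- spec$diseased_hr
    # per-subject heart-rate location: class location plus the sympathetic
    # coupling to the subject's blood-pressure standard score
    bp_z <- ifelse(healthy,
                   (bp - spec$healthy_bp[1]) / spec$healthy_bp[2],
                   (bp - spec$diseased_bp[1]) / spec$diseased_bp[2])
    for (i in seq_len(n)) {
      shift <- spec$hr_bp_coupling * bp_z[i]
      streams[i, ] <- if (healthy[i])
        rtrunc_above(Tn, function(k)
          hh$location + shift + hh$scale * stats::rt(k, df = hh$df), hh$cap)
      else
        rtrunc_above(Tn, function(k)
          stats::rnorm(k, dh$location + shift, dh$scale), dh$cap)
    }
    ecg <- rowMeans(streams) + stats::rnorm(n, 0, spec$ecg_noise_sd)

    ids <- sprintf("ID%03d", seq_len(n))
    records <- data.frame(patient_id = ids, age = age, gender = gender,
                          ecg = ecg, bp = bp,
                          label = ifelse(healthy, "normal", "disease"),
                          stringsAsFactors = FALSE)
    rownames(streams) <- ids
    list(records = records, streams = streams)
  })
}

#' Inject missingness for imputation experiments
#'
#' Marks `ecg` and `bp` missing independently with probability `rate`; the
#' original values are preserved in attribute `"shadow"` so imputation error
#' can be scored against ground truth.
#'
#' @param records cohort record data.frame.
#' @param rate per-entry missingness probability in [0, 0.5].
#' @param seed integer seed.
#' @export
inject_missing <- function(records, rate, seed = 1L) {
  if (rate < 0 || rate > 0.5) stop_config("missing rate must be in [0, 0.5]")
  shadow <- records[, c("patient_id", "ecg", "bp")]
  if (rate > 0) {
    with_seed(seed, {
      records$ecg[stats::runif(nrow(records)) < rate] <- NA_real_
      records$bp[stats::runif(nrow(records)) < rate] <- NA_real_
    })
  }
  attr(records, "shadow") <- shadow
  records
}

#' Cohort CSV input and output
#'
#' Dialect: UTF-8 comma-separated with header
#' `patient_id,age,gender,ecg,bp,label`; gender is `Male`/`Female`, label is
#' `normal`/`disease`/`disease1`/`disease2` or empty (unlabeled), missing
#' numeric values are empty fields. The round trip is lossless, including
#' missing markers.
#'
#' @param records cohort record data.frame.
#' @param path CSV file path.
#' @export
write_cohort <- function(records, path) {
  out <- records[, c("patient_id", "age", "gender", "ecg", "bp", "label")]
  out$ecg <- ifelse(is.na(out$ecg), "", format_num(out$ecg))
  out$bp <- ifelse(is.na(out$bp), "", format_num(out$bp))
  out$label[is.na(out$label)] <- ""
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop_io("cannot write cohort: ", conditionMessage(e)))
  invisible(path)
}

# Full-precision, locale-stable number formatting for the CSV round trip.
format_num <- function(x) formatC(x, digits = 17, format = "g")

#' @rdname write_cohort
#' @return `read_cohort` returns the records data.frame; malformed rows
#'   raise an error naming the offending line numbers.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_io("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("patient_id", "age", "gender", "ecg", "bp", "label")
  if (!identical(names(raw)[seq_along(need)], need))
    stop_io("cohort header must be: ", paste(need, collapse = ","))
  num_or_na <- function(s) ifelse(trimws(s) == "", NA_real_,
                                  suppressWarnings(as.numeric(s)))
  age <- suppressWarnings(as.integer(raw$age))
  ecg <- num_or_na(raw$ecg)
  bp <- num_or_na(raw$bp)
  bad <- which(is.na(age) | !raw$gender %in% c("Male", "Female") |
                 (trimws(raw$ecg) != "" & is.na(ecg)) |
                 (trimws(raw$bp) != "" & is.na(bp)))
  if (length(bad))
    stop_io("malformed cohort rows at line(s): ",
            paste(bad + 1L, collapse = ", "))   # +1 for the header line
  label <- trimws(raw$label)
  label[label == ""] <- NA_character_
  data.frame(patient_id = raw$patient_id, age = age, gender = raw$gender,
             ecg = ecg, bp = bp, label = label, stringsAsFactors = FALSE)
}

#' Stream sidecar input and output
#'
#' Long CSV with columns `patient_id,sample_index,value`, one row per
#' heart-rate sample.
#'
#' @param streams matrix with rownames = patient ids.
#' @param path CSV file path.
#' @export
write_streams <- function(streams, path) {
  long <- data.frame(patient_id = rep(rownames(streams), each = ncol(streams)),
                     sample_index = rep(seq_len(ncol(streams)),
                                        times = nrow(streams)),
                     value = format_num(as.vector(t(streams))))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_streams
#' @export
read_streams <- function(path) {
  if (!file.exists(path)) stop_io("stream file not found: ", path)
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(long$patient_id)
  T_len <- max(long$sample_index)
  m <- matrix(NA_real_, length(ids), T_len, dimnames = list(ids, NULL))
  m[cbind(match(long$patient_id, ids), long$sample_index)] <- long$value
  if (any(is.na(m))) stop_io("incomplete stream sidecar: ", path)
  m
}
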