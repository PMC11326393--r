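# RECIST 1.1 response classification, ORR with exact binomial CI, Simon
# two-stage design operating characteristics, Kaplan-Meier estimation and
# adverse-event tabulation.
#
# Scope note: RECIST is applied to the target-lesion diameter sum only (the
# trial tracked the primary renal tumor); non-target and new-lesion rules
# are out of scope. Measurements are centimetres, so RECIST's 5 mm absolute
# progression floor is encoded as 0.5 cm.

RECIST_LEVELS <- c("CR", "PR", "SD", "PD")  # best to worst

# round-half-up to `digits`, matching the printed style of trial tables
# (base round() is round-half-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Percent change of a follow-up measurement versus baseline
#'
#' @param baseline,followup Target-lesion diameter sums in cm.
#' @return Signed percent change, `100 * (followup - baseline) / baseline`.
#' @examples
#' percent_change(10, 6.5)  # -35
#' @export
percent_change <- function(baseline, followup) {
  if (any(!is.finite(baseline)) || any(baseline <= 0)) {
    stop("invalid measurement: baseline must be > 0", call. = FALSE)
  }
  100 * (followup - baseline) / baseline
}

#' Classify a lesion series under RECIST 1.1 (target lesions only)
#'
#' Per follow-up timepoint: CR when the diameter sum is 0; PR when the
#' change from baseline is <= -30%; PD when the increase from the series
#' minimum (nadir, baseline included) is >= +20% and >= 0.5 cm absolute;
#' SD otherwise. The best response is the best category achieved under the
#' ordering CR > PR > SD > PD.
#'
#' @param series A list or data.frame row set for one patient: either a
#'   named numeric vector of diameter sums in cm with names among
#'   `baseline`, `week6`, `week12` (baseline required), or a data.frame
#'   with columns `timepoint` and `sum_diameters_cm`.
#' @param patient_id Optional identifier carried into the result.
#' @return A list of class `response_record`: `patient_id`, `percent_change`
#'   (named by timepoint), `category` (named by timepoint), `best_response`.
#' @examples
#' classify_recist(c(baseline = 10, week6 = 9, week12 = 6.5))$best_response
#' @export
classify_recist <- function(series, patient_id = NA_character_) {
  if (is.data.frame(series)) {
    m <- stats::setNames(series$sum_diameters_cm, series$timepoint)
  } else {
    m <- series
  }
  if (!"baseline" %in% names(m) || is.na(m[["baseline"]])) {
    stop("incomplete series: baseline measurement missing", call. = FALSE)
  }
  baseline <- m[["baseline"]]
  if (baseline <= 0) {
    stop("invalid measurement: baseline must be > 0", call. = FALSE)
  }
  if (any(m < 0)) stop("invalid measurement: negative diameter", call. = FALSE)
  followups <- m[setdiff(names(m), "baseline")]
  # keep chronological order for nadir tracking
  tp_order <- intersect(c("week6", "week12"), names(followups))
  followups <- followups[c(tp_order, setdiff(names(followups), tp_order))]

  pct <- percent_change(baseline, followups)
  cat_out <- character(length(followups))
  nadir <- baseline
  for (i in seq_along(followups)) {
    v <- followups[[i]]
    if (v == 0) {
      cat_out[i] <- "CR"
    } else if (pct[[i]] <= -30) {
      cat_out[i] <- "PR"
    } else if (nadir > 0 && (v - nadir) / nadir >= 0.20 && v - nadir >= 0.5) {
      cat_out[i] <- "PD"
    } else {
      cat_out[i] <- "SD"
    }
    nadir <- min(nadir, v)
  }
  names(cat_out) <- names(followups)
  best <- RECIST_LEVELS[min(match(cat_out, RECIST_LEVELS))]
  structure(
    list(patient_id = patient_id, percent_change = pct, category = cat_out,
         best_response = best),
    class = "response_record"
  )
}

#' Classify every patient in a lesion table
#'
#' @param lesions Data.frame `patient_id, timepoint, sum_diameters_cm`.
#' @return Data.frame with one row per patient: `patient_id`,
#'   `best_response`, `pct_week6`, `pct_week12` (NA when absent).
#' @export
classify_cohort <- function(lesions) {
  ids <- unique(lesions$patient_id)
  rows <- lapply(ids, function(id) {
    rec <- classify_recist(lesions[lesions$patient_id == id, ], patient_id = id)
    data.frame(
      patient_id = id, best_response = rec$best_response,
      pct_week6 = if ("week6" %in% names(rec$percent_change))
        rec$percent_change[["week6"]] else NA_real_,
      pct_week12 = if ("week12" %in% names(rec$percent_change))
        rec$percent_change[["week12"]] else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Objective response rate with exact binomial confidence interval
#'
#' Responders are CR or PR. The default interval is Clopper-Pearson
#' (exact beta quantiles); Wilson is available by `method`.
#'
#' @param responses Character vector of best responses (`CR`, `PR`, `SD`,
#'   `PD`).
#' @param confidence Confidence level (default 0.95).
#' @param method `"clopper-pearson"` (default) or `"wilson"`.
#' @return List: `n`, `responders`, `rate`, `ci` (length-2), `method`.
#' @examples
#' orr_with_ci(c(rep("PR", 6), rep("SD", 11)))$rate  # 0.3529...
#' @export
orr_with_ci <- function(responses, confidence = 0.95,
                        method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  n <- length(responses)
  if (n < 1) stop("need at least one response", call. = FALSE)
  bad <- setdiff(unique(responses), RECIST_LEVELS)
  if (length(bad) > 0) {
    stop("unknown response categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  k <- sum(responses %in% c("CR", "PR"))
  a <- 1 - confidence
  ci <- if (method == "clopper-pearson") {
    c(if (k == 0) 0 else stats::qbeta(a / 2, k, n - k + 1),
      if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k))
  } else {
    z <- stats::qnorm(1 - a / 2)
    p <- k / n
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    pmax(0, pmin(1, c(ctr - hw, ctr + hw)))
  }
  list(n = n, responders = k, rate = k / n, ci = ci, method = method,
       confidence = confidence)
}

#' Clinical benefit rate (CR + PR + SD)
#'
#' The trial's "clinical benefit" convention, exposed separately from ORR.
#'
#' @inheritParams orr_with_ci
#' @return List as in [orr_with_ci()], responders counted as CR/PR/SD.
#' @export
clinical_benefit_rate <- function(responses, confidence = 0.95) {
  n <- length(responses)
  if (n < 1) stop("need at least one response", call. = FALSE)
  k <- sum(responses %in% c("CR", "PR", "SD"))
  a <- 1 - confidence
  ci <- c(if (k == 0) 0 else stats::qbeta(a / 2, k, n - k + 1),
          if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k))
  list(n = n, responders = k, rate = k / n, ci = ci)
}

#' Define a Simon two-stage design
#'
#' Defaults are the trial's minimax design: 11 patients in stage 1, stop
#' for futility at 0 responses, 17 patients total, reject the null at 3 or
#' more responses, null response rate 0.05, alternative 0.24.
#'
#' @param n1 Stage-1 sample size.
#' @param futility_stop_at Stop (accept the null) when stage-1 responses are
#'   at or below this count.
#' @param n_total Total sample size.
#' @param reject_threshold Reject the null when total responses reach this
#'   count.
#' @param p0,p1 Null and alternative response probabilities.
#' @return An object of class `two_stage_design`.
#' @export
two_stage_design <- function(n1 = 11, futility_stop_at = 0, n_total = 17,
                             reject_threshold = 3, p0 = 0.05, p1 = 0.24) {
  if (!(futility_stop_at >= 0 && futility_stop_at < reject_threshold &&
        reject_threshold <= n_total && n1 < n_total)) {
    stop("invalid design: need 0 <= stop < reject <= n_total and n1 < n_total",
         call. = FALSE)
  }
  if (!(p0 > 0 && p0 < p1 && p1 < 1)) {
    stop("invalid design: need 0 < p0 < p1 < 1", call. = FALSE)
  }
  structure(list(n1 = as.integer(n1),
                 futility_stop_at = as.integer(futility_stop_at),
                 n_total = as.integer(n_total),
                 reject_threshold = as.integer(reject_threshold),
                 p0 = p0, p1 = p1),
            class = "two_stage_design")
}

#' Operating characteristics of a Simon two-stage design
#'
#' Exact binomial computation: over stage-1 outcomes `x1`, the trial stops
#' (accepting the null) when `x1 <= futility_stop_at`; otherwise
#' `n_total - n1` further patients accrue and the null is rejected when
#' `x1 + x2 >= reject_threshold`.
#'
#' @param design A [two_stage_design()].
#' @param p True response probability in \[0, 1\].
#' @return List: `reject_prob`, `early_stop_prob`, `expected_n`.
#' @examples
#' d <- two_stage_design()
#' simon_oc(d, 0.05)$reject_prob  # ~0.049 -> type I error 0.05
#' simon_oc(d, 0.24)$reject_prob  # ~0.805 -> power 80%
#' @export
simon_oc <- function(design, p) {
  stopifnot(inherits(design, "two_stage_design"))
  if (!is.finite(p) || p < 0 || p > 1) {
    stop("p must lie in [0, 1]", call. = FALSE)
  }
  n1 <- design$n1
  n2 <- design$n_total - n1
  r1 <- design$futility_stop_at
  r <- design$reject_threshold
  x1 <- 0:n1
  p_x1 <- stats::dbinom(x1, n1, p)
  # P(reject | x1): 0 when stopped early; else P(X2 >= r - x1). pbinom with
  # a negative quantile and lower.tail = FALSE returns 1 (x1 >= r rejects
  # regardless of stage 2).
  p_rej_given <- ifelse(
    x1 <= r1, 0,
    stats::pbinom(r - x1 - 1, n2, p, lower.tail = FALSE)
  )
  pet <- stats::pbinom(r1, n1, p)
  list(
    reject_prob = sum(p_x1 * p_rej_given),
    early_stop_prob = pet,
    expected_n = n1 + (1 - pet) * n2
  )
}

#' Kaplan-Meier survival estimate at a landmark time
#'
#' Product-limit estimator with a Greenwood-variance confidence interval on
#' the log-survival scale. With no censoring before the landmark, the
#' estimate equals the empirical survivor fraction exactly.
#'
#' @param time Event/censoring times (months), `>= 0`.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param at_time Landmark time (months).
#' @param confidence Confidence level (default 0.95).
#' @return List: `survival`, `ci`, and the full step `curve` (data.frame
#'   `time, n_risk, n_event, survival, lower, upper`).
#' @examples
#' km_estimate(c(3, 6, 9, rep(25, 14)), c(1, 1, 1, rep(0, 14)), 12)$survival
#' @export
km_estimate <- function(time, event, at_time, confidence = 0.95) {
  if (length(time) < 1) stop("need at least one subject", call. = FALSE)
  if (any(time < 0)) stop("negative survival times rejected", call. = FALSE)
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)))
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  tev <- sort(unique(time[event == 1]))
  s <- 1
  cumvar <- 0  # sum d / (n (n - d)), Greenwood on log S
  curve <- data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), survival = numeric(0),
                      lower = numeric(0), upper = numeric(0))
  for (t in tev) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    if (n_risk > d) {
      cumvar <- cumvar + d / (n_risk * (n_risk - d))
    } else {
      cumvar <- Inf
    }
    se_log <- sqrt(cumvar)
    lw <- if (s > 0 && is.finite(se_log)) exp(log(s) - z * se_log) else 0
    up <- if (s > 0 && is.finite(se_log)) min(1, exp(log(s) + z * se_log)) else s
    curve <- rbind(curve, data.frame(time = t, n_risk = n_risk, n_event = d,
                                     survival = s, lower = lw, upper = up))
  }
  at <- curve[curve$time <= at_time, , drop = FALSE]
  if (nrow(at) == 0) {
    list(survival = 1, ci = c(1, 1), curve = curve)
  } else {
    last <- at[nrow(at), ]
    list(survival = last$survival, ci = c(last$lower, last$upper),
         curve = curve)
  }
}

#' Tabulate treatment-related adverse events
#'
#' Counts patients (not events) per term, any grade and grade >= 3, with
#' percentages of the treated denominator rounded half-up to one decimal
#' (the printed convention of trial AE tables).
#'
#' @param events Data.frame `patient_id, term, grade` (grade an integer
#'   1-5).
#' @param n_treated Number of treated patients (the percent denominator).
#' @return Data.frame `term, n_any, pct_any, n_grade3plus, pct_grade3plus`,
#'   ordered by decreasing any-grade count.
#' @examples
#' ae <- data.frame(patient_id = sprintf("P%02d", 1:4),
#'                  term = "Hypertension", grade = c(3, 3, 3, 3))
#' tabulate_adverse_events(ae, n_treated = 17)
#' @export
tabulate_adverse_events <- function(events, n_treated) {
  stopifnot(n_treated >= 1)
  if (nrow(events) == 0) {
    return(data.frame(term = character(0), n_any = integer(0),
                      pct_any = numeric(0), n_grade3plus = integer(0),
                      pct_grade3plus = numeric(0)))
  }
  if (any(is.na(events$grade)) || !all(events$grade %in% 1:5)) {
    stop("data error: adverse-event grades must be integers 1-5",
         call. = FALSE)
  }
  terms <- unique(events$term)
  rows <- lapply(terms, function(tm) {
    e <- events[events$term == tm, ]
    n_any <- length(unique(e$patient_id))
    n_g3 <- length(unique(e$patient_id[e$grade >= 3]))
    data.frame(term = tm, n_any = n_any,
               pct_any = round_half_up(100 * n_any / n_treated, 1),
               n_grade3plus = n_g3,
               pct_grade3plus = round_half_up(100 * n_g3 / n_treated, 1))
  })
  out <- do.call(rbind, rows)
  out[order(-out$n_any, out$term), , drop = FALSE]
}
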