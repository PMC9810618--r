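#' Classify pathological response from residual viable tumor
#'
#' Converts the pathologist-scored percentage of residual viable tumor cells
#' into the standard nested response categories and the Becker tumor
#' regression grade (TRG):
#'
#' * CPR (complete pathological response): no viable tumor cells (0%).
#' * MPR (major pathological response): no more than 10% viable tumor.
#' * PPR+ : no more than 30% viable tumor.
#' * PPR (partial pathological response): no more than 50% viable tumor.
#'
#' All thresholds are inclusive ("no more than"), so the categories nest:
#' CPR implies MPR implies PPR+ implies PPR.
#'
#' @param viable_pct numeric vector of residual viable tumor percentages in
#'   \[0, 100\].
#' @param patient optional character vector of patient identifiers.
#' @return a `response_call` data frame with one row per patient and columns
#'   `patient`, `viable_pct`, `regression_pct` (= 100 - viable_pct),
#'   `is_cpr`, `is_mpr`, `is_ppr_plus`, `is_ppr`, and `trg`.
#' @examples
#' classify_response(c(0, 10, 25, 60))
#' @seealso [becker_trg()], [response_rate_table()]
#' @export
classify_response <- function(viable_pct, patient = NULL) {
  check_number(viable_pct, "viable_pct", 0, 100)
  if (is.null(patient)) {
    patient <- sprintf("P%02d", seq_along(viable_pct))
  }
  if (length(patient) != length(viable_pct)) {
    stopf("`patient` and `viable_pct` lengths differ")
  }
  out <- data.frame(
    patient = as.character(patient),
    viable_pct = as.numeric(viable_pct),
    regression_pct = 100 - as.numeric(viable_pct),
    is_cpr = viable_pct == 0,
    is_mpr = viable_pct <= 10,
    is_ppr_plus = viable_pct <= 30,
    is_ppr = viable_pct <= 50,
    trg = becker_trg(viable_pct),
    stringsAsFactors = FALSE
  )
  class(out) <- c("response_call", "data.frame")
  out
}

#' Becker tumor regression grade
#'
#' Assigns the four-level Becker TRG from percent residual viable tumor:
#' TRG1a (no residual tumor), TRG1b (under 10%), TRG2 (10% to under 50%),
#' TRG3 (50% or more). Note the asymmetry with [classify_response()]: a
#' tumor with exactly 10% viable cells is MPR ("no more than 10%") but TRG2
#' (TRG1b is strictly "<10%").
#'
#' @param viable_pct numeric vector in \[0, 100\].
#' @return factor with levels `TRG1a`, `TRG1b`, `TRG2`, `TRG3`.
#' @examples
#' becker_trg(c(0, 5, 10, 49, 50))
#' @export
becker_trg <- function(viable_pct) {
  check_number(viable_pct, "viable_pct", 0, 100)
  grade <- ifelse(viable_pct == 0, "TRG1a",
           ifelse(viable_pct < 10, "TRG1b",
           ifelse(viable_pct < 50, "TRG2", "TRG3")))
  factor(grade, levels = c("TRG1a", "TRG1b", "TRG2", "TRG3"))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The exact interval from beta quantiles: the lower bound is the
#' `alpha/2` quantile of Beta(k, n - k + 1) (0 when k = 0) and the upper
#' bound the `1 - alpha/2` quantile of Beta(k + 1, n - k) (1 when k = n).
#' Bounds are returned as percentages.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (>= 1).
#' @param conf confidence level in (0, 1); default 0.95.
#' @return named numeric vector `c(lower, upper)` in percent.
#' @examples
#' clopper_pearson_ci(3, 19)   # 3.4 to 39.6 percent
#' @export
clopper_pearson_ci <- function(k, n, conf = 0.95) {
  check_number(k, "k", 0, len = 1)
  check_number(n, "n", 1, len = 1)
  check_number(conf, "conf", len = 1)
  if (k > n) stopf("`k` (%d) exceeds `n` (%d)", k, n)
  if (conf <= 0 || conf >= 1) stopf("`conf` must be in (0, 1)")
  alpha <- 1 - conf
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = 100 * lower, upper = 100 * upper)
}

#' Cohort response-rate table with exact confidence intervals
#'
#' Tabulates each pathological endpoint (CPR, MPR, PPR+, the individual
#' Becker grades, and the combined TRG1a/b) over a cohort of response calls,
#' with the exact binomial confidence interval for each rate. Only patients
#' present in `calls` enter the denominator, so restricting the calls to the
#' evaluable (resected) cohort is the caller's denominator policy.
#'
#' @param calls a `response_call` data frame from [classify_response()].
#' @param conf confidence level; default 0.95.
#' @return a `rate_table` data frame with columns `endpoint`, `k`, `n`,
#'   `rate`, `ci_low`, `ci_high` (all rates in percent, full precision) and
#'   `conf`.
#' @examples
#' calls <- classify_response(c(0, 0, 0, 5, 8, 15, 20, 25, 40, rep(60, 10)))
#' response_rate_table(calls)
#' @export
response_rate_table <- function(calls, conf = 0.95) {
  if (!inherits(calls, "response_call")) {
    stopf("`calls` must be a response_call data frame from classify_response()")
  }
  n <- nrow(calls)
  if (n == 0) stopf("`calls` is empty")
  counts <- c(
    "CPR"     = sum(calls$is_cpr),
    "MPR"     = sum(calls$is_mpr),
    "PPR+"    = sum(calls$is_ppr_plus),
    "TRG1a"   = sum(calls$trg == "TRG1a"),
    "TRG1b"   = sum(calls$trg == "TRG1b"),
    "TRG1a/b" = sum(calls$trg %in% c("TRG1a", "TRG1b")),
    "TRG2"    = sum(calls$trg == "TRG2"),
    "TRG3"    = sum(calls$trg == "TRG3")
  )
  ci <- t(vapply(counts, clopper_pearson_ci, numeric(2), n = n, conf = conf))
  out <- data.frame(
    endpoint = names(counts),
    k = as.integer(counts),
    n = n,
    rate = 100 * counts / n,
    ci_low = ci[, "lower"],
    ci_high = ci[, "upper"],
    conf = conf,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  class(out) <- c("rate_table", "data.frame")
  out
}

#' @export
print.rate_table <- function(x, digits = 1, ...) {
  cat(sprintf("Pathological response rates (n = %d, %.0f%% CI, Clopper-Pearson)\n",
              x$n[1], 100 * x$conf[1]))
  shown <- data.frame(
    endpoint = x$endpoint,
    events = sprintf("%d/%d", x$k, x$n),
    rate = sprintf(paste0("%.", digits, "f%%"), x$rate),
    ci = sprintf(paste0("%.", digits, "f-%.", digits, "f%%"), x$ci_low, x$ci_high),
    stringsAsFactors = FALSE
  )
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}

#' @export
print.response_call <- function(x, ...) {
  cat(sprintf("Pathological response calls for %d patient(s)\n", nrow(x)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
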