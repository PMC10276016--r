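#' Compute normative control limits (mean +/- 2 SD)
#'
#' For each parameter, the limit is the control sample mean plus twice the
#' sample standard deviation (n - 1 denominator) for `"upper"` directions,
#' or minus twice the SD for `"lower"`. Thickness parameters use upper
#' limits (abnormally thick is the pathology); foveal depth uses a lower
#' limit (abnormally shallow). Limits are stored at full precision;
#' one-decimal values are a display convention.
#'
#' @param control_metrics Data frame of control eyes with the parameter
#'   columns.
#' @param params Parameter columns to use.
#' @param directions Named character vector over `params`, `"upper"` or
#'   `"lower"`; defaults to lower for `FD`, upper otherwise.
#' @return Data frame of class `normative_limits`: `parameter`,
#'   `control_mean`, `control_sd`, `direction`, `limit`, `n_controls`.
#' @export
#' @examples
#' ctrl <- sample_cohort_metrics(cohort_spec("control", n_eyes = 50, seed = 7))
#' compute_limits(ctrl)
compute_limits <- function(control_metrics, params = foveal_parameters(),
                           directions = NULL) {
  missing <- setdiff(params, names(control_metrics))
  if (length(missing))
    stop("control metrics missing parameter column(s): ",
         paste(missing, collapse = ", "))
  if (is.null(directions)) {
    directions <- stats::setNames(
      ifelse(params == "FD", "lower", "upper"), params)
  }
  stopifnot(all(params %in% names(directions)),
            all(directions %in% c("upper", "lower")))
  n <- nrow(control_metrics)
  if (n < 2L) stop("need at least 2 control eyes (got ", n, ")")
  rows <- lapply(params, function(p) {
    v <- control_metrics[[p]]
    if (anyNA(v)) stop("missing values in control column ", p)
    m <- mean(v)
    s <- stats::sd(v)
    if (s == 0) warning("zero variance in control column ", p,
                        "; limit equals the mean")
    data.frame(parameter = p, control_mean = m, control_sd = s,
               direction = directions[[p]],
               limit = if (directions[[p]] == "upper") m + 2 * s else m - 2 * s,
               n_controls = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("normative_limits", class(out))
  out
}

#' Build a limits table directly from summary statistics
#'
#' Used when only published control means and SDs are available rather
#' than per-eye data (e.g. to check printed limits).
#'
#' @param means,sds Named numeric vectors over the parameters.
#' @param directions As in [compute_limits()].
#' @param n_controls Control sample size, if known.
#' @return A `normative_limits` data frame.
#' @export
limits_from_summary <- function(means, sds, directions = NULL,
                                n_controls = NA_integer_) {
  params <- names(means)
  stopifnot(!is.null(params), identical(sort(params), sort(names(sds))))
  if (is.null(directions))
    directions <- stats::setNames(
      ifelse(params == "FD", "lower", "upper"), params)
  out <- data.frame(
    parameter = params,
    control_mean = as.numeric(means[params]),
    control_sd = as.numeric(sds[params]),
    direction = as.character(directions[params]),
    limit = ifelse(directions[params] == "upper",
                   means[params] + 2 * sds[params],
                   means[params] - 2 * sds[params]),
    n_controls = n_controls, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("normative_limits", class(out))
  out
}

#' Check recomputed limits against reference (printed) limits
#'
#' Flags parameters whose mean +/- 2 SD limit disagrees with the supplied
#' reference value by more than display rounding (`tol`, default 0.05 um,
#' i.e. one-decimal precision). A flagged parameter means the reference
#' table is internally inconsistent for that row and the recomputed value
#' should be preferred.
#'
#' @param limits A `normative_limits` data frame.
#' @param reference Named numeric vector of reference limit values (um).
#' @param tol Agreement tolerance (um).
#' @return Data frame with `parameter`, `computed`, `reference`,
#'   `difference`, `consistent`.
#' @export
#' @examples
#' def <- cohort_defaults("control")
#' lim <- limits_from_summary(def$means, def$sds)
#' verify_limit_consistency(lim, def$reference_limits)
verify_limit_consistency <- function(limits, reference, tol = 0.05) {
  common <- intersect(limits$parameter, names(reference))
  comp <- stats::setNames(limits$limit, limits$parameter)[common]
  diff <- comp - reference[common]
  out <- data.frame(parameter = common, computed = as.numeric(comp),
                    reference = as.numeric(reference[common]),
                    difference = as.numeric(diff),
                    consistent = abs(diff) <= tol + 1e-9,
                    stringsAsFactors = FALSE)
  if (any(!out$consistent))
    warning("reference limit inconsistent with mean +/- 2 SD for: ",
            paste(out$parameter[!out$consistent], collapse = ", "),
            " (computed ",
            paste(round(out$computed[!out$consistent], 2), collapse = ", "),
            " vs reference ",
            paste(out$reference[!out$consistent], collapse = ", "), ")")
  out
}

#' Classify eyes against normative limits
#'
#' An eye is `outside` for a parameter when its value strictly exceeds an
#' upper limit or falls strictly below a lower limit; exact equality with
#' the limit counts as `within`. Per-parameter outside proportions carry
#' exact (Clopper-Pearson) binomial 95% confidence intervals.
#'
#' @param metrics Data frame of eyes with the parameter columns.
#' @param limits A `normative_limits` data frame.
#' @return List of class `classification_result` with `calls` (data frame
#'   `eye_id` x parameter, `"within"`/`"outside"`) and `summary` (per
#'   parameter: `n_eyes`, `n_outside`, `proportion_outside`, `ci_lower`,
#'   `ci_upper`).
#' @export
classify_eyes <- function(metrics, limits) {
  missing <- setdiff(limits$parameter, names(metrics))
  if (length(missing))
    stop("metrics missing parameter column(s): ",
         paste(missing, collapse = ", "))
  ids <- if ("eye_id" %in% names(metrics)) metrics$eye_id
         else sprintf("eye_%04d", seq_len(nrow(metrics)))
  calls <- data.frame(eye_id = ids, stringsAsFactors = FALSE)
  summ <- lapply(seq_len(nrow(limits)), function(k) {
    p <- limits$parameter[k]
    v <- metrics[[p]]
    outside <- if (limits$direction[k] == "upper") v > limits$limit[k]
               else v < limits$limit[k]
    calls[[p]] <<- ifelse(outside, "outside", "within")
    n <- length(outside)
    x <- sum(outside)
    ci <- stats::binom.test(x, n)$conf.int
    data.frame(parameter = p, direction = limits$direction[k],
               limit = limits$limit[k], n_eyes = n, n_outside = x,
               proportion_outside = x / n,
               ci_lower = ci[1], ci_upper = ci[2],
               stringsAsFactors = FALSE)
  })
  structure(list(calls = calls, summary = do.call(rbind, summ)),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("<classification_result>", nrow(x$calls), "eyes\n")
  s <- x$summary
  s$proportion_outside <- round(s$proportion_outside, 3)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Cohort summary table in the normative-report layout
#'
#' One row per parameter with the range and mean +/- SD of each group,
#' the control limit and the percentage of test-group eyes outside it.
#'
#' @param control_metrics,test_metrics Data frames with parameter columns.
#' @param limits Optional precomputed `normative_limits` (defaults to
#'   limits from `control_metrics`).
#' @param params Parameters to summarize.
#' @return Data frame, one row per parameter.
#' @export
summary_table <- function(control_metrics, test_metrics, limits = NULL,
                          params = foveal_parameters()) {
  if (is.null(limits)) limits <- compute_limits(control_metrics, params)
  cls <- classify_eyes(test_metrics, limits)
  rows <- lapply(params, function(p) {
    cv <- control_metrics[[p]]
    tv <- test_metrics[[p]]
    k <- which(cls$summary$parameter == p)
    data.frame(
      parameter = p,
      control_range = sprintf("%.2f-%.2f", min(cv), max(cv)),
      test_range = sprintf("%.2f-%.2f", min(tv), max(tv)),
      control_mean = mean(cv), control_sd = stats::sd(cv),
      test_mean = mean(tv), test_sd = stats::sd(tv),
      direction = cls$summary$direction[k],
      limit = cls$summary$limit[k],
      pct_outside = 100 * cls$summary$proportion_outside[k],
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
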