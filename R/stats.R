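#' Shapiro-Wilk normality test with input validation
#'
#' Thin wrapper around the standard Shapiro-Wilk implementation with the
#' sample-size and degeneracy preconditions made explicit (3 <= n <= 5000,
#' non-constant input).
#'
#' @param x Numeric vector.
#' @return An object of class `htest` with statistic `W` and `p.value`.
#' @export
normality_test <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L || n > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got ", n, ")")
  if (diff(range(x)) == 0) stop("constant input: normality is undefined")
  stats::shapiro.test(x)
}

#' Pairwise Pearson correlation matrix with significance flags
#'
#' Pearson r and two-sided p-value for every parameter pair, using
#' pairwise-complete observations. Pairs involving a zero-variance column
#' are reported as `NA` with a warning. The significance flag is set when
#' p < `alpha` (default 0.001).
#'
#' @param metrics Data frame.
#' @param params Columns to correlate (>= 2).
#' @param alpha Significance level for the flag.
#' @return List of class `correlation_matrix` with matrices `r`, `p`,
#'   `n` (pairwise complete counts), logical `significant`, and `alpha`.
#' @export
correlation_matrix <- function(metrics, params = foveal_parameters(),
                               alpha = 0.001) {
  stopifnot(length(params) >= 2L)
  missing <- setdiff(params, names(metrics))
  if (length(missing))
    stop("metrics missing column(s): ", paste(missing, collapse = ", "))
  k <- length(params)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(params, params))
  n <- matrix(0L, k, k, dimnames = list(params, params))
  diag(r) <- 1
  diag(p) <- 0
  for (i in seq_len(k)) {
    n[i, i] <- sum(!is.na(metrics[[params[i]]]))
    for (j in seq_len(k)) {
      if (j <= i) next
      ok <- stats::complete.cases(metrics[[params[i]]],
                                  metrics[[params[j]]])
      x <- metrics[[params[i]]][ok]
      y <- metrics[[params[j]]][ok]
      n[i, j] <- n[j, i] <- length(x)
      if (length(x) < 3L) {
        warning("fewer than 3 complete pairs for ", params[i], " vs ",
                params[j])
        next
      }
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warning("zero variance: correlation undefined for ", params[i],
                " vs ", params[j])
        next
      }
      ct <- stats::cor.test(x, y, method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, n = n, significant = !is.na(p) & p < alpha,
                 alpha = alpha),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat("<correlation_matrix> alpha =", x$alpha,
      "(* = significant)\n")
  disp <- matrix(sprintf(paste0("%.", digits, "f%s"), x$r,
                         ifelse(x$significant, "*", " ")),
                 nrow = nrow(x$r), dimnames = dimnames(x$r))
  diag(disp) <- "1"
  print(disp, quote = FALSE)
  invisible(x)
}

#' Long-format view of a correlation matrix
#'
#' @param cm A [correlation_matrix()] result.
#' @return Data frame with one row per unordered pair: `param1`, `param2`,
#'   `r`, `p`, `n`, `significant`.
#' @export
correlation_long <- function(cm) {
  params <- rownames(cm$r)
  out <- NULL
  for (i in seq_along(params)) for (j in seq_along(params)) {
    if (j <= i) next
    out <- rbind(out, data.frame(
      param1 = params[i], param2 = params[j],
      r = cm$r[i, j], p = cm$p[i, j], n = cm$n[i, j],
      significant = cm$significant[i, j], stringsAsFactors = FALSE))
  }
  out
}

#' Central layer proportions per eye and per group
#'
#' Per-eye ratios of central layer thickness to central retinal thickness:
#' `(GCLp_FC + ONL_FC)/RT_FC`, `ONL_FC/RT_FC` and `GCLp_FC/RT_FC`, then
#' their mean and SD per group. The combined ratio equals the sum of the
#' two individual ratios for every eye by construction.
#'
#' @param metrics Data frame with `GCLp_FC`, `ONL_FC`, `RT_FC` and
#'   optionally `group_label`.
#' @return List of class `proportion_summary` with `per_eye` (data frame
#'   of ratios) and `summary` (per group mean and SD of each ratio).
#' @export
layer_proportions <- function(metrics) {
  need <- c("GCLp_FC", "ONL_FC", "RT_FC")
  missing <- setdiff(need, names(metrics))
  if (length(missing))
    stop("metrics missing column(s): ", paste(missing, collapse = ", "))
  bad <- which(metrics$RT_FC <= 0)
  if (length(bad)) {
    warning("dropping ", length(bad), " row(s) with non-positive RT_FC")
    metrics <- metrics[-bad, ]
  }
  grp <- if ("group_label" %in% names(metrics)) metrics$group_label
         else rep("all", nrow(metrics))
  per_eye <- data.frame(
    eye_id = if ("eye_id" %in% names(metrics)) metrics$eye_id
             else seq_len(nrow(metrics)),
    group_label = grp,
    ratio_combined = (metrics$GCLp_FC + metrics$ONL_FC) / metrics$RT_FC,
    ratio_onl = metrics$ONL_FC / metrics$RT_FC,
    ratio_gclp = metrics$GCLp_FC / metrics$RT_FC,
    stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(per_eye, per_eye$group_label),
    function(d) data.frame(
      group_label = d$group_label[1], n_eyes = nrow(d),
      combined_mean = mean(d$ratio_combined),
      combined_sd = stats::sd(d$ratio_combined),
      onl_mean = mean(d$ratio_onl), onl_sd = stats::sd(d$ratio_onl),
      gclp_mean = mean(d$ratio_gclp), gclp_sd = stats::sd(d$ratio_gclp),
      stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  structure(list(per_eye = per_eye, summary = summ),
            class = "proportion_summary")
}

#' @export
print.proportion_summary <- function(x, ...) {
  s <- x$summary
  for (col in setdiff(names(s), c("group_label", "n_eyes")))
    s[[col]] <- round(s[[col]], 2)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Two-group comparison from raw values
#'
#' Independent two-sample t-test, by default with Welch's correction
#' (unequal variances); two-sided. Rows with missing values are dropped
#' listwise per variable.
#'
#' @param data Data frame.
#' @param value_cols Numeric columns to compare.
#' @param group_col Column with exactly two groups, each n >= 2.
#' @param welch Use the Welch-Satterthwaite correction (default) or the
#'   pooled-variance Student test.
#' @return Data frame: one row per variable with group means/SDs/ns, `t`,
#'   `df`, `p`.
#' @export
group_compare <- function(data, value_cols, group_col = "group_label",
                          welch = TRUE) {
  g <- factor(data[[group_col]])
  if (nlevels(g) != 2L)
    stop("group column must have exactly two levels (got ",
         nlevels(g), ")")
  rows <- lapply(value_cols, function(vc) {
    v <- data[[vc]]
    ok <- !is.na(v) & !is.na(g)
    v <- v[ok]; gg <- droplevels(g[ok])
    n <- table(gg)
    if (any(n < 2L)) stop("each group needs n >= 2 for ", vc)
    tt <- stats::t.test(v ~ gg, var.equal = !welch)
    data.frame(variable = vc,
               group1 = levels(gg)[1], mean1 = mean(v[gg == levels(gg)[1]]),
               sd1 = stats::sd(v[gg == levels(gg)[1]]), n1 = as.integer(n[1]),
               group2 = levels(gg)[2], mean2 = mean(v[gg == levels(gg)[2]]),
               sd2 = stats::sd(v[gg == levels(gg)[2]]), n2 = as.integer(n[2]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, welch = welch, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-group comparison from summary statistics
#'
#' Reconstructs the independent t-test from per-group mean, SD and n -
#' the form needed when only tabulated summaries are available. With
#' `welch = TRUE` the standard error is `sqrt(s1^2/n1 + s2^2/n2)` and the
#' degrees of freedom follow Welch-Satterthwaite; otherwise the pooled
#' variance and `n1 + n2 - 2` are used. Two-sided p-value.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @param welch Welch correction (default `TRUE`).
#' @return List with `t`, `df`, `p`, `estimate` (mean difference), `se`.
#' @export
#' @examples
#' # gestational age (weeks) of preterm subgroups outside vs within the
#' # central retinal thickness limit
#' group_compare_summary(25.83, 0.39, 12, 25.71, 0.49, 7)
group_compare_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                  welch = TRUE) {
  stopifnot(n1 >= 2L, n2 >= 2L, sd1 >= 0, sd2 >= 0)
  est <- mean1 - mean2
  if (welch) {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  if (se == 0) {
    t <- if (est == 0) 0 else sign(est) * Inf
  } else t <- est / se
  p <- if (est == 0) 1 else 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, estimate = est, se = se, welch = welch)
}
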