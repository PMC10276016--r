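#' Construct a cohort specification for synthetic metric sampling
#'
#' A `cohort_spec` bundles the distributional recipe for one simulated
#' cohort of eyes: marginal means and SDs of the foveal parameters, the
#' correlation structure of the latent sampling variables, the residual
#' retinal-thickness component, a sample size, a seed and a laterality
#' policy. Defaults come from [cohort_defaults()] for the requested group.
#'
#' @param group `"control"` or `"ept_norop"`.
#' @param n_eyes Number of eyes to simulate (>= 1).
#' @param seed Integer seed; identical specs yield identical samples.
#' @param means,sds Optional named numeric vectors over
#'   [foveal_parameters()] overriding the group defaults (micrometres).
#' @param correlation Optional 5x5 correlation matrix over `GCLp_FC`,
#'   `GCLp_Q2Q`, `ONL_FC`, `FD`, `RESID`; must be symmetric with unit
#'   diagonal and positive semi-definite.
#' @param residual_sd SD of the residual retinal-thickness component
#'   (micrometres). Its mean is implied: `RT_FC - GCLp_FC - ONL_FC` means.
#' @param fwm_asym_sd SD of the nasal minus temporal rim retinal-thickness
#'   difference (micrometres).
#' @param laterality_policy `"all-left"`, `"all-right"` or `"mixed"`.
#' @return Object of class `cohort_spec`.
#' @seealso [sample_cohort_metrics()]
#' @export
#' @examples
#' spec <- cohort_spec("control", n_eyes = 10, seed = 1)
#' sample_cohort_metrics(spec)
cohort_spec <- function(group = c("control", "ept_norop"),
                        n_eyes = 100L,
                        seed = 1L,
                        means = NULL,
                        sds = NULL,
                        correlation = NULL,
                        residual_sd = NULL,
                        fwm_asym_sd = NULL,
                        laterality_policy = c("all-left", "all-right", "mixed")) {
  group <- match.arg(group)
  laterality_policy <- match.arg(laterality_policy)
  def <- cohort_defaults(group)
  p <- foveal_parameters()

  fill <- function(x, d, what) {
    if (is.null(x)) return(d)
    if (is.null(names(x)) && length(x) == length(d)) names(x) <- names(d)
    missing <- setdiff(names(d), names(x))
    if (length(missing)) x[missing] <- d[missing]
    x[names(d)]
  }
  means <- fill(means, def$means)
  sds <- fill(sds, def$sds)
  correlation <- if (is.null(correlation)) def$correlation else correlation
  residual_sd <- if (is.null(residual_sd)) def$residual_sd else residual_sd
  fwm_asym_sd <- if (is.null(fwm_asym_sd)) def$fwm_asym_sd else fwm_asym_sd

  spec <- structure(
    list(group_label = group, n_eyes = as.integer(n_eyes),
         seed = as.integer(seed), param_means = means, param_sds = sds,
         correlation = correlation, residual_sd = residual_sd,
         fwm_asym_sd = fwm_asym_sd, laterality_policy = laterality_policy),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' Checks the `cohort_spec` invariants: positive sample size, non-negative
#' SDs, a symmetric positive semi-definite correlation matrix with unit
#' diagonal, and a feasible structural decomposition of retinal thickness
#' (mean `RT_FC` must be at least mean `GCLp_FC + ONL_FC`).
#'
#' @param spec A `cohort_spec`.
#' @return The spec, invisibly; stops with a diagnostic otherwise.
#' @export
validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  p <- foveal_parameters()
  if (spec$n_eyes < 1L) stop("n_eyes must be >= 1")
  if (anyNA(spec$param_means[p]) || anyNA(spec$param_sds[p]))
    stop("means and sds must be provided for all of: ",
         paste(p, collapse = ", "))
  if (any(spec$param_sds < 0)) stop("parameter SDs must be >= 0")
  if (spec$residual_sd < 0 || spec$fwm_asym_sd < 0)
    stop("residual_sd and fwm_asym_sd must be >= 0")
  cm <- spec$correlation
  latent <- c("GCLp_FC", "GCLp_Q2Q", "ONL_FC", "FD", "RESID")
  if (!is.matrix(cm) || !identical(dim(cm), c(5L, 5L)))
    stop("correlation must be a 5x5 matrix over ",
         paste(latent, collapse = ", "))
  if (is.null(dimnames(cm))) dimnames(cm) <- list(latent, latent)
  if (!isTRUE(all.equal(cm, t(cm), tolerance = 1e-10)))
    stop("correlation matrix is not symmetric")
  if (any(abs(diag(cm) - 1) > 1e-10))
    stop("correlation matrix must have unit diagonal")
  ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("correlation matrix is not positive semi-definite ",
         "(smallest eigenvalue ", format(min(ev), digits = 4), ")")
  resid_mean <- spec$param_means[["RT_FC"]] -
    spec$param_means[["GCLp_FC"]] - spec$param_means[["ONL_FC"]]
  if (resid_mean < 0)
    stop("infeasible means: RT_FC mean (", spec$param_means[["RT_FC"]],
         ") is smaller than GCLp_FC + ONL_FC means (",
         spec$param_means[["GCLp_FC"]] + spec$param_means[["ONL_FC"]], ")")
  invisible(spec)
}

#' Sample per-eye target foveal metrics for a synthetic cohort
#'
#' Draws `n_eyes` rows from the multivariate normal implied by the spec's
#' means, SDs and correlation matrix over the latent variables `GCLp_FC`,
#' `GCLp_Q2Q`, `ONL_FC`, `FD` and `RESID` (residual retinal-thickness
#' component). Rows with any negative thickness or non-positive foveal
#' depth are rejected and redrawn, i.e. the thickness marginals are
#' normals truncated at zero. Central retinal thickness is the structural
#' sum `RT_FC = GCLp_FC + ONL_FC + RESID`; mean rim thickness follows from
#' the foveal-depth identity `RT_FWM_mean = RT_FC + FD` and is split into
#' nasal and temporal values by a zero-mean normal asymmetry.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with one row per eye: `eye_id`, `group_label`,
#'   `laterality`, `GCLp_FC`, `GCLp_Q2Q`, `ONL_FC`, `RT_FC`,
#'   `RT_FWM_nasal`, `RT_FWM_temporal`, `RT_FWM_mean`, `FD` (micrometres).
#' @export
sample_cohort_metrics <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_eyes
  mu <- c(spec$param_means[["GCLp_FC"]], spec$param_means[["GCLp_Q2Q"]],
          spec$param_means[["ONL_FC"]], spec$param_means[["FD"]],
          spec$param_means[["RT_FC"]] - spec$param_means[["GCLp_FC"]] -
            spec$param_means[["ONL_FC"]])
  sd <- c(spec$param_sds[["GCLp_FC"]], spec$param_sds[["GCLp_Q2Q"]],
          spec$param_sds[["ONL_FC"]], spec$param_sds[["FD"]],
          spec$residual_sd)
  latent <- c("GCLp_FC", "GCLp_Q2Q", "ONL_FC", "FD", "RESID")
  cm <- spec$correlation[latent, latent]
  Sigma <- diag(sd) %*% cm %*% diag(sd)

  set.seed(spec$seed)
  draw <- function(k) {
    x <- MASS::mvrnorm(k, mu = mu, Sigma = Sigma, tol = 1e-6)
    if (k == 1L) x <- matrix(x, nrow = 1)
    colnames(x) <- latent
    x
  }
  x <- draw(n)
  # truncation at zero by resampling whole eyes (FD must stay positive for
  # the pit geometry to exist)
  bad <- which(x[, 1] < 0 | x[, 2] < 0 | x[, 3] < 0 | x[, 5] < 0 |
                 x[, 4] <= 0)
  guard <- 0L
  while (length(bad) > 0L) {
    guard <- guard + 1L
    if (guard > 1000L) stop("truncation resampling did not converge; ",
                            "check means/SDs for feasibility")
    repl <- draw(length(bad))
    x[bad, ] <- repl
    bad <- bad[repl[, 1] < 0 | repl[, 2] < 0 | repl[, 3] < 0 |
                 repl[, 5] < 0 | repl[, 4] <= 0]
  }

  asym <- stats::rnorm(n, 0, spec$fwm_asym_sd)
  rt_fc <- x[, "GCLp_FC"] + x[, "ONL_FC"] + x[, "RESID"]
  rt_fwm_mean <- rt_fc + x[, "FD"]
  lat <- switch(spec$laterality_policy,
                "all-left" = rep("OS", n),
                "all-right" = rep("OD", n),
                "mixed" = sample(c("OD", "OS"), n, replace = TRUE))
  data.frame(
    eye_id = sprintf("%s_%04d", spec$group_label, seq_len(n)),
    group_label = spec$group_label,
    laterality = lat,
    GCLp_FC = x[, "GCLp_FC"],
    GCLp_Q2Q = x[, "GCLp_Q2Q"],
    ONL_FC = x[, "ONL_FC"],
    RT_FC = rt_fc,
    RT_FWM_nasal = rt_fwm_mean + asym / 2,
    RT_FWM_temporal = rt_fwm_mean - asym / 2,
    RT_FWM_mean = rt_fwm_mean,
    FD = x[, "FD"],
    stringsAsFactors = FALSE
  )
}
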