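#' Parameter names used throughout the package
#'
#' The six foveal parameters, in micrometres unless noted: `GCLp_FC`
#' (ganglion cell + inner plexiform layer thickness at the foveal centre),
#' `GCLp_Q2Q` (mean GCL+ thickness at the nasal and temporal quarter points
#' between centre and rim), `ONL_FC` (outer nuclear layer thickness at the
#' centre), `RT_FC` (retinal thickness at the centre), `FD` (foveal depth =
#' mean rim retinal thickness minus `RT_FC`) and `RT_FWM` (retinal thickness
#' at the foveal wall maximum, i.e. the rim).
#'
#' @return Character vector of the five scalar normative parameters.
#' @export
foveal_parameters <- function() {
  c("GCLp_FC", "GCLp_Q2Q", "ONL_FC", "RT_FC", "FD")
}

# canonical anterior-to-posterior boundary order
.boundary_names <- c("ILM", "GCLp_inner", "GCLp_outer",
                     "ONL_inner", "ONL_outer", "ISOS", "RPE_posterior")

#' Built-in cohort calibration defaults
#'
#' Normative calibration targets for the two study groups the synthetic
#' cohort generator emulates: full-term control eyes and eyes of children
#' born extremely preterm (before 27 gestational weeks) without retinopathy
#' of prematurity ("EPT-NoROP"), both imaged at 6.5 years of age. Means and
#' standard deviations are in micrometres. The control entry also carries
#' the reference normative limits (control mean +/- 2 SD as published with
#' the normative dataset, one-decimal display precision) and the reported
#' percentage of EPT-NoROP eyes falling outside each limit, so that
#' recomputed limits can be checked against them (see
#' [verify_limit_consistency()]).
#'
#' Retinal thickness at the centre is modelled structurally as
#' `RT_FC = GCLp_FC + ONL_FC + residual`, where the residual collects the
#' remaining bands (photoreceptor segments, external limiting membrane,
#' inner nuclear + outer plexiform layers, nerve fibre layer). The residual
#' mean is therefore implied by the `RT_FC`, `GCLp_FC` and `ONL_FC` means;
#' only its standard deviation (`residual_sd`) is a free setting.
#'
#' @param group `"control"` or `"ept_norop"`.
#' @return A list with elements `group_label`, `means`, `sds` (named over
#'   [foveal_parameters()]), `residual_sd`, `fwm_asym_sd` (SD of the
#'   nasal-temporal rim thickness difference), `correlation` (5x5 matrix
#'   over `GCLp_FC`, `GCLp_Q2Q`, `ONL_FC`, `FD`, `RESID`), and for controls
#'   `reference_limits`, `limit_directions` and `reference_pct_outside`.
#' @export
#' @examples
#' cohort_defaults("control")$means
cohort_defaults <- function(group = c("control", "ept_norop")) {
  group <- match.arg(group)
  p <- foveal_parameters()
  if (group == "control") {
    means <- c(3.47, 10.23, 107.78, 208.36, 131.15)
    sds   <- c(2.11, 4.76, 12.43, 12.53, 16.73)
    names(means) <- names(sds) <- p
    out <- list(
      group_label = "control",
      means = means, sds = sds,
      residual_sd = 8, fwm_asym_sd = 8,
      correlation = default_correlation("control"),
      reference_limits = c(GCLp_FC = 7.7, GCLp_Q2Q = 19.7, ONL_FC = 136.9,
                           RT_FC = 233.4, FD = 97.7),
      limit_directions = c(GCLp_FC = "upper", GCLp_Q2Q = "upper",
                           ONL_FC = "upper", RT_FC = "upper", FD = "lower"),
      reference_pct_outside = c(GCLp_FC = 68, GCLp_Q2Q = 73, ONL_FC = 76,
                                RT_FC = 68, FD = 51)
    )
  } else {
    means <- c(13.95, 27.19, 150.52, 247.09, 89.46)
    # the tabulated RT_FC SD (4.49) is inconsistent with the tabulated
    # range (192.72-303.95); RT_FC spread here is implied by the structural
    # sum GCLp + ONL + residual instead.
    sds <- c(11.66, 11.59, 26.75, 4.49, 22.98)
    names(means) <- names(sds) <- p
    out <- list(
      group_label = "ept_norop",
      means = means, sds = sds,
      residual_sd = 10, fwm_asym_sd = 8,
      correlation = default_correlation("ept_norop")
    )
  }
  out
}

#' Default inter-parameter correlation matrix for cohort simulation
#'
#' Correlations are specified over the latent sampling variables
#' `GCLp_FC`, `GCLp_Q2Q`, `ONL_FC`, `FD` and `RESID` (the residual
#' retinal-thickness component); `RT_FC` and `RT_FWM` correlations are then
#' induced structurally. For the preterm group all thickness parameters are
#' mutually correlated (0.7) and anticorrelated with foveal depth (-0.7),
#' reproducing the coordinated-arrest pattern; for controls the GCL+
#' parameters are decoupled from the rest (a mature fovea has essentially no
#' inner retina at the centre), with a moderate ONL-FD anticorrelation and a
#' 0.5 correlation between the two GCL+ parameters.
#'
#' @param group `"control"` or `"ept_norop"`.
#' @return Symmetric 5x5 correlation matrix with unit diagonal.
#' @export
default_correlation <- function(group = c("control", "ept_norop")) {
  group <- match.arg(group)
  v <- c("GCLp_FC", "GCLp_Q2Q", "ONL_FC", "FD", "RESID")
  m <- diag(5)
  dimnames(m) <- list(v, v)
  set2 <- function(a, b, r) {
    m[a, b] <<- r
    m[b, a] <<- r
  }
  if (group == "ept_norop") {
    set2("GCLp_FC", "GCLp_Q2Q", 0.7)
    set2("GCLp_FC", "ONL_FC", 0.7)
    set2("GCLp_Q2Q", "ONL_FC", 0.7)
    set2("GCLp_FC", "FD", -0.7)
    set2("GCLp_Q2Q", "FD", -0.7)
    set2("ONL_FC", "FD", -0.7)
  } else {
    set2("GCLp_FC", "GCLp_Q2Q", 0.5)
    set2("ONL_FC", "FD", -0.5)
  }
  m
}

#' Reference covariate comparison for the preterm subgroups
#'
#' Summary statistics (mean, SD, n per subgroup) of perinatal and clinical
#' covariates for right eyes of the extremely preterm group, split by
#' whether central retinal thickness fell outside the control limit. These
#' are reconstruction inputs for [group_compare_summary()]; the package
#' does not model the covariates themselves.
#'
#' @return Data frame with one row per covariate: `variable`, `unit`,
#'   `mean_outside`, `sd_outside`, `n_outside`, `mean_within`, `sd_within`,
#'   `n_within`.
#' @export
prematurity_covariates <- function() {
  data.frame(
    variable = c("gestational_age_weeks", "gestational_age_days",
                 "birth_weight_grams", "visual_acuity_decimal",
                 "refraction_se_diopters"),
    unit = c("weeks", "days", "g", "decimal", "D"),
    mean_outside = c(25.83, 185.83, 899.66, 0.81, 1.41),
    sd_outside = c(0.39, 3.13, 170.27, 0.17, 1.04),
    n_outside = 12L,
    mean_within = c(25.71, 184.57, 875.42, 0.83, 0.84),
    sd_within = c(0.49, 3.87, 95.23, 0.13, 0.84),
    n_within = 7L,
    stringsAsFactors = FALSE
  )
}
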