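# shared fixtures: small deterministic eyes and boundary sets built in code

# hand-written plausible single-eye targets (um)
control_like_targets <- function(gclp_fc = 3.5) {
  list(GCLp_FC = gclp_fc, GCLp_Q2Q = 10.2, ONL_FC = 107.8, RT_FC = 208.4,
       RT_FWM_nasal = 341, RT_FWM_temporal = 338, eye_id = "ctl_fix",
       laterality = "OD")
}

ept_like_targets <- function() {
  list(GCLp_FC = 14, GCLp_Q2Q = 27.2, ONL_FC = 150.5, RT_FC = 247.1,
       RT_FWM_nasal = 338, RT_FWM_temporal = 334, eye_id = "ept_fix",
       laterality = "OS")
}

# tiny synthetic boundary set with hand-set constant separations (px);
# independent of build_boundaries()
flat_stack_bset <- function(n = 64, rpe_row = 400, sep = c(10, 20, 30, 55, 58, 80),
                            laterality = "OD",
                            scan = scan_geometry(n_ascans = n, n_axial = 512)) {
  rpe <- rep(rpe_row, n)
  boundary_set(list(
    ILM = rpe - sep[6], GCLp_inner = rpe - sep[5], GCLp_outer = rpe - sep[4],
    ONL_inner = rpe - sep[3], ONL_outer = rpe - sep[2], ISOS = rpe - sep[1],
    RPE_posterior = rpe), laterality = laterality, scan = scan,
    eye_id = "flat_fix")
}

# brute-force centred moving average with symmetric edge shrinkage
brute_moving_average <- function(x, w) {
  h <- (w - 1) %/% 2
  n <- length(x)
  sapply(seq_len(n), function(i) {
    hh <- min(h, i - 1, n - i)
    mean(x[(i - hh):(i + hh)])
  })
}

# definitional Pearson r
brute_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
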