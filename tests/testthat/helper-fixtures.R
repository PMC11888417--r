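# Shared fixtures: the exemplary single-flash parameter set (8% bleach)
# and random parameter draws over the physiological ranges used for
# parameter-recovery studies.

exemplar_params <- function() response_params(a0 = -36.4, a1 = 200.8,
                                              tau_a = 9.5, tau_b = 0.07)

# random draws over the recovery-study ranges
draw_params <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    response_params(a0 = runif(1, -80, -5), a1 = runif(1, 30, 500),
                    tau_a = runif(1, 2, 20), tau_b = runif(1, 0.02, 0.3)))
}

rel_err <- function(est, truth) max(abs(est - truth) / abs(truth))

# dense-grid argmax oracle for the time of maximum elongation:
# coarse pass over [0, 20/tau_b], then 1e-5 s refinement near the
# coarse argmax (equivalent to a flat 1e-5 s grid at desk scale)
grid_tmax_oracle <- function(params, fine = 1e-5, coarse = 1e-2) {
  t_hi <- 20 / params$tau_b
  tc <- seq(0, t_hi, by = coarse)
  i <- which.max(eval_single_flash(params, tc))
  lo <- max(0, tc[i] - 2 * coarse)
  tf <- seq(lo, min(t_hi, tc[i] + 2 * coarse), by = fine)
  tf[which.max(eval_single_flash(params, tf))]
}
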