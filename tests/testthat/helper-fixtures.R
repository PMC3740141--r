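# Shared fixtures: the reference simulation conditions (four unit doses at
# 8/16/24/32 min, t_s = 0.43, t_half = 41 min, e_max = 10 over drift
# 1000 + 0.05 t, 800 frames at 3 s).

ref_schedule <- function() dose_schedule(c(8, 16, 24, 32), 1)
ref_pk <- function(t_shift = 0.43) pk_params(t_half_min = 41,
                                             t_shift_min = t_shift)
ref_drift <- function() drift_spec(c(1000, 0.05))

# scalar oracle for the superposed one-compartment concentration
oracle_conc <- function(t, doses, times, t_half, t_shift) {
  sum(ifelse(t - t_shift - times >= 0,
             doses * 0.5^((t - t_shift - times) / t_half), 0))
}
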