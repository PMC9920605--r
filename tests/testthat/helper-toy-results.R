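# Hand-built realisation results with tiny windows, for arithmetic oracles
# of the correlation estimators (no dynamics involved).
toy_result <- function(Y, E, times_ps, pre_mean_y = 0.1,
                       energy_per_site = 0.043) {
  rec <- structure(list(times_ps = times_ps, Y = Y, E = E,
                        H = rep(1, length(times_ps)),
                        window = seq_len(ncol(Y))),
                   class = "trajectory_record")
  structure(list(seed = 0L, record = rec, y0_window = Y[1, ],
                 e0_window = E[1, ], pre_insertion_mean_y = pre_mean_y,
                 lambda = 1, spec = NULL,
                 energy_per_site = energy_per_site),
            class = "realisation_result")
}
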