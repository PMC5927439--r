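# Shared fixtures: the default parameter set and a couple of standard
# short runs reused across test files.
default_params <- electrocyte_params()

# standard pulsatile run: 200 Hz, amplitude 1, default gNa_max of 700 uS
standard_run_200 <- function(params = default_params, n_aps = 20, ...) {
  run_train(params, stimulus_regime(amplitude = 1, frequency = 200),
            n_aps = n_aps, ...)
}
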