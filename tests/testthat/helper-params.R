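# Baseline parameter set used across tests: host cohort 1e8 emerging over
# one time unit, transmission 1e-8, decay 2, background mortality 0.5,
# season length 3, delay 1.5, 200 progeny per kill.
baseline_params <- function(...) {
  update_params(model_params(), ...)
}

rel_err <- function(a, b, floor = 1e-12) {
  abs(a - b) / pmax(abs(b), floor)
}
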