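# Shared simulated fixtures, built once per test run.
.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Small task-2 trial (2 cycles per segment) with stored envelopes.
fixture_trial <- function() {
  cached("trial_t2", simulate_trial(sim_config(
    task = 2, n_cycles_per_mode = 2, seed = 3, keep_envelope = TRUE)))
}

fixture_trial_pre <- function() {
  cached("trial_t2_pre", preprocess_trial(fixture_trial()))
}

# Build a bare decision_trace for evaluation tests without running a
# classifier: per-sample output labels at the given sampling rate.
manual_trace <- function(output, fs = 2000, t0 = 0) {
  output <- as_mode(output)
  structure(list(output = output, raw = output,
                 updates = data.frame(),
                 config = decision_config(1L, as.character(output[1])),
                 t = t0 + (seq_along(output) - 1L) / fs),
            class = "decision_trace")
}
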