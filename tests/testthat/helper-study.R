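# The full 126-run synthetic study is used by several integration tests;
# generate and measure it once per test session.
.study_cache <- new.env(parent = emptyenv())

get_full_study <- function() {
  if (!exists("study", envir = .study_cache)) {
    assign("study", simulate_study(study_design(), seed = 42),
           envir = .study_cache)
  }
  get("study", envir = .study_cache)
}

get_full_measurements <- function() {
  if (!exists("meas", envir = .study_cache)) {
    assign("meas", measure_slices(get_full_study()$slices),
           envir = .study_cache)
  }
  get("meas", envir = .study_cache)
}
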