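# Shared fixtures: one default synthetic input set and its prepared model,
# built once per test run.

test_raw <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_inputs(seed = 42L)
    cache
  }
})

test_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- prepare_inputs(test_raw())
    cache
  }
})

result_value <- function(res, outcome, disease = "all", sex = "both",
                         col = "value") {
  res[res$outcome == outcome & res$disease == disease & res$sex == sex,
      col]
}
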