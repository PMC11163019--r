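# Build synthetic fish records with a controllable river/year layout.
# counts: named list river -> named vector year -> n fish; all wild 1SW
# unless overridden afterwards.
make_records <- function(counts, mean_len = 540, sd_len = 20,
                         age = "1SW", origin = "wild", seed = 1) {
  set.seed(seed)
  out <- list()
  for (rv in names(counts)) {
    yrs <- counts[[rv]]
    for (j in seq_along(yrs)) {
      n <- yrs[[j]]
      out[[length(out) + 1L]] <- data.frame(
        river = rv, latitude = 47, year = as.integer(names(yrs)[j]),
        doy = 180L,
        fork_length_mm = rnorm(n, mean_len, sd_len),
        sea_age = age, origin = origin, gear = "trap")
    }
  }
  do.call(rbind, out)
}

# A quick small fitted model reused by several method tests.
small_fit <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      truth <- dfa_truth(S = 6, T = 25, m = 2, obs_sd = 4, offsets = 0,
                         missing = "random", missing_frac = 0.15,
                         seed = 42)
      pan <- center_panel(simulate_panel(truth)$panel)
      memo <<- varimax_rotate(
        fit_dfa(pan, m = 2, R = "diagonal_equal",
                control = dfa_control(max_iter = 2000)))
    }
    memo
  }
})
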