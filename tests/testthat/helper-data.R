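# small builders shared across test files

trials_df <- function(participant = "P01", condition = "aligned",
                      session = 2, x_level, y_level, response, rt_ms) {
  data.frame(participant = participant, condition = condition,
             session = session, x_level = x_level, y_level = y_level,
             response = response, rt_ms = rt_ms, stringsAsFactors = FALSE)
}

# four-item RT list with a known additive structure plus noise
additive_item_rts <- function(n = 200, base = 800, dx = 150, dy = 150,
                              sd = 100, seed = 1) {
  set.seed(seed)
  list(LL = base + dx + dy + rnorm(n, 0, sd),
       LH = base + dx + rnorm(n, 0, sd),
       HL = base + dy + rnorm(n, 0, sd),
       HH = base + rnorm(n, 0, sd))
}
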