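## Fixtures are built in code: no data files.

T0 <- as.POSIXct("2023-01-02 00:00:00", tz = "UTC")

## raw signal from explicit axis vectors at a fixed rate
make_signal <- function(x, y, z, fs = 80, start = T0, range_g = 8) {
  raw_signal(as.numeric(start) + (seq_along(x) - 1) / fs, x, y, z,
             sample_rate_hz = fs, dynamic_range_g = range_g)
}

## constant-orientation signal of `minutes` minutes with optional noise
make_still_signal <- function(minutes = 1, fs = 80, orient = c(0, 0, 1),
                              noise_sd = 0, seed = 1, start = T0) {
  set.seed(seed)
  n <- minutes * 60 * fs
  make_signal(orient[1] + rnorm(n, 0, noise_sd),
              orient[2] + rnorm(n, 0, noise_sd),
              orient[3] + rnorm(n, 0, noise_sd), fs = fs, start = start)
}

## minute-level frame for evaluation tests: one participant per list entry
make_minutes <- function(ac, measures = list(), id = "P1", valid = TRUE,
                         start = T0) {
  df <- data.frame(participant_id = id,
                   time = start + (seq_along(ac) - 1) * 60,
                   ac = ac)
  for (nm in names(measures)) df[[nm]] <- measures[[nm]]
  df$valid <- valid
  df
}

## noise-free identity harmonization model on [1, hi]
identity_model <- function(hi = 100, n = 2000) {
  ac <- seq(1, hi, length.out = n)
  suppressWarnings(fit_mapping(ac, ac, "measure"))
}
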