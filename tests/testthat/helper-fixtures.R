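# Shared fixtures, built in code.

oa_test_panel <- function() {
  # load once per session; the packaged panel is immutable
  if (is.null(.oa_test_env$panel)) {
    .oa_test_env$panel <- load_panel()
  }
  .oa_test_env$panel
}

.oa_test_env <- new.env(parent = emptyenv())

# a small panel subset (entries + the ISTDs they reference) for fast
# instrument-level tests
oa_mini_panel <- function(analytes = c("Lactic acid", "Methylmalonic acid",
                                       "Hexanoylglycine", "Citric acid",
                                       "Hawkinsin")) {
  p <- oa_test_panel()
  entries <- dplyr::filter(p$entries, .data$name %in% analytes)
  istds <- dplyr::filter(p$istds, .data$name %in% entries$istd_name)
  structure(list(entries = entries, istds = istds), class = "oa_panel")
}

# dense noise-free Gaussian chromatogram
gaussian_eic <- function(height = 1000, mu = 5, sigma = 0.05,
                         from = 4, to = 6, step = 0.002, baseline = 0) {
  rt <- seq(from, to, by = step)
  tibble::tibble(rt = rt,
                 intensity = baseline +
                   height * exp(-0.5 * ((rt - mu) / sigma)^2))
}

# independent exhaustive Passing-Bablok slope oracle: double loop over all
# pairs, explicit shifted median
pb_oracle_slope <- function(x, y) {
  n <- length(x)
  slopes <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (x[j] != x[i]) {
        s <- (y[j] - y[i]) / (x[j] - x[i])
        if (s != -1) slopes <- c(slopes, s)
      }
    }
  }
  slopes <- sort(slopes)
  N <- length(slopes)
  K <- sum(slopes < -1)
  if (N %% 2 == 1) {
    slopes[(N + 1) / 2 + K]
  } else {
    (slopes[N / 2 + K] + slopes[N / 2 + 1 + K]) / 2
  }
}
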