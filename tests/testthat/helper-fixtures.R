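# Shared fixture builders (all data generated in code).

mono_exp_profile <- function(c0 = 100, k = 0.5, times = seq(0, 15, by = 0.01),
                             matrix = "plasma", dose = NA_real_) {
  pk_profile("fix01", "fixture", matrix, times, c0 * exp(-k * times),
             dose_amount = dose)
}

simple_profile <- function(times, conc, matrix = "plasma",
                           dose = NA_real_) {
  pk_profile("fix01", "fixture", matrix, times, conc, dose_amount = dose)
}

write_pk_fixture_csv <- function(path, times = c(0.17, 2, 8),
                                 conc = c(50, 20, 5)) {
  df <- data.frame(subject_id = "m1", group = "WT", matrix = "plasma",
                   time = times, concentration = conc, dose_amount = 5,
                   route = "iv")
  write.csv(df, path, row.names = FALSE)
  path
}

# Independent product-limit oracle: no censoring support needed beyond
# the simple step-down construction used in the tests.
hand_km <- function(times) {
  times <- sort(times)
  n <- length(times)
  data.frame(time = times, surv = 1 - seq_len(n) / n)
}

# Independent two-group log-rank oracle: observed-minus-expected with the
# hypergeometric variance over pooled event times (no censoring).
hand_logrank2 <- function(a, b) {
  events <- sort(unique(c(a, b)))
  o <- e <- v <- 0
  for (tt in events) {
    na <- sum(a >= tt); nb <- sum(b >= tt); n <- na + nb
    d <- sum(a == tt) + sum(b == tt)
    o <- o + sum(a == tt)
    e <- e + d * na / n
    if (n > 1) v <- v + d * (na / n) * (nb / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}
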