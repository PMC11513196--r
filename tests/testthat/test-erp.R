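# hand-built epoch_set with prescribed waveforms
epochs_from_waves <- function(waves, time) {
  structure(list(epochs = waves, time = time, sampling_rate = NA,
                 condition = "error", truth = NULL, spec = NULL),
            class = "epoch_set")
}

test_that("mean amplitude matches simple area arguments", {
  time <- seq(-100, 600, by = 1000 / 256)
  flat <- matrix(5, 3, length(time))
  es <- epochs_from_waves(list(s1 = flat), time)
  expect_equal(unname(mean_amplitude(es, c(0, 100))), 5)

  # rectangular -8 uV pulse covering exactly half the window samples
  sel <- which(time >= 0 & time <= 100)
  half <- sel[seq_len(floor(length(sel) / 2))]
  w <- rep(0, length(time))
  w[half] <- -8
  es2 <- epochs_from_waves(list(s1 = rbind(w)), time)
  got <- unname(mean_amplitude(es2, c(0, 100)))
  expect_equal(got, -8 * length(half) / length(sel))
})

test_that("windowed means match a loop-based per-sample oracle", {
  es <- make_epochs(epoch_spec(n_subjects = 4, trials_per_subject = 6,
                               seed = 21))
  sel <- es$time >= 0 & es$time <= 100
  oracle <- vapply(es$epochs, function(m) {
    acc <- 0
    for (tr in seq_len(nrow(m))) {
      s <- 0
      for (j in which(sel)) s <- s + m[tr, j]
      acc <- acc + s / sum(sel)
    }
    acc / nrow(m)
  }, numeric(1))
  expect_equal(mean_amplitude(es, c(0, 100)), oracle, tolerance = 1e-12)
})

test_that("empty trial sets are rejected", {
  time <- seq(-100, 600, by = 4)
  es <- epochs_from_waves(list(s1 = matrix(0, 0, length(time))), time)
  expect_error(mean_amplitude(es, c(0, 100)), "no trials")
})

test_that("fractional-area latency recovers symmetric and uniform pulses", {
  time <- seq(-100, 600, by = 1000 / 256)
  step <- 1000 / 256
  tri <- -pmax(0, 1 - abs(time - 50) / 30)        # triangle centered at 50
  expect_equal(fractional_area_latency(tri, time, c(0, 100)), 50,
               tolerance = step)
  rect <- ifelse(time >= 20 & time <= 60, -8, 0)  # uniform area 20..60
  expect_equal(fractional_area_latency(rect, time, c(0, 100)), 40,
               tolerance = step)
})

test_that("latency matches a dense trapezoid oracle on asymmetric waves", {
  time <- seq(-100, 600, by = 1000 / 256)
  w <- -(pmax(0, 1 - abs(time - 30) / 15) + 2 * pmax(0, 1 - abs(time - 70) / 10))
  got <- fractional_area_latency(w, time, c(0, 100))
  # oracle: cumulative trapezoid on a 100x denser grid
  dense <- seq(0, 100, by = step <- (1000 / 256) / 100)
  wd <- -( pmax(0, 1 - abs(dense - 30) / 15) +
             2 * pmax(0, 1 - abs(dense - 70) / 10))
  y <- pmax(-wd, 0)
  cum <- cumsum((y[-1] + y[-length(y)]) / 2 * diff(dense))
  oracle <- dense[which(cum >= 0.5 * cum[length(cum)])[1] + 1]
  expect_equal(got, oracle, tolerance = 1000 / 256)
  # invariant to amplitude scaling
  expect_equal(fractional_area_latency(13.7 * w, time, c(0, 100)), got)
})

test_that("latency is undefined for polarity-inconsistent signals", {
  time <- seq(-100, 600, by = 4)
  pos <- ifelse(time >= 20 & time <= 60, 5, 0)
  expect_warning(lat <- fractional_area_latency(pos, time, c(0, 100),
                                                polarity = "negative"),
                 "undefined")
  expect_true(is.na(lat))
})

test_that("trial variability follows its definitional cases", {
  time <- seq(-100, 600, by = 4)
  same <- matrix(3, 5, length(time))
  two <- rbind(rep(0, length(time)), rep(2, length(time)))
  es <- epochs_from_waves(list(s1 = same, s2 = two), time)
  v <- trial_variability(es, c(0, 100))
  expect_equal(unname(v$within_sd["s1"]), 0)
  expect_equal(unname(v$within_sd["s2"]), sqrt(2))
  expect_equal(v$between_sd, sd(c(3, 1)))
})

test_that("within-subject SD estimates the generating trial SD", {
  spec <- epoch_spec(n_subjects = 12, trials_per_subject = 1000,
                     amp_sd_within = 4, noise_sd = 0, seed = 22,
                     latency_sd = 0)
  es <- make_epochs(spec)
  sel <- es$time >= 0 & es$time <= 100
  shape_bar <- mean(exp(-(es$time[sel] - 50)^2 / (2 * spec$peak_sd^2)))
  v <- trial_variability(es, c(0, 100))
  expect_equal(mean(v$within_sd), 4 * shape_bar, tolerance = 0.1)
})

test_that("dependability hits its noise-free limit and grows with trials", {
  spec0 <- epoch_spec(n_subjects = 8, trials_per_subject = 10,
                      amp_sd_within = 0, noise_sd = 0, seed = 23)
  dep0 <- dependability(make_epochs(spec0), c(0, 100))
  expect_equal(unname(dep0), rep(1, 8))

  mk <- function(nt) make_epochs(epoch_spec(
    n_subjects = 40, trials_per_subject = nt, amp_sd_between = 2,
    amp_sd_within = 8, noise_sd = 0, seed = 24))
  dep5 <- mean(dependability(mk(5), c(0, 100)))
  dep200 <- mean(dependability(mk(200), c(0, 100)))
  expect_gt(dep200, dep5)
})

test_that("dependability matches the generating-variance plug-in", {
  spec <- epoch_spec(n_subjects = 50, trials_per_subject = 100,
                     amp_sd_between = 2, amp_sd_within = 8, noise_sd = 0,
                     latency_sd = 0, seed = 25)
  dep <- dependability(make_epochs(spec), c(0, 100))
  plugin <- 2^2 / (2^2 + 8^2 / 100)  # shape factor cancels in the ratio
  expect_equal(mean(dep), plugin, tolerance = 0.05)
})

test_that("exclusion rules use strict inequalities at both boundaries", {
  metrics <- data.frame(
    subject_id = c("a", "b", "c", "d", "e"),
    mean_amplitude = 0, latency = 50,
    n_trials = c(4, 5, 30, 30, 30),
    within_sd = 1,
    dependability = c(0.9, 0.9, 0.69, 0.70, 0.95))
  res <- apply_exclusions(metrics)
  expect_setequal(res$kept$subject_id, c("b", "d", "e"))
  expect_setequal(res$log$subject_id, c("a", "c"))
  expect_equal(res$log$rule[res$log$subject_id == "a"], "min_trials")
  expect_equal(res$log$rule[res$log$subject_id == "c"], "min_dependability")
  all_pass <- apply_exclusions(metrics[metrics$subject_id %in% c("b", "e"), ])
  expect_equal(nrow(all_pass$kept), 2)
  expect_equal(nrow(all_pass$log), 0)
})

test_that("subject amplitudes correlate with the generating truth", {
  es <- make_epochs(epoch_spec(n_subjects = 30, trials_per_subject = 200,
                               amp_sd_within = 2, noise_sd = 1, seed = 26))
  amp <- mean_amplitude(es, c(0, 100))
  expect_gt(cor(amp, es$truth$amplitude), 0.95)
})

test_that("erp_metrics assembles a coherent per-subject table", {
  es <- make_epochs(epoch_spec(n_subjects = 5, trials_per_subject = 20,
                               seed = 27))
  m <- erp_metrics(es)
  expect_equal(nrow(m), 5)
  expect_true(all(m$n_trials == 20))
  expect_true(all(m$dependability >= 0 & m$dependability <= 1))
  expect_true(all(m$latency >= 0 & m$latency <= 100))
})
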