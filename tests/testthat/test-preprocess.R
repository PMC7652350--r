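fs <- 500

test_that("band-pass filter meets its pass/stop-band contract", {
  t <- seq(0, 90, by = 1 / fs)
  mid <- 15000:30000
  atten_db <- function(f) {
    x <- sin(2 * pi * f * t)
    y <- bandpass_filter(x, fs)
    20 * log10(sd(y[mid]) / sd(x[mid]))
  }
  # 10 Hz passband tone preserved within 5%
  expect_lt(abs(atten_db(10)), 20 * log10(1 / 0.95))
  # 100 Hz reduced by at least 90%
  expect_lt(atten_db(100), -20)
  # probe sweep contract: >= 20 dB down at 0.01 Hz and 80 Hz
  expect_lt(atten_db(0.01), -20)
  expect_lt(atten_db(80), -20)
  # DC offset removed (high-pass behaviour)
  ydc <- bandpass_filter(rep(10, length(t)), fs)
  expect_lt(abs(mean(ydc[mid])), 0.1)
  # invalid cutoffs
  expect_error(bandpass_filter(numeric(1000), fs, high_hz = 300),
               "Nyquist")
  expect_error(bandpass_filter(numeric(100), fs), "shorter")
})

test_that("epoching uses the documented index arithmetic", {
  x <- seq_len(2000) # value == sample index
  ep0 <- epoch_trials(x, events = 1000, sample_rate = fs,
                      window_ms = c(-250, 1000), shift_ms = 0)
  expect_equal(ep0$signal[[1]], x[875:1500])
  expect_equal(epoch_times(ep0)[1], -250)

  ep3 <- epoch_trials(x, events = 1000, sample_rate = fs,
                      window_ms = c(-250, 1000), shift_ms = 300)
  expect_equal(ep3$signal[[1]], x[1025:1650])

  # impulse at the event sample appears at time zero
  imp <- numeric(2000); imp[1000] <- 1
  epi <- epoch_trials(imp, events = 1000, sample_rate = fs)
  expect_equal(epi$signal[[1]][epoch_times(epi) == 0], 1)
  expect_equal(sum(epi$signal[[1]]), 1)

  # event too close to the edge: flagged, not dropped
  epe <- epoch_trials(x, events = c(50, 1000), sample_rate = fs)
  expect_equal(nrow(epe), 2)
  expect_equal(epe$valid, c(FALSE, TRUE))
})

test_that("baseline correction zeroes the pre-stimulus mean", {
  times <- seq(-250, 1000, by = 2)
  const <- epochs_from_matrix(matrix(5, 1, length(times)), times)
  expect_true(all(baseline_correct(const)$signal[[1]] == 0))

  # baseline mean 2, peak 12 -> peak 10
  v <- rep(2, length(times)); v[times == 500] <- 12
  ep <- epochs_from_matrix(matrix(v, 1), times)
  out <- baseline_correct(ep)$signal[[1]]
  expect_equal(max(out), 10)

  # property: corrected baseline means vanish for random epochs
  set.seed(1)
  epr <- epochs_from_matrix(matrix(rnorm(20 * length(times), 3, 10), 20),
                            times)
  outr <- baseline_correct(epr)
  idx <- times >= -250 & times <= 0
  bl <- vapply(outr$signal, function(v) mean(v[idx]), numeric(1))
  expect_true(all(abs(bl) < 1e-9))
  expect_error(baseline_correct(epr, window_ms = c(-5000, -4000)),
               "outside")
})

test_that("artifact rejection applies the strict +/-100 uV boundary", {
  times <- seq(-250, 1000, by = 2)
  nt <- length(times)
  m <- matrix(0, 50, nt)
  m[1, 10] <- 99.9              # kept: within threshold
  m[2, 20] <- -101              # rejected
  crossing_rows <- c(2, 5, 9, 17, 23, 31, 44)
  for (r in setdiff(crossing_rows, 2)) m[r, r] <- 100 + r
  ep <- reject_artifacts(epochs_from_matrix(m, times))
  expect_false(ep$rejected[1])
  expect_true(ep$rejected[2])
  expect_equal(which(ep$rejected), crossing_rows)
  expect_equal(sum(ep$rejected), 7)
  # exactly +/-100 is kept (strict inequality)
  mb <- matrix(0, 1, nt); mb[1, 5] <- 100
  expect_false(reject_artifacts(epochs_from_matrix(mb, times))$rejected)
  # rejection is pure selection: retained samples unaltered
  expect_identical(ep$signal, lapply(seq_len(50), function(i) m[i, ]))
  # manual blacklist applied after the automatic pass
  epb <- reject_artifacts(epochs_from_matrix(m, times), blacklist = c(1, 3))
  expect_equal(sum(epb$rejected), 9)
})

test_that("low-trial participants are excluded at the 10-trial boundary", {
  mk <- function(id, n_int, n_dis) {
    tibble::tibble(
      participant = id, task = "Spatial",
      sequence_type = rep(c("intact", "disrupted"), c(n_int, n_dis)),
      rejected = FALSE)
  }
  dat <- dplyr::bind_rows(mk("keep", 10, 10), mk("drop1", 9, 30),
                          mk("ok", 25, 25), mk("drop2", 12, 8),
                          mk("drop3", 3, 3))
  out <- exclude_low_trial_participants(dat, min_trials = 10)
  expect_setequal(unique(out$participant), c("keep", "ok"))
  rep_tab <- exclusion_report(out)
  expect_equal(nrow(rep_tab), 3)
  expect_setequal(rep_tab$participant, c("drop1", "drop2", "drop3"))
  expect_equal(rep_tab$intact[rep_tab$participant == "drop1"], 9)
  # rejected trials do not count as usable
  dat2 <- mk("edge", 10, 10)
  dat2$rejected[1] <- TRUE
  expect_equal(nrow(exclude_low_trial_participants(dat2, 10)), 0)
})

test_that("ERP averaging pools correct, retained trials", {
  times <- seq(-250, 1000, by = 2)
  v <- sin(times / 100)
  ep <- epochs_from_matrix(rbind(v, v), times)
  avg <- average_erp(ep, correct_only = TRUE)
  expect_equal(avg$amplitude, v)
  expect_equal(unique(avg$n_trials), 2)

  # +1 and -1 epochs average to zero
  ep2 <- epochs_from_matrix(rbind(rep(1, length(times)),
                                  rep(-1, length(times))), times)
  expect_true(all(average_erp(ep2)$amplitude == 0))

  # rejected and incorrect trials are left out
  m <- rbind(v, v + 1, v + 100)
  ep3 <- epochs_from_matrix(m, times)
  ep3$rejected[3] <- TRUE
  ep3$response_correct[2] <- FALSE
  expect_equal(average_erp(ep3)$amplitude, v)
  expect_equal(unique(average_erp(ep3)$n_trials), 1)
  ep3$rejected <- TRUE
  expect_error(average_erp(ep3), "zero usable")
})

test_that("averaging beats single trials in template RMSE", {
  set.seed(7)
  times <- seq(-250, 1000, by = 2)
  template <- 10 * exp(-(times - 600)^2 / (2 * 80^2))
  n <- 20
  noise_sd <- 5
  m <- matrix(rnorm(n * length(times), 0, noise_sd), n,
              byrow = FALSE) + rep(template, each = n)
  avg <- average_erp(epochs_from_matrix(m, times))
  rmse <- function(x) sqrt(mean((x - template)^2))
  expect_lt(rmse(avg$amplitude), min(apply(m, 1, rmse)))
})

test_that("the preprocessing chain is deterministic and order-stable", {
  run_chain <- function() {
    ep <- simulate_epochs(tiny_config(seed = 21, trials_per_task = 16))
    ep |>
      baseline_correct() |>
      reject_artifacts() |>
      exclude_low_trial_participants(min_trials = 2) |>
      average_erp()
  }
  a <- run_chain(); b <- run_chain()
  expect_identical(a$amplitude, b$amplitude)
})
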