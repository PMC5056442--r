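test_that("background normalization subtracts the mean zero-time signal", {
  tr <- simulate_trace(k = 1e-3, plateau = 100)
  bg1 <- kinetic_trace(tr$times, rep(100, length(tr$times)))
  bg2 <- kinetic_trace(tr$times, rep(200, length(tr$times)))
  norm <- normalize_trace(tr, list(bg1, bg2))
  expect_equal(norm$intensities, tr$intensities - 150)
  expect_equal(norm$times, tr$times)
  ## trace as its own background starts at zero
  self <- normalize_trace(tr, list(tr))
  expect_equal(self$intensities[1], 0)
  expect_error(normalize_trace(tr, list()), "background")
})

test_that("plateau detection spans a flat trace and rejects a steep ramp", {
  t <- seq(0, 500, 10)
  lin <- kinetic_trace(t, 3 + 1e-5 * t)
  f <- fit_plateau_baseline(lin, slope_tol = 1e-4)
  expect_equal(f$plateau_start_index, 1L)
  expect_equal(f$slope, 1e-5, tolerance = 1e-10)
  expect_equal(f$intercept, 3, tolerance = 1e-6)
  ramp <- kinetic_trace(t, 5 * t)
  expect_error(fit_plateau_baseline(ramp, slope_tol = 1e-6), "no plateau")
})

test_that("plateau start matches a brute-force trailing-window scan", {
  k <- 1e-3; A <- 100
  tr <- simulate_trace(k = k, plateau = A, noise_sd = 2, seed = 8)
  tol <- 0.01 * A * k          # 1% of the true initial rate
  f <- fit_plateau_baseline(tr, slope_tol = tol)
  ## oracle: test every trailing window with lm(), mirroring the
  ## statistical acceptance rule |b| <= tol + 2 se(b)
  t <- tr$times; y <- tr$intensities; n <- length(t)
  ok <- vapply(1:(n - 19), function(i) {
    cf <- summary(lm(y[i:n] ~ t[i:n]))$coefficients
    abs(cf[2, 1]) <= tol + 2 * cf[2, 2]
  }, logical(1))
  expect_equal(f$plateau_start_index, which(ok)[1])
  ## and the chord-slope closed form places it in the saturated region
  t_p <- t[f$plateau_start_index]
  expect_gt(t_p, 2 / k)
  expect_lt(t_p, 5 / k)
})

test_that("half-times recover ln2/k for clean saturating traces", {
  ## fast reaction: within one sample interval
  ht <- half_time(simulate_trace(k = 1e-2, plateau = 50))
  expect_lt(abs(ht$half_time - log(2) / 1e-2), 10)
  ## slower reactions: the plateau-level estimate bounds accuracy at ~2%
  for (k in c(1e-4, 1e-3)) {
    ht <- half_time(simulate_trace(k = k, plateau = 50))
    expect_lt(abs(ht$half_time - log(2) / k) / (log(2) / k), 0.02)
  }
})

test_that("a step trace has its half-time at the step", {
  t <- seq(0, 1000, 10)
  ht <- half_time(kinetic_trace(t, ifelse(t < 300, 0, 80)))
  expect_lt(abs(ht$half_time - 300), 10)
})

test_that("half-time errors when the trace never reaches half-plateau", {
  t <- seq(0, 500, 10)
  ## rises then is truncated below half of its (forced) plateau level
  tr <- kinetic_trace(t, pmin(10 + 0 * t, 10))
  fit <- structure(list(plateau_start_index = 26L, intercept = 100,
                        slope = 0, slope_tol = 1, max_rate = 1,
                        min_points = 20), class = "plateau_fit")
  expect_error(half_time(tr, fit), "never reaches")
})

test_that("half-time is gain-invariant and monotone in rate", {
  tr <- simulate_trace(k = 2e-3, plateau = 80, noise_sd = 2, seed = 3)
  bg <- kinetic_trace(tr$times, rep(7, length(tr$times)))
  h1 <- half_time(normalize_trace(tr, list(bg)))$half_time
  scale_trace <- function(x, a, b) kinetic_trace(x$times,
                                                 a * x$intensities + b)
  h2 <- half_time(normalize_trace(scale_trace(tr, 3.7, 12),
                                  list(scale_trace(bg, 3.7, 12))))$half_time
  expect_equal(h1, h2, tolerance = 1e-9)
  ## monotone non-increasing in k
  hts <- vapply(c(5e-4, 1e-3, 2e-3, 5e-3),
                function(k) half_time(simulate_trace(k = k,
                                                     plateau = 60))$half_time,
                numeric(1))
  expect_true(all(diff(hts) < 0))
})

test_that("normalization of a background-free trace leaves half-time alone", {
  tr <- simulate_trace(k = 1e-3, plateau = 100)
  zero_bg <- kinetic_trace(tr$times, rep(0, length(tr$times)))
  expect_equal(half_time(normalize_trace(tr, list(zero_bg)))$half_time,
               half_time(tr)$half_time)
})

test_that("condition summaries compute mean and s.e.m. per group", {
  d <- data.frame(condition = c("WT", "WT", "WT", "WT", "MUT", "MUT"),
                  half_time = c(100, 110, 90, 104, 205, 195))
  out <- summarize_conditions(d)
  wt <- out[out$condition == "WT", ]
  expect_equal(wt$n, 4)
  expect_equal(wt$mean_half_time, mean(c(100, 110, 90, 104)))
  expect_equal(wt$sem, sd(c(100, 110, 90, 104)) / 2)
  mut <- out[out$condition == "MUT", ]
  expect_equal(mut$sem, sd(c(205, 195)) / sqrt(2))
  ## identical replicates
  same <- summarize_conditions(data.frame(condition = "X",
                                          half_time = c(50, 50, 50)))
  expect_equal(same$sem, 0)
})

test_that("traces read back from delimited files", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  tr <- simulate_trace(k = 1e-3, plateau = 40, noise_sd = 1, seed = 2)
  write.csv(data.frame(time = tr$times, intensity = tr$intensities,
                       condition = "WT"), tmp, row.names = FALSE)
  back <- read_traces(tmp)
  expect_equal(length(back), 1)
  expect_equal(back$WT$intensities, tr$intensities)
  expect_equal(back$WT$label, "WT")
})
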