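test_that("a single histogram inverts to omega proportional to h * exp(E/T)", {
  set.seed(61)
  E_grid <- seq(0, 10, by = 1)
  lw <- log(c(1, 3, 6, 10, 14, 16, 14, 10, 6, 3, 1))
  hs <- make_replica_energy_samples(E_grid, lw, temperatures = 2,
                                    n_per_replica = 5e4, seed = 61)
  fit <- solve_wham(hs)
  h <- hs$counts[1, ]
  expected <- log(h) + hs$centers / 2
  expected <- expected - max(expected[h > 0])
  expect_equal(fit$log_omega[h > 0], expected[h > 0], tolerance = 1e-9)
})

test_that("two-level degeneracy is recovered from two-temperature samples", {
  g <- 4
  hs <- make_replica_energy_samples(c(0, 1), c(0, log(g)),
                                    temperatures = c(0.5, 1.5),
                                    n_per_replica = 2e4, seed = 62)
  fit <- solve_wham(hs)
  ratio <- exp(fit$log_omega[2] - fit$log_omega[1])
  # binomial sampling error on the recovered ratio
  expect_lt(abs(ratio - g) / g, 0.1)
})

test_that("synthetic Gaussian density of states is recovered at the 8 study temperatures", {
  E_grid <- seq(-12, 12, by = 0.5)
  lw_true <- -E_grid^2 / 18
  temps <- c(0.85, 0.75, 0.68, 0.64, 0.6, 0.57, 0.53, 0.5)
  hs <- make_replica_energy_samples(E_grid, lw_true, temps,
                                    n_per_replica = 1e5, seed = 63)
  fit <- solve_wham(hs)
  truth <- attr(hs, "truth")
  ok <- is.finite(fit$log_omega)
  err <- fit$log_omega[ok] -
    truth$log_omega[match(round(fit$centers[ok], 6), round(truth$energy, 6))]
  err <- err - stats::median(err)          # overall scale is a gauge
  # well-sampled range: bins with many pooled counts
  heavy <- colSums(hs$counts)[ok] > 500
  expect_lt(max(abs(err[heavy])), 0.15)
})

test_that("exact two-level dos gives the closed-form Schottky heat capacity", {
  dos <- two_level_dos(eps = 1, g = 3)
  tg <- seq(0.1, 2, by = 0.005)
  cv <- heat_capacity(dos, tg)
  expect_true(all(cv$c_v >= 0))
  rel <- abs(cv$c_v - schottky_cv(tg)) / pmax(schottky_cv(tg), 1e-300)
  expect_lt(max(rel), 1e-6)
  # the located peak matches a dense scan of the closed form
  pk <- find_transition(cv)
  ts <- seq(0.1, 2, by = 1e-5)
  t_star <- ts[which.max(schottky_cv(ts))]
  expect_lt(abs(pk$peak_temperature - t_star), 2e-3)
  expect_true(pk$cooperative)
})

test_that("degenerate heat-capacity inputs behave sensibly", {
  # a single energy level has zero heat capacity
  one <- list(centers = 3, log_omega = 0)
  cv1 <- heat_capacity(one, c(0.5, 1, 2))
  expect_equal(cv1$c_v, c(0, 0, 0))
  # a Gaussian density of states gives C_V = sigma^2 / T^2
  E <- seq(-30, 30, by = 0.01); sig2 <- 4
  gdos <- list(centers = E, log_omega = -E^2 / (2 * sig2))
  cvg <- heat_capacity(gdos, c(0.7, 1.3))
  expect_equal(cvg$c_v, sig2 / c(0.7, 1.3)^2, tolerance = 1e-3)
})

test_that("transition finding handles monotone curves and ties", {
  mono <- tibble::tibble(temperature = 1:10, c_v = 1:10)
  class(mono) <- c("heat_capacity_curve", class(mono))
  res <- find_transition(mono)
  expect_false(res$has_peak)
  # two equal maxima: the lower-temperature peak wins
  twin <- tibble::tibble(temperature = 1:7, c_v = c(0, 1, 5, 1, 5, 1, 0))
  class(twin) <- c("heat_capacity_curve", class(twin))
  expect_lt(find_transition(twin)$peak_temperature, 4)
})

test_that("WHAM is invariant to replica order and count doubling", {
  E_grid <- seq(-8, 8, by = 0.5)
  lw <- -E_grid^2 / 10
  hs <- make_replica_energy_samples(E_grid, lw, c(0.8, 0.6, 0.5),
                                    n_per_replica = 5e3, seed = 64)
  fit <- solve_wham(hs)
  # reorder replicas
  perm <- c(3, 1, 2)
  hs2 <- hs
  hs2$counts <- hs$counts[perm, ]
  hs2$temperatures <- hs$temperatures[perm]
  hs2$N <- hs$N[perm]
  fit2 <- solve_wham(hs2)
  expect_equal(fit2$log_omega, fit$log_omega, tolerance = 1e-5)
  # doubling all counts changes nothing
  hs3 <- hs
  hs3$counts <- hs$counts * 2
  hs3$N <- hs$N * 2
  fit3 <- solve_wham(hs3)
  expect_equal(fit3$log_omega, fit$log_omega, tolerance = 1e-9)
  cv <- heat_capacity(fit, c(0.5, 0.7))
  cv3 <- heat_capacity(fit3, c(0.5, 0.7))
  expect_equal(cv3$c_v, cv$c_v, tolerance = 1e-9)
})

test_that("peak temperature recovery sharpens with sample size", {
  dos_spec <- list(E = c(0, 1), lw = c(0, log(50)))
  t_true <- local({
    ts <- seq(0.05, 1.5, by = 1e-4)
    cv <- vapply(ts, function(Tt) {
      r <- 50 * exp(-1 / Tt); (1 / Tt^2) * r / (1 + r)^2
    }, numeric(1))
    ts[which.max(cv)]
  })
  err_at <- function(n) {
    hs <- make_replica_energy_samples(dos_spec$E, dos_spec$lw,
                                      c(0.5, 0.35, 0.25, 0.2),
                                      n_per_replica = n, seed = 65)
    fit <- solve_wham(hs)
    cv <- heat_capacity(fit, seq(0.05, 1.5, length.out = 400))
    abs(find_transition(cv)$peak_temperature - t_true)
  }
  expect_lte(err_at(1e5), err_at(1e3) + 1e-6)
})

test_that("non-overlapping histograms and empty replicas are refused", {
  hs <- structure(list(
    edges = seq(-0.5, 10.5, 1), centers = 0:10,
    counts = rbind(c(5, 5, 0, 0, 0, 0, 0, 0, 0, 0, 0),
                   c(0, 0, 0, 0, 0, 0, 0, 0, 0, 5, 5)),
    temperatures = c(1, 2), N = c(10, 10)), class = "energy_histograms")
  expect_error(solve_wham(hs), "overlap")
  expect_error(make_replica_energy_samples(0:5, rep(0, 6), 1, 0), "empty")
})

test_that("transition-temperature averages reproduce the in-text arithmetic", {
  # the four exon1 peak temperatures average to 311 K and the four
  # no-polyP peaks to 340 K
  expect_equal(round(average_transition_temperature(c(308, 308, 325, 304))),
               311)
  expect_equal(round(average_transition_temperature(c(365, 335, 317, 343))),
               340)
  expect_equal(average_transition_temperature(42), 42)
  expect_error(average_transition_temperature(numeric(0)), "empty")
  # reduced-unit inputs convert at about 503 K per unit
  expect_equal(average_transition_temperature(1, units = "reduced"),
               503.219, tolerance = 1e-4)
  expect_equal(average_transition_temperature(1, units = "reduced",
                                              rounded = TRUE), 500)
})
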