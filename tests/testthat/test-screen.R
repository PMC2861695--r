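test_that("the Rg cutoff rule lands on the flank of the modal peak", {
  # single-bin histogram: cutoff is that bin's upper edge
  h1 <- screen_histogram(rep(15.2, 100), "RG")
  expect_equal(propose_rg_cutoff(h1), 16)
  # unimodal Gaussian like the study's worked instance (peak ~16 A,
  # cutoff 20 A)
  set.seed(71)
  rg <- rnorm(2e5, mean = 16, sd = 1.2)
  h <- screen_histogram(rg, "RG")
  expect_equal(attr(h, "bin_width"), 1)
  cut <- propose_rg_cutoff(h)
  expect_gte(cut, 19); expect_lte(cut, 21)
  # bimodal: the cutoff clears the first mode's right flank
  bi <- c(rnorm(5e4, 10, 0.8), rnorm(2e4, 30, 2))
  hb <- screen_histogram(bi, "RG")
  cb <- propose_rg_cutoff(hb)
  expect_gt(cb, 12)
})

test_that("the energy cutoff isolates the low-energy Gaussian", {
  set.seed(72)
  lowE <- rnorm(4e3, -300, 5)
  highE <- rnorm(6e3, -250, 8)
  cut <- propose_energy_cutoff(c(lowE, highE))
  expect_gt(mean(lowE <= cut), 0.95)
  expect_lt(mean(highE <= cut), 0.05)
  # translation equivariance
  cut_shifted <- propose_energy_cutoff(c(lowE, highE) + 40)
  expect_equal(cut_shifted, cut + 40, tolerance = 0.5)
  # a single Gaussian degenerates to the lowest-decile fallback
  single <- rnorm(5e3, -100, 4)
  expect_warning(cs <- propose_energy_cutoff(single), "degenerate")
  expect_equal(cs, unname(quantile(single, 0.1)), tolerance = 1e-9)
})

test_that("compact selection equals a by-hand filter and reports fractions", {
  frames <- tibble::tibble(
    rg = c(12, 25, 14, 16, 30, 11, 19, 22, 15, 13),
    e_pot = c(-300, -310, -200, -290, -320, -250, -295, -280, -310, -260),
    time = 1:10 * 10)
  ce <- select_compact(frames, rg_cut = 20, e_cut = -285)
  byhand <- which(frames$rg <= 20 & frames$e_pot <= -285)
  expect_equal(which(frames$time %in% ce$time), byhand)
  expect_equal(attr(ce, "fraction"), length(byhand) / 10)
  # cutoffs below everything: empty but valid
  none <- select_compact(frames, 5, -400)
  expect_equal(nrow(none), 0)
  expect_equal(attr(none, "fraction"), 0)
  # cutoffs above everything: full ensemble
  all_in <- select_compact(frames, 100, 0)
  expect_equal(attr(all_in, "fraction"), 1)
})

test_that("compact selection is monotone in both cutoffs", {
  set.seed(73)
  frames <- tibble::tibble(rg = runif(500, 10, 30),
                           e_pot = rnorm(500, -280, 20),
                           time = seq_len(500))
  base <- nrow(select_compact(frames, 18, -285))
  expect_gte(nrow(select_compact(frames, 22, -285)), base)
  expect_gte(nrow(select_compact(frames, 18, -275)), base)
})

test_that("crossing counts follow the sign-change definition", {
  expect_equal(count_crossings(rep(-300, 50), -285), 0)
  expect_equal(count_crossings(c(-300, -250, -300, -250), -285), 3)
  expect_equal(count_crossings(seq(-250, -320, by = -10), -285), 1)
  # values exactly at the cutoff attach to the preceding sign
  expect_equal(count_crossings(c(-300, -285, -300), -285), 0)
  expect_equal(count_crossings(c(-300, -285, -250), -285), 1)
  # invariant under uniform time rescaling (values unchanged) and the
  # count survives series reversal
  s <- c(-300, -250, -290, -240, -300)
  expect_equal(count_crossings(rev(s), -285), count_crossings(s, -285))
})

test_that("crossing counts match telegraph-process ground truth", {
  ts <- make_two_state_energy_series(E_low = -300, E_high = -250,
                                     switch_rate = 0.02, within_state_sd = 2,
                                     n = 5000, dt = 1, seed = 74)
  k_true <- attr(ts, "n_transitions")
  got <- count_crossings(ts$e_pot, -275)
  # small noise far from the cutoff adds no spurious crossings
  expect_equal(got, k_true)
  # zero switching rate: no crossings for any cutoff between the levels
  flat <- make_two_state_energy_series(-300, -250, 0, 1, n = 1000, seed = 75)
  expect_equal(count_crossings(flat$e_pot, -275), 0)
})

test_that("the probability standard error has the binomial form", {
  expect_equal(probability_standard_error(0, 10), 0)
  expect_equal(probability_standard_error(1, 10), 0)
  expect_equal(probability_standard_error(0.5, 100), 0.05)
  expect_error(probability_standard_error(0.5, 0), "undefined")
  expect_error(probability_standard_error(1.2, 10))
  # matches the spread of per-visit means on a synthetic two-state series
  set.seed(76)
  n_events <- 400
  p <- 0.3
  per_event <- rbinom(2000, n_events, p) / n_events
  expect_lt(abs(sd(per_event) - probability_standard_error(p, n_events)),
            3 * sd(per_event) / sqrt(2 * 2000))
})

test_that("compact fraction converges to the true state occupancy", {
  occ <- function(n, seed) {
    ts <- make_two_state_energy_series(-300, -250, switch_rate = 0.05,
                                       within_state_sd = 1, n = n, dt = 1,
                                       seed = seed)
    frames <- tibble::tibble(rg = rep(10, n), e_pot = ts$e_pot,
                             time = ts$time)
    attr(select_compact(frames, 100, -275), "fraction")
  }
  # stationary occupancy of the symmetric telegraph process is 1/2
  expect_lt(abs(occ(2e4, 77) - 0.5), 0.1)
})
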