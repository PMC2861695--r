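#' Energy histogram set for WHAM
#'
#' Bins per-replica energy samples on a shared grid. The bin width
#' defaults to the Freedman-Diaconis rule on the pooled energies.
#'
#' @param energies either a list of numeric vectors (one per replica) or a
#'   tibble with columns `temperature` and `e_pot`
#' @param temperatures replica temperatures (reduced units); required when
#'   `energies` is a list
#' @param bin_width energy bin width; `NULL` for Freedman-Diaconis
#' @param edges explicit bin edges (overrides `bin_width`)
#' @return object of class `energy_histograms`: bin `edges`, `centers`,
#'   counts matrix (replicas x bins), `temperatures`, totals `N`
#' @export
energy_histograms <- function(energies, temperatures = NULL, bin_width = NULL,
                              edges = NULL) {
  if (is.data.frame(energies)) {
    stopifnot(all(c("temperature", "e_pot") %in% names(energies)))
    sp <- split(energies$e_pot, energies$temperature)
    temperatures <- as.numeric(names(sp))
    energies <- unname(sp)
  }
  stopifnot(length(energies) == length(temperatures))
  if (any(lengths(energies) == 0)) stop("empty histogram for at least one replica")
  pooled <- unlist(energies)
  if (is.null(edges) && is.null(bin_width)) {
    iqr <- stats::IQR(pooled)
    bin_width <- if (iqr > 0) 2 * iqr / length(pooled)^(1 / 3)
                 else diff(range(pooled)) / 50
    if (bin_width <= 0) bin_width <- 1
  }
  if (is.null(edges)) {
    lo <- floor(min(pooled) / bin_width) * bin_width
    hi <- ceiling(max(pooled) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  }
  counts <- t(vapply(energies, function(e) {
    as.numeric(graphics::hist(e, breaks = edges, plot = FALSE)$counts)
  }, numeric(length(edges) - 1)))
  structure(list(edges = edges,
                 centers = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts,
                 temperatures = as.numeric(temperatures),
                 N = rowSums(counts)),
            class = "energy_histograms")
}

#' Solve the WHAM equations for the density of states
#'
#' Self-consistent solution (k_B = 1 units) of
#' \deqn{\Omega(E) = \frac{\sum_k h_k(E)}{\sum_k N_k \exp(f_k - E/T_k)},
#'       \qquad e^{-f_k} = \sum_E \Omega(E) e^{-E/T_k},}
#' iterated from f_k = 0 in log-domain arithmetic until
#' `max |delta f_k| < tol`, with the gauge f_1 = 0.
#'
#' @param hists an [energy_histograms()] set (>= 1 replica; replicas must
#'   have mutually overlapping energy ranges)
#' @param tol convergence tolerance on the free-energy shifts
#' @param max_iter iteration cap
#' @return object of class `wham_fit`: bin `centers`, `log_omega`
#'   (normalized so the maximum is 0), shifts `f`, `temperatures`,
#'   `iterations`, `converged`
#' @export
solve_wham <- function(hists, tol = 1e-7, max_iter = 1e5) {
  stopifnot(inherits(hists, "energy_histograms"))
  K <- length(hists$temperatures)
  E <- hists$centers
  h <- hists$counts                     # K x M
  N <- hists$N
  if (any(N == 0)) stop("a replica contributed no samples; WHAM refuses")
  occupied <- colSums(h) > 0
  if (K > 1) {
    # mutual support: pooled occupied bins must form one connected range
    # across replicas (no replica may be disjoint from all others)
    rng <- vapply(seq_len(K), function(k) {
      ii <- which(h[k, ] > 0); c(min(ii), max(ii))
    }, numeric(2))
    ord <- order(rng[1, ])
    for (q in seq_len(K - 1)) {
      if (rng[1, ord[q + 1]] > rng[2, ord[q]] + 1)
        stop("non-overlapping histograms: no mutual support between replicas")
    }
  }
  logsumexp <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(-Inf)
    m + log(sum(exp(x - m)))
  }
  f <- numeric(K)
  logN <- log(N)
  logh <- suppressWarnings(log(colSums(h)))   # -Inf on empty bins
  it <- 0L; converged <- FALSE
  repeat {
    it <- it + 1L
    # log denominator per bin: logsumexp_k(log N_k + f_k - E/T_k)
    A <- outer(logN + f, rep(1, length(E))) - outer(1 / hists$temperatures, E)
    mx <- apply(A, 2, max)
    logden <- mx + log(colSums(exp(sweep(A, 2, mx))))
    log_omega <- logh - logden
    log_omega[!occupied] <- -Inf
    fnew <- -vapply(seq_len(K), function(k) {
      logsumexp(log_omega[occupied] - E[occupied] / hists$temperatures[k])
    }, numeric(1))
    fnew <- fnew - fnew[1]              # gauge f_1 = 0
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  if (!converged) stop("WHAM did not converge within max_iter")
  log_omega <- log_omega - max(log_omega[occupied])
  structure(list(centers = E, log_omega = log_omega, f = f,
                 temperatures = hists$temperatures,
                 iterations = it, converged = converged, tol = tol),
            class = "wham_fit")
}

#' @export
print.wham_fit <- function(x, ...) {
  cat(sprintf("<wham_fit> %d bins, %d replicas, %d iterations (%s)\n",
              sum(is.finite(x$log_omega)), length(x$temperatures),
              x$iterations, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Heat capacity from a density of states
#'
#' `C_V(T) = (<E^2>_T - <E>_T^2) / T^2` with Boltzmann-weighted moments
#' computed by log-sum-exp over the density of states.
#'
#' @param dos a `wham_fit` (or list with `centers` and `log_omega`)
#' @param T_grid positive temperature grid (reduced units)
#' @return object of class `heat_capacity_curve`: tibble with columns
#'   `temperature`, `c_v`, `mean_energy`
#' @export
heat_capacity <- function(dos, T_grid) {
  stopifnot(all(T_grid > 0))
  ok <- is.finite(dos$log_omega)
  E <- dos$centers[ok]; lw <- dos$log_omega[ok]
  rows <- lapply(T_grid, function(Tt) {
    lz <- lw - E / Tt
    m <- max(lz)
    w <- exp(lz - m)
    Z <- sum(w)
    m1 <- sum(w * E) / Z
    m2 <- sum(w * (E - m1)^2) / Z       # centered for numerical stability
    tibble::tibble(temperature = Tt, c_v = m2 / Tt^2, mean_energy = m1)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("heat_capacity_curve", class(out))
  out
}

#' Locate the heat-capacity transition peak
#'
#' Grid argmax refined by a local quadratic through the three points
#' around the maximum. When two grid maxima tie, the lower-temperature
#' peak is returned. A peak whose prominence (height above the larger
#' curve endpoint) is below `prominence_frac` of the curve range is
#' flagged `cooperative = FALSE` (a broad, shallow collapse). A curve with
#' no interior maximum yields an explicit no-peak result.
#'
#' @param curve a [heat_capacity()] curve (>= 3 grid points)
#' @param prominence_frac cooperativity threshold as a fraction of the
#'   curve range
#' @return tibble with one row: `peak_temperature`, `peak_height`,
#'   `cooperative`, `has_peak`
#' @export
find_transition <- function(curve, prominence_frac = 0.1) {
  stopifnot(nrow(curve) >= 3)
  Tg <- curve$temperature; cv <- curve$c_v
  i <- which(cv == max(cv))[1]          # tie-break: lower temperature
  if (i == 1 || i == nrow(curve)) {
    return(tibble::tibble(peak_temperature = NA_real_,
                          peak_height = NA_real_,
                          cooperative = NA, has_peak = FALSE))
  }
  # quadratic refinement through the three points around the maximum
  x <- Tg[(i - 1):(i + 1)]; y <- cv[(i - 1):(i + 1)]
  d2 <- (y[3] - 2 * y[2] + y[1])
  if (d2 < 0) {
    co <- stats::coef(stats::lm(y ~ stats::poly(x, 2, raw = TRUE)))
    tp <- -co[2] / (2 * co[3])
    hp <- co[1] + co[2] * tp + co[3] * tp^2
    if (tp < x[1] || tp > x[3]) { tp <- Tg[i]; hp <- cv[i] }
  } else {
    tp <- Tg[i]; hp <- cv[i]
  }
  rng <- diff(range(cv))
  prominence <- hp - max(cv[1], cv[nrow(curve)])
  tibble::tibble(peak_temperature = unname(tp), peak_height = unname(hp),
                 cooperative = rng > 0 && prominence >= prominence_frac * rng,
                 has_peak = TRUE)
}

#' Average transition temperature over a set of models
#'
#' Arithmetic mean of peak temperatures, e.g. the mean over the four
#' repeat lengths of one construct. Inputs in reduced units are converted
#' to Kelvin via the unit system (about 503 K per unit, or the rounded
#' 500 K).
#'
#' @param peaks numeric vector of peak temperatures
#' @param units `"K"` if `peaks` are already Kelvin, `"reduced"` to
#'   convert
#' @param rounded use the rounded 500 K/unit conversion
#' @return mean transition temperature in Kelvin
#' @export
average_transition_temperature <- function(peaks, units = c("K", "reduced"),
                                           rounded = FALSE) {
  units <- match.arg(units)
  if (length(peaks) == 0) stop("empty list of peak temperatures")
  if (units == "reduced") peaks <- temperature_to_kelvin(peaks, rounded)
  mean(peaks)
}

#' @export
#' @importFrom generics tidy
tidy.wham_fit <- function(x, ...) {
  tibble::tibble(energy = x$centers, log_omega = x$log_omega)
}

#' @export
#' @importFrom generics glance
glance.wham_fit <- function(x, ...) {
  tibble::tibble(n_bins = length(x$centers),
                 n_replicas = length(x$temperatures),
                 iterations = x$iterations, converged = x$converged,
                 tol = x$tol)
}

#' @export
autoplot.heat_capacity_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$temperature, .data$c_v)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "temperature (reduced units)",
                  y = expression(C[V] ~ "(kcal/mol per unit"^2 * ")"))
}
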