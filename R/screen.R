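#' Histogram of a screening variable
#'
#' Pools a per-frame variable (radius of gyration or potential energy)
#' across replicas into a histogram used to choose screening cutoffs.
#' The Rg bin width defaults to 1 Angstrom.
#'
#' @param x numeric vector of per-frame values
#' @param kind `"RG"` or `"ENERGY"`
#' @param bin_width bin width (default 1 for Rg, Freedman-Diaconis for
#'   energy)
#' @return object of class `screen_histogram`: tibble (`mid`, `count`,
#'   `lower`, `upper`) with the kind and bin width as attributes
#' @export
screen_histogram <- function(x, kind = c("RG", "ENERGY"), bin_width = NULL) {
  kind <- match.arg(kind)
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("empty histogram")
  if (is.null(bin_width)) {
    if (kind == "RG") bin_width <- 1
    else {
      iqr <- stats::IQR(x)
      bin_width <- if (iqr > 0) 2 * iqr / length(x)^(1 / 3)
                   else max(diff(range(x)) / 50, 1e-9)
    }
  }
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  counts <- graphics::hist(x, breaks = edges, plot = FALSE)$counts
  out <- tibble::tibble(
    lower = edges[-length(edges)], upper = edges[-1],
    mid = (edges[-1] + edges[-length(edges)]) / 2,
    count = as.numeric(counts))
  attr(out, "kind") <- kind
  attr(out, "bin_width") <- bin_width
  attr(out, "n") <- length(x)
  class(out) <- c("screen_histogram", class(out))
  out
}

#' Propose a radius-of-gyration cutoff
#'
#' Eliminates highly extended structures. The default rule: the smallest
#' bin upper edge above the modal bin at which the count first falls below
#' `frac_of_mode` (10%) of the modal count. In the study's worked example
#' the Rg distribution peaks near 16 A and the cutoff lands at 20 A.
#'
#' @param hist a `screen_histogram` of kind `"RG"`
#' @param frac_of_mode flank threshold as a fraction of the modal count
#' @return cutoff in Angstrom
#' @export
propose_rg_cutoff <- function(hist, frac_of_mode = 0.1) {
  stopifnot(inherits(hist, "screen_histogram"))
  if (nrow(hist) == 0 || sum(hist$count) == 0) stop("empty histogram")
  if (nrow(hist) == 1) return(hist$upper[1])
  mode_i <- which.max(hist$count)
  thr <- frac_of_mode * hist$count[mode_i]
  after <- which(seq_len(nrow(hist)) > mode_i & hist$count < thr)
  if (length(after) == 0) return(hist$upper[nrow(hist)])
  hist$upper[after[1]]
}

#' Propose an energy cutoff
#'
#' Selects the lowest-energy population: a two-component Gaussian mixture
#' is fitted to the pooled energies and the cutoff is mu + 2 sigma of the
#' lowest-mean component ("the lowest energy Gaussians"). When the fit is
#' degenerate (components collapse onto each other) the fallback is the
#' lowest-decile cutoff, with a warning.
#'
#' @param energies pooled per-frame energies (typically the low-temperature
#'   replicas)
#' @param fallback_quantile quantile used when the mixture fit degenerates
#' @return energy cutoff
#' @export
propose_energy_cutoff <- function(energies, fallback_quantile = 0.1) {
  energies <- energies[is.finite(energies)]
  if (length(energies) < 10) stop("too few energies for a cutoff")
  # Mclust resolves helpers in the calling frame, so evaluate the call
  # inside an environment that inherits from the mclust namespace
  fit <- tryCatch(
    suppressWarnings(eval(
      quote(Mclust(.e, G = 2, modelNames = "V", verbose = FALSE)),
      envir = list2env(list(.e = energies),
                       parent = asNamespace("mclust")))),
    error = function(e) NULL)
  degenerate <- TRUE
  if (!is.null(fit) && length(fit$parameters$mean) == 2) {
    mu <- fit$parameters$mean
    sd <- sqrt(fit$parameters$variance$sigmasq)
    if (length(sd) == 1) sd <- rep(sd, 2)
    lo <- which.min(mu)
    # components that overlap within ~2 sd describe one mode, not two
    if (all(is.finite(sd)) && abs(diff(mu)) > 2 * max(sd)) {
      degenerate <- FALSE
      cutoff <- mu[lo] + 2 * sd[lo]
    }
  }
  if (degenerate) {
    warning("mixture fit degenerate; falling back to the lowest-decile cutoff")
    cutoff <- unname(stats::quantile(energies, fallback_quantile))
  }
  unname(cutoff)
}

#' Select the compact, low-energy sub-ensemble
#'
#' Membership is `(Rg <= rg_cut) & (E <= e_cut)` (cutoff equality counts
#' as compact). The fraction is reported against the total frame count,
#' and the number of energy-cutoff crossings is attached for error bars.
#'
#' @param frames tibble with at least `rg` and `e_pot` columns (e.g. the
#'   `info` of a `replex_result`, excluding equilibration)
#' @param rg_cut radius-of-gyration cutoff (Angstrom)
#' @param e_cut energy cutoff
#' @return a `compact_ensemble`: the member rows, with attributes
#'   `rg_cut`, `e_cut`, `fraction`, `n_total`, `n_events`
#' @export
select_compact <- function(frames, rg_cut, e_cut) {
  stopifnot(all(c("rg", "e_pot") %in% names(frames)))
  member <- frames$rg <= rg_cut & frames$e_pot <= e_cut
  out <- frames[member, , drop = FALSE]
  n_events <- if ("replica" %in% names(frames)) {
    sum(vapply(split(frames$e_pot, frames$replica),
               count_crossings, numeric(1), cutoff = e_cut))
  } else count_crossings(frames$e_pot, e_cut)
  attr(out, "rg_cut") <- rg_cut
  attr(out, "e_cut") <- e_cut
  attr(out, "n_total") <- nrow(frames)
  attr(out, "fraction") <- if (nrow(frames)) nrow(out) / nrow(frames) else 0
  attr(out, "n_events") <- n_events
  class(out) <- c("compact_ensemble", class(out))
  out
}

#' @export
print.compact_ensemble <- function(x, ...) {
  cat(sprintf(
    "<compact_ensemble> %d / %d frames (%.1f%%), Rg <= %.3g, E <= %.3g, %d crossings\n",
    nrow(x), attr(x, "n_total"), 100 * attr(x, "fraction"),
    attr(x, "rg_cut"), attr(x, "e_cut"), attr(x, "n_events")))
  invisible(x)
}

#' Count cutoff crossings of a time-ordered series
#'
#' Number of sign changes of `E - cutoff`, counting both entries into and
#' exits from the compact domain; values exactly at the cutoff attach to
#' the preceding sign.
#'
#' @param series time-ordered numeric series
#' @param cutoff threshold
#' @return number of crossings
#' @export
count_crossings <- function(series, cutoff) {
  s <- sign(series - cutoff)
  if (length(s) == 0) return(0L)
  # ties attach to the preceding sign
  for (i in seq_along(s)) {
    if (s[i] == 0) s[i] <- if (i == 1) 0 else s[i - 1]
  }
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(s[-1] != s[-length(s)])
}

#' Standard error of an ensemble probability
#'
#' `sqrt(p (1 - p) / n_events)`, with the number of cutoff-crossing
#' events as the effective sample size.
#'
#' @param p probability in [0, 1]
#' @param n_events number of crossing events (>= 1)
#' @return standard error
#' @export
probability_standard_error <- function(p, n_events) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (any(n_events < 1)) stop("standard error undefined for n_events < 1")
  sqrt(p * (1 - p) / n_events)
}

#' @export
autoplot.screen_histogram <- function(object, cutoff = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$mid, .data$count)) +
    ggplot2::geom_col(width = attr(object, "bin_width")) +
    ggplot2::labs(
      x = if (attr(object, "kind") == "RG") "radius of gyration (Å)"
          else "potential energy (kcal/mol)",
      y = "frames")
  if (!is.null(cutoff))
    p <- p + ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed")
  p
}
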