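#' Backbone dihedral angles of a frame
#'
#' Computes phi (C(i-1)-N(i)-CA(i)-C(i)) and psi (N(i)-CA(i)-C(i)-N(i+1))
#' for every residue of an N-CA-C backbone, IUPAC sign convention, degrees
#' in (-180, 180]. Phi is undefined at the N-terminus and psi at the
#' C-terminus; collinear atom triplets yield `NA` (flagged, excluded
#' downstream).
#'
#' @param coords (3 * n_res) x 3 backbone coordinates in N, CA, C order,
#'   unwrapped
#' @return tibble with columns `residue`, `phi`, `psi`
#' @export
compute_dihedrals <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) %% 3 != 0) stop("coordinates are not an N-CA-C backbone")
  n_res <- nrow(coords) / 3
  if (n_res < 2) stop("need at least 2 residues for any dihedral")
  phi <- rep(NA_real_, n_res); psi <- rep(NA_real_, n_res)
  for (i in seq_len(n_res)) {
    b <- 3 * (i - 1)
    if (i > 1)
      phi[i] <- torsion_angle(coords[b - 0, ], coords[b + 1, ],
                              coords[b + 2, ], coords[b + 3, ])
    if (i < n_res)
      psi[i] <- torsion_angle(coords[b + 1, ], coords[b + 2, ],
                              coords[b + 3, ], coords[b + 4, ])
  }
  tibble::tibble(residue = seq_len(n_res), phi = phi, psi = psi)
}

#' Ramachandran rectangle boundaries
#'
#' The declared default basins used to classify a (phi, psi) pair:
#' * ALPHA: phi in [-100, -30], psi in [-80, -5]
#' * BETA:  phi in [-180, -45], psi in [90, 180] or (-180, -160]
#' * TURN:  phi in [30, 100], psi in [-20, 80] (left-handed/turn basin)
#' * COIL:  everything else
#' * PPII (optional): carved out of BETA as phi in [-90, -55],
#'   psi in [120, 170]
#'
#' @return named list of basin rectangles (degrees)
#' @export
ss_basins <- function() {
  list(ALPHA = list(phi = c(-100, -30), psi = c(-80, -5)),
       BETA  = list(phi = c(-180, -45), psi_hi = c(90, 180),
                    psi_lo = c(-180, -160)),
       TURN  = list(phi = c(30, 100), psi = c(-20, 80)),
       PPII  = list(phi = c(-90, -55), psi = c(120, 170)))
}

#' Classify a dihedral pair into a secondary-structure class
#'
#' Maps each defined (phi, psi) pair to exactly one of ALPHA, BETA, TURN
#' or COIL (the rectangles are disjoint and COIL absorbs the rest). When
#' `ppii` is enabled, the PPII sub-basin is carved out of BETA so that
#' BETA(off) = BETA(on) + PPII(on).
#'
#' @param phi,psi angles in degrees (vectorized)
#' @param ppii report PPII as its own class (default off, matching the
#'   4-class scheme)
#' @return character vector of class labels; `NA` input yields `NA`
#' @export
classify_ss <- function(phi, psi, ppii = FALSE) {
  b <- ss_basins()
  inb <- function(x, r) !is.na(x) & x >= r[1] & x <= r[2]
  # psi low edge of the wrapped BETA strip is open at -180 by the (-180,180]
  # angle convention, so a plain closed test is exact on that domain
  alpha <- inb(phi, b$ALPHA$phi) & inb(psi, b$ALPHA$psi)
  beta <- inb(phi, b$BETA$phi) &
    (inb(psi, b$BETA$psi_hi) | (!is.na(psi) & psi > -180 & psi <= -160))
  turn <- inb(phi, b$TURN$phi) & inb(psi, b$TURN$psi)
  out <- ifelse(is.na(phi) | is.na(psi), NA_character_,
         ifelse(alpha, "ALPHA",
         ifelse(beta, "BETA",
         ifelse(turn, "TURN", "COIL"))))
  if (ppii) {
    pp <- inb(phi, b$PPII$phi) & inb(psi, b$PPII$psi) & out == "BETA"
    out[which(pp)] <- "PPII"
  }
  out
}

#' Secondary-structure classes in use
#' @param ppii include the PPII class
#' @return character vector of class labels
#' @export
ss_classes <- function(ppii = FALSE) {
  if (ppii) c("ALPHA", "BETA", "PPII", "TURN", "COIL")
  else c("ALPHA", "BETA", "TURN", "COIL")
}

#' Per-residue secondary-structure probability profile
#'
#' Class frequencies per residue across an ensemble of frames (averages
#' over the compact ensemble). Residues whose dihedrals are undefined in
#' a frame (termini, collinear triplets) are excluded from that frame's
#' counts, with the denominator adjusted. Standard errors use the
#' ensemble's crossing-event count via [probability_standard_error()].
#'
#' @param frames list of backbone coordinate matrices (N, CA, C order)
#' @param ppii report PPII separately
#' @param n_events crossing-event count for error bars (optional)
#' @return a `ss_profile` tibble: `residue`, one probability column per
#'   class, `n_frames`, and `se_*` columns when `n_events` is given
#' @export
ss_probability_profile <- function(frames, ppii = FALSE, n_events = NULL) {
  if (length(frames) == 0) stop("empty ensemble")
  cls <- ss_classes(ppii)
  n_res <- nrow(frames[[1]]) / 3
  counts <- matrix(0, n_res, length(cls), dimnames = list(NULL, cls))
  denom <- numeric(n_res)
  for (fr in frames) {
    d <- compute_dihedrals(fr)
    lab <- classify_ss(d$phi, d$psi, ppii = ppii)
    ok <- !is.na(lab)
    denom[d$residue[ok]] <- denom[d$residue[ok]] + 1
    for (k in cls) {
      hit <- d$residue[ok & lab == k]
      if (length(hit)) counts[hit, k] <- counts[hit, k] + 1
    }
  }
  probs <- counts / pmax(denom, 1)
  probs[denom == 0, ] <- NA_real_
  out <- tibble::as_tibble(as.data.frame(probs))
  out <- dplyr::bind_cols(tibble::tibble(residue = seq_len(n_res)), out)
  out$n_frames <- denom
  if (!is.null(n_events)) {
    for (k in cls)
      out[[paste0("se_", k)]] <- probability_standard_error(
        replace(out[[k]], is.na(out[[k]]), 0), n_events) *
        ifelse(is.na(out[[k]]), NA, 1)
  }
  attr(out, "ppii") <- ppii
  attr(out, "n_events") <- n_events
  class(out) <- c("ss_profile", class(out))
  out
}

#' Average class probabilities over a region
#'
#' Arithmetic mean of the per-residue class probabilities over a residue
#' mask, e.g. the polyQ region of a construct. A region mean beta-strand
#' probability of 0.3 means an average residue of the region has a 30%
#' chance of adopting beta-strand dihedral angles.
#'
#' @param profile an [ss_probability_profile()]
#' @param mask 0-based half-open `c(start, end)` range (as returned by
#'   [region_mask()]) or a vector of 1-based residue positions
#' @return one-row tibble of per-class mean probabilities (and mean
#'   standard errors when present)
#' @export
region_average <- function(profile, mask) {
  stopifnot(inherits(profile, "ss_profile"))
  resids <- if (length(mask) == 2 && all(c("start", "end") %in% names(mask)))
    seq.int(mask[["start"]] + 1L, mask[["end"]]) else as.integer(mask)
  resids <- intersect(resids, profile$residue[profile$n_frames > 0])
  if (length(resids) == 0) stop("empty region mask")
  cls <- ss_classes(isTRUE(attr(profile, "ppii")))
  sub <- profile[profile$residue %in% resids, , drop = FALSE]
  out <- tibble::as_tibble(lapply(sub[cls], mean))
  for (k in paste0("se_", cls))
    if (k %in% names(sub)) out[[k]] <- mean(sub[[k]])
  out$n_residues <- length(resids)
  out
}

#' @export
autoplot.ss_profile <- function(object, ...) {
  cls <- ss_classes(isTRUE(attr(object, "ppii")))
  long <- tidyr::pivot_longer(
    dplyr::select(object, "residue", dplyr::all_of(cls)),
    dplyr::all_of(cls), names_to = "class", values_to = "probability")
  ggplot2::ggplot(long, ggplot2::aes(.data$residue, .data$probability,
                                     colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "probability")
}
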