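#' Synthetic-data generators
#'
#' Every analysis stage can be fed deterministic inputs with known ground
#' truth: ideal backbones with prescribed dihedral content, two-state
#' (telegraph) energy series, per-replica Boltzmann energy samples from a
#' known density of states, and perturbed structure blobs for clustering.
#' Identical parameters and seed give bit-identical output.
#'
#' @name synthetic-data
NULL

#' Ideal backbone with prescribed dihedral content
#'
#' Builds an N-CA-C chain from standard bond geometry with per-class
#' canonical dihedrals (ALPHA: -57/-47; BETA: -120/130; PPII: -75/145;
#' TURN: 60/30; COIL: uniform random), plus isotropic Gaussian coordinate
#' noise.
#'
#' @param ss one class name for the whole chain, a per-residue vector of
#'   class names, or a 2-column matrix/data frame of explicit (phi, psi)
#'   in degrees
#' @param length number of residues (ignored when `ss` gives per-residue
#'   values)
#' @param noise_sd isotropic Gaussian coordinate noise sd (Angstrom)
#' @param seed RNG seed
#' @return (3 * length) x 3 coordinate matrix with attribute `dihedrals`
#'   (the ground-truth phi/psi tibble)
#' @export
make_ideal_backbone <- function(ss, length = NULL, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.matrix(ss) || is.data.frame(ss)) {
    ang <- as.matrix(ss)
    n_res <- nrow(ang)
    phi <- ang[, 1]; psi <- ang[, 2]
  } else {
    ss <- as.character(ss)
    if (base::length(ss) == 1 && !is.null(length)) ss <- rep(ss, length)
    n_res <- base::length(ss)
    bad <- setdiff(unique(ss), c(names(.ss_dihedrals), "COIL"))
    if (base::length(bad)) stop("invalid class: ", paste(bad, collapse = ", "))
    phi <- psi <- numeric(n_res)
    for (i in seq_len(n_res)) {
      if (ss[i] == "COIL") {
        phi[i] <- stats::runif(1, -180, 180)
        psi[i] <- stats::runif(1, -180, 180)
      } else {
        phi[i] <- .ss_dihedrals[[ss[i]]]["phi"]
        psi[i] <- .ss_dihedrals[[ss[i]]]["psi"]
      }
    }
  }
  if (n_res < 2) stop("length must be >= 2")
  xyz <- build_backbone(phi, psi, n_res)
  if (noise_sd > 0)
    xyz <- xyz + matrix(stats::rnorm(3 * nrow(xyz), sd = noise_sd),
                        nrow(xyz), 3)
  attr(xyz, "dihedrals") <- tibble::tibble(residue = seq_len(n_res),
                                           phi = phi, psi = psi)
  xyz
}

#' Two-state (telegraph) energy series
#'
#' Alternates between two energy levels with exponential holding times
#' (symmetric switching rate) and adds Gaussian within-state noise. The
#' true level sequence and transition count are returned as ground truth.
#'
#' @param E_low,E_high level energies
#' @param switch_rate transitions per unit time (>= 0)
#' @param within_state_sd Gaussian noise sd around the level
#' @param n number of samples
#' @param dt sampling interval
#' @param seed RNG seed
#' @return tibble (`time`, `e_pot`, `state`) with attributes
#'   `n_transitions` (true level switches within the sampled span) and
#'   `p_low` (stationary low-state occupancy, 0.5 for symmetric rates)
#' @export
make_two_state_energy_series <- function(E_low, E_high, switch_rate,
                                         within_state_sd = 0, n = 1000,
                                         dt = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n < 1) stop("n must be >= 1")
  if (switch_rate < 0) stop("switch_rate must be >= 0")
  t_end <- n * dt
  # exact switch times of the telegraph process
  switches <- numeric(0)
  if (switch_rate > 0) {
    t <- 0
    repeat {
      t <- t + stats::rexp(1, switch_rate)
      if (t >= t_end) break
      switches <- c(switches, t)
    }
  }
  times <- seq_len(n) * dt
  state_idx <- findInterval(times, switches)       # number of switches so far
  state <- ifelse(state_idx %% 2 == 0, "low", "high")
  level <- ifelse(state == "low", E_low, E_high)
  e <- level + stats::rnorm(n, sd = within_state_sd)
  out <- tibble::tibble(time = times, e_pot = e, state = state)
  # transitions visible in the sampled series (switches between samples
  # cancel pairwise; count changes of the sampled state sequence)
  attr(out, "n_transitions") <- sum(state[-1] != state[-n])
  attr(out, "p_low") <- 0.5
  out
}

#' Boltzmann energy samples from a known density of states
#'
#' Draws i.i.d. energies per replica from p_k(E) proportional to
#' Omega(E) exp(-E/T_k) on a discrete energy grid, and returns the
#' histogram set ready for WHAM together with the ground truth.
#'
#' @param E energy grid
#' @param log_omega log density of states on the grid
#' @param temperatures replica temperatures
#' @param n_per_replica samples per replica
#' @param seed RNG seed
#' @return an [energy_histograms()] set with attribute `truth`
#'   (tibble `energy`, `log_omega`, normalized to max 0)
#' @export
make_replica_energy_samples <- function(E, log_omega, temperatures,
                                        n_per_replica, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(E) == length(log_omega), length(E) >= 2)
  if (n_per_replica < 1) stop("need n_per_replica >= 1 (empty histograms refused)")
  dE <- diff(sort(E))
  if (max(dE) - min(dE) > 1e-9 * max(dE)) stop("energy grid must be uniform")
  samples <- lapply(temperatures, function(Tt) {
    lw <- log_omega - E / Tt
    lw <- lw - max(lw)
    w <- exp(lw)
    if (!all(is.finite(w)) || sum(w) <= 0)
      stop("density of states not normalizable at T = ", Tt)
    sample(E, n_per_replica, replace = TRUE, prob = w / sum(w))
  })
  bw <- dE[1]
  Es <- sort(E)
  hs <- energy_histograms(samples, temperatures,
                          edges = seq(Es[1] - bw / 2,
                                      Es[length(Es)] + bw / 2, by = bw))
  attr(hs, "truth") <- tibble::tibble(energy = E,
                                      log_omega = log_omega - max(log_omega))
  hs
}

#' Perturbed structure blobs with known cluster labels
#'
#' Generates `sizes[k]` noisy copies of each template structure; the true
#' partition is returned for oracle tests of the clustering stage.
#'
#' @param sizes cluster sizes
#' @param centers list of template coordinate matrices (equal atom
#'   counts); by default, well-separated ideal backbones
#' @param spread isotropic Gaussian perturbation sd (Angstrom)
#' @param seed RNG seed
#' @return list with `structures` (list of matrices) and `labels`
#'   (true cluster id per structure)
#' @export
make_cluster_blobs <- function(sizes, centers = NULL, spread = 0.2,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(centers)) {
    # alpha/beta/turn 12-mers are mutually >= 2.5 A apart after superposition
    base <- c("ALPHA", "BETA", "TURN")
    centers <- lapply(seq_along(sizes), function(k) {
      make_ideal_backbone(base[(k - 1) %% 3 + 1], length = 12)
    })
  }
  stopifnot(length(centers) == length(sizes))
  na <- vapply(centers, nrow, integer(1))
  if (length(unique(na)) != 1) stop("templates of unequal atom counts")
  structures <- list(); labels <- integer(0)
  for (k in seq_along(sizes)) {
    for (s in seq_len(sizes[k])) {
      pert <- centers[[k]] +
        matrix(stats::rnorm(3 * na[1], sd = spread), na[1], 3)
      structures[[length(structures) + 1]] <- pert
      labels <- c(labels, k)
    }
  }
  list(structures = structures, labels = labels)
}
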