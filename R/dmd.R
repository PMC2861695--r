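#' Square-well pair potential
#'
#' A discretized pair potential: strictly ascending boundary distances with
#' one energy per inter-boundary shell. The region inside the first
#' boundary is a hard core; the shell outside the last boundary has energy
#' zero, unless `bounded = TRUE`, in which case the last boundary is an
#' infinite outer wall (used for bonds and 1-3 pseudo-angle constraints).
#'
#' @param boundaries ascending positive distances (Angstrom)
#' @param energies shell energies (kcal/mol), length `length(boundaries) - 1`
#' @param bounded outermost boundary reflects (confining wall)
#' @return object of class `square_well`
#' @export
square_well <- function(boundaries, energies = numeric(length(boundaries) - 1),
                        bounded = FALSE) {
  boundaries <- as.numeric(boundaries)
  energies <- as.numeric(energies)
  if (length(boundaries) < 1 || any(boundaries <= 0))
    stop("boundaries must be positive")
  if (is.unsorted(boundaries, strictly = TRUE))
    stop("boundaries must be strictly ascending")
  if (length(energies) != length(boundaries) - 1)
    stop("need one energy per inter-boundary shell")
  if (any(!is.finite(energies))) stop("shell energies must be finite")
  structure(list(boundaries = boundaries, energies = energies,
                 bounded = bounded),
            class = "square_well")
}

#' Discretize a continuous potential into square wells
#'
#' Each shell's energy is the continuous potential evaluated at the shell
#' midpoint; the outermost shell is forced to zero (the innermost boundary
#' is a hard core).
#'
#' @param f function distance -> energy
#' @param boundaries ascending distances delimiting the shells
#' @return a [square_well()]
#' @examples
#' lj <- function(r) 4 * 1 * ((3.5 / r)^12 - (3.5 / r)^6)
#' discretize_potential(lj, c(3.5, 4.5, 6.0))
#' @export
discretize_potential <- function(f, boundaries) {
  boundaries <- as.numeric(boundaries)
  if (is.unsorted(boundaries, strictly = TRUE))
    stop("boundaries must be strictly ascending")
  if (length(boundaries) < 2) return(square_well(boundaries))
  mids <- (boundaries[-length(boundaries)] + boundaries[-1]) / 2
  e <- vapply(mids, f, numeric(1))
  if (any(!is.finite(e))) stop("potential not finite at a shell midpoint")
  square_well(boundaries, e)
}

#' Shell index of a pair distance under a square-well potential
#'
#' 0-based: shell s lies between boundaries s and s+1; the outermost
#' (zero-energy) region has index `length(boundaries) - 1`. Negative
#' means inside the hard core.
#' @keywords internal
.shell_of <- function(d, pot) {
  s <- findInterval(d, pot$boundaries) - 1L
  s
}

#' Default backbone force field parameters
#'
#' A deliberately simple square-well backbone force field for the 3-bead
#' (N, CA, C) chain: narrow bond wells, 1-3 pseudo-angle wells, a 2.0 A
#' nonbonded hard core, and single-well attractions whose depth depends on
#' residue type (glutamine CA pairs attract more strongly than generic
#' backbone pairs) — enough to produce a temperature-driven coil-globule
#' collapse, which is what the downstream thermodynamic analysis needs.
#'
#' @param eps_qq well depth (kcal/mol) for glutamine CA - glutamine CA pairs
#' @param eps_bb well depth for all other nonbonded pairs
#' @param well_range outer edge of the attractive well (Angstrom)
#' @param hard_core nonbonded hard-core diameter (Angstrom)
#' @param angle_tol half-width of the 1-3 pseudo-angle wells (Angstrom)
#' @return named list of parameters
#' @export
dmd_forcefield <- function(eps_qq = 0.5, eps_bb = 0.15, well_range = 6.0,
                           hard_core = 2.0, angle_tol = 0.12) {
  list(eps_qq = eps_qq, eps_bb = eps_bb, well_range = well_range,
       hard_core = hard_core, angle_tol = angle_tol)
}

#' United-atom bead masses per backbone role
#' @keywords internal
.role_masses <- function(roles, uniform = TRUE) {
  if (uniform) return(rep(1, length(roles)))
  unname(c(N = 15, CA = 13, C = 28)[roles])
}

#' Prepare a DMD system from a construct
#'
#' Builds the bead topology (N, CA, C per residue), the pair interaction
#' table and an extended initial conformation inside a periodic cube whose
#' edge is `box_factor` times the fully extended contour length.
#'
#' @param model a [build_construct()] model
#' @param forcefield parameters from [dmd_forcefield()]
#' @param box_factor box edge as a multiple of the extended contour length
#' @param uniform_mass use unit masses (default); otherwise united-atom
#'   backbone masses
#' @return a `dmd_system` list: topology tibble, positions, interaction
#'   matrix, potential table, box edge
#' @export
dmd_system <- function(model, forcefield = dmd_forcefield(),
                       box_factor = 1.2, uniform_mass = TRUE) {
  stopifnot(inherits(model, "construct_model"))
  n_res <- nchar(model$sequence)
  if (n_res < 2) stop("need at least 2 residues")
  g <- backbone_geometry()
  roles <- rep(c("N", "CA", "C"), n_res)
  topology <- tibble::tibble(
    bead = seq_len(3 * n_res),
    residue = rep(seq_len(n_res), each = 3),
    role = roles,
    aa = rep(strsplit(model$sequence, "")[[1]], each = 3),
    mass = .role_masses(roles, uniform_mass))

  # fully extended conformation (all torsions trans)
  pos <- build_backbone(rep(180, n_res), rep(180, n_res), n_res)
  contour <- (n_res - 1) * (g$bond_n_ca + g$bond_ca_c + g$bond_c_n) +
    g$bond_n_ca + g$bond_ca_c
  L <- box_factor * contour

  n <- 3 * n_res
  itype <- matrix(0L, n, n)
  pots <- list()
  pot_key <- character(0)
  add_pot <- function(key, p) {
    k <- match(key, pot_key)
    if (!is.na(k)) return(k)
    pots[[length(pots) + 1]] <<- p
    pot_key[length(pot_key) + 1] <<- key
    length(pots)
  }

  bond_pot <- function(d0, tol) {
    list(boundaries = c(d0 - tol, d0 + tol), energies = 0, bounded = TRUE)
  }
  # covalent bonds along the chain
  bonds <- list(c("N", "CA", g$bond_n_ca), c("CA", "C", g$bond_ca_c))
  for (i in seq_len(n - 1)) {
    r1 <- roles[i]; r2 <- roles[i + 1]
    d0 <- if (r1 == "N") g$bond_n_ca else if (r1 == "CA") g$bond_ca_c else g$bond_c_n
    k <- add_pot(paste0("bond_", r1, r2),
                 bond_pot(d0, g$bond_tol))
    itype[i, i + 1] <- k
  }
  # 1-3 pseudo-angle wells: nominal distance from the initial (ideal) chain
  ff <- forcefield
  for (i in seq_len(n - 2)) {
    d0 <- sqrt(sum((pos[i + 2, ] - pos[i, ])^2))
    k <- add_pot(sprintf("ang_%.4f", d0), bond_pot(d0, ff$angle_tol))
    itype[i, i + 2] <- k
  }
  # nonbonded: all pairs separated by >= 3 bonds
  is_q_ca <- topology$role == "CA" & topology$aa == "Q"
  k_qq <- add_pot("nb_qq", list(
    boundaries = c(ff$hard_core, ff$well_range),
    energies = -ff$eps_qq, bounded = FALSE))
  k_bb <- add_pot("nb_bb", list(
    boundaries = c(ff$hard_core, ff$well_range),
    energies = -ff$eps_bb, bounded = FALSE))
  for (i in seq_len(n - 3)) {
    js <- (i + 3):n
    itype[i, js] <- ifelse(is_q_ca[i] & is_q_ca[js], k_qq, k_bb)
  }

  structure(list(model = model, topology = topology, positions = pos,
                 velocities = matrix(0, n, 3), time = 0,
                 itype = itype, potentials = pots, box = L,
                 forcefield = ff),
            class = "dmd_system")
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Per-component normal with sd sqrt(T/m); the total linear momentum is
#' removed.
#' @param masses bead masses
#' @param temperature reduced temperature
#' @return n x 3 velocity matrix
#' @export
maxwell_velocities <- function(masses, temperature) {
  n <- length(masses)
  v <- matrix(stats::rnorm(3 * n), n, 3) * sqrt(temperature / masses)
  p <- colSums(v * masses)
  sweep(v, 2, p / sum(masses))
}

#' Next boundary event for one bead pair
#'
#' Earliest positive root of |r + v t|^2 = d^2 over the reachable
#' boundaries of the pair's potential, using minimum-image relative
#' coordinates.
#'
#' @param state a `dmd_system` (with velocities set)
#' @param i,j bead indices (1-based)
#' @return `NULL` when no boundary is reachable, else a list with `time`,
#'   `boundary` (1-based index) and `dir` (-1 inward, +1 outward)
#' @export
next_pair_event <- function(state, i, j) {
  stopifnot(inherits(state, "dmd_system"), i != j)
  a <- min(i, j); b <- max(i, j)
  ty <- state$itype[a, b]
  if (ty == 0) return(NULL)
  pot <- state$potentials[[ty]]
  r <- state$positions[a, ] - state$positions[b, ]
  if (is.finite(state$box)) r <- r - state$box * round(r / state$box)
  v <- state$velocities[a, ] - state$velocities[b, ]
  s <- .shell_of(sqrt(sum(r^2)), pot)
  if (s < 0) stop("beads overlap inside the hard core: corrupted state")
  if (isTRUE(pot$bounded) && s > length(pot$boundaries) - 2)
    stop("pair outside its confining wall: corrupted state")
  pair_event_time_cpp(r, v, pot$boundaries, s, isTRUE(pot$bounded))
}

#' Resolve a square-well collision
#'
#' Updates the two beads' velocities for a collision at a potential
#' boundary: the radial relative velocity component either transmits
#' (crossing a step of height `dU` when the radial kinetic energy
#' suffices) or reflects. Linear momentum, angular momentum about the pair
#' midpoint and total energy are conserved exactly.
#'
#' @param x_i,x_j positions (the pair must sit at the boundary)
#' @param v_i,v_j velocities
#' @param m_i,m_j masses
#' @param dU energy step for crossing in the current radial direction
#' @param infinite_wall force reflection (hard core or bond wall)
#' @return list with updated `v_i`, `v_j` and `transmitted`
#' @export
resolve_collision <- function(x_i, x_j, v_i, v_j, m_i = 1, m_j = 1,
                              dU = 0, infinite_wall = FALSE) {
  resolve_collision_cpp(as.numeric(x_i), as.numeric(x_j),
                        as.numeric(v_i), as.numeric(v_j),
                        m_i, m_j, dU, infinite_wall)
}

#' Run an event-driven DMD simulation
#'
#' Processes pair, thermostat and frame-save events in time order through
#' a priority queue. The thermostat is Andersen-style: at exponentially
#' distributed intervals one random bead's velocity is redrawn from the
#' Maxwell-Boltzmann distribution at `temperature`. Frames saved during
#' the first `discard` time units are flagged as equilibration and
#' excluded from analysis by default.
#'
#' @param model a [build_construct()] model (or a prepared `dmd_system`)
#' @param temperature reduced temperature (> 0)
#' @param duration simulation length (tu)
#' @param save_interval frame save interval (tu, default 10)
#' @param seed RNG seed for reproducibility (optional)
#' @param thermo_rate Andersen ghost-collision rate (events/tu; 0 = NVE)
#' @param discard equilibration span flagged for exclusion (tu)
#' @param forcefield see [dmd_forcefield()]
#' @param ... passed to [dmd_system()]
#' @return a `dmd_trajectory`: list with `info` tibble (time, e_pot,
#'   e_kin, rg, equilibration), `frames` (unwrapped coordinate matrices),
#'   `topology`, `params` and the final `state`
#' @export
run_dmd <- function(model, temperature, duration, save_interval = 10,
                    seed = NULL, thermo_rate = 1, discard = 500,
                    forcefield = dmd_forcefield(), ...) {
  if (temperature <= 0) stop("temperature must be positive")
  if (duration < 0) stop("duration must be non-negative")
  sys <- if (inherits(model, "dmd_system")) model
         else dmd_system(model, forcefield = forcefield, ...)
  if (!is.null(seed)) set.seed(seed)
  vel <- maxwell_velocities(sys$topology$mass, temperature)
  res <- dmd_engine_cpp(sys$positions, vel, sys$topology$mass,
                        sys$itype, sys$potentials, sys$box,
                        temperature, duration, save_interval,
                        thermo_rate, 0)
  info <- tibble::tibble(
    time = res$time, e_pot = res$epot, e_kin = res$ekin, rg = res$rg,
    equilibration = res$time <= discard)
  structure(list(
    info = info, frames = res$frames,
    topology = sys$topology,
    params = list(temperature = temperature, duration = duration,
                  save_interval = save_interval, seed = seed,
                  thermo_rate = thermo_rate, discard = discard,
                  box = sys$box, forcefield = sys$forcefield),
    final = list(positions = res$pos, velocities = res$vel,
                 time = res$t_end),
    diagnostics = list(n_collisions = res$n_collisions,
                       epot_tracked = res$epot_tracked,
                       epot_scratch = res$epot_scratch),
    system = sys),
    class = "dmd_trajectory")
}

#' @export
print.dmd_trajectory <- function(x, ...) {
  cat(sprintf("<dmd_trajectory> %d beads, T = %g, %d frames, %.0f collisions\n",
              nrow(x$topology), x$params$temperature, nrow(x$info),
              x$diagnostics$n_collisions))
  invisible(x)
}

#' Energy/observable series of a trajectory
#'
#' @param traj a `dmd_trajectory`
#' @param include_equilibration keep frames from the equilibration span
#' @return tibble (time, e_pot, e_kin, rg)
#' @export
energy_series <- function(traj, include_equilibration = FALSE) {
  info <- traj$info
  if (!include_equilibration) info <- dplyr::filter(info, !info$equilibration)
  dplyr::select(info, "time", "e_pot", "e_kin", "rg")
}
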