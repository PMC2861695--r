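#' Replica-exchange schedule
#'
#' Defaults mirror the study protocol: eight replicas at reduced
#' temperatures {0.85, 0.75, 0.68, 0.64, 0.6, 0.57, 0.53, 0.5}, a swap
#' attempt every 500 tu (about 25 ps) and 1e6 tu (about 50 ns) per
#' replica, saving one conformation per 10 tu per replica.
#'
#' @param temperatures replica temperatures (reduced units)
#' @param swap_interval time between swap attempts (tu)
#' @param duration total simulated time per replica (tu)
#' @param save_interval frame save interval (tu)
#' @return object of class `replica_schedule`
#' @export
replica_schedule <- function(temperatures = c(0.85, 0.75, 0.68, 0.64,
                                              0.6, 0.57, 0.53, 0.5),
                             swap_interval = 500, duration = 1e6,
                             save_interval = 10) {
  temperatures <- as.numeric(temperatures)
  if (length(temperatures) < 2) stop("need at least 2 replicas")
  if (any(temperatures <= 0)) stop("temperatures must be positive")
  if (anyDuplicated(temperatures)) stop("replica temperatures must be distinct")
  if (swap_interval <= 0 || duration <= 0 || save_interval <= 0)
    stop("intervals must be positive")
  if (duration %% swap_interval != 0)
    stop("duration must be a multiple of the swap interval")
  structure(list(temperatures = temperatures, swap_interval = swap_interval,
                 duration = duration, save_interval = save_interval),
            class = "replica_schedule")
}

#' Metropolis acceptance for a temperature swap
#'
#' Accepts the exchange iff
#' `u < min(1, exp((1/T_i - 1/T_j) * (E_i - E_j)))`, the detailed-balance
#' rule for swapping the temperatures of two replicas.
#'
#' @param E_i,E_j potential energies of the two replicas
#' @param T_i,T_j their temperatures (reduced units, > 0)
#' @param u uniform random number in [0, 1)
#' @return logical: accepted
#' @export
attempt_swap <- function(E_i, E_j, T_i, T_j, u = stats::runif(1)) {
  if (T_i <= 0 || T_j <= 0) stop("temperatures must be positive")
  if (T_i == T_j) stop("degenerate swap between identical temperatures")
  log_p <- (1 / T_i - 1 / T_j) * (E_i - E_j)
  if (log_p >= 0) return(TRUE)
  u < exp(log_p)
}

#' Run replica-exchange DMD
#'
#' Advances each replica with the event-driven engine between swap times.
#' At each swap epoch all adjacent temperature pairs of alternating parity
#' (odd epochs: 1-2, 3-4, ...; even epochs: 2-3, 4-5, ...) are attempted
#' with the Metropolis rule; accepted swaps exchange temperatures (not
#' coordinates) and rescale the two replicas' velocities by
#' sqrt(T_new / T_old).
#'
#' @param model a [build_construct()] model
#' @param schedule a [replica_schedule()]
#' @param seed RNG seed
#' @param thermo_rate Andersen thermostat rate (events/tu)
#' @param discard equilibration span (tu) flagged for exclusion
#' @param forcefield see [dmd_forcefield()]
#' @param ... passed to [dmd_system()]
#' @return a `replex_result`: per-replica `info` tibble (replica,
#'   temperature at save time, time, e_pot, e_kin, rg, equilibration),
#'   per-replica frame lists, and the `exchange_log` tibble
#' @export
run_replex <- function(model, schedule = replica_schedule(), seed = NULL,
                       thermo_rate = 1, discard = 500,
                       forcefield = dmd_forcefield(), ...) {
  stopifnot(inherits(schedule, "replica_schedule"))
  if (!is.null(seed)) set.seed(seed)
  sys <- dmd_system(model, forcefield = forcefield, ...)
  K <- length(schedule$temperatures)
  temps <- schedule$temperatures
  n_epochs <- schedule$duration / schedule$swap_interval

  reps <- lapply(seq_len(K), function(k) {
    list(pos = sys$positions,
         vel = maxwell_velocities(sys$topology$mass, temps[k]),
         temp = temps[k], epot = NA_real_)
  })

  info <- vector("list", K)
  frames <- lapply(seq_len(K), function(k) list())
  log_rows <- list()

  for (ep in seq_len(n_epochs)) {
    t0 <- (ep - 1) * schedule$swap_interval
    for (k in seq_len(K)) {
      res <- dmd_engine_cpp(reps[[k]]$pos, reps[[k]]$vel, sys$topology$mass,
                            sys$itype, sys$potentials, sys$box,
                            reps[[k]]$temp, schedule$swap_interval,
                            schedule$save_interval, thermo_rate, t0)
      reps[[k]]$pos <- res$pos
      reps[[k]]$vel <- res$vel
      reps[[k]]$epot <- res$epot_tracked
      info[[k]][[ep]] <- tibble::tibble(
        time = res$time, temperature = reps[[k]]$temp,
        e_pot = res$epot, e_kin = res$ekin, rg = res$rg)
      frames[[k]] <- c(frames[[k]], res$frames)
    }
    t_swap <- ep * schedule$swap_interval
    first <- if (ep %% 2 == 1) 1 else 2
    # replica currently holding the r-th highest temperature
    holder <- order(vapply(reps, `[[`, numeric(1), "temp"), decreasing = TRUE)
    pairs <- if (first > K - 1) integer(0) else seq(first, K - 1, by = 2)
    for (r in pairs) {
      i <- holder[r]; j <- holder[r + 1]    # adjacent in temperature
      u <- stats::runif(1)
      acc <- attempt_swap(reps[[i]]$epot, reps[[j]]$epot,
                          reps[[i]]$temp, reps[[j]]$temp, u)
      log_rows[[length(log_rows) + 1]] <- tibble::tibble(
        time = t_swap, rank_i = r, rank_j = r + 1,
        replica_i = i, replica_j = j,
        T_i = reps[[i]]$temp, T_j = reps[[j]]$temp,
        E_i = reps[[i]]$epot, E_j = reps[[j]]$epot,
        accepted = acc)
      if (acc) {
        Ti <- reps[[i]]$temp; Tj <- reps[[j]]$temp
        reps[[i]]$vel <- reps[[i]]$vel * sqrt(Tj / Ti)
        reps[[j]]$vel <- reps[[j]]$vel * sqrt(Ti / Tj)
        reps[[i]]$temp <- Tj
        reps[[j]]$temp <- Ti
      }
    }
  }

  info <- lapply(seq_len(K), function(k) {
    d <- dplyr::bind_rows(info[[k]])
    d$replica <- k
    d$equilibration <- d$time <= discard
    dplyr::relocate(d, "replica")
  })
  structure(list(
    info = dplyr::bind_rows(info),
    frames = frames,
    topology = sys$topology,
    schedule = schedule,
    exchange_log = dplyr::bind_rows(log_rows),
    params = list(seed = seed, thermo_rate = thermo_rate, discard = discard,
                  box = sys$box, forcefield = sys$forcefield),
    system = sys),
    class = "replex_result")
}

#' @export
print.replex_result <- function(x, ...) {
  acc <- if (nrow(x$exchange_log)) mean(x$exchange_log$accepted) else NA
  cat(sprintf(
    "<replex_result> %d replicas, %d frames total, swap acceptance %.2f\n",
    length(x$schedule$temperatures), nrow(x$info), acc))
  invisible(x)
}

#' Total number of saved frames across all replicas
#' @param x a `replex_result` or a `replica_schedule`
#' @return integer frame count (duration / save_interval per replica)
#' @export
n_saved_frames <- function(x) {
  s <- if (inherits(x, "replex_result")) x$schedule else x
  stopifnot(inherits(s, "replica_schedule"))
  length(s$temperatures) * (s$duration / s$save_interval)
}
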