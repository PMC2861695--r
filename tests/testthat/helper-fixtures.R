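# shared fixture builders; everything generated in code, nothing on disk

# an exact two-level density of states: E = 0 (degeneracy 1), E = eps (g)
two_level_dos <- function(eps = 1, g = 3) {
  list(centers = c(0, eps), log_omega = c(0, log(g)))
}

# closed-form Schottky heat capacity of the two-level system (k_B = 1)
schottky_cv <- function(Tt, eps = 1, g = 3) {
  r <- g * exp(-eps / Tt)
  (eps^2 / Tt^2) * r / (1 + r)^2
}

# dense time-stepping oracle for the next boundary crossing of a pair:
# scans |r + v t| across a fine time grid and returns the first bracketed
# crossing of any boundary, refined by bisection
stepping_next_event <- function(r, v, boundaries, t_max = 20, dt = 1e-4) {
  tt <- seq(0, t_max, by = dt)
  d <- sqrt((r[1] + v[1] * tt)^2 + (r[2] + v[2] * tt)^2 +
              (r[3] + v[3] * tt)^2)
  best <- NULL
  for (b in boundaries) {
    s <- sign(d - b)
    hit <- which(s[-1] != s[-length(s)] & s[-length(s)] != 0)
    if (length(hit) == 0) next
    i <- hit[1]
    lo <- tt[i]; hi <- tt[i + 1]
    f <- function(t) sqrt(sum((r + v * t)^2)) - b
    for (q in 1:60) {
      mid <- (lo + hi) / 2
      if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
    }
    t_cross <- (lo + hi) / 2
    if (is.null(best) || t_cross < best$time)
      best <- list(time = t_cross, boundary_distance = b)
  }
  best
}

# by-hand single linkage: connected components via repeated flood fill
flood_fill_components <- function(D, cutoff) {
  n <- nrow(D)
  comp <- integer(n)
  cur <- 0
  for (s in seq_len(n)) {
    if (comp[s] != 0) next
    cur <- cur + 1
    queue <- s
    while (length(queue) > 0) {
      i <- queue[1]; queue <- queue[-1]
      if (comp[i] != 0) next
      comp[i] <- cur
      nb <- which(D[i, ] < cutoff & comp == 0)
      queue <- c(queue, setdiff(nb, i))
    }
  }
  comp
}

# ideal-dihedral frames for profile tests
helix_frame <- function(n_res = 10) make_ideal_backbone("ALPHA", n_res)
strand_frame <- function(n_res = 10) make_ideal_backbone("BETA", n_res)
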