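#' Pipeline configuration
#'
#' Bundles every stage's parameters, with defaults mirroring the study
#' protocol (8 replica temperatures, 500 tu swap interval, 1e6 tu per
#' replica, 1 frame per 10 tu, 2 A clustering cutoff). Small smoke
#' configurations simply override the sizes.
#'
#' @param construct construct kind (`"QN"`, `"XN1"`, `"XN1_DP"`)
#' @param n polyQ repeat length
#' @param schedule a [replica_schedule()]
#' @param rg_cut,e_cut manual screening cutoff overrides (NULL = propose
#'   from histograms)
#' @param ppii report PPII separately in the secondary-structure profile
#' @param cluster_cutoff RMSD cutoff (Angstrom)
#' @param min_separation minimum time between clustered frames (tu;
#'   1000 tu = 50 ps)
#' @param subsample_target approximate number of structures to cluster
#' @param seed RNG seed
#' @param thermo_rate thermostat rate (events/tu)
#' @param discard equilibration discard (tu)
#' @param forcefield see [dmd_forcefield()]
#' @return a `run_config` list
#' @export
run_config <- function(construct = "XN1", n = 23,
                       schedule = replica_schedule(),
                       rg_cut = NULL, e_cut = NULL, ppii = FALSE,
                       cluster_cutoff = 2.0, min_separation = 1000,
                       subsample_target = 2000, seed = 1,
                       thermo_rate = 1, discard = 500,
                       forcefield = dmd_forcefield()) {
  construct <- match.arg(construct, .construct_kinds)
  if (!is.numeric(n) || n < 1) stop("invalid repeat length")
  stopifnot(inherits(schedule, "replica_schedule"))
  structure(list(construct = construct, n = n, schedule = schedule,
                 rg_cut = rg_cut, e_cut = e_cut, ppii = ppii,
                 cluster_cutoff = cluster_cutoff,
                 min_separation = min_separation,
                 subsample_target = subsample_target,
                 seed = seed, thermo_rate = thermo_rate, discard = discard,
                 forcefield = forcefield),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes build -> replica exchange -> WHAM heat capacity -> compact
#' screening -> secondary-structure profile -> RMSD clustering, and
#' returns every stage's result in one bundle. Identical config and seed
#' reproduce identical results.
#'
#' @param config a [run_config()]
#' @param out_dir optional directory for per-stage TSV/PDB outputs
#' @return a `pipeline_result` list: `model`, `replex`, `wham`,
#'   `heat_capacity`, `transition`, `screen` (histograms + cutoffs),
#'   `compact`, `ss_profile`, `region_summary`, `clustering`, `summary`
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  model <- build_construct(config$construct, config$n)
  rx <- run_replex(model, config$schedule, seed = config$seed,
                   thermo_rate = config$thermo_rate,
                   discard = config$discard,
                   forcefield = config$forcefield)
  prod <- dplyr::filter(rx$info, !rx$info$equilibration)

  # thermodynamics
  hists <- energy_histograms(prod)
  dos <- solve_wham(hists)
  tgrid <- seq(min(config$schedule$temperatures) * 0.8,
               max(config$schedule$temperatures) * 1.3, length.out = 200)
  cv <- heat_capacity(dos, tgrid)
  trans <- find_transition(cv)

  # compact screening
  rg_hist <- screen_histogram(prod$rg, "RG")
  e_hist <- screen_histogram(prod$e_pot, "ENERGY")
  rg_cut <- config$rg_cut %||% propose_rg_cutoff(rg_hist)
  e_cut <- config$e_cut %||%
    suppressWarnings(propose_energy_cutoff(prod$e_pot))
  # frame bookkeeping: row index within each replica's saved frames
  info_idx <- dplyr::ungroup(
    dplyr::mutate(dplyr::group_by(rx$info, .data$replica),
                  frame_idx = dplyr::row_number()))
  prod2 <- dplyr::filter(info_idx, !info_idx$equilibration)
  compact <- select_compact(prod2, rg_cut, e_cut)

  get_frames <- function(rows) {
    purrr::map2(rows$replica, rows$frame_idx,
                function(r, i) rx$frames[[r]][[i]])
  }

  # secondary structure over the compact ensemble
  n_events <- max(attr(compact, "n_events"), 1)
  ss <- NULL; region_summary <- NULL
  if (nrow(compact) > 0) {
    comp_frames <- get_frames(compact)
    ss <- ss_probability_profile(comp_frames, ppii = config$ppii,
                                 n_events = n_events)
    region_summary <- dplyr::bind_rows(lapply(model$regions$name, function(rn) {
      dplyr::bind_cols(tibble::tibble(region = rn),
                       region_average(ss, region_mask(model, rn)))
    }))
  }

  # clustering on a time-separated subsample of the compact ensemble
  clustering <- NULL
  if (nrow(compact) >= 2) {
    sub <- subsample_frames(compact, config$min_separation)
    if (nrow(sub) > config$subsample_target)
      sub <- sub[seq(1, nrow(sub),
                     length.out = config$subsample_target), , drop = FALSE]
    if (nrow(sub) >= 2) {
      ca <- which(rx$topology$role == "CA")
      D <- rmsd_matrix(get_frames(sub), atoms = ca)
      clustering <- single_linkage(D, config$cluster_cutoff)
    }
  }

  summary <- tibble::tibble(
    model = sprintf("%s_Q%d", config$construct, config$n),
    n_frames_total = nrow(rx$info),
    n_frames_production = nrow(prod),
    t_peak = trans$peak_temperature,
    t_peak_K = temperature_to_kelvin(trans$peak_temperature),
    c_v_peak = trans$peak_height,
    rg_cut = rg_cut, e_cut = e_cut,
    compact_fraction = attr(compact, "fraction"),
    n_events = attr(compact, "n_events"),
    n_clustered = if (is.null(clustering)) 0L else clustering$n,
    n_clusters = if (is.null(clustering)) NA_integer_
                 else length(clustering$clusters),
    largest_cluster_fraction = if (is.null(clustering)) NA_real_
                               else clustering$largest_fraction)

  res <- structure(list(
    config = config, model = model, replex = rx, wham = dos,
    heat_capacity = cv, transition = trans,
    screen = list(rg_hist = rg_hist, e_hist = e_hist,
                  rg_cut = rg_cut, e_cut = e_cut),
    compact = compact, ss_profile = ss, region_summary = region_summary,
    clustering = clustering, summary = summary),
    class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$summary)
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Emits per-stage TSVs (energy series, heat capacity, histograms,
#' secondary-structure profile, cluster table, summary) and the
#' representative structure as a single-model PDB.
#'
#' @param res a `pipeline_result`
#' @param out_dir output directory (created if missing)
#' @return `out_dir`, invisibly
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  w(res$replex$info, "energy_series.tsv")
  w(res$heat_capacity, "heat_capacity.tsv")
  w(res$screen$rg_hist, "rg_histogram.tsv")
  w(res$screen$e_hist, "energy_histogram.tsv")
  w(res$summary, "summary.tsv")
  if (!is.null(res$ss_profile)) w(res$ss_profile, "ss_profile.tsv")
  if (!is.null(res$region_summary)) w(res$region_summary, "ss_regions.tsv")
  if (!is.null(res$clustering)) {
    w(tidy(res$clustering), "clusters.tsv")
    rep_idx <- res$clustering$centroids[1]
    sub <- subsample_frames(res$compact, res$config$min_separation)
    if (nrow(sub) > res$config$subsample_target)
      sub <- sub[seq(1, nrow(sub),
                     length.out = res$config$subsample_target), , drop = FALSE]
    fr <- res$replex$frames[[sub$replica[rep_idx]]][[sub$frame_idx[rep_idx]]]
    write_multi_model_pdb(list(fr), res$replex$topology,
                          file.path(out_dir, "representative.pdb"))
  }
  invisible(out_dir)
}
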