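#' Read sequences from a FASTA file
#'
#' @param path FASTA file
#' @return tibble with columns `name`, `sequence`
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readAAStringSet(path)
    return(tibble::tibble(name = names(ss), sequence = as.character(ss)))
  }
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA headers in ", path)
  grp <- cumsum(hdr)
  tibble::tibble(
    name = sub("^>", "", lines[hdr]),
    sequence = vapply(split(lines[!hdr], grp[!hdr]),
                      paste0, character(1), collapse = ""))
}

#' Write sequences to a FASTA file
#'
#' @param x tibble with `name` and `sequence` columns (or a
#'   `construct_model`)
#' @param path output file
#' @param width line wrap width
#' @export
write_fasta <- function(x, path, width = 60) {
  if (inherits(x, "construct_model"))
    x <- tibble::tibble(name = sprintf("%s_n%d", x$kind, x$n_repeats),
                        sequence = x$sequence)
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(paste0(">", x$name[[i]]), con)
    s <- x$sequence[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL per saved frame; beads become ATOM records named by their
#' backbone role (N, CA, C). Coordinates are written at the fixed PDB
#' precision of 3 decimals.
#'
#' @param frames list of n x 3 coordinate matrices
#' @param topology tibble with columns `residue` (1-based) and `role`
#'   (one of "N", "CA", "C"); one row per bead
#' @param path output file
#' @param resname 3-letter residue names, recycled (default "GLY")
#' @export
write_multi_model_pdb <- function(frames, topology, path, resname = "GLN") {
  stopifnot(length(frames) >= 1)
  resname <- rep_len(resname, max(topology$residue))
  con <- file(path, "w"); on.exit(close(con))
  for (k in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", k), con)
    fr <- frames[[k]]
    if (nrow(fr) != nrow(topology)) stop("frame ", k, " does not match topology")
    lines <- sprintf(
      "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(nrow(fr)) %% 100000,
      topology$role,
      resname[topology$residue],
      topology$residue %% 10000,
      fr[, 1], fr[, 2], fr[, 3])
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB trajectory
#'
#' Parses the subset of PDB this package writes (MODEL / ATOM / ENDMDL).
#' Malformed records are reported with their line numbers.
#'
#' @param path PDB file
#' @return list with `frames` (list of n x 3 matrices) and `topology`
#'   (tibble: residue, role) taken from the first model
#' @export
read_multi_model_pdb <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty trajectory file: ", path)
  rec <- substr(lines, 1, 6)
  atom_idx <- which(rec == "ATOM  ")
  if (length(atom_idx) == 0) stop("no ATOM records in ", path)
  model_of <- cumsum(rec == "MODEL ")
  if (all(model_of[atom_idx] == 0)) model_of[atom_idx] <- 1  # single-model file
  x <- suppressWarnings(as.numeric(substr(lines[atom_idx], 31, 38)))
  y <- suppressWarnings(as.numeric(substr(lines[atom_idx], 39, 46)))
  z <- suppressWarnings(as.numeric(substr(lines[atom_idx], 47, 54)))
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0)
    stop("malformed ATOM coordinates at line(s) ",
         paste(utils::head(atom_idx[bad], 5), collapse = ", "))
  role <- trimws(substr(lines[atom_idx], 13, 16))
  resid <- suppressWarnings(as.integer(substr(lines[atom_idx], 23, 26)))
  mids <- model_of[atom_idx]
  frames <- lapply(split(seq_along(atom_idx), mids), function(ii) {
    m <- cbind(x = x[ii], y = y[ii], z = z[ii])
    m
  })
  first <- which(mids == mids[1])
  list(frames = unname(frames),
       topology = tibble::tibble(residue = resid[first], role = role[first]))
}

#' Write an energy/observable series as TSV
#'
#' @param series tibble with at least `time`; typically `time`, `e_pot`,
#'   `e_kin`, `rg`
#' @param path output file
#' @export
write_energy_series <- function(series, path) {
  utils::write.table(series, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an energy/observable series written by [write_energy_series()]
#' @param path TSV file
#' @return tibble
#' @export
read_energy_series <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t", check.names = FALSE))
}
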