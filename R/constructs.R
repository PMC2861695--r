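#' Polypeptide constructs
#'
#' Three constructs are modelled, each at glutamine repeat lengths
#' n = 23, 36, 40, 47 (12 models in total):
#'
#' * `QN` — an isolated polyglutamine homopolymer of n glutamines;
#' * `XN1` — huntingtin exon1: the 17 N-terminal residues (Nt17), the polyQ
#'   run of n glutamines, an 11-proline run (P11), a 17-residue tether, a
#'   10-proline run (P10) and a 12-residue C-terminus (n + 67 residues);
#' * `XN1_DP` — XN1 with both polyproline runs deleted seamlessly
#'   (n + 46 residues).
#'
#' Region indexing is 0-based half-open internally; report output is
#' 1-based.
#'
#' @name constructs
NULL

.construct_kinds <- c("QN", "XN1", "XN1_DP")
.region_names   <- c("NT17", "POLYQ", "P11", "TETHER17", "P10", "CTERM12")

#' Load the packaged huntingtin exon1 sequence fixture
#'
#' Reads the canonical first 90 residues of human huntingtin (the 23-Q
#' allele) from the packaged FASTA fixture and validates it against the
#' expected region lengths 17 (Nt17), 23 (polyQ), 11 (P11), 17 (tether),
#' 10 (P10) and 12 (C-terminus).
#'
#' @return a single amino-acid string of length 90
#' @export
htt_exon1_sequence <- function() {
  path <- system.file("extdata", "htt_exon1_first90.fasta", package = "polyqdmd")
  seqs <- read_fasta(path)
  s <- seqs$sequence[[1]]
  lens <- c(17, 23, 11, 17, 10, 12)
  stopifnot(nchar(s) == sum(lens))
  offs <- cumsum(c(0, lens))
  polyq  <- substr(s, offs[2] + 1, offs[3])
  p11    <- substr(s, offs[3] + 1, offs[4])
  p10    <- substr(s, offs[5] + 1, offs[6])
  if (polyq != strrep("Q", 23) || p11 != strrep("P", 11) || p10 != strrep("P", 10))
    stop("packaged exon1 fixture failed region validation")
  s
}

#' Build a polypeptide construct model
#'
#' Assembles the sequence and region map for one of the three constructs at
#' a given polyQ repeat length. The XN1 sequence is taken from the packaged
#' exon1 fixture with the polyQ run replaced by `n` glutamines; `XN1_DP`
#' additionally deletes the P11 and P10 runs seamlessly.
#'
#' @param kind one of `"QN"`, `"XN1"`, `"XN1_DP"`
#' @param n number of glutamine repeats (n >= 1); the study uses 23, 36,
#'   40 and 47
#' @return an object of class `construct_model`: a list with `kind`,
#'   `n_repeats`, `sequence` and a `regions` tibble
#'   (`name`, `start`, `end`; 0-based half-open)
#' @examples
#' build_construct("XN1", 23)   # 90 residues
#' build_construct("QN", 47)
#' @export
build_construct <- function(kind, n) {
  kind <- match.arg(kind, .construct_kinds)
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("n must be a positive integer repeat count")
  n <- as.integer(n)

  fix <- htt_exon1_sequence()
  nt17   <- substr(fix, 1, 17)
  p11    <- substr(fix, 41, 51)
  tether <- substr(fix, 52, 68)
  p10    <- substr(fix, 69, 78)
  cterm  <- substr(fix, 79, 90)
  polyq  <- strrep("Q", n)

  pieces <- switch(kind,
    QN     = list(POLYQ = polyq),
    XN1    = list(NT17 = nt17, POLYQ = polyq, P11 = p11,
                  TETHER17 = tether, P10 = p10, CTERM12 = cterm),
    XN1_DP = list(NT17 = nt17, POLYQ = polyq,
                  TETHER17 = tether, CTERM12 = cterm))

  lens <- vapply(pieces, nchar, integer(1))
  ends <- cumsum(lens)
  regions <- tibble::tibble(
    name  = names(pieces),
    start = as.integer(ends - lens),
    end   = as.integer(ends))

  structure(
    list(kind = kind, n_repeats = n,
         sequence = paste0(unlist(pieces), collapse = ""),
         regions = regions),
    class = "construct_model")
}

#' @export
print.construct_model <- function(x, ...) {
  cat(sprintf("<construct_model> %s, n = %d, %d residues\n",
              x$kind, x$n_repeats, nchar(x$sequence)))
  print(x$regions)
  invisible(x)
}

#' Residue index range of a named region
#'
#' @param model a `construct_model`
#' @param name region name (`"NT17"`, `"POLYQ"`, `"P11"`, `"TETHER17"`,
#'   `"P10"`, `"CTERM12"`)
#' @return integer vector `c(start, end)`, 0-based half-open
#' @export
region_mask <- function(model, name) {
  stopifnot(inherits(model, "construct_model"))
  name <- match.arg(name, .region_names)
  row <- model$regions[model$regions$name == name, ]
  if (nrow(row) == 0)
    stop(sprintf("region %s is absent from a %s construct", name, model$kind))
  c(start = row$start, end = row$end)
}

#' Residue positions (1-based) covered by a region
#' @param model a `construct_model`
#' @param name region name
#' @return integer vector of 1-based residue positions
#' @export
region_residues <- function(model, name) {
  m <- region_mask(model, name)
  seq.int(m[[1]] + 1L, m[[2]])
}
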