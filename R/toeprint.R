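# Ribosome toeprint stall prediction and electropherogram quantification.
#
# When reverse transcriptase runs into a stalled ribosome, the 3' end of the
# cDNA falls approximately 13 or 14 nt downstream of the first base of the
# ribosomal A-site; predictions therefore carry the offset pair {13, 14} and
# consumers use the union of the two windows.

.toeprint_offsets <- c(13L, 14L)

#' Construct an mRNA template for toeprint prediction
#'
#' @param sequence RNA (or DNA) string.
#' @param start_codon 0-based index of the first base of the start codon,
#'   which must be AUG.
#' @return object of class `mrna_template` with the in-frame codon list.
#' @export
mrna_template <- function(sequence, start_codon) {
  sequence <- chartr("T", "U", toupper(gsub("\\s", "", sequence)))
  if (grepl("[^ACGU]", sequence)) stop("non-nucleotide characters in mRNA")
  n <- nchar(sequence)
  if (n < start_codon + 3) stop("mRNA shorter than start codon + 3")
  if (substr(sequence, start_codon + 1, start_codon + 3) != "AUG")
    stop("no AUG at start_codon index ", start_codon)
  cds <- substr(sequence, start_codon + 1, n)
  rem <- nchar(cds) %% 3
  if (rem != 0) {
    warning("trailing ", rem, " nt truncated from the reading frame")
    cds <- substr(cds, 1, nchar(cds) - rem)
  }
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  structure(list(sequence = sequence, start_codon = as.integer(start_codon),
                 codons = codons),
            class = "mrna_template")
}

#' Predict the ribosome stall position for a set of depleted codons
#'
#' The first in-frame codon at or after the start codon that belongs to
#' `depleted_codons` becomes the A-site codon: with its cognate tRNA
#' depleted, the ribosome stalls awaiting delivery. The toeprint (cDNA 3'
#' end) is predicted 13-14 nt downstream of the A-site first base.
#'
#' @param mrna an [mrna_template()].
#' @param depleted_codons character vector of codons whose tRNAs are
#'   depleted (RNA alphabet).
#' @return list of class `stall_prediction`: `stall` flag, `codon_index`
#'   (codons from the start codon, 0-based), `codon`, `a_site` (0-based mRNA
#'   index of the A-site first base), `toeprint_positions` (A-site first
#'   base + 13 and + 14), `offsets`.
#' @export
predict_stall <- function(mrna, depleted_codons) {
  stopifnot(inherits(mrna, "mrna_template"))
  depleted_codons <- chartr("T", "U", toupper(depleted_codons))
  hit <- which(mrna$codons %in% depleted_codons)
  if (length(hit) == 0)
    return(structure(list(stall = FALSE, codon_index = NA_integer_,
                          codon = NA_character_, a_site = NA_integer_,
                          toeprint_positions = integer(0),
                          offsets = .toeprint_offsets),
                     class = "stall_prediction"))
  i <- hit[1] - 1L                       # codons from start, 0-based
  a_site <- mrna$start_codon + 3L * i
  structure(list(stall = TRUE, codon_index = i, codon = mrna$codons[hit[1]],
                 a_site = a_site,
                 toeprint_positions = a_site + .toeprint_offsets,
                 offsets = .toeprint_offsets),
            class = "stall_prediction")
}

#' @export
print.stall_prediction <- function(x, ...) {
  if (!x$stall) cat("stall_prediction: no stall\n")
  else cat(sprintf(
    "stall_prediction: codon %s (index %d), A-site first base %d, toeprint at %s\n",
    x$codon, x$codon_index, x$a_site,
    paste(x$toeprint_positions, collapse = "/")))
  invisible(x)
}

#' Initiation (start-codon) control toeprint
#'
#' The control reaction stalls initiating ribosomes at the start codon (as a
#' thiostrepton control does). Precise initiation geometry is deliberately
#' not modelled: the control prediction places the A-site first base at the
#' start codon index and applies the same 13/14 nt offsets, a documented
#' simplification that keeps start and elongation signals on one coordinate
#' rule.
#'
#' @param mrna an [mrna_template()].
#' @return a `stall_prediction` at the initiation codon.
#' @export
start_control <- function(mrna) {
  stopifnot(inherits(mrna, "mrna_template"))
  structure(list(stall = TRUE, codon_index = 0L, codon = mrna$codons[1],
                 a_site = mrna$start_codon,
                 toeprint_positions = mrna$start_codon + .toeprint_offsets,
                 offsets = .toeprint_offsets),
            class = "stall_prediction")
}

#' Signal windows around predicted toeprint positions
#'
#' @param prediction a `stall_prediction`.
#' @param slack half-width added around the 13-14 nt offset pair (default 2).
#' @return named list with one `c(lo, hi)` window covering the offset union.
#' @export
stall_windows <- function(prediction, slack = 2) {
  if (!prediction$stall) return(list())
  tp <- prediction$toeprint_positions
  stats::setNames(list(c(min(tp) - slack, max(tp) + slack)),
                  paste0("codon_", prediction$codon))
}

#' Area under an electropherogram trace within named windows
#'
#' Integrates a piecewise-linear (capillary electropherogram) trace by the
#' trapezoid rule within each window, interpolating at window edges.
#'
#' @param trace data.frame with columns `position` (sorted ascending) and
#'   `intensity`.
#' @param windows named list of `c(lo, hi)` position intervals (e.g. from
#'   [stall_windows()]).
#' @return named numeric vector of areas.
#' @export
quantify_peaks <- function(trace, windows) {
  if (nrow(trace) == 0) stop("empty trace")
  x <- trace$position
  y <- trace$intensity
  if (is.unsorted(x)) stop("trace positions must be sorted")
  vapply(windows, function(w) {
    lo <- max(w[1], min(x)); hi <- min(w[2], max(x))
    if (hi <= lo) return(0)
    xs <- sort(unique(c(lo, hi, x[x > lo & x < hi])))
    ys <- stats::approx(x, y, xout = xs)$y
    sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  }, numeric(1))
}

#' Reconstructed all-codon toeprint template
#'
#' A short reconstructed mRNA (clearly a stand-in, not the published
#' template) arranged as the toeprint experiment requires: AUG start, a
#' lysine AAA codon at codon index 5, a downstream threonine ACA codon at
#' index 8, alanine codons, and a stop. The `"k5a"` variant replaces AAA
#' with the alanine codon GCA; `"k5a_t8a"` additionally replaces ACA with
#' GCA, so that depleting lysine and threonine tRNAs moves or removes the
#' predicted stall accordingly.
#'
#' @param variant `"wt"`, `"k5a"` or `"k5a_t8a"`.
#' @return an [mrna_template()] (5' UTR of 10 nt; start codon at index 10).
#' @export
toeprint_template <- function(variant = c("wt", "k5a", "k5a_t8a")) {
  variant <- match.arg(variant)
  codons <- c("AUG", "ACC", "GGU", "UUC", "GAA", "AAA",
              "CGU", "GAU", "ACA", "GCU", "GCA", "UAA")
  if (variant %in% c("k5a", "k5a_t8a")) codons[6] <- "GCA"
  if (variant == "k5a_t8a") codons[9] <- "GCA"
  utr5 <- "GGAGGAUACC"
  utr3 <- "CAAUUGGAAUUCGCA"   # in frame with the CDS so no truncation
  mrna_template(paste0(utr5, paste(codons, collapse = ""), utr3),
                start_codon = nchar(utr5))
}
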