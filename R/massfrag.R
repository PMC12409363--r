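# In-silico RNase T1 digestion and average-mass MH+ prediction.
#
# Masses are average (not monoisotopic) throughout by default, matching
# linear-mode MALDI-TOF measurement of average MH+ molecular ions; a
# monoisotopic mode is exposed. The neutral mass of an oligo with 5'-P/3'-OH
# termini is the sum of nucleoside-5'-monophosphate masses minus (n-1)
# waters; other terminal chemistries are adjustments relative to that
# baseline.

.avg_atomic <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                 P = 30.973762)
.mono_atomic <- c(H = 1.0078250319, C = 12.0, N = 14.0030740052,
                  O = 15.9949146221, P = 30.97376151)

# nucleoside-5'-monophosphate elemental compositions
.nmp_formula <- list(
  A = c(C = 10, H = 14, N = 5, O = 7, P = 1),
  C = c(C = 9,  H = 14, N = 3, O = 8, P = 1),
  G = c(C = 10, H = 14, N = 5, O = 8, P = 1),
  U = c(C = 9,  H = 13, N = 2, O = 9, P = 1)
)

.formula_mass <- function(formula, atomic) {
  sum(atomic[names(formula)] * formula)
}

.mass_tables <- function(monoisotopic = FALSE) {
  at <- if (monoisotopic) .mono_atomic else .avg_atomic
  list(
    nmp = vapply(.nmp_formula, .formula_mass, numeric(1), atomic = at),
    h2o = .formula_mass(c(H = 2, O = 1), at),
    hpo3 = .formula_mass(c(H = 1, P = 1, O = 3), at),
    h = at[["H"]]
  )
}

#' Construct an RNA oligonucleotide with explicit terminal chemistries
#'
#' @param sequence RNA string over A, C, G, U (T transliterated).
#' @param five_prime 5' terminus: `"OH"`, `"P"` (monophosphate) or `"PPP"`
#'   (triphosphate).
#' @param three_prime 3' terminus: `"OH"`, `"P"` (linear phosphate) or
#'   `"cP"` (2',3'-cyclic phosphate).
#' @param mod_deltas numeric vector of average-mass deltas in Da, optionally
#'   named by 1-based position within the oligo.
#' @return object of class `oligo`.
#' @export
oligo <- function(sequence, five_prime = c("P", "OH", "PPP"),
                  three_prime = c("OH", "P", "cP"), mod_deltas = numeric(0)) {
  five_prime <- match.arg(five_prime)
  three_prime <- match.arg(three_prime)
  sequence <- chartr("T", "U", toupper(sequence))
  if (nchar(sequence) == 0) stop("empty oligo")
  if (grepl("[^ACGU]", sequence))
    stop("unknown residue in oligo sequence")
  if (any(!is.finite(mod_deltas))) stop("mod_deltas must be finite")
  structure(list(sequence = sequence, five_prime = five_prime,
                 three_prime = three_prime, mod_deltas = mod_deltas),
            class = "oligo")
}

#' Neutral average mass of an RNA oligo
#'
#' Sum of residue (nucleoside-5'-monophosphate) masses minus (n-1) waters
#' for the 5'-phosphate/3'-OH baseline, adjusted for the terminal
#' chemistries (5'-OH: -HPO3; 5'-PPP: +2 HPO3; 3'-P: +HPO3; 3'-cP: +HPO3 -
#' H2O) plus any modification mass deltas.
#'
#' @param x an [oligo()].
#' @param monoisotopic use monoisotopic atomic masses (default `FALSE`,
#'   average masses).
#' @return neutral mass in Da.
#' @export
average_mass <- function(x, monoisotopic = FALSE) {
  stopifnot(inherits(x, "oligo"))
  mt <- .mass_tables(monoisotopic)
  res <- strsplit(x$sequence, "")[[1]]
  n <- length(res)
  m <- sum(mt$nmp[res]) - (n - 1) * mt$h2o
  m <- m + switch(x$five_prime, P = 0, OH = -mt$hpo3, PPP = 2 * mt$hpo3)
  m <- m + switch(x$three_prime, OH = 0, P = mt$hpo3, cP = mt$hpo3 - mt$h2o)
  m + sum(x$mod_deltas)
}

#' Average MH+ (singly protonated molecular ion) of an oligo
#'
#' @inheritParams average_mass
#' @return MH+ mass in Da (neutral mass + mass of H).
#' @export
mh_plus <- function(x, monoisotopic = FALSE) {
  average_mass(x, monoisotopic) + .mass_tables(monoisotopic)$h
}

#' In-silico RNase T1 digestion of a tRNA
#'
#' RNase T1 cleaves 3' of every guanosine, leaving a 3'-phosphate (linear by
#' default; 2',3'-cyclic with `cyclic = TRUE`) on the upstream product and a
#' 5'-OH on the downstream product. Nuclease nicks (e.g. the AriB nick
#' between canonical positions 40 and 41) instead leave 3'-OH upstream and
#' 5'-phosphate downstream, the signature of a two-metal-ion nuclease.
#' Molecule termini keep the configured chemistries (5'-triphosphate for
#' transcripts, 3'-OH, by default). Modified residues contribute mass deltas
#' from the modification table; in-vitro transcripts carry none, so leave
#' `mods = NULL` for transcript digests.
#'
#' @param record a `trna_record`.
#' @param nicks list of length-2 character vectors of adjacent canonical
#'   labels (or a single such vector), e.g. `c("40", "41")`; `NULL` for an
#'   intact molecule.
#' @param mods optional `modification_table`; rows for this tRNA with finite
#'   deltas are applied.
#' @param cyclic leave T1 products with 2',3'-cyclic phosphate (default
#'   `FALSE`, linear 3'-phosphate).
#' @param five_prime,three_prime chemistries of the parent molecule termini.
#' @param monoisotopic passed to the mass computation.
#' @return data.frame of class `digest_products`: `trna_id`, `start_label`,
#'   `end_label`, `sequence`, `five_prime`, `three_prime`, `left_src`,
#'   `right_src` (molecule end / T1 cut / nick), `length`, `neutral_mass`,
#'   `mh_plus`. Products tile the parent sequence in order.
#' @export
digest_t1 <- function(record, nicks = NULL, mods = NULL, cyclic = FALSE,
                      five_prime = "PPP", three_prime = "OH",
                      monoisotopic = FALSE) {
  seq_ch <- strsplit(record$sequence, "")[[1]]
  n <- length(seq_ch)
  t1_after <- which(seq_ch == "G")
  t1_after <- t1_after[t1_after < n]   # a 3'-terminal G has nothing to cut off
  if (!is.null(nicks) && !is.list(nicks)) nicks <- list(nicks)
  nick_after <- integer(0)
  for (nk in nicks) {
    i5 <- canonical_to_index(record, nk[1])
    i3 <- canonical_to_index(record, nk[2])
    if (i3 != i5 + 1L)
      stop("nick labels ", nk[1], "|", nk[2], " not adjacent in ", record$id)
    nick_after <- c(nick_after, i5)
  }
  # a junction that is both a T1 cut and a nick takes the nick chemistry
  t1_after <- setdiff(t1_after, nick_after)
  cuts <- sort(unique(c(t1_after, nick_after)))
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  src <- ifelse(cuts %in% nick_after, "nick", "T1")

  deltas_at <- numeric(n)
  if (!is.null(mods)) {
    m <- mods[mods$trna_id == record$id & is.finite(mods$mass_delta_avg_da), ,
              drop = FALSE]
    if (nrow(m) > 0) {
      idx <- match(m$position_label, record$numbering)
      ok <- !is.na(idx)
      deltas_at[idx[ok]] <- m$mass_delta_avg_da[ok]
    }
  }

  rows <- lapply(seq_along(starts), function(i) {
    a <- starts[i]; b <- ends[i]
    left <- if (i == 1L) "molecule" else src[i - 1L]
    right <- if (i == length(starts)) "molecule" else src[i]
    fp <- switch(left, molecule = five_prime, T1 = "OH", nick = "P")
    tp <- switch(right, molecule = three_prime,
                 T1 = if (cyclic) "cP" else "P", nick = "OH")
    dts <- deltas_at[a:b]
    ol <- oligo(paste(seq_ch[a:b], collapse = ""), five_prime = fp,
                three_prime = tp,
                mod_deltas = stats::setNames(dts[dts != 0],
                                             which(dts != 0)))
    data.frame(trna_id = record$id,
               start_label = record$numbering[a],
               end_label = record$numbering[b],
               sequence = ol$sequence, five_prime = fp, three_prime = tp,
               left_src = left, right_src = right,
               length = b - a + 1L,
               neutral_mass = average_mass(ol, monoisotopic),
               mh_plus = mh_plus(ol, monoisotopic),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("digest_products", "data.frame")
  out
}

#' Diagnostic mass signature of a nick inside one T1 product
#'
#' Returns the T1 product that spans the nick in the intact molecule (the
#' species present only if the molecule is uncut) together with the two
#' sub-products the nick generates (present only if cut: upstream 3'-OH,
#' downstream 5'-P), each with its predicted MH+. For the reconstructed
#' E. coli tRNA-Lys(UUU) transcript and the 40|41 nick the spanning product
#' is 14 nt.
#'
#' @inheritParams digest_t1
#' @param nick length-2 character vector of adjacent canonical labels.
#' @return list with `spanning` (1-row data.frame) and `nicked` (2-row
#'   data.frame).
#' @export
nick_signature <- function(record, nick, mods = NULL, cyclic = FALSE,
                           five_prime = "PPP", three_prime = "OH",
                           monoisotopic = FALSE) {
  i5 <- canonical_to_index(record, nick[1])
  seq_ch <- strsplit(record$sequence, "")[[1]]
  if (seq_ch[i5] == "G")
    stop("nick ", nick[1], "|", nick[2], " coincides with a T1 cut in ",
         record$id)
  intact <- digest_t1(record, nicks = NULL, mods = mods, cyclic = cyclic,
                      five_prime = five_prime, three_prime = three_prime,
                      monoisotopic = monoisotopic)
  cut <- digest_t1(record, nicks = list(nick), mods = mods, cyclic = cyclic,
                   five_prime = five_prime, three_prime = three_prime,
                   monoisotopic = monoisotopic)
  pos5 <- canonical_to_index(record, nick[1])
  pos3 <- canonical_to_index(record, nick[2])
  idx_of <- function(d) {
    a <- match(d$start_label, record$numbering)
    b <- match(d$end_label, record$numbering)
    cbind(a, b)
  }
  ii <- idx_of(intact)
  span <- intact[ii[, 1] <= pos5 & ii[, 2] >= pos3, , drop = FALSE]
  ic <- idx_of(cut)
  nicked <- cut[ic[, 2] == pos5 | ic[, 1] == pos3, , drop = FALSE]
  list(spanning = span, nicked = nicked)
}

#' Match observed MALDI peaks to predicted digest products
#'
#' Each observed m/z is matched to the nearest predicted MH+ within the
#' tolerance (default 1 Da, the stated accuracy of average-mass peak
#' measurement in linear mode). Peaks with two or more predictions within
#' tolerance are flagged ambiguous; unmatched peaks are reported with `NA`
#' identity.
#'
#' @param predicted `digest_products` data.frame.
#' @param observed numeric vector of observed m/z values, or a data.frame
#'   with an `mz` column (see [read_peak_list()]).
#' @param tol matching tolerance in Da (default 1.0).
#' @return data.frame of class `peak_matches`: `observed_mz`,
#'   `predicted_mh`, `delta`, `product` (sequence), `start_label`,
#'   `end_label`, `ambiguous`, `matched`.
#' @export
match_peaks <- function(predicted, observed, tol = 1.0) {
  if (tol <= 0) stop("tol must be > 0")
  if (is.data.frame(observed)) observed <- observed$mz
  rows <- lapply(observed, function(mz) {
    d <- abs(predicted$mh_plus - mz)
    within <- which(d <= tol)
    if (length(within) == 0)
      return(data.frame(observed_mz = mz, predicted_mh = NA_real_,
                        delta = NA_real_, product = NA_character_,
                        start_label = NA_character_,
                        end_label = NA_character_,
                        ambiguous = FALSE, matched = FALSE,
                        stringsAsFactors = FALSE))
    j <- within[which.min(d[within])]
    data.frame(observed_mz = mz, predicted_mh = predicted$mh_plus[j],
               delta = mz - predicted$mh_plus[j],
               product = predicted$sequence[j],
               start_label = predicted$start_label[j],
               end_label = predicted$end_label[j],
               ambiguous = length(within) > 1, matched = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("peak_matches", "data.frame")
  out
}

#' Read an observed MALDI peak list
#' @param path CSV file with a column `mz`.
#' @return data.frame with column `mz`.
#' @export
read_peak_list <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"mz" %in% names(tab)) stop("peak list needs a column 'mz'")
  tab
}
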