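# Ground-truthed small-RNA read simulation under two library protocols.
#
# Protocol A emulates a cDNA-adapter library: apparent read 5' ends reflect
# reverse-transcriptase stalls at modified positions, so truncated cDNAs are
# sequenced at full depth. Protocol B emulates an RNA-end-ligated library:
# read 5' ends are true RNA 5' ends and only fully reverse-transcribed
# molecules are amplified.

#' Specification of a simulated tRNA pool
#'
#' @param abundance named positive weights, one per tRNA id (fixed, not
#'   resampled, so expected counts are analytic).
#' @param nick_sites data.frame with columns `trna_id`, `site5`, `site3`
#'   (adjacent canonical labels flanking the nick, e.g. `"40"`, `"41"`) and
#'   `prob` in `[0,1]`; or `NULL` for no nicking.
#' @param stall_prob probability that reverse transcription terminates
#'   immediately 3' of a modified position (protocol A only). Either a single
#'   number applied to every modified position or a named vector by
#'   modification name.
#' @param protocol `"A"` (RT-stall-visible, 150 nt paired default) or
#'   `"B"` (RNA-end-ligated, 50 nt single default).
#' @param error_rate per-base substitution probability.
#' @param read_length read length in nt; default 150 (A) / 50 (B).
#' @param paired emit mate 2; default `TRUE` for protocol A, `FALSE` for B.
#' @param n_reads number of reads to emit.
#' @param seed integer seed; all randomness in [simulate_pool()] derives from
#'   it.
#' @return list of class `pool_spec`.
#' @export
pool_spec <- function(abundance, nick_sites = NULL, stall_prob = 0.5,
                      protocol = c("B", "A"), error_rate = 0.001,
                      read_length = NULL, paired = NULL,
                      n_reads = 10000L, seed = 1L) {
  protocol <- match.arg(protocol)
  if (is.null(names(abundance)) || any(abundance <= 0))
    stop("abundance must be named positive weights")
  if (!is.null(nick_sites)) {
    stopifnot(all(c("trna_id", "site5", "site3", "prob") %in%
                    names(nick_sites)))
    if (any(nick_sites$prob < 0 | nick_sites$prob > 1))
      stop("nick probabilities must be in [0,1]")
  }
  if (any(stall_prob < 0 | stall_prob > 1))
    stop("stall_prob must be in [0,1]")
  if (n_reads < 0) stop("n_reads must be >= 0")
  if (is.null(read_length))
    read_length <- if (protocol == "A") 150L else 50L
  if (is.null(paired)) paired <- protocol == "A"
  structure(list(abundance = abundance, nick_sites = nick_sites,
                 stall_prob = stall_prob, protocol = protocol,
                 error_rate = error_rate, read_length = as.integer(read_length),
                 paired = paired, n_reads = as.integer(n_reads),
                 seed = as.integer(seed)),
            class = "pool_spec")
}

#' Simulate nicking of one tRNA molecule
#'
#' With probability `p` the molecule is cut between two adjacent canonical
#' positions, yielding a 5' and a 3' fragment whose lengths sum to the parent
#' length; otherwise it stays intact.
#'
#' @param record a `trna_record`.
#' @param site length-2 character vector of adjacent canonical labels, e.g.
#'   `c("40", "41")`.
#' @param p nick probability.
#' @return list with `nicked` flag and one (`intact`) or two (`frag5`,
#'   `frag3`) fragments, each a list of `start`, `end` (1-based, inclusive).
#' @export
simulate_cleavage <- function(record, site, p) {
  i5 <- canonical_to_index(record, site[1])
  i3 <- canonical_to_index(record, site[2])
  if (i3 != i5 + 1L)
    stop("nick site labels ", site[1], "|", site[2],
         " are not adjacent in ", record$id)
  n <- nchar(record$sequence)
  if (stats::runif(1) < p) {
    list(nicked = TRUE,
         frag5 = list(start = 1L, end = i5),
         frag3 = list(start = i3, end = n))
  } else {
    list(nicked = FALSE, intact = list(start = 1L, end = n))
  }
}

# Stall point for protocol A: scan modified positions 3'->5' from the
# fragment 3' end; the first that fires truncates the cDNA immediately 3' of
# it. Returns the interval start index after stalling.
.stall_start <- function(frag_start, frag_end, mod_idx, mod_names, stall_prob) {
  within <- mod_idx >= frag_start & mod_idx < frag_end
  idx <- mod_idx[within]
  nm <- mod_names[within]
  if (length(idx) == 0) return(frag_start)
  ord <- order(idx, decreasing = TRUE)
  idx <- idx[ord]; nm <- nm[ord]
  p <- if (is.null(names(stall_prob))) rep(stall_prob[1], length(idx))
       else ifelse(nm %in% names(stall_prob), stall_prob[nm], 0)
  fire <- stats::runif(length(idx)) < p
  if (any(fire)) idx[which(fire)[1]] + 1L else frag_start
}

#' Simulate sequencing of one RNA fragment
#'
#' Protocol B reads start at the fragment's true 5' end. Protocol A reads
#' start at the reverse-transcriptase stall point: scanning modified
#' positions from the fragment 3' end towards 5', the first that fires under
#' `stall_prob` truncates the apparent molecule immediately 3' of itself.
#' The interval is then truncated to the read length and substitution errors
#' applied.
#'
#' @param record a `trna_record`.
#' @param fragment list with `start`, `end` (1-based inclusive interval).
#' @param spec a [pool_spec()].
#' @param mods optional `modification_table` (protocol A stalling).
#' @return list with `start`, `end` of the sequenced interval on the tRNA and
#'   `seq`, the read sequence (RNA alphabet, errors applied); `NULL` for a
#'   degenerate empty interval.
#' @export
simulate_read <- function(record, fragment, spec, mods = NULL) {
  start <- fragment$start
  end <- fragment$end
  if (end < start) return(NULL)
  if (spec$protocol == "A" && !is.null(mods)) {
    m <- mods[mods$trna_id == record$id, , drop = FALSE]
    if (nrow(m) > 0) {
      idx <- match(m$position_label, record$numbering)
      keep <- !is.na(idx)
      start <- .stall_start(start, end, idx[keep], m$mod_name[keep],
                            spec$stall_prob)
    }
  }
  end_seq <- min(end, start + spec$read_length - 1L)
  s <- substr(record$sequence, start, end_seq)
  s <- .apply_errors(s, spec$error_rate)
  list(start = start, end = end_seq, seq = s)
}

.other_bases <- list(A = c("C", "G", "U"), C = c("A", "G", "U"),
                     G = c("A", "C", "U"), U = c("A", "C", "G"))

.apply_errors <- function(s, rate) {
  if (rate <= 0) return(s)
  n <- nchar(s)
  k <- stats::rbinom(1, n, rate)
  if (k == 0) return(s)
  pos <- sample.int(n, k)
  ch <- strsplit(s, "")[[1]]
  for (p in pos) ch[p] <- sample(.other_bases[[ch[p]]], 1)
  paste(ch, collapse = "")
}

#' Simulate a sequencing run over a tRNA pool
#'
#' Samples `n_reads` molecules from the pool with the spec's fixed abundance
#' weights, applies per-tRNA nicking, picks one fragment per nicked molecule
#' (5' or 3', equiprobable), sequences it under the protocol model, and
#' returns reads plus a per-read ground-truth table. With `out_prefix` set,
#' FASTQ (Phred+33, constant quality "I", DNA alphabet) and a truth TSV are
#' written; identical spec and seed give byte-identical files.
#'
#' @param spec a [pool_spec()].
#' @param references a `trna_set` covering every id in the spec.
#' @param mods optional `modification_table` for protocol A stalling.
#' @param out_prefix optional path prefix for `<prefix>_R1.fastq`
#'   (`_R2.fastq` when paired) and `<prefix>_truth.tsv`.
#' @return list with `reads` (named character vector, read 1, RNA alphabet),
#'   `reads2` (mate 2 or `NULL`) and `truth` (data.frame: read_id, trna_id,
#'   frag_start/frag_end in canonical labels, nick, stall).
#' @export
simulate_pool <- function(spec, references, mods = NULL, out_prefix = NULL) {
  stopifnot(inherits(spec, "pool_spec"))
  ids <- names(spec$abundance)
  missing_ids <- setdiff(ids, names(references))
  if (length(missing_ids))
    stop("unknown trna_id(s) in spec: ", paste(missing_ids, collapse = ", "))
  if (!is.null(spec$nick_sites)) {
    bad <- setdiff(spec$nick_sites$trna_id, ids)
    if (length(bad))
      stop("unknown trna_id(s) in nick_sites: ", paste(bad, collapse = ", "))
  }

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)

  n <- spec$n_reads
  empty_truth <- data.frame(read_id = character(0), trna_id = character(0),
                            frag_start = character(0), frag_end = character(0),
                            nick = character(0), stall = character(0),
                            stringsAsFactors = FALSE)
  if (n == 0) {
    out <- list(reads = stats::setNames(character(0), character(0)),
                reads2 = NULL, truth = empty_truth)
    if (!is.null(out_prefix)) .write_pool(out, spec, out_prefix)
    return(out)
  }

  pick <- sample(ids, n, replace = TRUE, prob = spec$abundance)
  nick_p <- stats::setNames(numeric(length(ids)), ids)
  nick_lab <- stats::setNames(vector("list", length(ids)), ids)
  if (!is.null(spec$nick_sites)) {
    for (i in seq_len(nrow(spec$nick_sites))) {
      id <- spec$nick_sites$trna_id[i]
      nick_p[id] <- spec$nick_sites$prob[i]
      nick_lab[[id]] <- c(spec$nick_sites$site5[i], spec$nick_sites$site3[i])
    }
  }

  read_id <- sprintf("read%06d", seq_len(n))
  seqs <- character(n); seqs2 <- character(n)
  t_tr <- pick
  t_fs <- character(n); t_fe <- character(n)
  t_nick <- rep("none", n); t_stall <- rep("none", n)
  keep <- rep(TRUE, n)

  for (i in seq_len(n)) {
    rec <- references[[pick[i]]]
    p <- nick_p[[pick[i]]]
    if (p > 0) {
      cl <- simulate_cleavage(rec, nick_lab[[pick[i]]], p)
    } else {
      cl <- list(nicked = FALSE,
                 intact = list(start = 1L, end = nchar(rec$sequence)))
    }
    if (cl$nicked) {
      frag <- if (stats::runif(1) < 0.5) cl$frag5 else cl$frag3
      t_nick[i] <- paste0(nick_lab[[pick[i]]][1], "|", nick_lab[[pick[i]]][2])
    } else {
      frag <- cl$intact
    }
    rd <- simulate_read(rec, frag, spec, mods)
    if (is.null(rd) || nchar(rd$seq) == 0) { keep[i] <- FALSE; next }
    if (rd$start > frag$start)
      t_stall[i] <- index_to_canonical(rec, rd$start - 1L)
    seqs[i] <- rd$seq
    t_fs[i] <- index_to_canonical(rec, rd$start)
    t_fe[i] <- index_to_canonical(rec, rd$end)
    if (spec$paired) {
      m2_start <- max(frag$start, frag$end - spec$read_length + 1L)
      seqs2[i] <- .revcomp_rna(substr(rec$sequence, m2_start, frag$end))
    }
  }

  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " degenerate read(s) dropped")
  truth <- data.frame(read_id = read_id[keep], trna_id = t_tr[keep],
                      frag_start = t_fs[keep], frag_end = t_fe[keep],
                      nick = t_nick[keep], stall = t_stall[keep],
                      stringsAsFactors = FALSE)
  out <- list(reads = stats::setNames(seqs[keep], read_id[keep]),
              reads2 = if (spec$paired)
                stats::setNames(seqs2[keep], read_id[keep]) else NULL,
              truth = truth)
  if (!is.null(out_prefix)) .write_pool(out, spec, out_prefix)
  out
}

.revcomp_rna <- function(s) {
  chartr("ACGU", "UGCA",
         vapply(s, function(x)
           paste(rev(strsplit(x, "")[[1]]), collapse = ""), character(1),
           USE.NAMES = FALSE))
}

.write_pool <- function(out, spec, out_prefix) {
  write_fastq(out$reads, paste0(out_prefix, "_R1.fastq"))
  if (!is.null(out$reads2))
    write_fastq(out$reads2, paste0(out_prefix, "_R2.fastq"))
  utils::write.table(out$truth, paste0(out_prefix, "_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_prefix)
}

#' Write reads to FASTQ
#'
#' Sequences are written in the DNA alphabet (U transliterated to T) with a
#' constant Phred+33 quality of "I", matching pre-trimmed simulator output.
#'
#' @param reads named character vector (names become read ids).
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  if (length(reads) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  dna <- chartr("U", "T", reads)
  qual <- strrep("I", nchar(dna))
  writeLines(as.vector(rbind(paste0("@", names(reads)), dna, "+", qual)), path)
  invisible(path)
}

#' Read a FASTQ file into a named character vector (RNA alphabet)
#' @param path FASTQ file.
#' @return named character vector of read sequences with T transliterated to
#'   U.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) return(stats::setNames(character(0), character(0)))
  if (length(lines) %% 4 != 0) stop("truncated FASTQ: ", path)
  ids <- sub("^@", "", sub("\\s.*$", "", lines[seq(1, length(lines), 4)]))
  seqs <- chartr("T", "U", toupper(lines[seq(2, length(lines), 4)]))
  stats::setNames(seqs, ids)
}

#' Generate decoy tRNA references
#'
#' Random tRNA-like 76-nt sequences (G at position 1, NCCA 3' end, random
#' anticodon) used to pad reference pools for power analyses. Sequences whose
#' 36-41 hexamer is within one mismatch of the nuclease consensus are
#' rejected so decoys are genuine negatives.
#'
#' @param n number of decoys.
#' @param seed integer seed.
#' @param consensus hexamer to avoid, default `"UAAUCA"`.
#' @return a `trna_set` of records named `Dec-01`, `Dec-02`, ...
#' @export
decoy_trnas <- function(n, seed = 1L, consensus = "UAAUCA") {
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  bases <- c("A", "C", "G", "U")
  cons <- strsplit(consensus, "")[[1]]
  recs <- list()
  while (length(recs) < n) {
    body <- sample(bases, 72, replace = TRUE)
    s <- paste0("G", paste(body, collapse = ""), "CCA")
    hex <- strsplit(substr(s, 36, 41), "")[[1]]
    if (sum(hex != cons) <= 1) next
    id <- sprintf("Dec-%02d", length(recs) + 1L)
    recs[[id]] <- trna_record(id, s, source = "host")
  }
  structure(recs, class = "trna_set")
}
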