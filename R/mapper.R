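# Built-in read mapper: exact k-mer seed index + ungapped extension.
#
# tRNA references are short (~76 nt), so the load-bearing behaviour is the
# uniqueness semantics, not gapped alignment. Seeds are taken at
# (max_mismatch + 1) disjoint offsets with k = floor(L / (max_mismatch + 1))
# (capped at 20), so by pigeonhole every placement with <= max_mismatch
# substitutions has at least one exact seed: the mapper is equivalent to a
# brute-force scan over all placements.

.kmer_index <- function(refs, k) {
  idx <- list()
  for (id in names(refs)) {
    s <- refs[[id]]
    n <- nchar(s)
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    for (j in seq_along(kmers)) {
      idx[[kmers[j]]] <- c(idx[[kmers[j]]], list(c(id = id, pos = starts[j])))
    }
  }
  idx
}

.count_mm <- function(read_chars, ref_chars, pos, L) {
  sum(read_chars != ref_chars[pos:(pos + L - 1L)])
}

#' Map reads to tRNA references
#'
#' Each read is placed at its best-scoring (fewest-mismatch) ungapped
#' location over all references; reads whose best score is tied across
#' distinct tRNAs are dropped when `unique_only = TRUE` (the uniqueness rule
#' used for tRNA-seq scatter analyses). Ties within one tRNA keep the
#' leftmost placement. Reads are assumed sense-strand: the two library
#' protocols are directional.
#'
#' @param reads named character vector of read sequences, or a FASTQ path.
#' @param references a `trna_set` or named character vector of sequences.
#' @param max_mismatch maximum substitutions allowed (default 2; no indels).
#' @param unique_only drop reads with tied best placements across distinct
#'   tRNAs (default `TRUE`).
#' @param min_read_len reads shorter than this are left unmapped (default
#'   15 nt).
#' @return data.frame of alignment records: `read_id`, `trna_id`, `start`,
#'   `end` (0-based half-open on the tRNA), `n_mismatches`, `unique`.
#' @export
map_reads <- function(reads, references, max_mismatch = 2L,
                      unique_only = TRUE, min_read_len = 15L) {
  refs <- reference_sequences(references)
  if (length(refs) == 0) stop("empty reference set")
  if (is.character(reads) && length(reads) == 1 && is.null(names(reads)) &&
      file.exists(reads))
    reads <- read_fastq(reads)
  if (length(reads) == 0) return(.empty_alignments())
  if (is.null(names(reads))) names(reads) <- sprintf("read%06d", seq_along(reads))
  reads <- chartr("T", "U", toupper(reads))

  ref_chars <- lapply(refs, function(s) strsplit(s, "")[[1]])
  ref_len <- vapply(refs, nchar, integer(1))

  useq <- unique(reads)
  lens <- nchar(useq)
  res <- vector("list", length(useq))
  idx_cache <- list()

  for (u in seq_along(useq)) {
    L <- lens[u]
    if (L < min_read_len) next
    k <- min(20L, max(4L, L %/% (max_mismatch + 1L)))
    key <- as.character(k)
    if (is.null(idx_cache[[key]])) idx_cache[[key]] <- .kmer_index(refs, k)
    idx <- idx_cache[[key]]
    rc <- strsplit(useq[u], "")[[1]]

    offs <- seq(1L, by = k, length.out = max_mismatch + 1L)
    offs <- offs[offs + k - 1L <= L]
    cand <- character(0)
    for (o in offs) {
      hits <- idx[[substr(useq[u], o, o + k - 1L)]]
      if (is.null(hits)) next
      for (h in hits) {
        pos <- as.integer(h[["pos"]]) - o + 1L
        cand <- c(cand, paste0(h[["id"]], "\r", pos))
      }
    }
    cand <- unique(cand)
    if (length(cand) == 0) next

    best_mm <- max_mismatch + 1L
    best <- list()
    for (cd in cand) {
      parts <- strsplit(cd, "\r", fixed = TRUE)[[1]]
      id <- parts[1]; pos <- as.integer(parts[2])
      if (pos < 1L || pos + L - 1L > ref_len[[id]]) next
      mm <- .count_mm(rc, ref_chars[[id]], pos, L)
      if (mm < best_mm) {
        best_mm <- mm
        best <- list(list(id = id, pos = pos, mm = mm))
      } else if (mm == best_mm) {
        best <- c(best, list(list(id = id, pos = pos, mm = mm)))
      }
    }
    if (best_mm > max_mismatch || length(best) == 0) next
    ids_hit <- unique(vapply(best, `[[`, character(1), "id"))
    uniq <- length(ids_hit) == 1L
    # deterministic representative: reference order, then leftmost position
    key <- order(match(vapply(best, `[[`, character(1), "id"), names(refs)),
                 vapply(best, `[[`, integer(1), "pos"))
    b <- best[[key[1]]]
    res[[u]] <- list(id = b$id, pos = b$pos, mm = best_mm, unique = uniq)
  }

  uid <- vapply(res, function(r) if (is.null(r)) NA_character_ else r$id,
                character(1))
  upos <- vapply(res, function(r) if (is.null(r)) NA_integer_ else r$pos,
                 integer(1))
  umm <- vapply(res, function(r) if (is.null(r)) NA_integer_
                else as.integer(r$mm), integer(1))
  uuniq <- vapply(res, function(r) if (is.null(r)) NA else r$unique,
                  logical(1))
  m <- match(reads, useq)
  hit <- !is.na(uid[m])
  out <- data.frame(read_id = names(reads)[hit], trna_id = uid[m][hit],
                    start = upos[m][hit] - 1L,
                    end = upos[m][hit] - 1L + nchar(reads[hit]),
                    n_mismatches = umm[m][hit], unique = uuniq[m][hit],
                    stringsAsFactors = FALSE)
  if (unique_only) out <- out[out$unique, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_alignments <- function() {
  data.frame(read_id = character(0), trna_id = character(0),
             start = integer(0), end = integer(0),
             n_mismatches = integer(0), unique = logical(0),
             stringsAsFactors = FALSE)
}

#' Import alignments from a SAM file
#'
#' Reads mapped, primary, non-supplementary SAM lines into alignment
#' records. Uniqueness is inferred from the absence of equal-scoring (AS tag)
#' secondary alignments for the same read; with no AS tags, any secondary
#' alignment marks the read non-unique. Only a minimal column subset is
#' parsed; the deliverable interoperates with external mappers through
#' plain-text SAM.
#'
#' @param path SAM file.
#' @param references a `trna_set` or named character vector; reference names
#'   in the SAM must be a subset of its ids.
#' @return alignment data.frame as from [map_reads()].
#' @export
import_alignments <- function(path, references) {
  refs <- reference_sequences(references)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) return(.empty_alignments())
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  rname <- vapply(f, `[`, character(1), 3)
  mapped <- bitwAnd(flag, 4L) == 0L
  primary <- bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  used <- rname[mapped]
  bad <- setdiff(unique(used), c(names(refs), "*"))
  if (length(bad))
    stop("SAM reference name(s) absent from loaded tRNAs: ",
         paste(bad, collapse = ", "))

  get_tag <- function(x, tag) {
    hit <- grep(paste0("^", tag, ":"), x[-(1:11)], value = TRUE)
    if (length(hit) == 0) NA_character_
    else sub("^[^:]+:[^:]+:", "", hit[1])
  }
  ref_span <- function(cigar) {
    if (cigar == "*") return(0L)
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
    lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]]
    typs <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
    sum(as.integer(lens)[typs %in% c("M", "D", "N", "=", "X")])
  }

  qn <- vapply(f, `[`, character(1), 1)
  as_tag <- vapply(f, get_tag, character(1), "AS")
  sec <- bitwAnd(flag, 256L) != 0L & mapped

  rows <- list()
  for (i in which(mapped & primary)) {
    x <- f[[i]]
    pos <- as.integer(x[4])
    span <- ref_span(x[6])
    nm <- get_tag(x, "NM")
    others <- which(sec & qn == qn[i])
    uniq <- if (length(others) == 0) TRUE
            else if (!is.na(as_tag[i]))
              !any(as_tag[others] == as_tag[i], na.rm = TRUE)
            else FALSE
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = qn[i], trna_id = x[3], start = pos - 1L,
      end = pos - 1L + span,
      n_mismatches = if (is.na(nm)) NA_integer_ else as.integer(nm),
      unique = uniq, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(.empty_alignments())
  rownames(out) <- NULL
  out
}
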