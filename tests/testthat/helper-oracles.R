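# Independent oracles and shared fixture builders for the test suite.

# Brute-force mapper oracle: evaluates every ungapped placement of every
# read on every reference, applying the same best-score and uniqueness rules
# as the mapper but through exhaustive enumeration.
bf_map <- function(reads, references, max_mismatch = 2L, unique_only = TRUE,
                   min_read_len = 15L) {
  refs <- reference_sequences(references)
  ref_chars <- lapply(refs, function(s) strsplit(s, "")[[1]])
  rows <- list()
  for (i in seq_along(reads)) {
    rc <- strsplit(chartr("T", "U", toupper(reads[i])), "")[[1]]
    L <- length(rc)
    if (L < min_read_len) next
    best_mm <- max_mismatch + 1L
    best <- list()
    for (id in names(refs)) {
      refc <- ref_chars[[id]]
      if (length(refc) < L) next
      for (pos in seq_len(length(refc) - L + 1L)) {
        mm <- sum(rc != refc[pos:(pos + L - 1L)])
        if (mm < best_mm) {
          best_mm <- mm
          best <- list(list(id = id, pos = pos))
        } else if (mm == best_mm) {
          best <- c(best, list(list(id = id, pos = pos)))
        }
      }
    }
    if (best_mm > max_mismatch) next
    ids_hit <- unique(vapply(best, `[[`, character(1), "id"))
    uniq <- length(ids_hit) == 1L
    key <- order(match(vapply(best, `[[`, character(1), "id"), names(refs)),
                 vapply(best, `[[`, integer(1), "pos"))
    b <- best[[key[1]]]
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = names(reads)[i], trna_id = b$id, start = b$pos - 1L,
      end = b$pos - 1L + L, n_mismatches = best_mm, unique = uniq,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(read_id = character(0), trna_id = character(0),
                      start = integer(0), end = integer(0),
                      n_mismatches = integer(0), unique = logical(0))
  if (unique_only) out <- out[out$unique, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Atomic-composition mass oracle: builds the oligo from nucleoside
# compositions plus explicit phosphodiester bonds, an independent route from
# the residue-monophosphate bookkeeping in the package.
oracle_mass <- function(sequence, five_prime = "P", three_prime = "OH") {
  at <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.973762)
  fm <- function(f) sum(at[names(f)] * f)
  nucleoside <- list(
    A = c(C = 10, H = 13, N = 5, O = 4),
    C = c(C = 9, H = 13, N = 3, O = 5),
    G = c(C = 10, H = 13, N = 5, O = 5),
    U = c(C = 9, H = 12, N = 2, O = 6))
  hpo3 <- fm(c(H = 1, P = 1, O = 3))
  h2o <- fm(c(H = 2, O = 1))
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  # 5'-OH/3'-OH backbone: nucleosides joined by (n-1) phosphodiester bonds,
  # each bond adding HPO3 and removing H2O
  m <- sum(vapply(res, function(b) fm(nucleoside[[b]]), numeric(1))) +
    (n - 1) * (hpo3 - h2o)
  m <- m + switch(five_prime, OH = 0, P = hpo3, PPP = 3 * hpo3)
  m + switch(three_prime, OH = 0, P = hpo3, cP = hpo3 - h2o)
}

# Reference pool for power analyses: the four host targets plus decoys.
build_pool <- function(n_decoys = 36, seed = 99) {
  h <- host_trnas()
  pool <- c(h[setdiff(names(h), "Eco-Phe-GAA")],
            decoy_trnas(n_decoys, seed = seed))
  class(pool) <- "trna_set"
  pool
}

# Skewed fixed abundance weights for a pool (deterministic in seed).
pool_weights <- function(pool, seed = 7) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  w <- exp(stats::rnorm(length(pool), 0, 0.5))
  names(w) <- names(pool)
  w
}

main_nick_sites <- function() {
  data.frame(trna_id = c("Eco-Lys-UUU", "Eco-Thr-UGU", "Eco-Asn-GUU"),
             site5 = "40", site3 = "41", prob = c(0.9, 0.7, 0.3),
             stringsAsFactors = FALSE)
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
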