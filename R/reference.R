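# Canonical (Sprinzl-style) numbering ----------------------------------------

# 76 core labels; insertions go into defined D-loop / variable-loop slots,
# deletions are taken from the D-loop first.
.core_labels <- as.character(1:76)
.insertion_slots <- c("17a" = "17", "20a" = "20", "20b" = "20a",
                      "e1" = "47", "e2" = "e1", "e3" = "e2",
                      "e4" = "e3", "e5" = "e4")
.deletion_order <- c("17", "20", "47")

#' Canonical tRNA position labels
#'
#' The ordered template of canonical labels used for automatic numbering:
#' the 76 core positions, optionally with D-loop ("17a", "20a", "20b") and
#' variable-loop ("e1".."e5") insertions spliced in after their slot
#' positions.
#'
#' @param insertions character vector of insertion labels to include.
#' @param deletions character vector of core labels to drop.
#' @return character vector of canonical labels in 5' to 3' order.
#' @export
canonical_labels <- function(insertions = character(), deletions = character()) {
  labs <- setdiff(.core_labels, deletions)
  for (ins in names(.insertion_slots)) {
    if (ins %in% insertions) {
      after <- match(.insertion_slots[[ins]], labs)
      if (is.na(after)) stop("insertion slot for '", ins, "' absent")
      labs <- append(labs, ins, after = after)
    }
  }
  labs
}

.label_num <- function(label) {
  # numeric core of a label: "17a" -> 17, "e2" -> 47.5 (variable loop)
  ifelse(grepl("^e[0-9]$", label), 47.5,
         suppressWarnings(as.numeric(sub("[a-z]+$", "", label))))
}

# TRNARecord ------------------------------------------------------------------

#' Construct a tRNA record with canonical numbering
#'
#' A `trna_record` holds one tRNA sequence (RNA alphabet) together with the
#' ordered canonical label of every residue, so that biology stated in
#' canonical coordinates (anticodon at 34-36, anticodon stem 27-31/39-43,
#' D-loop contacts at 16-17, and so on) can be mapped onto the actual string.
#'
#' @param id identifier, e.g. `"Eco-Lys-UUU"`.
#' @param sequence RNA (or DNA; `T` is transliterated to `U`) string, 60-100 nt.
#' @param numbering optional character vector of canonical labels, one per
#'   residue. When `NULL` it is assigned with [assign_canonical_numbering()].
#' @param amino_acid three-letter amino-acid code, e.g. `"Lys"`.
#' @param source `"host"` or `"phage"`.
#' @param has_cca whether the 3' CCA end is part of the sequence.
#' @return an object of class `trna_record`.
#' @export
trna_record <- function(id, sequence, numbering = NULL,
                        amino_acid = NA_character_,
                        source = c("host", "phage"),
                        has_cca = NA) {
  source <- match.arg(source)
  sequence <- toupper(gsub("\\s", "", sequence))
  sequence <- chartr("T", "U", sequence)
  if (grepl("[^ACGU]", sequence))
    stop("non-nucleotide characters in sequence for '", id, "'")
  n <- nchar(sequence)
  if (n < 60 || n > 100)
    stop("sequence length ", n, " outside 60-100 nt for '", id, "'")
  if (is.null(numbering)) {
    numbering <- assign_canonical_numbering(sequence)
  }
  numbering <- as.character(numbering)
  if (length(numbering) != n)
    stop("numbering length != sequence length for '", id, "'")
  nums <- .label_num(numbering)
  if (any(is.na(nums)))
    stop("unparseable canonical label in numbering for '", id, "'")
  if (anyDuplicated(numbering))
    stop("duplicated canonical labels in numbering for '", id, "'")
  if (any(diff(nums) < 0))
    stop("canonical labels do not increase for '", id, "'")
  if (is.na(has_cca)) has_cca <- endsWith(sequence, "CCA")
  res <- strsplit(sequence, "")[[1]]
  names(res) <- numbering
  anticodon <- if (all(c("34", "35", "36") %in% numbering))
    paste0(res[["34"]], res[["35"]], res[["36"]]) else NA_character_
  structure(list(id = id, amino_acid = amino_acid, anticodon = anticodon,
                 sequence = sequence, numbering = numbering,
                 residues = res, has_cca = has_cca, source = source),
            class = "trna_record")
}

#' @export
print.trna_record <- function(x, ...) {
  cat(sprintf("trna_record %s (%s, %s): %d nt, anticodon %s\n",
              x$id, x$amino_acid, x$source, nchar(x$sequence), x$anticodon))
  invisible(x)
}

#' Assign canonical numbering to a tRNA sequence
#'
#' For a 76-nt sequence, residue i gets label `as.character(i)`. Lengths
#' 74-78 are aligned onto the 76-label template by removing D-loop labels
#' (17, then 20) or adding D-loop insertions (17a, then 20a). Any other
#' length requires an explicit sidecar map: class-II variable arms cannot be
#' inferred from length alone.
#'
#' @param sequence RNA string or a `trna_record`.
#' @return character vector of canonical labels, one per residue.
#' @export
assign_canonical_numbering <- function(sequence) {
  if (inherits(sequence, "trna_record")) sequence <- sequence$sequence
  n <- nchar(sequence)
  if (n < 74 || n > 78)
    stop("numbering required: length ", n,
         " outside 74-78 nt needs an explicit numbering map")
  d <- n - 76L
  if (d == 0) return(.core_labels)
  if (d < 0) return(canonical_labels(deletions = .deletion_order[seq_len(-d)]))
  canonical_labels(insertions = c("17a", "20a")[seq_len(d)])
}

#' Map between canonical labels and residue indices
#'
#' @param record a `trna_record`.
#' @param label canonical label(s), e.g. `"41"`.
#' @param index 1-based residue index(es).
#' @return `canonical_to_index()` gives 1-based indices; `index_to_canonical()`
#'   gives labels.
#' @export
canonical_to_index <- function(record, label) {
  i <- match(as.character(label), record$numbering)
  if (anyNA(i)) stop("label(s) ", paste(label[is.na(i)], collapse = ", "),
                     " absent from ", record$id)
  i
}

#' @rdname canonical_to_index
#' @export
index_to_canonical <- function(record, index) {
  if (any(index < 1 | index > length(record$numbering)))
    stop("index out of range for ", record$id)
  record$numbering[index]
}

# Region map -------------------------------------------------------------

.regions <- list(
  `acceptor stem`  = c(1:7, 66:72),
  `D-loop`         = 14:21,
  `anticodon stem` = c(27:31, 39:43),
  `anticodon loop` = c(32:33, 37:38),   # loop minus the anticodon itself
  anticodon        = 34:36,
  `variable loop`  = 44:48,
  `T-loop`         = 54:60
)

#' Leaf region of a canonical position
#'
#' Maps a canonical label to its named tRNA region. The anticodon (34-36) is
#' reported as its own leaf inside the anticodon loop (32-38), which nests in
#' the anticodon stem-loop (27-43).
#'
#' @param label canonical label, e.g. `"40"`.
#' @return region name, or `"other"` for positions not in a named window.
#' @export
region_of <- function(label) {
  vapply(as.character(label), function(l) {
    v <- .label_num(l)
    if (is.na(v)) stop("unknown label '", l, "'")
    if (grepl("^e[0-9]$", l)) return("variable loop")
    for (r in names(.regions)) if (floor(v) %in% .regions[[r]]) return(r)
    "other"
  }, character(1), USE.NAMES = FALSE)
}

#' The anticodon stem-loop window used for fragment classification
#'
#' Canonical labels 27-43: stem 27-31/39-43 plus loop 32-38, the window in
#' which nuclease-generated fragment 5' ends are sought.
#' @return integer vector `c(27, 43)`.
#' @export
anticodon_window <- function() c(27L, 43L)

#' Hexamer over the nuclease recognition site (labels 36-41)
#'
#' The six residues at canonical positions 36-41. For the E. coli
#' tRNA-Lys(UUU) target this is `"UAAUCA"`, the AriB consensus with the
#' scissile bond between positions 40 and 41.
#'
#' @param record a `trna_record`.
#' @return a 6-character string.
#' @export
site_hexamer <- function(record) {
  labs <- as.character(36:41)
  if (!all(labs %in% record$numbering))
    stop("labels 36-41 not all present in ", record$id)
  paste(record$residues[labs], collapse = "")
}

# FASTA / sidecar IO -----------------------------------------------------

#' Load tRNA reference sequences from FASTA
#'
#' Reads a FASTA file (RNA or DNA alphabet; `T` becomes `U`) into a named
#' list of [trna_record()]s, ordered by id. Header tokens of the form
#' `key=value` (e.g. `aa=Lys source=phage`) are honoured.
#'
#' @param path FASTA file.
#' @param numbering_map optional sidecar TSV (columns `index0`, `label`) or a
#'   named list of per-id label vectors, for tRNAs whose numbering cannot be
#'   assigned automatically.
#' @return named list of `trna_record`s (class `trna_set`).
#' @export
load_trna_fasta <- function(path, numbering_map = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA: ", path)
  headers <- names(seqs)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  meta <- lapply(headers, function(h) {
    toks <- strsplit(h, "\\s+")[[1]][-1]
    kv <- toks[grepl("=", toks)]
    stats::setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
  })
  if (is.character(numbering_map) && length(numbering_map) == 1) {
    sidecar <- utils::read.delim(numbering_map, stringsAsFactors = FALSE,
                                 colClasses = "character")
    if (!all(c("index0", "label") %in% names(sidecar)))
      stop("numbering sidecar needs columns index0, label")
    numbering_map <- if ("trna_id" %in% names(sidecar)) {
      lapply(split(sidecar, sidecar$trna_id),
             function(d) d$label[order(as.integer(d$index0))])
    } else {
      stats::setNames(list(sidecar$label[order(as.integer(sidecar$index0))]),
                      ids[1])
    }
  }
  recs <- lapply(order(ids), function(k) {
    id <- ids[k]
    m <- meta[[k]]
    trna_record(
      id = id,
      sequence = as.character(seqs[[k]]),
      numbering = if (!is.null(numbering_map) && id %in% names(numbering_map))
        numbering_map[[id]] else NULL,
      amino_acid = if ("aa" %in% names(m)) m[["aa"]] else NA_character_,
      source = if ("source" %in% names(m)) m[["source"]] else "host"
    )
  })
  names(recs) <- sort(ids)
  structure(recs, class = "trna_set")
}

#' Reference sequences as a named character vector
#' @param references a `trna_set`, list of `trna_record`s, or named character
#'   vector of sequences.
#' @return named character vector (RNA alphabet).
#' @export
reference_sequences <- function(references) {
  if (is.character(references)) {
    if (length(references) == 0) return(references)
    if (is.null(names(references))) stop("references must be named")
    return(chartr("T", "U", toupper(references)))
  }
  vapply(references, function(r) r$sequence, character(1))
}

# Modification tables ----------------------------------------------------

#' Load a tRNA modification table
#'
#' TSV with columns `trna_id`, `position_label`, `mod_name`,
#' `mass_delta_avg_da` (average-mass delta in Da relative to the unmodified
#' residue; may be empty).
#'
#' @param path TSV file.
#' @param references optional `trna_set`; when given, each (id, position) is
#'   checked to exist in that tRNA's numbering.
#' @return data.frame of class `modification_table`.
#' @export
load_modification_table <- function(path, references = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(position_label = "character"))
  need <- c("trna_id", "position_label", "mod_name", "mass_delta_avg_da")
  if (!all(need %in% names(tab)))
    stop("modification table needs columns: ", paste(need, collapse = ", "))
  key <- paste(tab$trna_id, tab$position_label)
  if (anyDuplicated(key))
    stop("duplicate (trna_id, position) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (!is.null(references)) {
    for (i in seq_len(nrow(tab))) {
      rec <- references[[tab$trna_id[i]]]
      if (is.null(rec)) stop("unknown trna_id '", tab$trna_id[i], "'")
      if (!tab$position_label[i] %in% rec$numbering)
        stop("position ", tab$position_label[i], " absent from ",
             tab$trna_id[i])
    }
  }
  class(tab) <- c("modification_table", "data.frame")
  tab
}

#' Summarize modification load over a set of tRNAs
#'
#' @param table a `modification_table`.
#' @param trna_ids ids to summarize.
#' @return list with `positions_per_trna` (named integer vector of distinct
#'   modified positions) and `n_types` (distinct modification names over the
#'   union of the given tRNAs).
#' @export
modification_summary <- function(table, trna_ids) {
  if (length(trna_ids) == 0)
    return(list(positions_per_trna = stats::setNames(integer(0), character(0)),
                n_types = 0L))
  unknown <- setdiff(trna_ids, unique(table$trna_id))
  if (length(unknown))
    stop("unknown trna_id(s): ", paste(unknown, collapse = ", "))
  sub <- table[table$trna_id %in% trna_ids, , drop = FALSE]
  pos <- vapply(trna_ids, function(id)
    length(unique(sub$position_label[sub$trna_id == id])), integer(1))
  list(positions_per_trna = pos,
       n_types = length(unique(sub$mod_name)))
}

# Packaged fixtures ------------------------------------------------------

#' Packaged reconstructed tRNA fixtures
#'
#' Reconstructed sequences for the four E. coli tRNA targets of AriB
#' (Lys-UUU, Thr-UGU, Asn-GUU, Thr-CGU) plus a non-target Phe-GAA control,
#' the three bacteriophage T5 escape variants, and a modification table.
#' These are synthetic reconstructions consistent with the published site
#' hexamers, escape substitutions and modification counts, not database
#' copies; see the package vignette.
#'
#' @return `host_trnas()`/`phage_trnas()` give a `trna_set`;
#'   `trna_modifications()` a `modification_table`.
#' @export
host_trnas <- function() {
  load_trna_fasta(system.file("extdata", "host_trnas.fasta",
                              package = "trnanick"))
}

#' @rdname host_trnas
#' @export
phage_trnas <- function() {
  load_trna_fasta(system.file("extdata", "phage_trnas.fasta",
                              package = "trnanick"))
}

#' @rdname host_trnas
#' @export
trna_modifications <- function() {
  load_modification_table(system.file("extdata", "modifications.tsv",
                                      package = "trnanick"))
}
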