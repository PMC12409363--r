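# 5'-end pileups, nick-site calling, consensus scanning and escape-mutation
# annotation.
#
# A nick between canonical positions p and p+1 is evidenced by the 5' ends
# of downstream fragments piling up at p+1. 3'-end evidence of the upstream
# fragment is tabulated as well but not required for a call: RT-stall
# truncation corrupts apparent 3' ends in cDNA-adapter libraries, while
# RNA-end-ligated libraries read true 5' ends faithfully.

#' Per-position 5'/3'-end pileup of fragment-class reads
#'
#' @param alignments classified alignments; only rows with
#'   `class == "anticodon_fragment"` are counted unless `class = NULL`.
#' @param references a `trna_set`.
#' @param class read class to pile up (default `"anticodon_fragment"`;
#'   `NULL` for all alignments).
#' @return data.frame of class `end_pileup`: `trna_id`, `label`, `end5`,
#'   `end3`, one row per (tRNA, canonical label), plus per-tRNA totals in
#'   `attr(, "totals")`. Positional counts sum to the total per tRNA.
#' @export
end_pileup <- function(alignments, references, class = "anticodon_fragment") {
  if (!is.null(class) && "class" %in% names(alignments))
    alignments <- alignments[alignments$class == class, , drop = FALSE]
  rows <- lapply(names(references), function(id) {
    rec <- references[[id]]
    sub <- alignments[alignments$trna_id == id, , drop = FALSE]
    lab5 <- table(factor(rec$numbering[sub$start + 1L],
                         levels = rec$numbering))
    lab3 <- table(factor(rec$numbering[sub$end], levels = rec$numbering))
    data.frame(trna_id = id, label = rec$numbering,
               end5 = as.integer(lab5), end3 = as.integer(lab3),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  totals <- vapply(split(out$end5, out$trna_id), sum, integer(1))
  attr(out, "totals") <- totals
  class(out) <- c("end_pileup", "data.frame")
  out
}

#' Call nick sites from treated versus control 5'-end pileups
#'
#' For every canonical position inside the window, the treated 5'-end
#' fraction (per tRNA) is compared with the control fraction through
#' `score = log2((treated_frac + eps) / (control_frac + eps))` with
#' `eps = 1/(total + 1)` keeping scores finite. Positions with treated
#' fraction >= `min_frac` and score >= `min_score` yield a call for a nick
#' between the preceding label and the position. When no control is supplied
#' - or a tRNA has no control fragment reads at all - the control fraction
#' falls back to the uniform in-window expectation, so single-sample data
#' can still be scored.
#'
#' @param treated `end_pileup` for the treated sample.
#' @param control optional `end_pileup` for the control sample.
#' @param window numeric `c(lo, hi)` canonical window (default 27-43).
#' @param min_frac minimum treated 5'-end fraction (default 0.05).
#' @param min_score minimum log2 score (default 1).
#' @return data.frame of class `cleavage_calls`: `trna_id`, `nick5`, `nick3`
#'   (labels flanking the nick), `treated_frac`, `control_frac`, `score`,
#'   sorted by decreasing score (ties by smaller position).
#' @export
call_sites <- function(treated, control = NULL, window = anticodon_window(),
                       min_frac = 0.05, min_score = 1.0) {
  tot_t <- attr(treated, "totals")
  if (sum(tot_t) == 0) {
    warning("treated pileup has zero fragment reads; no calls")
    return(.empty_calls())
  }
  tot_c <- if (!is.null(control)) attr(control, "totals")
  rows <- list()
  for (id in unique(treated$trna_id)) {
    tt <- tot_t[[id]]
    if (is.na(tt) || tt == 0) next
    sub_t <- treated[treated$trna_id == id, , drop = FALSE]
    nums <- .label_num(sub_t$label)
    in_win <- !is.na(nums) & floor(nums) >= window[1] &
      floor(nums) <= window[2]
    n_win <- sum(in_win)
    eps_t <- 1 / (tt + 1)
    tc <- if (!is.null(control) && id %in% names(tot_c)) tot_c[[id]] else 0L
    if (tc > 0) {
      sub_c <- control[control$trna_id == id, , drop = FALSE]
      cf_all <- sub_c$end5[match(sub_t$label, sub_c$label)] / tc
      cf_all[is.na(cf_all)] <- 0
      eps_c <- 1 / (tc + 1)
    } else {
      cf_all <- rep(1 / n_win, nrow(sub_t))
      eps_c <- eps_t
    }
    for (j in which(in_win)) {
      if (j == 1L) next   # no upstream residue to nick after
      tf <- sub_t$end5[j] / tt
      if (tf < min_frac) next
      score <- log2((tf + eps_t) / (cf_all[j] + eps_c))
      if (score < min_score) next
      rows[[length(rows) + 1L]] <- data.frame(
        trna_id = id, nick5 = sub_t$label[j - 1L], nick3 = sub_t$label[j],
        treated_frac = tf, control_frac = cf_all[j], score = score,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(.empty_calls())
  ord <- order(-out$score, .label_num(out$nick3))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cleavage_calls", "data.frame")
  out
}

.empty_calls <- function() {
  out <- data.frame(trna_id = character(0), nick5 = character(0),
                    nick3 = character(0), treated_frac = numeric(0),
                    control_frac = numeric(0), score = numeric(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("cleavage_calls", "data.frame")
  out
}

#' Scan a tRNA for the nuclease consensus site
#'
#' Places the consensus hexamer (default `"UAAUCA"`, the AriB site spanning
#' canonical positions 36-41 on E. coli tRNA-Lys(UUU)) on the sequence and
#' predicts a nick between the 5th and 6th matched residues, i.e. 40|41 for
#' the anchored default. Anchored mode (default) only tests the placement
#' starting at canonical label 36, since the site is positionally defined;
#' unanchored mode slides over the whole sequence for exploratory use.
#'
#' @param record a `trna_record`.
#' @param consensus consensus oligomer (default `"UAAUCA"`).
#' @param max_mismatch allowed mismatches (default 0).
#' @param anchor36 restrict to the placement starting at label 36 (default
#'   `TRUE`).
#' @return data.frame: `trna_id`, `start_label`, `mismatches`, `nick5`,
#'   `nick3`; zero rows when no placement passes.
#' @export
scan_consensus <- function(record, consensus = "UAAUCA", max_mismatch = 0L,
                           anchor36 = TRUE) {
  cons <- strsplit(chartr("T", "U", toupper(consensus)), "")[[1]]
  w <- length(cons)
  seq_ch <- strsplit(record$sequence, "")[[1]]
  starts <- if (anchor36) {
    if (!"36" %in% record$numbering)
      stop("label 36 absent from ", record$id)
    canonical_to_index(record, "36")
  } else {
    seq_len(max(0L, length(seq_ch) - w + 1L))
  }
  rows <- list()
  for (s in starts) {
    if (s + w - 1L > length(seq_ch)) next
    mm <- sum(seq_ch[s:(s + w - 1L)] != cons)
    if (mm > max_mismatch) next
    rows[[length(rows) + 1L]] <- data.frame(
      trna_id = record$id,
      start_label = record$numbering[s],
      mismatches = mm,
      nick5 = record$numbering[s + w - 2L],
      nick3 = record$numbering[s + w - 1L],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(trna_id = character(0), start_label = character(0),
                      mismatches = integer(0), nick5 = character(0),
                      nick3 = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Annotate host-versus-phage escape substitutions
#'
#' Lists all substitutions between a host tRNA and its phage counterpart
#' over their shared canonical labels, classifying the known escape
#' mutations of the T5 tRNA-Lys(UUU): Mut1 (U39 to A), Mut2 (A41 to C) and
#' the D-loop contact Mut3 (U16 to C). Other differences at canonical
#' positions 36-43 are `site-proximal`, everything else `distal`.
#'
#' @param host,phage `trna_record`s.
#' @return data.frame of class `escape_annotation`: `label`, `host_base`,
#'   `phage_base`, `class`.
#' @export
annotate_escape <- function(host, phage) {
  shared <- intersect(host$numbering, phage$numbering)
  if (length(shared) == 0) stop("no shared canonical labels")
  hb <- host$residues[shared]
  pb <- phage$residues[shared]
  diff <- which(hb != pb)
  cls <- character(length(diff))
  for (k in seq_along(diff)) {
    lab <- shared[diff[k]]
    h <- hb[[diff[k]]]; p <- pb[[diff[k]]]
    cls[k] <- if (lab == "39" && h == "U" && p == "A") "Mut1"
      else if (lab == "41" && h == "A" && p == "C") "Mut2"
      else if (lab == "16" && h == "U" && p == "C") "Mut3"
      else if (!is.na(.label_num(lab)) &&
               floor(.label_num(lab)) %in% 36:43) "site-proximal"
      else "distal"
  }
  out <- data.frame(label = shared[diff], host_base = unname(hb[diff]),
                    phage_base = unname(pb[diff]), class = cls,
                    stringsAsFactors = FALSE)
  class(out) <- c("escape_annotation", "data.frame")
  out
}
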