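# Read classification, abundance normalization, and the log-log depletion
# regression used to detect nuclease targets from tRNA-seq.

#' Classify alignments into full-length proxies and anticodon fragments
#'
#' A read is a `full_length` proxy when its aligned span is at least
#' `min_full` nt (reads covering most of the tRNA body; 65 nt for 150 nt
#' libraries). It is an `anticodon_fragment` when the span is below
#' `max_frag` nt *and* the canonical label of its 5'-most aligned residue
#' falls inside the anticodon stem-loop window. Everything else is `other`.
#' For 50 nt read lengths the full-length proxy cannot reach 65 nt; set
#' `min_full` to the read length (or just below) so that only reads running
#' the whole sequencing length, which derive from un-nicked molecules, count
#' as full length.
#'
#' @param alignments alignment data.frame from [map_reads()] or
#'   [import_alignments()].
#' @param references a `trna_set`.
#' @param min_full minimum span (nt) for the full-length class (default 65).
#' @param max_frag maximum span (nt) for the fragment class (default 45).
#' @param window anticodon stem-loop window, numeric `c(lo, hi)` canonical
#'   positions (default [anticodon_window()], 27-43).
#' @return the alignment data.frame with columns `span`, `label5` (canonical
#'   label of the 5'-most aligned residue) and `class` added.
#' @export
classify_reads <- function(alignments, references, min_full = 65L,
                           max_frag = 45L, window = anticodon_window()) {
  if (nrow(alignments) == 0) {
    alignments$span <- integer(0)
    alignments$label5 <- character(0)
    alignments$class <- character(0)
    return(alignments)
  }
  unknown <- setdiff(unique(alignments$trna_id), names(references))
  if (length(unknown))
    stop("alignments reference unknown tRNA(s): ",
         paste(unknown, collapse = ", "))
  span <- alignments$end - alignments$start
  label5 <- mapply(function(id, s)
    index_to_canonical(references[[id]], s + 1L),
    alignments$trna_id, alignments$start, USE.NAMES = FALSE)
  num5 <- .label_num(label5)
  in_window <- !is.na(num5) & floor(num5) >= window[1] & floor(num5) <= window[2]
  cls <- ifelse(span >= min_full, "full_length",
                ifelse(span < max_frag & in_window, "anticodon_fragment",
                       "other"))
  alignments$span <- span
  alignments$label5 <- label5
  alignments$class <- cls
  alignments
}

#' Per-tRNA abundance (counts and CPM) for one read class
#'
#' Counts reads of the requested class per tRNA and normalizes to counts per
#' million over that class's total, so CPM sums to 1e6 whenever any read is
#' counted.
#'
#' @param alignments classified alignments (see [classify_reads()]).
#' @param references a `trna_set`; every reference id appears in the output,
#'   with zero counts where no reads were seen.
#' @param class read class to count (default `"full_length"`).
#' @param sample sample label stored in the table.
#' @return data.frame of class `abundance_table`: `trna_id`, `count`, `cpm`,
#'   `sample`, `class`.
#' @export
abundance <- function(alignments, references, class = "full_length",
                      sample = NA_character_) {
  ids <- names(references)
  sub <- alignments[alignments$class == class, , drop = FALSE]
  counts <- table(factor(sub$trna_id, levels = ids))
  count <- as.integer(counts)
  total <- sum(count)
  if (total == 0) {
    warning("no reads of class '", class, "'; all CPM set to 0")
    cpm <- numeric(length(ids))
  } else {
    cpm <- count / total * 1e6
  }
  out <- data.frame(trna_id = ids, count = count, cpm = cpm,
                    sample = sample, class = class, stringsAsFactors = FALSE)
  class(out) <- c("abundance_table", "data.frame")
  out
}

#' Log-log depletion regression between control and treated samples
#'
#' Fits `log10(treated CPM + pseudo) ~ log10(control CPM + pseudo)` by
#' ordinary least squares over the common tRNA universe and flags tRNAs whose
#' residual falls below `-k_mad` times the median absolute deviation of the
#' residuals, i.e. tRNAs depleted in the treated sample well beyond the bulk
#' scatter. The threshold mirrors how depleted targets stand out below the
#' regression line in a log-log scatter; it is exposed because the underlying
#' experiment reads the plot visually.
#'
#' @param control,treated `abundance_table`s over the same tRNA universe.
#' @param pseudo pseudo-count in CPM units added before logs (default 0.5).
#' @param k_mad MAD multiplier for the depletion flag (default 3).
#' @return list of class `depletion_result`: `slope`, `intercept`, `table`
#'   (per-tRNA log-CPMs, residual, depleted flag), `threshold`, `k_mad`.
#' @export
depletion_analysis <- function(control, treated, pseudo = 0.5, k_mad = 3) {
  if (!setequal(control$trna_id, treated$trna_id))
    stop("control and treated must cover the same tRNA universe")
  d <- merge(control[, c("trna_id", "cpm")], treated[, c("trna_id", "cpm")],
             by = "trna_id", suffixes = c("_control", "_treated"))
  if (sum(d$cpm_control > 0) < 3)
    stop("fewer than 3 tRNAs with nonzero control counts")
  d$log_control <- log10(d$cpm_control + pseudo)
  d$log_treated <- log10(d$cpm_treated + pseudo)
  fit <- stats::lm(log_treated ~ log_control, data = d)
  d$residual <- stats::residuals(fit)
  mad_r <- stats::mad(d$residual)
  thr <- -k_mad * mad_r
  # strict tolerance so numerically-zero residual spread flags nothing
  d$depleted <- d$residual < thr - 1e-9
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 table = d, threshold = thr, k_mad = k_mad, pseudo = pseudo),
            class = "depletion_result")
}

#' @export
print.depletion_result <- function(x, ...) {
  cat(sprintf("depletion_result: slope %.3f, intercept %.3f, threshold %.3f\n",
              x$slope, x$intercept, x$threshold))
  dep <- x$table$trna_id[x$table$depleted]
  cat("depleted:", if (length(dep)) paste(dep, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

#' Log-log abundance scatter with the fitted regression line
#'
#' @param result a `depletion_result`.
#' @param highlight tRNA ids drawn in red (defaults to the flagged set).
#' @return a ggplot object.
#' @export
plot_depletion <- function(result, highlight = NULL) {
  d <- result$table
  if (is.null(highlight)) highlight <- d$trna_id[d$depleted]
  d$highlight <- d$trna_id %in% highlight
  ggplot2::ggplot(d, ggplot2::aes(x = log_control, y = log_treated)) +
    ggplot2::geom_abline(slope = result$slope, intercept = result$intercept,
                         linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = highlight),
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "log10 control CPM", y = "log10 treated CPM") +
    ggplot2::theme_minimal()
}
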