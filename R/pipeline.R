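# End-to-end orchestration: simulate (optional) -> map -> classify ->
# abundance/depletion -> pileup/calls -> consensus/escape -> digest ->
# toeprint, with logged parameters and machine-readable outputs.

#' Pipeline configuration
#'
#' Collects the thresholds of the analysis (all exposed; defaults follow the
#' analysis the package models), input paths and the seed. Can be read from
#' a YAML file with [load_pipeline_config()].
#'
#' @param references path to a reference FASTA or a `trna_set`; default the
#'   packaged host fixtures.
#' @param phage path to a phage-variant FASTA or `trna_set` (escape
#'   annotation stage); default the packaged phage fixtures; `NULL` skips.
#' @param modification_table path or `modification_table`; default packaged.
#' @param reads,control_reads FASTQ paths (or named read vectors). `NULL`
#'   with `simulate = TRUE` generates both from `sim_spec`.
#' @param sim_spec a [pool_spec()] for the treated sample when simulating;
#'   the control is the same spec without nicks.
#' @param simulate generate reads instead of reading them.
#' @param min_full,max_frag,window,k_mad,min_frac,min_score,tol,pseudo
#'   analysis thresholds (see the stage functions).
#' @param max_mismatch mapper mismatch cap.
#' @param nick nick site assayed in the digest stage (default
#'   `c("40","41")`).
#' @param seed integer seed.
#' @param out_dir output directory for TSV/JSON reports; `NULL` for none.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(references = NULL, phage = NULL,
                            modification_table = NULL,
                            reads = NULL, control_reads = NULL,
                            sim_spec = NULL, simulate = FALSE,
                            min_full = 65L, max_frag = 45L,
                            window = anticodon_window(), k_mad = 3,
                            min_frac = 0.05, min_score = 1.0, tol = 1.0,
                            pseudo = 0.5, max_mismatch = 2L,
                            nick = c("40", "41"), seed = 1L,
                            out_dir = NULL) {
  stopifnot(min_full > 0, max_frag > 0, k_mad > 0, min_frac > 0,
            min_score > 0, tol > 0)
  if (window[1] < 1 || window[2] > 76) stop("window outside 1-76")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

.load_refs <- function(x, default_fun) {
  if (is.null(x)) return(default_fun())
  if (inherits(x, "trna_set") || is.list(x)) return(x)
  load_trna_fasta(x)
}

#' Run the full analysis pipeline
#'
#' Executes every stage with the configured thresholds, logging each stage
#' and its parameters via `message()`. Identical config and seed give
#' identical results. Any stage error aborts with a stage-named message.
#'
#' @param config a [pipeline_config()].
#' @return list with per-stage results: `alignments`, `abundance_control`,
#'   `abundance_treated`, `depletion`, `pileup_treated`, `pileup_control`,
#'   `calls`, `consensus`, `escape`, `digest`, `signature`, `toeprint`;
#'   written as TSVs plus a JSON summary when `out_dir` is set. Returned
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  refs <- stage("reference", .load_refs(config$references, host_trnas))
  phage <- if (!is.null(config$phage) || is.null(config$references))
    stage("reference", .load_refs(config$phage, phage_trnas)) else NULL
  mods <- stage("reference", {
    mt <- config$modification_table
    if (is.null(mt)) trna_modifications()
    else if (inherits(mt, "modification_table")) mt
    else load_modification_table(mt)
  })

  sim <- NULL
  if (isTRUE(config$simulate)) {
    if (is.null(config$sim_spec)) stop("stage 'simulate': no sim_spec")
    spec_t <- config$sim_spec
    spec_t$seed <- config$seed
    spec_c <- spec_t
    spec_c$nick_sites <- NULL
    spec_c$seed <- config$seed + 1L
    sim <- stage("simulate", list(
      treated = simulate_pool(spec_t, refs, mods),
      control = simulate_pool(spec_c, refs, mods)))
    reads_t <- sim$treated$reads
    reads_c <- sim$control$reads
    message("[simulate] protocol ", spec_t$protocol, ", n_reads ",
            spec_t$n_reads, ", seed ", config$seed)
  } else {
    if (is.null(config$reads)) stop("stage 'input': no input reads")
    reads_t <- if (is.character(config$reads) && length(config$reads) == 1)
      read_fastq(config$reads) else config$reads
    reads_c <- if (is.null(config$control_reads)) NULL
      else if (is.character(config$control_reads) &&
               length(config$control_reads) == 1)
        read_fastq(config$control_reads) else config$control_reads
  }

  aln_t <- stage("map", classify_reads(
    map_reads(reads_t, refs, max_mismatch = config$max_mismatch),
    refs, min_full = config$min_full, max_frag = config$max_frag,
    window = config$window))
  aln_c <- if (!is.null(reads_c)) stage("map", classify_reads(
    map_reads(reads_c, refs, max_mismatch = config$max_mismatch),
    refs, min_full = config$min_full, max_frag = config$max_frag,
    window = config$window)) else NULL
  message("[map] ", nrow(aln_t), " treated alignments, max_mismatch ",
          config$max_mismatch)

  ab_t <- stage("abundance", abundance(aln_t, refs, sample = "treated"))
  ab_c <- if (!is.null(aln_c))
    stage("abundance", abundance(aln_c, refs, sample = "control")) else NULL
  depl <- if (!is.null(ab_c) && sum(ab_c$count) > 0 && sum(ab_t$count) > 0)
    stage("depletion", depletion_analysis(ab_c, ab_t, pseudo = config$pseudo,
                                          k_mad = config$k_mad)) else NULL

  pil_t <- stage("pileup", end_pileup(aln_t, refs))
  pil_c <- if (!is.null(aln_c)) stage("pileup", end_pileup(aln_c, refs))
    else NULL
  calls <- stage("callsites", call_sites(
    pil_t, pil_c, window = config$window, min_frac = config$min_frac,
    min_score = config$min_score))

  cons <- stage("scan", do.call(rbind, lapply(refs, scan_consensus,
                                              max_mismatch = 1L)))
  esc <- if (!is.null(phage)) stage("escape", {
    pairs <- list()
    for (pid in names(phage)) {
      hid <- sub("^[^-]+-", "Eco-", pid)
      if (hid %in% names(refs))
        pairs[[pid]] <- annotate_escape(refs[[hid]], phage[[pid]])
    }
    pairs
  }) else NULL

  target <- intersect(c("Eco-Lys-UUU"), names(refs))
  dig <- if (length(target)) stage("digest",
    digest_t1(refs[[target]], nicks = list(config$nick))) else NULL
  sig <- if (length(target)) stage("digest",
    nick_signature(refs[[target]], config$nick)) else NULL

  depleted_ids <- if (!is.null(depl))
    depl$table$trna_id[depl$table$depleted] else character(0)
  dep_codons <- .anticodon_codons(refs[depleted_ids])
  toe <- stage("toeprint", list(
    template = toeprint_template("wt"),
    stall = predict_stall(toeprint_template("wt"),
                          if (length(dep_codons)) dep_codons else "AAA"),
    control = start_control(toeprint_template("wt"))))

  out <- list(alignments = aln_t, abundance_treated = ab_t,
              abundance_control = ab_c, depletion = depl,
              pileup_treated = pil_t, pileup_control = pil_c, calls = calls,
              consensus = cons, escape = esc, digest = dig, signature = sig,
              toeprint = toe, config = config, sim = sim)
  if (!is.null(config$out_dir)) .write_bundle(out, config)
  invisible(out)
}

# codons read by a set of tRNAs (reverse complement of the anticodon)
.anticodon_codons <- function(refs) {
  acs <- vapply(refs, function(r) r$anticodon, character(1))
  acs <- acs[!is.na(acs)]
  unname(vapply(acs, .revcomp_rna, character(1)))
}

.write_bundle <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) if (!is.null(d))
    utils::write.table(d, file.path(config$out_dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(out$alignments, "alignments.tsv")
  wt(out$abundance_treated, "abundance_treated.tsv")
  wt(out$abundance_control, "abundance_control.tsv")
  if (!is.null(out$depletion)) wt(out$depletion$table, "depletion.tsv")
  wt(as.data.frame(out$pileup_treated), "pileup_treated.tsv")
  wt(as.data.frame(out$calls), "calls.tsv")
  wt(out$consensus, "consensus.tsv")
  wt(out$digest, "digest.tsv")
  summary <- list(
    seed = config$seed,
    thresholds = config[c("min_full", "max_frag", "window", "k_mad",
                          "min_frac", "min_score", "tol", "max_mismatch")],
    n_alignments = nrow(out$alignments),
    depleted = if (!is.null(out$depletion))
      out$depletion$table$trna_id[out$depletion$table$depleted] else list(),
    calls = if (nrow(out$calls))
      paste(out$calls$trna_id, paste0(out$calls$nick5, "|", out$calls$nick3))
      else list(),
    spanning_product_length = if (!is.null(out$signature))
      out$signature$spanning$length else NULL,
    toeprint_positions = out$toeprint$stall$toeprint_positions)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(config$out_dir)
}
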