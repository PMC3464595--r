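## End-to-end orchestration: clean -> collapse -> classify -> known miRNA ->
## hairpin discovery -> differential expression -> target scan, with
## report-table TSV outputs and a reproducibility log.

#' Build and validate a pipeline configuration
#'
#' @param x either a named list of settings or the path to a YAML file
#'   containing them.  Required: \code{perfect_fastq}, \code{imperfect_fastq},
#'   \code{genome_fasta}, \code{reference_fasta}, \code{adapter3},
#'   \code{outdir}.  Optional: \code{transcripts_fasta} (enables the target
#'   scan), \code{adapter5}, length bounds, hairpin thresholds, fold/alpha,
#'   target thresholds, \code{seed}.
#' @return validated config list of class \code{pipeline_config}
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x) && length(x) == 1) yaml::read_yaml(x) else x
  if (!is.list(cfg)) stop("pipeline_config: expected a list or a YAML path", call. = FALSE)
  defaults <- list(
    adapter5 = NULL, transcripts_fasta = NULL,
    min_len = 18, max_len = 30,
    flank = 250, mfe_max = -18, duplex_max_mismatch = 4, duplex_max_bulge = 2,
    min_hairpin_len = 50, min_mature_count = 5, max_loci = 20,
    fold_threshold = 1.5, alpha = 0.05,
    target_max_mismatch = 3, target_max_penalty = 4.0,
    seed = 1
  )
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  required <- c("perfect_fastq", "imperfect_fastq", "genome_fasta",
                "reference_fasta", "adapter3", "outdir")
  missing <- required[!vapply(required, function(nm) !is.null(cfg[[nm]]), logical(1))]
  if (length(missing)) {
    stop("pipeline_config: missing required settings: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  paths <- c("perfect_fastq", "imperfect_fastq", "genome_fasta", "reference_fasta")
  if (!is.null(cfg$transcripts_fasta)) paths <- c(paths, "transcripts_fasta")
  for (nm in paths) {
    if (!file.exists(cfg[[nm]])) {
      stop("pipeline_config: file not found for ", nm, ": ", cfg[[nm]], call. = FALSE)
    }
  }
  if (cfg$min_len < 1 || cfg$max_len < cfg$min_len) {
    stop("pipeline_config: invalid length bounds", call. = FALSE)
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("pipeline_config: alpha must be in (0,1)", call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full small RNA pipeline
#'
#' Executes all stages on the two libraries and writes the report bundle to
#' \code{config$outdir}: the cleaning ledger, category tallies, overlap
#' statistics, known-miRNA and family tables, novel hairpin candidates,
#' the differential expression table, per-length histograms, first-nucleotide
#' bias of accepted novel matures, target hits (when transcripts are given)
#' and a run log.  All outputs are pure functions of the inputs and the
#' configuration, so a rerun with the same config yields byte-identical
#' files.
#'
#' @param config a \code{\link{pipeline_config}} (or list / YAML path, which
#'   is validated first)
#' @return invisible list of the computed tables and output paths
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  cfg <- config
  set.seed(cfg$seed)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    sprintf("sRNAbud %s", as.character(utils::packageVersion("sRNAbud"))),
    sprintf("seed: %d", cfg$seed),
    sprintf("parameters: %s",
            paste(sprintf("%s=%s",
                          c("min_len", "max_len", "flank", "mfe_max",
                            "min_mature_count", "fold_threshold", "alpha"),
                          c(cfg$min_len, cfg$max_len, cfg$flank, cfg$mfe_max,
                            cfg$min_mature_count, cfg$fold_threshold, cfg$alpha)),
                  collapse = " "))
  )
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_lines <<- c(log_lines, sprintf("stage %s: done", name))
    res
  }

  ## 1. clean + collapse
  libs <- list(perfect = cfg$perfect_fastq, imperfect = cfg$imperfect_fastq)
  cleaned <- stage("clean", lapply(libs, function(p) {
    clean_reads(read_fastq(p), adapter3 = cfg$adapter3, adapter5 = cfg$adapter5,
                min_len = cfg$min_len, max_len = cfg$max_len)
  }))
  table1 <- do.call(rbind, lapply(names(cleaned), function(nm) {
    cbind(library = nm, cleaned[[nm]]$summary)
  }))
  tags_by_lib <- stage("collapse", lapply(cleaned, function(cl) collapse_tags(cl$clean)))
  tags <- merge(tags_by_lib$perfect, tags_by_lib$imperfect, by = "seq", all = TRUE)
  names(tags) <- c("seq", "count_perfect", "count_imperfect")
  tags$count_perfect[is.na(tags$count_perfect)] <- 0L
  tags$count_imperfect[is.na(tags$count_imperfect)] <- 0L
  tags <- tags[order(-(tags$count_perfect + tags$count_imperfect), tags$seq), ]
  rownames(tags) <- NULL
  N1 <- cleaned$perfect$summary$clean_total
  N2 <- cleaned$imperfect$summary$clean_total
  log_lines <- c(log_lines, sprintf("clean totals: N1=%d N2=%d", N1, N2))

  ## 2. summaries
  fig1 <- do.call(rbind, lapply(names(tags_by_lib), function(nm) {
    cbind(library = nm, length_histogram(tags_by_lib[[nm]], weighted = TRUE))
  }))
  table3 <- overlap_stats(tags_by_lib$perfect, tags_by_lib$imperfect,
                          labels = c("perfect", "imperfect"))
  table3$mean_frequency <- round_half_up(table3$mean_frequency, 2)

  ## 3. annotation
  refs <- stage("annotate", read_reference_fasta(cfg$reference_fasta))
  ann <- classify_tags(tags, refs)
  table2 <- ann$tally
  mature <- refs[refs$class == "mature_miRNA", ]
  hits <- match_known_mirnas(tags, mature)
  table4 <- hits[order(hits$family_id, hits$mirna_id), ]
  rownames(table4) <- NULL
  families <- family_summary(hits)

  ## 4. hairpin discovery on unannotated tags
  unann <- ann$assignments[ann$assignments$class == "unannotated", ]
  genome <- stage("load genome", {
    g <- Biostrings::readDNAStringSet(cfg$genome_fasta)
    setNames(as.character(g), sub("\\s.*", "", names(g)))
  })
  th <- hairpin_thresholds(mfe_max = cfg$mfe_max,
                           max_mismatch = cfg$duplex_max_mismatch,
                           max_bulge = cfg$duplex_max_bulge,
                           min_hairpin_len = cfg$min_hairpin_len,
                           min_mature_count = cfg$min_mature_count,
                           flank = cfg$flank, max_loci = cfg$max_loci)
  table5 <- stage("hairpin", predict_hairpins(unann, genome, th))
  novel <- attr(table5, "clusters")
  fig6 <- first_nt_bias(novel$tag)
  log_lines <- c(log_lines,
                 sprintf("hairpin: %d candidate loci, %d accepted (%d after clustering)",
                         nrow(table5), sum(table5$accepted), nrow(novel)))

  ## 5. differential expression (known miRNAs + accepted novel matures)
  de_in <- rbind(
    data.frame(name = hits$mirna_id, x = hits$count_perfect,
               y = hits$count_imperfect, stringsAsFactors = FALSE),
    if (nrow(novel) > 0) {
      idx <- match(novel$tag, tags$seq)
      data.frame(name = sprintf("novel_%s", novel$location),
                 x = tags$count_perfect[idx], y = tags$count_imperfect[idx],
                 stringsAsFactors = FALSE)
    }
  )
  de <- stage("diffexp", call_differential(de_in, N1, N2,
                                           fold_threshold = cfg$fold_threshold,
                                           alpha = cfg$alpha))
  table6 <- format_de_table(de[de$significant, , drop = FALSE])
  log_lines <- c(log_lines, sprintf("diffexp: %d records, %d significant",
                                    nrow(de), sum(de$significant)))

  ## 6. targets for differential miRNAs
  target_hits <- NULL
  if (!is.null(cfg$transcripts_fasta)) {
    tx <- Biostrings::readDNAStringSet(cfg$transcripts_fasta)
    tx <- setNames(as.character(tx), sub("\\s.*", "", names(tx)))
    sig <- de[de$significant, , drop = FALSE]
    seq_of <- c(setNames(hits$seq, hits$mirna_id),
                if (nrow(novel) > 0) setNames(novel$tag,
                                              sprintf("novel_%s", novel$location)))
    target_hits <- stage("targets", do.call(rbind, lapply(sig$name, function(nm) {
      scan_targets(seq_of[[nm]], tx, max_mismatch = cfg$target_max_mismatch,
                   max_penalty = cfg$target_max_penalty, mirna_id = nm)
    })))
    log_lines <- c(log_lines, sprintf("targets: %d hits",
                                      if (is.null(target_hits)) 0L else nrow(target_hits)))
  }

  out <- list(table1_cleaning = table1, table2_categories = table2,
              table3_overlap = table3, table4_known = table4,
              families = families, table5_hairpins = table5,
              novel_accepted = novel, table6_diffexp = table6,
              de_records = de, fig1_length = fig1, fig6_first_nt = fig6,
              targets = target_hits, N1 = N1, N2 = N2)
  for (nm in c("table1_cleaning", "table2_categories", "table3_overlap",
               "table4_known", "families", "table5_hairpins",
               "novel_accepted", "table6_diffexp", "fig1_length",
               "fig6_first_nt", "targets")) {
    if (!is.null(out[[nm]])) {
      write_tsv(out[[nm]], file.path(cfg$outdir, paste0(nm, ".tsv")))
    }
  }
  writeLines(log_lines, file.path(cfg$outdir, "run_log.txt"))
  invisible(out)
}
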