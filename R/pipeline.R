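## Pipeline orchestration: the subcommands of the command-line interface
## (simulate, extract, features, motifs, train, evaluate) as one R entry
## point.  Every run writes a JSON manifest (config + seed + package
## version) next to its outputs; outputs are plain TSV/JSON.

write_manifest <- function(out_dir, config) {
  manifest <- list(config = config,
                   package = "intronclass",
                   version = as.character(utils::packageVersion("intronclass")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

cfg_get <- function(config, key, default) {
  if (!is.null(config[[key]])) config[[key]] else default
}

#' Run a pipeline stage
#'
#' Dispatches one subcommand with a named-list configuration (the R-level
#' equivalent of the command line; the `intronclass` script under
#' `inst/cli/` forwards shell arguments here).  Stages:
#'
#' * `simulate` — toy genome + GFF3 + truth table
#'   (`n_genes`, `seed`, `out`).
#' * `extract` — introns from `gff` + `genome` (`min_len`, `max_len_ri`,
#'   `max_len_csi`, `keep_all_rna_types`, `out`): writes `introns.tsv`
#'   (coordinates, labels, terminal dinucleotides), `introns.fa` and
#'   `windows.tsv`.
#' * `features` — full 52-column feature table from `introns`
#'   (the `introns.tsv`/`windows.tsv` pair or a combined TSV): writes
#'   `features.tsv`.
#' * `motifs` — contrastive k-mer statistics from `introns`
#'   (`kmin`, `kmax`, `conf_min`, `d_min`): writes `motif_stats.tsv` with
#'   a `selected` column.
#' * `train` — fit [ri_classifier()] on `features` (`preset`, `model`
#'   = `rf`/`psosvm`, `seed`): writes `report.json` and `roc.csv`.
#' * `evaluate` — [evaluate()] on a TSV of `score`,`label` columns
#'   (`scores`, `threshold`): writes `report.json`.
#'
#' @param config Named list with at least `command` and `out` (output
#'   directory).
#' @return Invisibly, the stage's main result object.
#' @export
run_pipeline <- function(config) {
  command <- config$command
  if (is.null(command) ||
      !command %in% c("simulate", "extract", "features", "motifs",
                      "train", "evaluate"))
    stop("unknown command: ", if (is.null(command)) "<none>" else command)
  out_dir <- cfg_get(config, "out", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg_get(config, "seed", 1L))

  result <- switch(command,
    simulate = {
      cfg <- sim_config(n_genes = as.integer(cfg_get(config, "n_genes", 60L)),
                        seed = seed)
      simulate_genome_annotation(cfg, out_dir)
    },
    extract = {
      if (is.null(config$gff) || is.null(config$genome))
        stop("extract requires --gff and --genome")
      max_len <- c(RI = as.numeric(cfg_get(config, "max_len_ri", NA)),
                   CSI = as.numeric(cfg_get(config, "max_len_csi", NA)))
      introns <- extract_introns(
        config$gff, config$genome,
        min_len = as.integer(cfg_get(config, "min_len", 20L)),
        max_len = max_len,
        keep_all_rna_types = isTRUE(config$keep_all_rna_types))
      dinuc <- terminal_dinucleotide_summary(introns)
      coords <- introns[, c("gene_id", "transcript_ids", "chromosome",
                            "strand", "start", "end", "length", "label")]
      coords$terminal_dinucleotides <-
        paste0(substr(introns$sequence, 1, 2), "-",
               substring(introns$sequence, nchar(introns$sequence) - 1))
      utils::write.table(coords, file.path(out_dir, "introns.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      fa <- Biostrings::DNAStringSet(toupper(introns$sequence))
      names(fa) <- sprintf("%s|%s:%d-%d|%s", introns$gene_id,
                           introns$chromosome, introns$start, introns$end,
                           introns$label)
      Biostrings::writeXStringSet(fa, file.path(out_dir, "introns.fa"))
      utils::write.table(
        introns[, c("gene_id", "chromosome", "start", "end", "label",
                    "sequence", "donor_pwm_window", "acceptor_pwm_window",
                    "donor_exon_window", "donor_intron_window",
                    "acceptor_intron_window", "acceptor_exon_window")],
        file.path(out_dir, "windows.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(dinuc, file.path(out_dir, "terminal_dinucleotides.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      introns
    },
    features = {
      records <- read_records(config)
      feats <- intron_features(records)
      utils::write.table(feats, file.path(out_dir, "features.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      feats
    },
    motifs = {
      records <- read_records(config)
      stats <- dataset_motif_stats(
        records$sequence[records$label == "RI"],
        records$sequence[records$label == "CSI"],
        k_range = as.integer(cfg_get(config, "kmin", 2L)):
                  as.integer(cfg_get(config, "kmax", 5L)))
      conf_min <- as.numeric(cfg_get(config, "conf_min", 0.8))
      d_min <- as.numeric(cfg_get(config, "d_min", 0.1))
      stats$selected <- stats$motif %in%
        select_frequent_motifs(stats, conf_min, d_min)
      utils::write.table(stats, file.path(out_dir, "motif_stats.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      stats
    },
    train = {
      records <- read_records(config)
      preset <- cfg_get(config, "preset", "ABC")
      if (!preset %in% c("A", "AC", "ABC", "complete52", "optimized27"))
        stop("invalid preset: ", preset)
      model <- cfg_get(config, "model", "rf")
      fit <- ri_classifier(records, method = model, preset = preset,
                           seed = seed,
                           undersample_n = as.integer(cfg_get(config, "undersample_n", NA)))
      rep <- fit$report
      payload <- list(method = model, preset = preset, seed = seed,
                      confusion = rep[c("tp", "fp", "tn", "fn")],
                      metrics = rep[c("accuracy", "sensitivity",
                                      "specificity", "f_measure", "auc")])
      if (model == "rf") {
        payload$num_trees <- fit$fit$num_trees
        payload$mtry <- fit$fit$mtry
      } else {
        payload$best_c <- fit$fit$pso$best_c
        payload$best_gamma <- fit$fit$pso$best_gamma
        payload$fitness_trace <- fit$fit$pso$trace
      }
      jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      utils::write.table(rep$roc, file.path(out_dir, "roc.csv"),
                         sep = ",", quote = FALSE, row.names = FALSE)
      fit
    },
    evaluate = {
      tab <- utils::read.delim(config$scores)
      rep <- evaluate(tab$score, tab$label,
                      threshold = as.numeric(cfg_get(config, "threshold", 0.5)))
      jsonlite::write_json(
        rep[c("tp", "fp", "tn", "fn", "accuracy", "sensitivity",
              "specificity", "f_measure", "auc")],
        file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
      rep
    })
  write_manifest(out_dir, config)
  invisible(result)
}

## records from either a windows.tsv path or an in-memory data frame
read_records <- function(config) {
  if (!is.null(config$records)) return(config$records)
  if (is.null(config$introns))
    stop(config$command, " requires --introns (windows.tsv from extract)")
  utils::read.delim(config$introns, stringsAsFactors = FALSE)
}
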