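#' Write a complete simulated input bundle to disk
#'
#' Generates one dual-ORF gene plus every downstream input the pipeline
#' consumes — FASTA, GFF3 anchor, P-site count TSV, luciferase replicate
#' TSV, codon-alignment FASTA and DMS reactivity TSV — together with a
#' manifest JSON recording the seed and all true parameters. All generation
#' is driven by `seed`, so the bundle is bit-reproducible.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed driving all randomness.
#' @param theta true frameshifting efficiency.
#' @param motif heptamer motif name.
#' @param depth expected footprint total.
#' @param frame_fidelity,per_codon_dispersion see [simulate_ribo_profile()].
#' @param n_replicates,luc_sigma see [simulate_luciferase()].
#' @param n_rows,syn_rate,constraint_factor see
#'   [simulate_codon_alignment()]; the constrained window is placed over the
#'   codons upstream of the heptamer, where the stem-loop stimulator sits.
#' @param dms_snr see [simulate_dms()].
#' @return invisibly, the manifest list.
#' @export
simulate_inputs <- function(dir, seed = 1L, theta = 0.4, motif = "Ty1",
                            depth = 1e5, frame_fidelity = 0.9,
                            per_codon_dispersion = 5,
                            n_replicates = 8L, luc_sigma = 0.1,
                            n_rows = 20L, syn_rate = 0.3,
                            constraint_factor = 0.2, dms_snr = 2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  gene <- simulate_gene(motif = motif, orf0_codons = 60L, orf1_codons = 40L,
                        seq_id = "simgene")
  write_fasta(stats::setNames(gene$sequence, "simgene"),
              file.path(dir, "transcript.fasta"))
  gr <- GenomicRanges::GRanges("simgene",
          IRanges::IRanges(gene$orf_start, gene$model$orf0_end),
          strand = "+", type = "CDS", phase = 0L, ID = "simgene.orf0")
  rtracklayer::export(gr, file.path(dir, "annotation.gff3"), format = "gff3")
  prof <- simulate_ribo_profile(gene, theta = theta, depth = depth,
                                frame_fidelity = frame_fidelity,
                                per_codon_dispersion = per_codon_dispersion)
  write_ribo_counts(prof, file.path(dir, "psite_counts.tsv"))
  luc <- simulate_luciferase(theta = theta, n_replicates = n_replicates,
                             luc_sigma = luc_sigma)
  write_luciferase_tsv(luc, file.path(dir, "luciferase.tsv"))
  ## conservation: constrain the 17 codons upstream of the P-site codon and
  ## freeze the heptamer codons themselves
  cds <- substr(gene$sequence, gene$orf_start, gene$model$orf0_end)
  p_codon_idx <- (gene$model$site$start - gene$orf_start) %/% 3L + 1L
  win <- c(max(1L, p_codon_idx - 17L), p_codon_idx - 1L)
  aln <- simulate_codon_alignment(cds, n_rows = n_rows, syn_rate = syn_rate,
                                  constraint_window = win,
                                  constraint_factor = constraint_factor,
                                  freeze_columns = p_codon_idx + 0:2)
  write_codon_alignment(aln, file.path(dir, "orthologs_codon.fasta"))
  fold_win <- c(max(1L, gene$model$site$start - 80L),
                gene$model$site$start - 1L)
  stem <- find_best_hairpin(gene$sequence, fold_win)
  if (!is.null(stem)) {
    track <- simulate_dms(stem, gene$sequence, dms_snr = dms_snr)
    write_reactivity_tsv(track, file.path(dir, "dms_reactivity.tsv"))
  }
  manifest <- list(seed = seed, theta = theta, motif = motif, depth = depth,
                   frame_fidelity = frame_fidelity,
                   per_codon_dispersion = per_codon_dispersion,
                   n_replicates = n_replicates, luc_sigma = luc_sigma,
                   n_rows = n_rows, syn_rate = syn_rate,
                   constraint_window = win,
                   constraint_factor = constraint_factor, dms_snr = dms_snr,
                   orf_start = gene$orf_start,
                   site_start = gene$model$site$start,
                   orf0_end = gene$model$orf0_end,
                   orf1_end = gene$model$orf1_end,
                   has_hairpin = !is.null(stem))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

pipeline_defaults <- function() {
  list(orf_start = 1L, motifs = NULL, trim_codons = 1L, mode = "region",
       window = 17L, method = "mean_of_ratios", reference = 1L,
       fold_upstream = 80L, seed = 1L)
}

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  def <- pipeline_defaults()
  for (k in names(def)) if (is.null(config[[k]])) config[[k]] <- def[[k]]
  if (is.null(config$out)) stop("config error: 'out' directory is required")
  for (k in c("fasta", "gff", "counts", "luciferase", "alignment",
              "reactivity")) {
    if (!is.null(config[[k]]) && !file.exists(config[[k]])) {
      stop("config error: ", k, " path does not exist: ", config[[k]])
    }
  }
  if (!config$mode %in% c("region", "frame")) {
    stop("config error: mode must be 'region' or 'frame'")
  }
  if (!config$method %in% c("mean_of_ratios", "ratio_of_means")) {
    stop("config error: unknown method ", config$method)
  }
  config
}

#' Run the frameshift-discovery pipeline
#'
#' Executes the stages the supplied inputs allow, in dependency order:
#' `scan` (FASTA, optional GFF3 anchors) -> `ribofs` (P-site counts) and
#' `fold` (upstream hairpin + optional DMS consistency); `lucfs`
#' (luciferase TSV) and `consscan` (codon alignment FASTA) run
#' independently. Each stage writes a TSV under `out`; a combined per-site
#' report (`report.tsv`) and machine-readable `summary.json` are written at
#' the end. A failing stage halts its dependents but not independent
#' stages; its error is recorded in the summary and `failed`.
#'
#' @param config list or YAML file path. Recognised fields: `fasta`, `gff`,
#'   `counts`, `luciferase`, `alignment`, `reactivity` (input paths);
#'   `stages` (subset to run); `orf_start`, `motifs`, `trim_codons`,
#'   `mode`, `window`, `method`, `reference`, `fold_upstream`, `seed`;
#'   `out` (output directory, required).
#' @return invisibly, list(results, failed); `failed` is a named character
#'   vector of stage error messages (empty on full success).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  results <- list(); failed <- character(0)
  want <- function(stage) is.null(config$stages) || stage %in% config$stages
  run_stage <- function(stage, fn) {
    out <- tryCatch(fn(), error = function(e) {
      message("stage ", stage, " failed: ", conditionMessage(e))
      structure(conditionMessage(e), class = "stage_error")
    })
    if (inherits(out, "stage_error")) {
      failed[[stage]] <<- as.character(out)
      NULL
    } else {
      results[[stage]] <<- out
      out
    }
  }

  seqs <- NULL; scan_res <- NULL
  if (!is.null(config$fasta) && want("scan")) {
    scan_res <- run_stage("scan", function() {
      seqs <<- read_fasta(config$fasta)
      anchors <- rep(as.integer(config$orf_start), length(seqs))
      names(anchors) <- names(seqs)
      if (!is.null(config$gff)) {
        orfs <- read_gff3_orfs(config$gff)
        anchors[orfs$seq_id] <- orfs$start
      }
      motifs <- if (is.null(config$motifs)) heptamer_motifs() else
        heptamer_motifs(config$motifs)
      sites <- list(); models <- list()
      for (id in names(seqs)) {
        s <- scan_heptamers(seqs[[id]], orf_start = anchors[[id]],
                            motifs = motifs, seq_id = id)
        for (r in seq_len(nrow(s))) {
          m <- build_dual_orf_model(seqs[[id]], s[r, ],
                                    orf_start = anchors[[id]], seq_id = id)
          models[[length(models) + 1L]] <- m
        }
        sites[[id]] <- s
      }
      sites <- do.call(rbind, sites)
      rownames(sites) <- NULL
      write_sites_tsv(sites, file.path(config$out, "sites.tsv"),
                      models = models)
      if (length(models)) {
        write_models_gff3(models, file.path(config$out, "models.gff3"))
      }
      list(sites = sites, models = models)
    })
  }

  if (!is.null(config$counts) && want("ribofs")) {
    if (is.null(scan_res)) {
      failed[["ribofs"]] <- "dependency 'scan' did not run"
    } else {
      run_stage("ribofs", function() {
        ests <- lapply(scan_res$models, function(m) {
          prof <- read_ribo_counts(config$counts, seq_id = m$seq_id,
                                   transcript_length = nchar(seqs[[m$seq_id]]))
          fs_efficiency(prof, m, trim_codons = config$trim_codons,
                        mode = config$mode)
        })
        df <- do.call(rbind, lapply(ests, function(e) {
          data.frame(seq_id = e$seq_id, efficiency_pct = e$efficiency_pct,
                     rpf0 = e$rpf0, rpf1 = e$rpf1, codons0 = e$codons0,
                     codons1 = e$codons1, mode = e$mode)
        }))
        utils::write.table(df, file.path(config$out, "ribo_fs.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        ests
      })
    }
  }

  if (!is.null(config$luciferase) && want("lucfs")) {
    run_stage("lucfs", function() {
      reps <- read_luciferase_tsv(config$luciferase)
      res <- fs_from_luciferase(reps$tests, reps$controls,
                                method = config$method)
      df <- data.frame(efficiency_pct = res$efficiency_pct,
                       sd_pct = res$sd_pct, n_test = res$n_test,
                       n_control = res$n_control, method = res$method)
      utils::write.table(df, file.path(config$out, "reporter_fs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res
    })
  }

  if (!is.null(config$alignment) && want("consscan")) {
    run_stage("consscan", function() {
      aln <- read_codon_alignment(config$alignment,
                                  reference = config$reference)
      scan <- window_synonymy_scan(aln, window = config$window)
      utils::write.table(scan, file.path(config$out, "conservation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      calls <- classify_columns(aln)
      utils::write.table(
        data.frame(row = rownames(calls)[row(calls)],
                   codon = as.integer(col(calls)),
                   kind = as.character(calls))[!is.na(as.character(calls)), ],
        file.path(config$out, "substitution_calls.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      scan
    })
  }

  if (!is.null(config$fasta) && want("fold")) {
    if (is.null(scan_res)) {
      failed[["fold"]] <- "dependency 'scan' did not run"
    } else {
      run_stage("fold", function() {
        rows <- list(); db_lines <- character(0)
        for (m in scan_res$models) {
          w <- c(max(1L, m$site$start - config$fold_upstream),
                 m$site$start - 1L)
          stem <- find_best_hairpin(seqs[[m$seq_id]], w)
          if (is.null(stem)) {
            rows[[length(rows) + 1L]] <- data.frame(
              seq_id = m$seq_id, site_start = m$site$start, score = NA,
              span_start = NA, span_end = NA, spacer_nt = NA,
              spacer_codons = NA, dms_consistency = NA)
            next
          }
          sp <- spacer_to_site(stem, m$site)
          dms <- NA_real_
          if (!is.null(config$reactivity)) {
            track <- read_reactivity_tsv(config$reactivity)
            dms <- dms_consistency(stem, track)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            seq_id = m$seq_id, site_start = m$site$start,
            score = stem$score, span_start = stem$span[1],
            span_end = stem$span[2], spacer_nt = sp$spacer_nt,
            spacer_codons = sp$spacer_codons, dms_consistency = dms)
          db <- stem_to_dotbracket(stem, seqs[[m$seq_id]])
          db_lines <- c(db_lines, paste0(">", m$seq_id, " window ", w[1],
                                         "-", w[2]), db[["sequence"]],
                        db[["structure"]])
        }
        df <- do.call(rbind, rows)
        utils::write.table(df, file.path(config$out, "hairpins.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        if (length(db_lines)) {
          writeLines(db_lines, file.path(config$out, "structures.db"))
        }
        df
      })
    }
  }

  ## combined per-site report
  if (!is.null(scan_res) && nrow(scan_res$sites)) {
    rep_df <- scan_res$sites
    if (!is.null(results$ribofs)) {
      rep_df$ribo_fs_pct <- vapply(results$ribofs, function(e)
        e$efficiency_pct, numeric(1))[seq_len(nrow(rep_df))]
    }
    if (!is.null(results$lucfs)) {
      rep_df$reporter_fs_pct <- results$lucfs$efficiency_pct
    }
    if (!is.null(results$consscan)) {
      sc <- results$consscan
      best <- sc[which.min(sc$p_value), , drop = FALSE]
      rep_df$min_p_window_center <- if (nrow(best)) best$center_codon else NA
      rep_df$min_p <- if (nrow(best)) best$p_value else NA
    }
    if (!is.null(results$fold)) {
      rep_df$hairpin_score <- results$fold$score[seq_len(nrow(rep_df))]
      rep_df$spacer_nt <- results$fold$spacer_nt[seq_len(nrow(rep_df))]
    }
    utils::write.table(rep_df, file.path(config$out, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- list(
    seed = config$seed,
    stages_run = names(results),
    stages_failed = as.list(failed),
    n_sites = if (!is.null(scan_res)) nrow(scan_res$sites) else 0L
  )
  jsonlite::write_json(summary, file.path(config$out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = results, failed = failed))
}
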