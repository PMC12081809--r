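#' Pipeline run configuration
#'
#' One source of truth for every tunable constant of the pipeline. The
#' defaults are the analysis constants: fold-change threshold 1.5, bimodal
#' ratio threshold 2, isotype-set cutoff 40, KDE bandwidth 0.05 (log10
#' units), Savitzky-Golay window 5 / order 2, bootstrap count 1000.
#'
#' If `screen_dir` / `lfc_path` etc. are `NULL`, synthetic inputs with
#' planted ground truth are generated from `seed` (see [screen_truth()],
#' [transcriptome_truth()]).
#'
#' @param out_dir Output directory for all stage tables and the manifest.
#' @param seed Integer seed governing every stochastic stage.
#' @param fc_threshold Upregulation fold-change threshold.
#' @param isotype_cutoff Isotype-set size above which the KDE-mode baseline
#'   applies.
#' @param kde_bandwidth Baseline KDE bandwidth, log10 units.
#' @param sg_window,sg_order Savitzky-Golay derivative filter parameters.
#' @param eval_band Percentile band for the bimodality ratio.
#' @param gsea_B Bootstrap sets per GSEA null.
#' @param gsea_exponent GSEA weight exponent p.
#' @param screen_dir Optional existing screen bundle (see [read_screen_bundle()]).
#' @param lfc_path,gmt_path,go_path,panel_path Optional existing transcriptome
#'   inputs; all four must be given together.
#' @param screen_truth,transcriptome_truth Optional truth objects overriding
#'   the defaults for simulation.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       seed = 1L,
                       fc_threshold = 1.5,
                       isotype_cutoff = 40L,
                       kde_bandwidth = 0.05,
                       sg_window = 5L,
                       sg_order = 2L,
                       eval_band = c(5, 95),
                       gsea_B = 1000L,
                       gsea_exponent = 1,
                       screen_dir = NULL,
                       lfc_path = NULL, gmt_path = NULL, go_path = NULL,
                       panel_path = NULL,
                       screen_truth = NULL,
                       transcriptome_truth = NULL) {
  if (fc_threshold <= 1) abort("fc_threshold must be > 1")
  if (kde_bandwidth <= 0 || isotype_cutoff < 1 || gsea_B < 2) {
    abort("thresholds must be positive (cutoff >= 1, B >= 2)")
  }
  tx_paths <- list(lfc_path, gmt_path, go_path, panel_path)
  if (any(!vapply(tx_paths, is.null, logical(1))) &&
      any(vapply(tx_paths, is.null, logical(1)))) {
    abort("lfc_path, gmt_path, go_path and panel_path must be given together")
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         fc_threshold = fc_threshold, isotype_cutoff = isotype_cutoff,
         kde_bandwidth = kde_bandwidth, sg_window = sg_window,
         sg_order = sg_order, eval_band = eval_band, gsea_B = gsea_B,
         gsea_exponent = gsea_exponent, screen_dir = screen_dir,
         lfc_path = lfc_path, gmt_path = gmt_path, go_path = go_path,
         panel_path = panel_path, screen_truth = screen_truth,
         transcriptome_truth = transcriptome_truth),
    class = "run_config"
  )
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full surfaceome + transcriptome pipeline
#'
#' Stages, in dependency order: ingest (or simulate) the screen; baseline
#' normalization; fold changes with Venn partition and ternary coordinates;
#' QDF bimodality; ingest (or simulate) the transcriptome tables; bootstrap
#' z-scored GSEA; membrane-target triage. All stage outputs are
#' self-describing delimited tables under `config$out_dir`, plus a JSON
#' manifest recording the package version, seed, and a hash of the
#' configuration. Reruns with the same config and inputs are byte-identical.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the in-memory stage results
#'   (`screen`, `normalized`, `fc`, `venn`, `ternary`, `bimodality`,
#'   `enrichment`, `triage`, `manifest`).
#' @export
run_all <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) abort("`config` must be a run_config")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[sasome] ", ...)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort("stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  # -- ingest / simulate screen ------------------------------------------
  screen <- stage("ingest", {
    if (!is.null(config$screen_dir)) {
      read_screen_bundle(config$screen_dir)
    } else {
      truth <- config$screen_truth %||% default_screen_truth()
      generate_screen(truth, seed = config$seed)
    }
  })
  write_screen(screen, file.path(out, "screen"))
  say("ingest: ", length(screen$plate_map$marker), " markers x ",
      length(screen$conditions), " conditions, ",
      nrow(screen$events[[1]]), " events/well")

  # -- normalize ----------------------------------------------------------
  normalized <- stage("normalize", {
    normalize_screen(screen, cutoff = config$isotype_cutoff,
                     bandwidth = config$kde_bandwidth)
  })
  write_tsv(normalized, file.path(out, "normalized.tsv"))
  say("normalize: ", nrow(normalized), " marker x condition profiles")

  # -- differential -------------------------------------------------------
  fc <- stage("diff", fold_changes(normalized))
  venn <- stage("diff", select_and_partition(fc, tau_up = config$fc_threshold))
  sel <- unlist(venn$regions, use.names = FALSE)
  ternary <- stage("diff", {
    if (length(sel)) ternary_coordinates(fc, sel) else NULL
  })
  write_tsv(fc, file.path(out, "fc.tsv"))
  jsonlite::write_json(
    list(regions = venn$regions, total_selected = venn$total_selected,
         down_set = venn$down_set, tau_up = venn$tau_up,
         tau_down = venn$tau_down),
    file.path(out, "venn.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(ternary)) write_tsv(ternary, file.path(out, "ternary.tsv"))
  say("diff: ", venn$total_selected, " markers selected at fold change >= ",
      config$fc_threshold)

  # -- bimodality ---------------------------------------------------------
  bimod <- stage("bimod", {
    screen_bimodality(screen, band = config$eval_band,
                      window = config$sg_window, order = config$sg_order)
  })
  write_tsv(bimod, file.path(out, "bimodality.tsv"))
  say("bimod: ", sum(bimod$class == "bimodal"), " wells flagged bimodal of ",
      nrow(bimod))

  # -- transcriptome inputs ----------------------------------------------
  tx <- stage("transcriptome", {
    if (!is.null(config$lfc_path)) {
      list(lfc = read.delim(config$lfc_path),
           gene_sets = read_gmt(config$gmt_path),
           go = read_go_table(config$go_path),
           panel = readLines(config$panel_path))
    } else {
      truth <- config$transcriptome_truth %||% transcriptome_truth()
      generate_lfc_table(truth, seed = config$seed)
    }
  })
  write_tsv(tx$lfc, file.path(out, "lfc.tsv"))
  write_gmt(tx$gene_sets, file.path(out, "gene_sets.gmt"))
  write_tsv(tx$go, file.path(out, "go.tsv"))
  writeLines(tx$panel, file.path(out, "panel.txt"))

  # -- GSEA ---------------------------------------------------------------
  enrichment <- stage("gsea", {
    run_enrichment(tx$lfc, tx$gene_sets, B = config$gsea_B,
                   seed = config$seed, exponent = config$gsea_exponent)
  })
  write_tsv(enrichment, file.path(out, "enrichment.tsv"))
  say("gsea: ", length(tx$gene_sets), " sets x ",
      nrow(unique(tx$lfc[, c("cell_line", "treatment")])), " rankings, B = ",
      config$gsea_B)

  # -- triage -------------------------------------------------------------
  triage <- stage("triage", {
    suppressWarnings(triage_membrane_targets(
      tx$lfc, tx$go, screen_panel = tx$panel,
      fc_threshold = config$fc_threshold))
  })
  write_tsv(triage$results, file.path(out, "triage.tsv"))
  say("triage: ", nrow(triage$emitted), " candidate membrane targets (",
      paste(triage$venn_counts, collapse = "/"), " by 1/2/3 treatments)")

  # -- manifest -----------------------------------------------------------
  cfg_json <- file.path(out, "config.json")
  cfg <- config
  cfg$out_dir <- NULL  # keeps reruns into different directories comparable
  cfg$screen_truth <- NULL
  cfg$transcriptome_truth <- NULL
  jsonlite::write_json(unclass(cfg), cfg_json, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  manifest <- list(
    package = "sasome",
    version = as.character(utils::packageVersion("sasome")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_json)),
    outputs = c("normalized.tsv", "fc.tsv", "venn.json", "ternary.tsv",
                "bimodality.tsv", "lfc.tsv", "gene_sets.gmt", "go.tsv",
                "panel.txt", "enrichment.tsv", "triage.tsv")
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: outputs in ", out)

  invisible(list(screen = screen, normalized = normalized, fc = fc,
                 venn = venn, ternary = ternary, bimodality = bimod,
                 transcriptome = tx, enrichment = enrichment,
                 triage = triage, manifest = manifest))
}

# Default simulated screen: 100 markers, two isotype groups (95 + 5), a few
# planted up/down effects and one bimodal marker, so every downstream branch
# is exercised by the default pipeline.
default_screen_truth <- function() {
  truth <- screen_truth()
  fx <- truth$marker_effects
  fx["M001", ] <- c(3.0, 1.0, 1.0)       # alisertib-only
  fx["M002", ] <- c(2.0, 2.0, 2.0)       # shared across treatments
  fx["M003", ] <- c(1.0, 2.5, 2.5)       # two-treatment
  fx["M004", ] <- c(0.4, 1.0, 1.0)       # downregulated
  truth$marker_effects <- fx
  truth$bimodal_markers <- list(
    M010 = list(weight = 0.5, logmeans = c(2.0, 3.5), logsds = c(0.25, 0.25))
  )
  truth
}
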