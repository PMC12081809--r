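#' Ground-truth specification for a synthetic surfaceome screen
#'
#' Describes a LegendScreen-style antibody panel: each marker well holds
#' per-cell fluorescence intensities for one surface antigen in one condition,
#' and every marker is assigned to an isotype-control well that defines its
#' nonspecific-binding baseline. Intensities are lognormal on the linear scale
#' (Gaussian in log10 units); treatments act multiplicatively on intensity,
#' i.e. additively on the log10 location. A minority of markers may carry a
#' two-component mixture emulating a bimodally expressed antigen.
#'
#' The default panel is a desk-scale stand-in for a ~360-antigen screen:
#' 100 markers over untreated + three senescence-inducing treatments, with one
#' large shared-isotype group (95 markers, resolved by the KDE-mode baseline
#' rule) and one small group (5 markers, resolved by its isotype well).
#'
#' @param markers Character vector of marker ids.
#' @param treatments Character vector of treatment condition ids (the
#'   untreated condition is always generated in addition).
#' @param isotype_groups Named list mapping isotype id to the marker ids that
#'   share it. Every marker must appear in exactly one group. Default: a
#'   95-marker group `"IgG1"` and a 5-marker group `"IgG2a"`.
#' @param marker_effects Numeric matrix (markers x treatments) of true
#'   multiplicative fold changes on intensity; all entries must be > 0.
#'   Default: all 1 (null screen).
#' @param baseline_logmean Per-marker log10 intensity location of the
#'   unexpressed/baseline population; scalar recycled to all markers.
#' @param logsd Per-marker log10 intensity spread; scalar recycled.
#' @param bimodal_markers Named list, one entry per bimodal marker:
#'   `list(weight = w, logmeans = c(lo, hi), logsds = c(s1, s2))` with
#'   `w` strictly in (0, 1) the fraction of cells in the *low* component.
#' @param isotype_logmean log10 location of the isotype-control wells (the
#'   shared baseline distribution, no marker effect).
#' @param events_per_well Number of cells acquired per well.
#' @return An object of class `screen_truth`.
#' @seealso [generate_screen()]
#' @export
screen_truth <- function(markers = sprintf("M%03d", seq_len(100)),
                         treatments = c("alisertib", "cx5461", "etoposide"),
                         isotype_groups = NULL,
                         marker_effects = NULL,
                         baseline_logmean = 2.0,
                         logsd = 0.25,
                         bimodal_markers = list(),
                         isotype_logmean = 2.0,
                         events_per_well = 2000L) {
  markers <- as.character(markers)
  if (anyDuplicated(markers)) abort("duplicated marker ids")
  if (length(treatments) < 1L) abort("at least one treatment required")

  if (is.null(isotype_groups)) {
    n_big <- min(length(markers), 95L)
    isotype_groups <- list(IgG1 = markers[seq_len(n_big)])
    if (length(markers) > n_big) {
      isotype_groups$IgG2a <- markers[(n_big + 1L):length(markers)]
    }
  }
  assigned <- unlist(isotype_groups, use.names = FALSE)
  if (anyDuplicated(assigned)) {
    abort("markers assigned to more than one isotype group: ",
          paste(unique(assigned[duplicated(assigned)]), collapse = ", "))
  }
  missing <- setdiff(markers, assigned)
  if (length(missing)) {
    abort("markers without isotype group: ", paste(missing, collapse = ", "))
  }
  if (any(lengths(isotype_groups) == 0L)) abort("empty isotype group")

  if (is.null(marker_effects)) {
    marker_effects <- matrix(1, length(markers), length(treatments),
                             dimnames = list(markers, treatments))
  }
  marker_effects <- as.matrix(marker_effects)
  if (!identical(rownames(marker_effects), markers) ||
      !identical(colnames(marker_effects), treatments)) {
    abort("`marker_effects` must have rownames = markers, colnames = treatments")
  }
  if (any(!is.finite(marker_effects)) || any(marker_effects <= 0)) {
    abort("fold changes must be finite and > 0")
  }

  baseline_logmean <- rep_len(baseline_logmean, length(markers))
  names(baseline_logmean) <- markers
  logsd <- rep_len(logsd, length(markers))
  names(logsd) <- markers

  for (m in names(bimodal_markers)) {
    bm <- bimodal_markers[[m]]
    if (!m %in% markers) abort("bimodal marker not in panel: ", m)
    if (!is.numeric(bm$weight) || bm$weight <= 0 || bm$weight >= 1) {
      abort("mixture weight must be strictly in (0, 1) for marker ", m)
    }
    if (length(bm$logmeans) != 2L || length(bm$logsds) != 2L) {
      abort("bimodal marker ", m, " needs 2 component log-means and log-sds")
    }
  }

  structure(
    list(markers = markers, treatments = treatments,
         isotype_groups = isotype_groups, marker_effects = marker_effects,
         baseline_logmean = baseline_logmean, logsd = logsd,
         bimodal_markers = bimodal_markers, isotype_logmean = isotype_logmean,
         events_per_well = as.integer(events_per_well)),
    class = "screen_truth"
  )
}

#' Generate a synthetic surfaceome screen with known ground truth
#'
#' Draws per-event intensities for every marker x condition well and every
#' isotype-control well. Unimodal markers are lognormal; bimodal markers are
#' drawn from the specified two-component lognormal mixture; treated wells are
#' scaled by the true multiplicative fold change. Isotype wells are drawn from
#' the shared baseline distribution with no marker effect. Identical seeds
#' yield identical screens.
#'
#' @param truth A [screen_truth()] object.
#' @param seed Integer RNG seed.
#' @return A `sasome_screen` object (see [read_screen()]) with the `truth`
#'   echoed in its `$truth` field. Isotype-control wells appear as event
#'   columns named `ISO_<isotype id>`.
#' @export
generate_screen <- function(truth, seed = 1L) {
  if (!inherits(truth, "screen_truth")) abort("`truth` must be a screen_truth")
  if (truth$events_per_well < 100L) {
    abort("events_per_well must be >= 100 (got ", truth$events_per_well, ")")
  }
  n <- truth$events_per_well
  conditions <- c("untreated", truth$treatments)

  events <- with_seed(seed, {
    out <- vector("list", length(conditions))
    names(out) <- conditions
    for (cond in conditions) {
      cols <- vector("list", length(truth$markers))
      names(cols) <- truth$markers
      for (m in truth$markers) {
        fc <- if (cond == "untreated") 1 else truth$marker_effects[m, cond]
        shift <- log10(fc)
        bm <- truth$bimodal_markers[[m]]
        draws <- if (is.null(bm)) {
          rnorm(n, truth$baseline_logmean[[m]] + shift, truth$logsd[[m]])
        } else {
          low <- rbinom(n, 1L, bm$weight) == 1L
          mu <- ifelse(low, bm$logmeans[1L], bm$logmeans[2L]) + shift
          s <- ifelse(low, bm$logsds[1L], bm$logsds[2L])
          rnorm(n, mu, s)
        }
        cols[[m]] <- 10^draws
      }
      for (iso in names(truth$isotype_groups)) {
        cols[[paste0("ISO_", iso)]] <-
          10^rnorm(n, truth$isotype_logmean, truth$logsd[[1L]])
      }
      out[[cond]] <- as.data.frame(cols, check.names = FALSE)
    }
    out
  })

  plate_map <- data.frame(
    marker = truth$markers,
    isotype_id = vapply(truth$markers, function(m) {
      names(truth$isotype_groups)[vapply(truth$isotype_groups,
                                         function(g) m %in% g, logical(1))]
    }, character(1)),
    well = sprintf("W%03d", seq_along(truth$markers)),
    stringsAsFactors = FALSE
  )
  rownames(plate_map) <- NULL

  new_screen(events, plate_map, conditions, truth = truth)
}

#' Ground-truth specification for a synthetic transcriptome LFC table
#'
#' Describes a differential-expression design of cell lines x treatments x
#' two timepoints, per-gene log2 fold changes (LFC) with Gaussian noise, and
#' two kinds of planted signal: (i) gene sets whose members carry an additive
#' LFC effect (for enrichment testing) and (ii) plasma-membrane-annotated
#' genes planted to pass the surface-target triage under a known number of
#' treatments (for triage testing). Planted membrane entries are written with
#' exact LFC values (no noise) so the ground-truth treatment multiplicity is
#' unambiguous; noise applies everywhere else.
#'
#' @param n_genes Number of genes (ids `G0001`, ...).
#' @param set_size,n_sets Gene-set collection layout: `n_sets` disjoint sets
#'   of `set_size` consecutive genes, named `SET_01`, ...
#' @param planted_sets Named numeric vector: additive LFC effect applied to
#'   all members of each named set, in every cell line / treatment /
#'   timepoint. At least one set must be planted.
#' @param n_membrane_per_class Number of membrane genes planted per
#'   treatment-multiplicity class (passing exactly 1, 2 and 3 treatments).
#' @param n_membrane_decoys Membrane-annotated genes with no planted effect.
#' @param n_panel_genes Membrane genes planted to pass triage but listed in
#'   the surfaceome screen panel (so triage must exclude them).
#' @param membrane_lfc LFC values (log2) written at the two timepoints for a
#'   planted membrane gene under its designated treatments; must be
#'   nondecreasing and above `log2(1.5)`.
#' @param lfc_noise_sd Gaussian noise sd on LFC (log2 units).
#' @param cell_lines,treatments,timepoints The design; at least 2 cell lines,
#'   3 treatments, 2 timepoints.
#' @return An object of class `transcriptome_truth`.
#' @seealso [generate_lfc_table()]
#' @export
transcriptome_truth <- function(n_genes = 2000L,
                                set_size = 50L,
                                n_sets = 20L,
                                planted_sets = c(SET_01 = 2.0),
                                n_membrane_per_class = 4L,
                                n_membrane_decoys = 6L,
                                n_panel_genes = 2L,
                                membrane_lfc = c(1.5, 2.5),
                                lfc_noise_sd = 0.5,
                                cell_lines = c("HUH7", "HepG2"),
                                treatments = c("alisertib", "cx5461",
                                               "etoposide"),
                                timepoints = c("t1", "t2")) {
  if (length(cell_lines) < 2L) abort("design needs >= 2 cell lines")
  if (length(treatments) != 3L) abort("design needs 3 treatments")
  if (length(timepoints) != 2L) abort("design needs 2 timepoints")
  if (length(planted_sets) < 1L) abort("at least one planted set required")
  if (n_sets * set_size > n_genes) abort("gene-set layout exceeds n_genes")
  if (lfc_noise_sd < 0) abort("lfc_noise_sd must be >= 0")
  if (length(membrane_lfc) != 2L || membrane_lfc[2L] < membrane_lfc[1L] ||
      membrane_lfc[1L] < log2(1.5)) {
    abort("membrane_lfc must be nondecreasing and >= log2(1.5)")
  }

  genes <- sprintf("G%04d", seq_len(n_genes))
  gene_sets <- lapply(seq_len(n_sets), function(i) {
    genes[((i - 1L) * set_size + 1L):(i * set_size)]
  })
  names(gene_sets) <- sprintf("SET_%02d", seq_len(n_sets))
  missing <- setdiff(names(planted_sets), names(gene_sets))
  if (length(missing)) {
    abort("planted set absent from collection: ", paste(missing, collapse = ", "))
  }

  # membrane genes are taken from the tail of the gene list, outside the
  # gene-set blocks so the two kinds of planted signal do not interact
  n_mem <- 3L * n_membrane_per_class + n_membrane_decoys + n_panel_genes
  free <- setdiff(genes, unlist(gene_sets, use.names = FALSE))
  if (length(free) < n_mem) abort("not enough genes outside sets for membrane truth")
  mem_genes <- rev(free)[seq_len(n_mem)]
  planted <- mem_genes[seq_len(3L * n_membrane_per_class)]
  membrane <- data.frame(
    gene = planted,
    multiplicity = rep(1:3, each = n_membrane_per_class),
    stringsAsFactors = FALSE
  )
  decoys <- mem_genes[3L * n_membrane_per_class + seq_len(n_membrane_decoys)]
  panel <- mem_genes[3L * n_membrane_per_class + n_membrane_decoys +
                       seq_len(n_panel_genes)]

  structure(
    list(genes = genes, gene_sets = gene_sets, planted_sets = planted_sets,
         membrane = membrane, membrane_decoys = decoys, panel_genes = panel,
         membrane_lfc = membrane_lfc, lfc_noise_sd = lfc_noise_sd,
         cell_lines = cell_lines, treatments = treatments,
         timepoints = timepoints),
    class = "transcriptome_truth"
  )
}

#' Generate a synthetic per-gene LFC table with planted signal
#'
#' Emits a long-format table of per-gene log2 fold changes across the cell
#' line x treatment x timepoint design, plus the matching gene-set collection
#' (GMT-style named list), a flat gene-to-GO annotation table, and the
#' surfaceome panel gene list. Members of planted sets carry their additive
#' effect plus noise; planted membrane genes carry exact threshold-passing,
#' monotonic LFC values under their designated treatments (the first
#' `multiplicity` treatments of the design).
#'
#' @param truth A [transcriptome_truth()] object.
#' @param seed Integer RNG seed.
#' @return A list with elements `lfc` (data.frame: gene, cell_line,
#'   treatment, timepoint, lfc, pvalue), `gene_sets` (named list),
#'   `go` (data.frame: gene, go_term), `panel` (character) and `truth`.
#' @export
generate_lfc_table <- function(truth, seed = 1L) {
  if (!inherits(truth, "transcriptome_truth")) {
    abort("`truth` must be a transcriptome_truth")
  }
  design <- expand.grid(
    gene = truth$genes, cell_line = truth$cell_lines,
    treatment = truth$treatments, timepoint = truth$timepoints,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  effect <- numeric(nrow(design))
  for (s in names(truth$planted_sets)) {
    effect[design$gene %in% truth$gene_sets[[s]]] <-
      effect[design$gene %in% truth$gene_sets[[s]]] + truth$planted_sets[[s]]
  }

  lfc <- with_seed(seed, effect + rnorm(nrow(design), 0, truth$lfc_noise_sd))

  plant_exact <- function(genes_mult) {
    for (i in seq_len(nrow(genes_mult))) {
      g <- genes_mult$gene[i]
      for (tr in truth$treatments[seq_len(genes_mult$multiplicity[i])]) {
        for (tp_i in 1:2) {
          sel <- design$gene == g & design$treatment == tr &
            design$timepoint == truth$timepoints[tp_i]
          lfc[sel] <<- truth$membrane_lfc[tp_i]
        }
      }
    }
  }
  plant_exact(truth$membrane)
  if (length(truth$panel_genes)) {
    plant_exact(data.frame(gene = truth$panel_genes,
                           multiplicity = rep_len(3L, length(truth$panel_genes))))
  }

  sd0 <- max(truth$lfc_noise_sd, 1e-8)
  out <- cbind(design, lfc = lfc,
               pvalue = 2 * stats::pnorm(-abs(lfc) / sd0))

  membrane_genes <- c(truth$membrane$gene, truth$membrane_decoys,
                      truth$panel_genes)
  go <- data.frame(gene = membrane_genes,
                   go_term = rep("plasma membrane", length(membrane_genes)),
                   stringsAsFactors = FALSE)

  list(lfc = out, gene_sets = truth$gene_sets, go = go,
       panel = truth$panel_genes, truth = truth)
}
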