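#' Triage transcripts for plasma-membrane surface-target candidates
#'
#' Filters a per-gene LFC table to candidate surface targets that the
#' antibody screen could not have seen: a gene passes for a treatment iff its
#' fold change is at least `fc_threshold` (LFC >= log2(threshold)) in every
#' cell line at both timepoints, with the timepoint-2 LFC no smaller than the
#' timepoint-1 LFC (monotonic upregulation) in every cell line. A gene is
#' emitted iff it passes at least one treatment, carries the plasma-membrane
#' GO annotation, and is absent from the surfaceome screen panel. Emitted
#' genes are partitioned by the number of treatments passed (Venn counts).
#'
#' Genes with missing design rows (cell line x timepoint) under a treatment
#' cannot pass that treatment; such gene x treatment pairs are reported in
#' the `incomplete` element.
#'
#' @param lfc_table data.frame with columns gene, cell_line, treatment,
#'   timepoint, lfc (log2).
#' @param go_table data.frame with columns gene, go_term (flat annotation;
#'   no ontology traversal).
#' @param screen_panel Character vector of gene ids already covered by the
#'   antibody screen.
#' @param fc_threshold Linear fold-change threshold (> 1).
#' @param membrane_term GO term defining membrane annotation.
#' @return A list of class `triage_result`: `results` (data.frame gene,
#'   treatments_passing, n_treatments, monotonic, membrane, in_screen_panel,
#'   emitted), `emitted` (data.frame of emitted genes), `venn_counts` (named
#'   counts for 1, 2, 3 treatments), `incomplete` (data.frame of skipped
#'   gene x treatment pairs).
#' @export
triage_membrane_targets <- function(lfc_table, go_table,
                                    screen_panel = character(0),
                                    fc_threshold = 1.5,
                                    membrane_term = "plasma membrane") {
  if (fc_threshold <= 1) abort("fc_threshold must be > 1")
  need <- c("gene", "cell_line", "treatment", "timepoint", "lfc")
  if (!all(need %in% names(lfc_table))) {
    abort("lfc table needs columns: ", paste(need, collapse = ", "))
  }
  lthr <- log2(fc_threshold)
  cell_lines <- sort(unique(lfc_table$cell_line))
  treatments <- sort(unique(lfc_table$treatment))
  timepoints <- sort(unique(lfc_table$timepoint))
  if (length(timepoints) != 2L) abort("triage expects exactly 2 timepoints")

  membrane_genes <- unique(go_table$gene[go_table$go_term == membrane_term])
  genes <- sort(unique(lfc_table$gene))

  key <- paste(lfc_table$gene, lfc_table$cell_line, lfc_table$treatment,
               lfc_table$timepoint, sep = "\r")
  lfc_map <- setNames(lfc_table$lfc, key)

  rows <- list(); incomplete <- list()
  for (g in genes) {
    passing <- character(0); mono_all <- TRUE
    for (tr in treatments) {
      k1 <- paste(g, cell_lines, tr, timepoints[1L], sep = "\r")
      k2 <- paste(g, cell_lines, tr, timepoints[2L], sep = "\r")
      v1 <- lfc_map[k1]; v2 <- lfc_map[k2]
      if (any(is.na(v1)) || any(is.na(v2))) {
        # would this treatment otherwise have passed on the rows present?
        vals <- c(v1, v2)
        if (all(vals[!is.na(vals)] >= lthr)) {
          incomplete[[length(incomplete) + 1L]] <-
            data.frame(gene = g, treatment = tr, stringsAsFactors = FALSE)
        }
        next
      }
      if (all(c(v1, v2) >= lthr) && all(v2 >= v1)) passing <- c(passing, tr)
    }
    if (length(passing) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g,
      treatments_passing = paste(passing, collapse = "&"),
      n_treatments = length(passing),
      monotonic = TRUE,
      membrane = g %in% membrane_genes,
      in_screen_panel = g %in% screen_panel,
      stringsAsFactors = FALSE
    )
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), treatments_passing = character(0),
               n_treatments = integer(0), monotonic = logical(0),
               membrane = logical(0), in_screen_panel = logical(0))
  results$emitted <- results$membrane & !results$in_screen_panel
  emitted <- results[results$emitted, , drop = FALSE]
  rownames(emitted) <- NULL
  venn_counts <- vapply(1:3, function(k) sum(emitted$n_treatments == k),
                        integer(1))
  names(venn_counts) <- as.character(1:3)
  incomplete <- if (length(incomplete)) do.call(rbind, incomplete) else
    data.frame(gene = character(0), treatment = character(0))
  if (nrow(incomplete)) {
    warning(nrow(incomplete), " gene x treatment pair(s) skipped for ",
            "missing timepoint rows")
  }
  structure(list(results = results, emitted = emitted,
                 venn_counts = venn_counts, incomplete = incomplete,
                 fc_threshold = fc_threshold),
            class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  cat("triage_result:", nrow(x$emitted), "candidate membrane targets",
      "(fold change >=", x$fc_threshold, "in all cell lines, both",
      "timepoints, monotonic)\n")
  cat("  by number of treatments passed: ",
      paste(names(x$venn_counts), x$venn_counts, sep = ":", collapse = "  "),
      "\n")
  invisible(x)
}
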