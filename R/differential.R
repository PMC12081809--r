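#' Per-marker fold changes between treated and untreated conditions
#'
#' Differential surface expression is the ratio of baseline-normalized MFIs,
#' treated over untreated, per marker and treatment.
#'
#' @param profiles data.frame from [normalize_screen()].
#' @param untreated Id of the untreated reference condition.
#' @return data.frame with columns marker, treatment, fold_change.
#' @export
fold_changes <- function(profiles, untreated = "untreated") {
  if (!untreated %in% profiles$condition) {
    abort("untreated condition '", untreated, "' not present")
  }
  ref <- profiles[profiles$condition == untreated, ]
  ref_map <- setNames(ref$normalized_mfi, ref$marker)
  trt <- profiles[profiles$condition != untreated, ]
  missing <- setdiff(unique(trt$marker), names(ref_map))
  if (length(missing)) {
    abort("markers without an untreated row: ", paste(missing, collapse = ", "))
  }
  denom <- ref_map[trt$marker]
  if (any(denom == 0)) {
    abort("untreated normalized MFI is zero for: ",
          paste(unique(trt$marker[denom == 0]), collapse = ", "))
  }
  res <- data.frame(marker = trt$marker, treatment = trt$condition,
                    fold_change = trt$normalized_mfi / denom,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Threshold selection and Venn partitioning of upregulated markers
#'
#' A marker is selected as upregulated if its fold change is `>= tau_up`
#' under at least one treatment, and assigned to the Venn region of exactly
#' the treatments where it passes. Downregulated markers
#' (`fold change <= tau_down`, default the mirrored `1/1.5`) are reported as
#' a flat set.
#'
#' @param fc_table data.frame from [fold_changes()]; every marker must have
#'   exactly one row per treatment.
#' @param tau_up Upregulation inclusion threshold on fold change.
#' @param tau_down Downregulation threshold; default `1/tau_up`.
#' @return A list of class `venn_partition`: `regions` (named list over the
#'   `2^T - 1` regions, names are `&`-joined treatment combinations),
#'   `total_selected`, `down_set`, `treatments`.
#' @export
select_and_partition <- function(fc_table, tau_up = 1.5,
                                 tau_down = 1 / tau_up) {
  treatments <- unique(fc_table$treatment)
  tab <- table(fc_table$marker, fc_table$treatment)
  if (any(tab != 1L)) {
    abort("fold-change table must have exactly one row per marker x treatment")
  }
  if (any(fc_table$fold_change <= 0)) abort("fold changes must be > 0")

  markers <- unique(fc_table$marker)
  pass <- vapply(treatments, function(tr) {
    ft <- fc_table[fc_table$treatment == tr, ]
    setNames(ft$fold_change, ft$marker)[markers] >= tau_up
  }, logical(length(markers)))
  pass <- matrix(pass, nrow = length(markers),
                 dimnames = list(markers, treatments))

  combos <- unlist(lapply(seq_along(treatments), function(k) {
    apply(utils::combn(treatments, k), 2L, paste, collapse = "&")
  }))
  regions <- setNames(vector("list", length(combos)), combos)
  for (cb in combos) regions[[cb]] <- character(0)
  for (m in markers[rowSums(pass) > 0L]) {
    key <- paste(treatments[pass[m, ]], collapse = "&")
    regions[[key]] <- c(regions[[key]], m)
  }

  down <- vapply(treatments, function(tr) {
    ft <- fc_table[fc_table$treatment == tr, ]
    setNames(ft$fold_change, ft$marker)[markers] <= tau_down
  }, logical(length(markers)))
  down_set <- markers[rowSums(matrix(down, nrow = length(markers))) > 0L]

  structure(
    list(regions = regions, total_selected = sum(rowSums(pass) > 0L),
         down_set = down_set, treatments = treatments,
         tau_up = tau_up, tau_down = tau_down),
    class = "venn_partition"
  )
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("venn_partition:", x$total_selected, "markers selected at fold change >=",
      x$tau_up, "\n")
  for (r in names(x$regions)) {
    if (length(x$regions[[r]])) {
      cat("  ", r, ": ", length(x$regions[[r]]), "\n", sep = "")
    }
  }
  cat("  downregulated (<=", format(x$tau_down, digits = 4), "):",
      length(x$down_set), "\n")
  invisible(x)
}

#' Ternary (relative-contribution) coordinates of selected markers
#'
#' Each marker's barycentric coordinate for treatment *i* is its fold change
#' under *i* divided by the sum of its fold changes over the three
#' treatments, so position reflects the relative contribution of each
#' treatment to the average fold change; the size metric is that average.
#'
#' @param fc_table data.frame from [fold_changes()] with exactly three
#'   treatments.
#' @param markers Markers to place; default all in the table.
#' @return data.frame with columns marker, one coordinate column per
#'   treatment (summing to 1 per row), and avg_fold_change.
#' @export
ternary_coordinates <- function(fc_table, markers = unique(fc_table$marker)) {
  treatments <- unique(fc_table$treatment)
  if (length(treatments) != 3L) abort("ternary coordinates need 3 treatments")
  fc <- vapply(treatments, function(tr) {
    ft <- fc_table[fc_table$treatment == tr, ]
    setNames(ft$fold_change, ft$marker)[markers]
  }, numeric(length(markers)))
  fc <- matrix(fc, nrow = length(markers),
               dimnames = list(markers, treatments))
  if (any(!is.finite(fc)) || any(fc <= 0)) {
    abort("all three fold changes must be positive for ternary coordinates")
  }
  coords <- fc / rowSums(fc)
  res <- data.frame(marker = markers, coords,
                    avg_fold_change = rowMeans(fc),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(res) <- NULL
  res
}
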