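#' Median fluorescent intensity of an event sample
#'
#' The MFI is the sample median of the per-event intensities (for an even
#' number of events, the mean of the two central order statistics).
#'
#' @param intensities Numeric vector of per-event linear intensities.
#' @return The MFI in linear units.
#' @export
compute_mfi <- function(intensities) {
  if (length(intensities) < 1L) abort("empty event sample")
  if (any(!is.finite(intensities))) abort("non-finite intensities")
  median(intensities)
}

#' Mode of a Gaussian kernel density estimate of log10 intensities
#'
#' Fits a Gaussian KDE to `log10(values)` with a fixed bandwidth (the kernel
#' standard deviation, in log10 units) and returns the grid argmax
#' back-transformed to the linear scale. The grid has `n_grid` points spanning
#' `[min - 3h, max + 3h]` of the log10 values; ties are resolved to the lowest
#' grid location, making the estimate deterministic and conservative.
#'
#' Fluorescence spans decades, so a bandwidth of 0.05 is meaningful only on
#' the log scale — roughly a 12% coefficient of variation in linear units.
#'
#' @param values Numeric vector of positive MFIs (or intensities), length >= 2.
#' @param bandwidth Kernel sd in log10 units.
#' @param n_grid Number of evaluation grid points.
#' @return The KDE mode in linear units, with attributes `grid` (log10
#'   locations) and `bandwidth`.
#' @export
kde_mode <- function(values, bandwidth = 0.05, n_grid = 512L) {
  if (length(values) < 2L) abort("kde_mode needs >= 2 values")
  if (any(!is.finite(values)) || any(values <= 0)) {
    abort("kde_mode needs finite positive values")
  }
  lx <- log10(values)
  d <- density(lx, bw = bandwidth, kernel = "gaussian", n = n_grid,
               from = min(lx) - 3 * bandwidth, to = max(lx) + 3 * bandwidth)
  mode_log10 <- d$x[which.max(d$y)]  # which.max: first (lowest) on ties
  structure(10^mode_log10, grid = d$x, bandwidth = bandwidth)
}

#' Assign per-marker baselines from isotype controls
#'
#' Each marker's baseline is the nonspecific-binding level of its isotype
#' control. For isotype sets of `<= cutoff` markers the baseline is the MFI
#' of the corresponding isotype-control well. For large sets (`> cutoff`,
#' default 40) a single control well's MFI variability would propagate to
#' many markers, so the baseline is instead the [kde_mode()] of the member
#' markers' own MFIs in that condition — the mode tracks the unexpressed
#' majority and is robust to the expressed minority. Baselines are computed
#' per condition (plate-wise).
#'
#' @param screen A `sasome_screen`.
#' @param cutoff Isotype-set size above which the KDE-mode rule applies
#'   (strict inequality).
#' @param bandwidth KDE bandwidth in log10 units, passed to [kde_mode()].
#' @return data.frame with columns marker, condition, baseline,
#'   baseline_method (`"direct-isotype"` or `"kde-mode"`).
#' @export
assign_baselines <- function(screen, cutoff = 40L, bandwidth = 0.05) {
  pm <- screen$plate_map
  groups <- split(pm$marker, pm$isotype_id)
  out <- list()
  for (cond in screen$conditions) {
    ev <- screen$events[[cond]]
    for (iso in names(groups)) {
      members <- groups[[iso]]
      if (length(members) > cutoff) {
        mfis <- vapply(members, function(m) compute_mfi(ev[[m]]), numeric(1))
        base <- as.numeric(kde_mode(mfis, bandwidth = bandwidth))
        method <- "kde-mode"
      } else {
        iso_col <- paste0("ISO_", iso)
        if (!iso_col %in% colnames(ev)) {
          abort("isotype control well ", iso_col, " absent for set of size ",
                length(members), " in condition ", cond)
        }
        base <- compute_mfi(ev[[iso_col]])
        method <- "direct-isotype"
      }
      if (base <= 0) abort("nonpositive baseline for isotype ", iso)
      out[[length(out) + 1L]] <- data.frame(
        marker = members, condition = cond, baseline = base,
        baseline_method = method, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$condition, screen$conditions),
                   match(res$marker, pm$marker)), ]
  rownames(res) <- NULL
  res
}

#' Baseline-normalized MFIs for every marker x condition
#'
#' Computes each marker well's MFI and divides it by its isotype baseline
#' (see [assign_baselines()]), yielding a dimensionless normalized MFI per
#' marker and condition.
#'
#' @inheritParams assign_baselines
#' @return data.frame with columns marker, condition, mfi, baseline,
#'   baseline_method, normalized_mfi.
#' @export
normalize_screen <- function(screen, cutoff = 40L, bandwidth = 0.05) {
  bl <- assign_baselines(screen, cutoff = cutoff, bandwidth = bandwidth)
  bl$mfi <- mapply(function(m, cond) compute_mfi(screen$events[[cond]][[m]]),
                   bl$marker, bl$condition)
  if (any(bl$baseline <= 0)) abort("nonpositive baseline")
  bl$normalized_mfi <- bl$mfi / bl$baseline
  bl[, c("marker", "condition", "mfi", "baseline", "baseline_method",
         "normalized_mfi")]
}
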