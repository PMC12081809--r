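# Independent oracles used across tests; none shares code with the package
# paths it checks.

# Exhaustive Gaussian-KDE argmax on a grid `refine`-times finer than the
# package's 512-point grid.
fine_grid_kde_mode <- function(values, bandwidth = 0.05, refine = 10L) {
  lx <- log10(values)
  g <- seq(min(lx) - 3 * bandwidth, max(lx) + 3 * bandwidth,
           length.out = 512L * refine)
  dens <- vapply(g, function(x) mean(stats::dnorm(x, lx, bandwidth)),
                 numeric(1))
  10^g[which.max(dens)]
}

# log10-grid step of the package's kde_mode grid
kde_grid_step <- function(values, bandwidth = 0.05, n_grid = 512L) {
  lx <- log10(values)
  (diff(range(lx)) + 6 * bandwidth) / (n_grid - 1L)
}

# Full O(N) GSEA running sum; returns the signed extremum.
brute_force_es <- function(ranking, gene_set, exponent = 1) {
  N <- length(ranking)
  hit <- names(ranking) %in% gene_set
  w <- abs(ranking)^exponent
  sw <- sum(w[hit])
  inc <- ifelse(hit, w / sw, -1 / (N - sum(hit)))
  rs <- cumsum(inc)
  up <- max(rs)
  down <- min(rs)
  if (up >= -down) up else down
}

# Small deterministic fold-change table (three treatments)
toy_fc_table <- function() {
  markers <- c("A", "B", "C", "D", "E")
  data.frame(
    marker = rep(markers, times = 3),
    treatment = rep(c("T1", "T2", "T3"), each = 5),
    fold_change = c(2.0, 1.6, 1.0, 0.5, 1.4,    # T1
                    1.0, 1.6, 1.0, 2.0, 1.49,   # T2
                    1.0, 1.6, 1.0, 2.0, 1.2),   # T3
    stringsAsFactors = FALSE
  )
}

# Minimal hand-built screen: constant intensities per well so MFIs are exact.
# `wells` is a named list of per-well constant values (markers and ISO_*).
constant_screen <- function(wells, plate_map, conditions = "untreated",
                            n_events = 120L) {
  events <- lapply(conditions, function(cond) {
    as.data.frame(lapply(wells, function(v) rep(v, n_events)),
                  check.names = FALSE)
  })
  names(events) <- conditions
  sasome:::new_screen(events, plate_map, conditions)
}

# A small unimodal screen with one optional planted bimodal marker.
bimodal_test_truth <- function(n_markers = 100L, weight = 0.5,
                               sep_sds = 6, logsd = 0.25,
                               events = 2000L, bimodal_marker = "M050") {
  bm <- list()
  if (!is.null(bimodal_marker)) {
    bm[[bimodal_marker]] <- list(
      weight = weight,
      logmeans = c(2, 2 + sep_sds * logsd),
      logsds = c(logsd, logsd)
    )
  }
  screen_truth(markers = sprintf("M%03d", seq_len(n_markers)),
               treatments = "tis", isotype_groups = NULL,
               baseline_logmean = 2, logsd = logsd,
               bimodal_markers = bm, events_per_well = events)
}
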