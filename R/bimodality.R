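#' Empirical quantile function of log10 intensity
#'
#' Evaluates the empirical quantile function of `log10(intensities)` on a
#' percentile grid, with linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param intensities Numeric vector of positive linear intensities.
#' @param grid Percentile grid (0-100); must be uniform for [qdf()].
#' @param min_events Minimum number of events required for stable quantile
#'   estimates.
#' @return Numeric vector `Q` of log10-intensity quantiles, named by
#'   percentile.
#' @export
quantile_function <- function(intensities, grid = 0:100, min_events = 100L) {
  if (length(intensities) < min_events) {
    abort("need >= ", min_events, " events (got ", length(intensities), ")")
  }
  if (any(!is.finite(intensities)) || any(intensities <= 0)) {
    abort("intensities must be finite and positive")
  }
  quantile(log10(intensities), probs = grid / 100, names = TRUE, type = 7)
}

#' Smoothed quantile density function (QDF)
#'
#' The QDF is the derivative of the quantile function, q(p) = dQ/dp =
#' 1/f(Q(p)): it is large where the intensity density is sparse, so a
#' pronounced interior peak marks the gap (antimode) between two cell
#' subpopulations. The derivative is estimated with a quadratic
#' Savitzky-Golay filter over a 5-percentile window (polynomial boundary fit
#' at the grid ends); negative estimates are clipped to zero.
#'
#' @param Q Quantile-function values on a uniform percentile grid.
#' @param window Savitzky-Golay window width in grid points (odd).
#' @param order Polynomial order of the local fit.
#' @param grid_step Grid spacing in percentiles.
#' @param clip Clip negative derivative estimates to 0 (the quantile density
#'   is nonnegative by definition; negatives are smoothing artifacts).
#' @return Numeric vector `q`, log10 units per percentile, same length as `Q`.
#' @export
qdf <- function(Q, window = 5L, order = 2L, grid_step = 1, clip = TRUE) {
  if (window > length(Q)) abort("Savitzky-Golay window larger than grid")
  if (window %% 2L != 1L) abort("window must be odd")
  q <- signal::sgolayfilt(as.numeric(Q), p = order, n = window, m = 1L,
                          ts = grid_step)
  if (clip) q <- pmax(q, 0)
  names(q) <- names(Q)
  q
}

#' Screen-wide QDF reference function
#'
#' The pointwise 95th percentile across all supplied QDFs at each grid
#' percentile. Normalizing each QDF against this reference expresses how
#' extreme its local sparsity is relative to the whole screen, without
#' parametric assumptions.
#'
#' @param qdfs Numeric matrix, one row per marker x condition QDF, one column
#'   per grid percentile.
#' @param prob Reference quantile (default 0.95).
#' @return Numeric vector, length `ncol(qdfs)`.
#' @export
reference_function <- function(qdfs, prob = 0.95) {
  qdfs <- as.matrix(qdfs)
  if (nrow(qdfs) < 2L) abort("need >= 2 QDFs for a reference")
  if (nrow(qdfs) < 20L) {
    warning("reference computed from only ", nrow(qdfs),
            " QDFs; the 95th percentile may be unstable")
  }
  apply(qdfs, 2L, quantile, probs = prob, names = FALSE, type = 7)
}

#' Bimodality score from a QDF and the screen reference
#'
#' The ratio q/reference is evaluated on an interior percentile band
#' (default 5-95; derivative estimates at extreme percentiles are dominated
#' by extreme order statistics). The score is the maximum ratio; if it
#' exceeds 2 the marker is flagged bimodal and the location of the maximum is
#' the separating quantile between the low- and high-intensity populations.
#' Scores in (1, 2] are classed potentially bimodal, scores <= 1 unimodal.
#'
#' @param q QDF values on the grid.
#' @param ref Reference function on the same grid.
#' @param grid Percentile grid both are evaluated on.
#' @param band Inclusive percentile band over which the ratio is evaluated.
#' @return A list: `score` (max ratio), `separating_quantile` (percentile of
#'   the maximum, lowest on ties), `class` (`"unimodal"`,
#'   `"potentially-bimodal"`, `"bimodal"`).
#' @export
bimodality_score <- function(q, ref, grid = 0:100, band = c(5, 95)) {
  if (length(q) != length(ref) || length(q) != length(grid)) {
    abort("q, ref and grid must have equal length")
  }
  idx <- grid >= band[1] & grid <= band[2]
  if (any(ref[idx] <= 0)) {
    abort("reference function is nonpositive inside the evaluated band")
  }
  ratio <- q[idx] / ref[idx]
  i <- which.max(ratio)  # first (lowest percentile) on ties
  score <- ratio[i]
  cls <- if (score > 2) "bimodal" else if (score > 1) "potentially-bimodal"
         else "unimodal"
  list(score = unname(score), separating_quantile = grid[idx][i], class = cls)
}

#' Bimodality scores for every marker x condition in a screen
#'
#' Computes each marker well's smoothed QDF of log10 intensity, pools all of
#' them into the screen-wide 95th-percentile reference, and scores each well
#' against it. The low-intensity population fraction is the separating
#' quantile / 100.
#'
#' @param screen A `sasome_screen`.
#' @param grid,band,window,order See [quantile_function()], [qdf()],
#'   [bimodality_score()].
#' @param min_events Minimum events per well.
#' @return data.frame with columns marker, condition, score,
#'   separating_quantile, class, low_fraction; the reference function is
#'   attached as attribute `"reference"`.
#' @export
screen_bimodality <- function(screen, grid = 0:100, band = c(5, 95),
                              window = 5L, order = 2L, min_events = 100L) {
  pm <- screen$plate_map
  keys <- expand.grid(marker = pm$marker, condition = screen$conditions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  qmat <- matrix(NA_real_, nrow(keys), length(grid))
  for (i in seq_len(nrow(keys))) {
    x <- event_sample(screen, keys$marker[i], keys$condition[i])
    Q <- quantile_function(x, grid = grid, min_events = min_events)
    qmat[i, ] <- qdf(Q, window = window, order = order,
                     grid_step = diff(grid[1:2]))
  }
  ref <- reference_function(qmat)
  scores <- lapply(seq_len(nrow(keys)), function(i) {
    bimodality_score(qmat[i, ], ref, grid = grid, band = band)
  })
  res <- data.frame(
    marker = keys$marker, condition = keys$condition,
    score = vapply(scores, `[[`, numeric(1), "score"),
    separating_quantile = vapply(scores, `[[`, numeric(1),
                                 "separating_quantile"),
    class = vapply(scores, `[[`, character(1), "class"),
    stringsAsFactors = FALSE
  )
  res$low_fraction <- res$separating_quantile / 100
  attr(res, "reference") <- ref
  res
}
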