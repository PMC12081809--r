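# Running-sum extremum from sorted hit positions only. Between hits the
# running sum decays linearly, so the candidate extrema are the values just
# after and just before each hit; this makes one ES O(set size) instead of
# O(ranking size).
es_from_hits <- function(w_all, hits, N) {
  k <- length(hits)
  w <- w_all[hits]
  sw <- sum(w)
  if (sw <= 0) abort("zero total hit weight (constant-zero metric?)")
  cw <- cumsum(w) / sw
  d <- 1 / (N - k)
  miss <- hits - seq_len(k)
  after <- cw - miss * d
  before <- c(0, cw[-k]) - miss * d
  up <- max(after)
  down <- min(before)
  if (up >= -down) up else down
}

#' Preranked GSEA enrichment score
#'
#' The classic weighted Kolmogorov-Smirnov running sum over a ranked gene
#' list: walking down the ranking, the sum increases by
#' `|metric|^p / sum_set(|metric|^p)` at set members and decreases by
#' `1/(N - N_set)` at non-members; the enrichment score (ES) is the signed
#' extremum. With `exponent = 0` this is the unweighted KS statistic of the
#' member positions.
#'
#' @param ranking Named numeric vector of ranking metrics (log fold changes),
#'   sorted in decreasing order; names are unique gene ids.
#' @param gene_set Character vector of member gene ids.
#' @param exponent Weight exponent p (default 1, the preranked GSEA default).
#' @return The ES, a single number in \[-1, 1\].
#' @export
enrichment_score <- function(ranking, gene_set, exponent = 1) {
  N <- length(ranking)
  if (N < 2L) abort("ranking needs >= 2 genes")
  if (is.unsorted(rev(ranking))) abort("ranking must be sorted decreasing")
  hits <- which(names(ranking) %in% gene_set)
  if (length(hits) == 0L) abort("empty overlap between set and ranking")
  if (length(hits) == N) abort("gene set covers the whole ranking")
  es_from_hits(abs(ranking)^exponent, hits, N)
}

#' Bootstrap null distribution of the enrichment score
#'
#' Samples `B` random gene sets of the given size uniformly without
#' replacement from the ranking's genes, scores each, and returns the sample
#' mean and standard deviation of their ES — the null against which a real
#' set's ES is z-scored.
#'
#' @inheritParams enrichment_score
#' @param set_size Size of the random sets (match the tested set's overlap).
#' @param B Number of bootstrap sets.
#' @param seed Integer RNG seed.
#' @return A list with `null_mean`, `null_sd`, `B`.
#' @export
bootstrap_null <- function(ranking, set_size, B = 1000L, seed = 1L,
                           exponent = 1) {
  N <- length(ranking)
  if (set_size < 1L || set_size >= N) {
    abort("set_size must be in [1, ranking size)")
  }
  w_all <- abs(ranking)^exponent
  es <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      es_from_hits(w_all, sort(sample.int(N, set_size)), N)
    }, numeric(1))
  })
  null_sd <- sd(es)
  if (!is.finite(null_sd) || null_sd <= 0) {
    abort("degenerate bootstrap null (sd <= 0)")
  }
  list(null_mean = mean(es), null_sd = null_sd, B = B)
}

# One ranking per cell line x treatment: LFC averaged over the timepoints,
# sorted decreasing, ties broken by gene id for determinism.
build_ranking <- function(lfc_sub) {
  agg <- tapply(lfc_sub$lfc, lfc_sub$gene, mean)
  genes <- names(agg)
  metric <- as.numeric(agg)
  ord <- order(-metric, genes)
  setNames(metric[ord], genes[ord])
}

#' Bootstrap z-scored preranked GSEA over a design
#'
#' Builds one ranking per cell line x treatment (log fold changes averaged
#' across the two timepoints), computes each gene set's ES, and standardizes
#' it against a bootstrap null of random gene sets of the same overlap size
#' drawn from the ranked universe: z = (ES - null mean) / null sd. Nulls are
#' cached per overlap size within a ranking. Results are sorted by z
#' (descending) within each cell line x treatment, ties by |ES|.
#'
#' @param lfc_table data.frame with columns gene, cell_line, treatment,
#'   timepoint, lfc.
#' @param gene_sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param B Bootstrap sets per null.
#' @param seed Integer RNG seed.
#' @param exponent Weight exponent p.
#' @return data.frame with columns cell_line, treatment, gene_set, es,
#'   null_mean, null_sd, z, overlap, B.
#' @export
run_enrichment <- function(lfc_table, gene_sets, B = 1000L, seed = 1L,
                           exponent = 1) {
  if (length(gene_sets) == 0L) abort("empty gene-set collection")
  need <- c("gene", "cell_line", "treatment", "timepoint", "lfc")
  if (!all(need %in% names(lfc_table))) {
    abort("lfc table needs columns: ", paste(need, collapse = ", "))
  }
  groups <- unique(lfc_table[, c("cell_line", "treatment")])
  groups <- groups[order(groups$cell_line, groups$treatment), ]
  out <- list()
  gi <- 0L
  for (r in seq_len(nrow(groups))) {
    cl <- groups$cell_line[r]; tr <- groups$treatment[r]
    sub <- lfc_table[lfc_table$cell_line == cl & lfc_table$treatment == tr, ]
    ranking <- build_ranking(sub)
    if (sd(ranking) == 0) abort("constant ranking metric in ", cl, "/", tr)
    w_all <- abs(ranking)^exponent
    N <- length(ranking)
    null_cache <- list()
    res <- data.frame(cell_line = cl, treatment = tr,
                      gene_set = names(gene_sets), es = NA_real_,
                      null_mean = NA_real_, null_sd = NA_real_,
                      z = NA_real_, overlap = NA_integer_, B = as.integer(B),
                      stringsAsFactors = FALSE)
    for (i in seq_along(gene_sets)) {
      hits <- which(names(ranking) %in% gene_sets[[i]])
      res$overlap[i] <- length(hits)
      if (length(hits) == 0L || length(hits) == N) next
      res$es[i] <- es_from_hits(w_all, hits, N)
      key <- as.character(length(hits))
      if (is.null(null_cache[[key]])) {
        gi <- gi + 1L
        null_cache[[key]] <- bootstrap_null(
          ranking, length(hits), B = B,
          seed = (as.integer(seed) + gi * 1009L) %% .Machine$integer.max,
          exponent = exponent)
      }
      nl <- null_cache[[key]]
      res$null_mean[i] <- nl$null_mean
      res$null_sd[i] <- nl$null_sd
      res$z[i] <- (res$es[i] - nl$null_mean) / nl$null_sd
    }
    res <- res[order(-res$z, -abs(res$es)), ]
    out[[r]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
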