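#' Weighted running-sum enrichment score
#'
#' The classic pre-ranked GSEA statistic: walking down the ranked list, the
#' running sum gains `|score|^exponent / sum(|score[hits]|^exponent)` at genes
#' in the set and loses `1 / (N - N_hits)` at genes outside it. The
#' enrichment score is the extremum of largest absolute value; its index is
#' the peak position (the leading-edge boundary).
#'
#' @param ranked_scores Named numeric vector, sorted by decreasing relevance
#'   (names are gene ids).
#' @param gene_set Character vector; must be a non-empty strict subset of the
#'   universe.
#' @param exponent Weighting exponent (0 gives the unweighted
#'   Kolmogorov-Smirnov form).
#' @return List: `ES`, `peak_position`, `leading_edge` (set genes at or
#'   before a positive peak / at or after a negative peak), `running`
#'   (the full running sum).
#' @export
enrichment_score <- function(ranked_scores, gene_set, exponent = 1) {
  genes <- names(ranked_scores)
  hit <- genes %in% gene_set
  N <- length(genes); Nh <- sum(hit)
  if (Nh == 0L) stop("empty gene set (no overlap with the universe)")
  if (Nh == N) stop("gene set equals the whole universe")
  w <- abs(ranked_scores)^exponent
  inc <- numeric(N)
  sw <- sum(w[hit])
  inc[hit] <- if (sw > 0) w[hit] / sw else 1 / Nh
  inc[!hit] <- -1 / (N - Nh)
  running <- cumsum(inc)
  peak <- which.max(abs(running))
  ES <- running[peak]
  leading <- if (ES >= 0) genes[hit & seq_len(N) <= peak]
             else genes[hit & seq_len(N) >= peak]
  list(ES = ES, peak_position = peak, leading_edge = leading,
       running = running)
}

#' Pre-ranked gene-set enrichment with a gene-sampling null
#'
#' Scores every set in a collection against a ranked list. The null draws
#' random gene sets of the same size from the universe; p-values use +1
#' smoothing and are BH-adjusted across the tested sets. Sets outside the
#' size window are dropped before testing.
#'
#' @param ranked_scores Named numeric vector sorted by decreasing relevance.
#' @param collection Named list of gene sets (ids may extend beyond the
#'   universe; only the overlap is used).
#' @param n_perm Null draws per set size (>= 100).
#' @param seed Integer seed.
#' @param min_size,max_size Size filter applied to the in-universe overlap.
#' @return data.frame (class `enrichment_result`): set, size, ES, NES,
#'   peak_position, p, adj_p, leading_edge (semicolon-joined).
#' @export
preranked_gsea <- function(ranked_scores, collection, n_perm = 1000, seed = 1,
                           min_size = 15, max_size = 1000) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  genes <- names(ranked_scores)
  sets <- lapply(collection, function(s) intersect(s, genes))
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size & sizes < length(genes)
  sets <- sets[keep]
  if (length(sets) == 0L) {
    return(structure(data.frame(set = character(), size = integer(),
                                ES = numeric(), NES = numeric(),
                                peak_position = integer(), p = numeric(),
                                adj_p = numeric(),
                                leading_edge = character(),
                                stringsAsFactors = FALSE),
                     class = c("enrichment_result", "data.frame")))
  }
  set.seed(seed)
  # one shared null ensemble per distinct set size
  null_by_size <- list()
  for (k in unique(lengths(sets))) {
    null_by_size[[as.character(k)]] <- vapply(seq_len(n_perm), function(i) {
      enrichment_score(ranked_scores, sample(genes, k))$ES
    }, 0)
  }
  rows <- lapply(names(sets), function(nm) {
    es <- enrichment_score(ranked_scores, sets[[nm]])
    null <- null_by_size[[as.character(length(sets[[nm]]))]]
    p <- (sum(abs(null) >= abs(es$ES)) + 1) / (n_perm + 1)
    same_sign <- null[sign(null) == sign(es$ES)]
    nes <- if (length(same_sign) > 0) es$ES / mean(abs(same_sign)) else NA_real_
    data.frame(set = nm, size = length(sets[[nm]]), ES = es$ES, NES = nes,
               peak_position = es$peak_position, p = p,
               leading_edge = paste(es$leading_edge, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  out <- out[, c("set", "size", "ES", "NES", "peak_position", "p", "adj_p",
                 "leading_edge")]
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Peak-based signature cut of a consensus rank
#'
#' Collects the running-sum peak position of every significantly enriched
#' set and places the cut at the stated percentile of those positions
#' (type-7 interpolated quantile, rounded up). Genes ranked at or above the
#' cut form the signature.
#'
#' @param consensus_rank A `consensus_rank` (or a character vector of gene
#'   ids, best first).
#' @param significant_enrichments An `enrichment_result` data.frame (already
#'   filtered to significant sets), or a numeric vector of peak positions.
#' @param percentile Percentile of the peak positions (default 10 = top 10th).
#' @return List: `cut_position`, `signature_genes`.
#' @export
select_signature_cut <- function(consensus_rank, significant_enrichments,
                                 percentile = 10) {
  order <- if (inherits(consensus_rank, "consensus_rank"))
    consensus_rank$order else consensus_rank
  peaks <- if (is.data.frame(significant_enrichments))
    significant_enrichments$peak_position else significant_enrichments
  if (length(peaks) == 0L) stop("no significant enrichments to cut on")
  cut <- ceiling(stats::quantile(peaks, percentile / 100, type = 7,
                                 names = FALSE))
  list(cut_position = cut, signature_genes = utils::head(order, cut))
}

#' Batch signature-similarity testing against an external collection
#'
#' Runs pre-ranked GSEA of every external gene set against the consensus
#' rank and summarises evidence per category: mean and standard error of
#' -log10 p, and a significance flag when any set in the category reaches
#' BH-adjusted p below `alpha`.
#'
#' @param consensus_rank A `consensus_rank` or ranked gene-id vector.
#' @param external_collection Named list of gene sets with a `category`
#'   attribute (named character; see [read_gmt()]).
#' @param n_perm,seed Passed to [preranked_gsea()].
#' @param min_size,max_size Size filter (compendium-scale default 15-1000).
#' @param alpha Adjusted-p significance threshold.
#' @return data.frame: category, n_sets, mean_neglog10_p, se_neglog10_p,
#'   significant.
#' @export
batch_signature_similarity <- function(consensus_rank, external_collection,
                                       n_perm = 1000, seed = 1,
                                       min_size = 15, max_size = 1000,
                                       alpha = 0.05) {
  order <- if (inherits(consensus_rank, "consensus_rank"))
    consensus_rank$order else consensus_rank
  scores <- stats::setNames(rev(seq_along(order)), order)
  res <- preranked_gsea(scores, external_collection, n_perm = n_perm,
                        seed = seed, min_size = min_size, max_size = max_size)
  cat_map <- attr(external_collection, "category")
  res$category <- unname(cat_map[res$set])
  res <- res[!is.na(res$category) & nzchar(res$category), ]
  if (nrow(res) == 0L)
    return(data.frame(category = character(), n_sets = integer(),
                      mean_neglog10_p = numeric(), se_neglog10_p = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  sp <- split(res, res$category)
  out <- do.call(rbind, lapply(names(sp), function(cat) {
    v <- -log10(sp[[cat]]$p)
    data.frame(category = cat, n_sets = nrow(sp[[cat]]),
               mean_neglog10_p = mean(v),
               se_neglog10_p = stats::sd(v) / sqrt(length(v)),
               significant = any(sp[[cat]]$adj_p < alpha),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
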