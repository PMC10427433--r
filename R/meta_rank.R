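#' Assemble a differential-expression statistic collection
#'
#' The central input container: per-gene, per-contrast differential-expression
#' statistics from many independent exposure experiments, restricted to the
#' genes shared by all contrasts, plus per-contrast metadata (exposure system,
#' duration class, ENM group, per-contrast sample size).
#'
#' @param logfc,p,adj_p Numeric gene x contrast matrices with identical
#'   dimnames; `p` and `adj_p` in (0, 1] with `adj_p >= p` elementwise.
#' @param meta data.frame with one row per contrast: columns `contrast_id`,
#'   `system` ("in_vitro"/"in_vivo"), `duration_class`
#'   ("short"/"intermediate"/"long"), `enm_group`, `n` (sample size).
#' @return An object of class `de_collection` with elements `genes`,
#'   `contrasts`, `logfc`, `p`, `adj_p`, `meta`.
#' @export
de_collection <- function(logfc, p, adj_p, meta) {
  stopifnot(is.matrix(logfc), is.matrix(p), is.matrix(adj_p),
            identical(dim(logfc), dim(p)), identical(dim(p), dim(adj_p)))
  if (any(p <= 0) || any(p > 1)) stop("p values must lie in (0, 1]")
  if (any(adj_p < p - 1e-12)) stop("adjusted p must be >= p elementwise")
  stopifnot(is.data.frame(meta), nrow(meta) == ncol(p),
            all(c("contrast_id", "system", "duration_class", "enm_group", "n")
                %in% names(meta)))
  if (!all(meta$system %in% c("in_vitro", "in_vivo")))
    stop("system must be 'in_vitro' or 'in_vivo'")
  structure(list(genes = rownames(p), contrasts = colnames(p),
                 logfc = logfc, p = p, adj_p = adj_p, meta = meta),
            class = "de_collection")
}

#' @export
print.de_collection <- function(x, ...) {
  cat("de_collection:", length(x$genes), "genes x", length(x$contrasts),
      "contrasts\n")
  cat("  systems:", paste(sprintf("%s=%d", names(table(x$meta$system)),
                                  table(x$meta$system)), collapse = ", "), "\n")
  cat("  durations:", paste(sprintf("%s=%d", names(table(x$meta$duration_class)),
                                    table(x$meta$duration_class)), collapse = ", "), "\n")
  invisible(x)
}

# clip p away from 0 so -log and chi-square transforms stay finite
clip_p <- function(p, eps = 1e-300) pmax(p, eps)

#' Effect-size meta-analysis of one gene's p-values
#'
#' Converts each contrast's two-sided p-value to a chi-square quantile (1 df),
#' then to a phi coefficient and Cohen's d (with variance 4/n), and pools by
#' fixed-effect inverse-variance weighting. Direction is supplied externally
#' (conventionally `sign(logFC)`). Phi is clipped just below 1 when the
#' chi-square quantile reaches the sample size, so extreme p-values yield a
#' large but finite d.
#'
#' @param p_row Numeric vector of per-contrast p-values in (0, 1].
#' @param n_per_contrast Sample sizes (scalar or vector), each >= 4.
#' @param direction_row Signs (+1/-1) per contrast; 0 treated as +1.
#' @return List with `pooled_d`, `z`, `p` (two-sided), and the per-contrast
#'   `d` and `var_d`.
#' @export
effect_size_meta <- function(p_row, n_per_contrast, direction_row) {
  k <- length(p_row)
  stopifnot(k > 0L, all(p_row > 0 & p_row <= 1))
  n <- rep_len(n_per_contrast, k)
  if (any(n < 4)) stop("per-contrast sample size must be >= 4")
  s <- sign(direction_row)
  s[s == 0] <- 1
  chi2 <- stats::qchisq(clip_p(p_row), df = 1, lower.tail = FALSE)
  phi <- sqrt(pmin(chi2 / n, 1 - 1e-8))  # cap: chi2 >= n would give phi >= 1
  d <- s * 2 * phi / sqrt(1 - phi^2)
  var_d <- 4 / n
  w <- 1 / var_d
  pooled_d <- sum(w * d) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- pooled_d / se
  list(pooled_d = pooled_d, z = z,
       p = 2 * stats::pnorm(-abs(z)), d = d, var_d = var_d)
}

#' Fisher's sum-of-logs combination of one gene's p-values
#'
#' @param p_row Numeric vector of p-values in (0, 1].
#' @return List with `X2 = -2 * sum(log p)`, `df = 2k`, and `combined_p`,
#'   the upper chi-square tail.
#' @export
fisher_meta <- function(p_row) {
  if (length(p_row) == 0L) stop("empty p-value row")
  stopifnot(all(p_row > 0 & p_row <= 1))
  X2 <- -2 * sum(log(clip_p(p_row)))
  df <- 2L * length(p_row)
  list(X2 = X2, df = df,
       combined_p = stats::pchisq(X2, df = df, lower.tail = FALSE))
}

# within-column ascending ranks (average ranks on ties)
rank_by_column <- function(m) apply(m, 2, rank, ties.method = "average")

#' Rank-product meta-analysis (one-class)
#'
#' Genes are ranked within each contrast by ascending statistic (smaller =
#' more relevant); the rank product is the geometric mean of a gene's
#' within-contrast ranks. Significance comes from the null in which each
#' contrast assigns a gene a uniform random rank: exhaustive enumeration when
#' `G^D` is small, otherwise Monte-Carlo with +1 smoothing.
#'
#' @param p_matrix Gene x contrast matrix of the within-contrast ranking
#'   statistic (ascending relevance; typically p-values).
#' @param n_perm Number of null draws (>= 100) when enumeration is infeasible.
#' @param seed Integer seed for the Monte-Carlo null.
#' @param exhaustive_limit Enumerate the null exactly when `G^D` does not
#'   exceed this.
#' @return List with `rp_values` (named per gene) and `rp_p`.
#' @export
rank_product_meta <- function(p_matrix, n_perm = 1000, seed = 1,
                              exhaustive_limit = 2e5) {
  stopifnot(is.matrix(p_matrix), !anyNA(p_matrix))
  G <- nrow(p_matrix); D <- ncol(p_matrix)
  r <- rank_by_column(p_matrix)
  rp <- exp(rowMeans(log(r)))
  names(rp) <- rownames(p_matrix)
  if (G^D <= exhaustive_limit) {
    grid <- as.matrix(expand.grid(rep(list(seq_len(G)), D)))
    null_rp <- exp(rowMeans(log(grid)))
    rp_p <- vapply(rp, function(v) mean(null_rp <= v + 1e-12), 0)
  } else {
    if (n_perm < 100) stop("n_perm must be >= 100")
    set.seed(seed)
    null_rp <- exp(rowMeans(log(matrix(sample.int(G, n_perm * D, replace = TRUE),
                                       n_perm, D))))
    rp_p <- vapply(rp, function(v) (sum(null_rp <= v + 1e-12) + 1) / (n_perm + 1), 0)
  }
  list(rp_values = rp, rp_p = rp_p)
}

#' Borda consensus of several gene rankings
#'
#' Mean rank across lists, ascending; ties broken lexicographically by
#' gene id so the result is deterministic.
#'
#' @param rank_lists List of character vectors, each a permutation of the
#'   same gene set (best gene first).
#' @return List with `mean_rank` (named numeric) and `order` (gene ids
#'   sorted by mean rank).
#' @export
borda_consensus <- function(rank_lists) {
  stopifnot(length(rank_lists) >= 1L)
  genes <- sort(rank_lists[[1]])
  for (l in rank_lists) {
    if (!identical(sort(l), genes)) stop("rank lists must share one gene set")
  }
  pos <- sapply(rank_lists, function(l) match(genes, l))
  mean_rank <- stats::setNames(rowMeans(pos), genes)
  ord <- genes[order(mean_rank, genes)]
  list(mean_rank = mean_rank, order = ord)
}

#' Ensemble meta-analysis: effect-size + Fisher + rank-product, Borda-merged
#'
#' Applies the three meta-analysis methods gene-wise to a collection, ranks
#' genes within each method (effect-size and Fisher by their combined p,
#' rank-product by the RP value), and merges the three rankings by Borda mean
#' rank. With `include_fold_change = TRUE` the within-contrast ranking
#' statistic for the rank-product arm becomes `|logFC| * (-log10 p)`
#' (descending relevance) instead of p alone.
#'
#' @param collection A [de_collection()].
#' @param n_perm Permutations for the rank-product null.
#' @param seed Integer seed.
#' @param include_fold_change Use the fold-change-weighted ranking statistic.
#' @return An object of class `consensus_rank`: `order` (best gene first),
#'   `mean_rank`, `per_method_rank` (matrix), `method_stats` (data.frame with
#'   pooled d, Fisher X2, RP value and per-method p).
#' @export
run_meta_analysis <- function(collection, n_perm = 1000, seed = 1,
                              include_fold_change = FALSE) {
  stopifnot(inherits(collection, "de_collection"))
  p <- collection$p
  genes <- collection$genes
  n <- collection$meta$n
  es <- lapply(seq_len(nrow(p)), function(i)
    effect_size_meta(p[i, ], n, sign(collection$logfc[i, ])))
  es_p <- vapply(es, `[[`, 0, "p")
  es_d <- vapply(es, `[[`, 0, "pooled_d")
  fi <- lapply(seq_len(nrow(p)), function(i) fisher_meta(p[i, ]))
  fi_p <- vapply(fi, `[[`, 0, "combined_p")
  fi_X2 <- vapply(fi, `[[`, 0, "X2")
  rp_stat <- if (include_fold_change) {
    # larger |logFC| * (-log10 p) = more relevant; negate for ascending ranks
    -abs(collection$logfc) * (-log10(clip_p(p)))
  } else p
  rp <- rank_product_meta(rp_stat, n_perm = n_perm, seed = seed)

  rank_of <- function(stat) {
    # ascending stat = better; lexicographic gene-id tie-break
    genes[order(stat, genes)]
  }
  lists <- list(effect_size = rank_of(es_p),
                fisher = rank_of(fi_p),
                rank_product = rank_of(rp$rp_values))
  bc <- borda_consensus(lists)
  per_method_rank <- sapply(lists, function(l) match(genes, l))
  rownames(per_method_rank) <- genes
  stats_df <- data.frame(
    gene_id = genes,
    pooled_d = es_d, effect_size_p = es_p,
    fisher_X2 = fi_X2, fisher_p = fi_p,
    rp_value = unname(rp$rp_values[genes]), rp_p = unname(rp$rp_p[genes]),
    mean_rank = unname(bc$mean_rank[genes]),
    stringsAsFactors = FALSE
  )
  structure(list(order = bc$order, mean_rank = bc$mean_rank,
                 per_method_rank = per_method_rank, method_stats = stats_df),
            class = "consensus_rank")
}

#' @export
print.consensus_rank <- function(x, ...) {
  cat("consensus_rank over", length(x$order), "genes\n")
  cat("  top genes:", paste(utils::head(x$order, 5), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.consensus_rank <- function(object, ...) {
  df <- object$method_stats
  df <- df[order(df$mean_rank, df$gene_id), ]
  utils::head(df, 10)
}

#' Compare two gene rankings
#'
#' Kendall's tau (normal-approximation p) between the two position vectors,
#' and an ordinary least-squares fit of position-in-b on position-in-a with
#' its R-squared and F-test p.
#'
#' @param rank_a,rank_b Character vectors over the same gene universe
#'   (best first).
#' @return `rank_comparison` list: `tau`, `tau_p`, `r2`, `fit_p`.
#' @export
compare_ranks <- function(rank_a, rank_b) {
  stopifnot(identical(sort(rank_a), sort(rank_b)), length(rank_a) >= 2L)
  genes <- rank_a
  pa <- seq_along(genes)
  pb <- match(genes, rank_b)
  ct <- suppressWarnings(stats::cor.test(pa, pb, method = "kendall"))
  fit <- stats::lm(pb ~ pa)
  sm <- suppressWarnings(summary(fit))  # exact fits warn harmlessly
  fit_p <- if (is.null(sm$fstatistic)) NA_real_ else
    stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE)
  structure(list(tau = unname(ct$estimate), tau_p = ct$p.value,
                 r2 = sm$r.squared, fit_p = unname(fit_p)),
            class = "rank_comparison")
}

#' @export
print.rank_comparison <- function(x, ...) {
  cat(sprintf("rank comparison: tau = %.4f (p = %.3g), R2 = %.4f (p = %.3g)\n",
              x$tau, x$tau_p, x$r2, x$fit_p))
  invisible(x)
}

#' Consensus-rank robustness under progressive contrast removal
#'
#' Recomputes the consensus after cumulatively removing groups of contrasts
#' (by ENM-group label) and compares each reduced ranking with the
#' full-collection ranking.
#'
#' @param collection A [de_collection()].
#' @param ordered_removal_groups Character vector of `enm_group` labels,
#'   removed cumulatively in order. May be empty.
#' @param n_perm,seed Passed to [run_meta_analysis()].
#' @return List of [compare_ranks()] results, one per cumulative step
#'   (step 0 = nothing removed).
#' @export
subset_robustness <- function(collection, ordered_removal_groups = character(),
                              n_perm = 1000, seed = 1) {
  full <- run_meta_analysis(collection, n_perm = n_perm, seed = seed)
  out <- list(step0 = compare_ranks(full$order, full$order))
  removed <- character()
  for (g in ordered_removal_groups) {
    removed <- c(removed, g)
    keep <- !(collection$meta$enm_group %in% removed)
    if (!any(keep)) stop("removal step '", g, "' empties the collection")
    sub <- de_collection(collection$logfc[, keep, drop = FALSE],
                         collection$p[, keep, drop = FALSE],
                         collection$adj_p[, keep, drop = FALSE],
                         collection$meta[keep, , drop = FALSE])
    red <- run_meta_analysis(sub, n_perm = n_perm, seed = seed)
    out[[paste0("step", length(removed))]] <- compare_ranks(full$order, red$order)
  }
  out
}

#' Write a consensus rank to TSV
#' @param x A `consensus_rank`.
#' @param path Output path.
#' @param header Optional comment header line.
#' @export
write_consensus_rank <- function(x, path, header = NULL) {
  df <- x$method_stats
  df$order_index <- match(df$gene_id, x$order)
  df$rank_effect_size <- x$per_method_rank[df$gene_id, "effect_size"]
  df$rank_fisher <- x$per_method_rank[df$gene_id, "fisher"]
  df$rank_rank_product <- x$per_method_rank[df$gene_id, "rank_product"]
  df <- df[order(df$order_index), ]
  write_tsv(df, path, header = header)
}
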