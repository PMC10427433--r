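#' Assign an exposure-duration class to a contrast
#'
#' In vitro exposures: short at up to 24 h, intermediate above 24 and up to
#' 72 h, long beyond 72 h. In vivo exposures: short up to 3 days,
#' intermediate above 3 days and up to 1 month (30 days), long beyond.
#'
#' @param duration Numeric duration value.
#' @param unit Duration unit: "h"/"hours" or "d"/"days".
#' @param system "in_vitro" or "in_vivo".
#' @return "short", "intermediate" or "long".
#' @export
assign_duration_class <- function(duration, unit, system) {
  if (is.na(duration) || !is.numeric(duration))
    stop("missing or unparseable duration")
  hours <- switch(tolower(unit),
                  h = , hr = , hrs = , hour = , hours = duration,
                  d = , day = , days = duration * 24,
                  stop("unknown duration unit: ", unit))
  if (system == "in_vitro") {
    if (hours <= 24) "short" else if (hours <= 72) "intermediate" else "long"
  } else if (system == "in_vivo") {
    days <- hours / 24
    if (days <= 3) "short" else if (days <= 30) "intermediate" else "long"
  } else stop("system must be 'in_vitro' or 'in_vivo'")
}

#' Frequency scores: percent of significant contrasts per duration class
#'
#' For each exposure system, the score of a gene in a duration class is the
#' percentage of that class's contrasts in which the gene is significantly
#' deregulated (BH-adjusted p below `alpha`).
#'
#' @param collection A [de_collection()].
#' @param signature_genes Genes to score (subset of the collection's genes).
#' @param alpha Adjusted-p significance threshold.
#' @return Named list (one per system present) of gene x duration-class
#'   matrices in `[0, 100]` with columns short/intermediate/long.
#' @export
frequency_scores <- function(collection, signature_genes, alpha = 0.05) {
  stopifnot(all(signature_genes %in% collection$genes))
  classes <- c("short", "intermediate", "long")
  sig <- collection$adj_p[signature_genes, , drop = FALSE] < alpha
  out <- list()
  for (sys in unique(collection$meta$system)) {
    m <- matrix(NA_real_, length(signature_genes), length(classes),
                dimnames = list(signature_genes, classes))
    for (cl in classes) {
      idx <- which(collection$meta$system == sys &
                     collection$meta$duration_class == cl)
      if (length(idx) == 0L)
        stop("no contrasts in group (", sys, ", ", cl, ")")
      m[, cl] <- 100 * rowMeans(sig[, idx, drop = FALSE])
    }
    out[[sys]] <- m
  }
  out
}

#' Ward hierarchical clustering of frequency profiles
#'
#' Agglomerative clustering of genes on the Euclidean distance of their
#' frequency-score profiles with Ward's linkage (`hclust`, method
#' "ward.D2"), cut into `n_clusters` groups.
#'
#' @param profile Gene x duration-class numeric matrix.
#' @param n_clusters Number of clusters (1..n_genes).
#' @return `cluster_assignment` list: `cluster` (named integer vector),
#'   `hclust` (the dendrogram object).
#' @export
ward_clusters <- function(profile, n_clusters = 4) {
  if (n_clusters < 1) stop("n_clusters must be >= 1")
  if (n_clusters > nrow(profile)) stop("more clusters than genes")
  hc <- stats::hclust(stats::dist(profile, method = "euclidean"),
                      method = "ward.D2")
  cl <- stats::cutree(hc, k = n_clusters)
  structure(list(cluster = cl, hclust = hc), class = "cluster_assignment")
}

#' Select the persistently deregulated cluster
#'
#' Among clusters whose mean long-duration frequency score reaches the
#' threshold, returns the genes of the cluster with the highest mean
#' long-duration frequency (ties: larger cluster, then lexicographically
#' smallest label). Warns and returns an empty set when no cluster
#' qualifies.
#'
#' @param assignment A [ward_clusters()] result.
#' @param profile The frequency-score matrix clustered (column `long` used).
#' @param threshold Minimum mean long-duration frequency (percent).
#' @return Character vector of gene ids (possibly empty).
#' @export
select_persistent_cluster <- function(assignment, profile, threshold = 40) {
  cl <- assignment$cluster
  labs <- sort(unique(cl))
  means <- vapply(labs, function(k)
    mean(profile[names(cl)[cl == k], "long"]), 0)
  sizes <- vapply(labs, function(k) sum(cl == k), 0L)
  ok <- means >= threshold
  if (!any(ok)) {
    warning("no cluster reaches a mean long-term frequency of ", threshold)
    return(character())
  }
  cand <- which(ok)
  best <- cand[order(-means[cand], -sizes[cand], labs[cand])][1]
  names(cl)[cl == labs[best]]
}

#' Venn counts of two gene sets
#' @param set_a,set_b Character vectors.
#' @return Named integer vector: only_a, only_b, shared.
#' @export
overlap_counts <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  shared <- length(intersect(set_a, set_b))
  c(only_a = length(set_a) - shared, only_b = length(set_b) - shared,
    shared = shared)
}
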