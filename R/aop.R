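#' One-sided Fisher overrepresentation test
#'
#' Tests enrichment of a target gene set within a term gene set over a
#' finite universe (hypergeometric / one-sided Fisher exact test).
#'
#' @param target_set,term_set Character vectors, subsets of `universe`.
#' @param universe Character vector of all genes.
#' @return `overrep_result` list: `table` (2 x 2), `odds_ratio`, `p`.
#' @export
fisher_overrepresentation <- function(target_set, term_set, universe) {
  if (length(universe) == 0L) stop("empty universe")
  target_set <- unique(target_set); term_set <- unique(term_set)
  stopifnot(all(target_set %in% universe), all(term_set %in% universe))
  in_t <- universe %in% target_set
  in_e <- universe %in% term_set
  tab <- matrix(c(sum(in_t & in_e), sum(!in_t & in_e),
                  sum(in_t & !in_e), sum(!in_t & !in_e)), 2, 2,
                dimnames = list(c("target", "non_target"),
                                c("in_term", "out_term")))
  ft <- stats::fisher.test(tab, alternative = "greater")
  structure(list(table = tab, odds_ratio = unname(ft$estimate),
                 p = ft$p.value), class = "overrep_result")
}

#' @export
print.overrep_result <- function(x, ...) {
  cat(sprintf("overrepresentation: OR = %.3g, p = %.3g\n", x$odds_ratio, x$p))
  invisible(x)
}

#' Enrichment of a target set across AOP event gene sets
#'
#' Fisher overrepresentation per event of the requested type(s), with
#' Bonferroni correction across the tested events.
#'
#' @param target_set Character vector of genes (e.g. zinc-finger targets).
#' @param annotation An `aop_annotation` (see [generate_aop_annotation()]
#'   or [read_aop_annotation()]).
#' @param event_type_filter Types to test (subset of MIE/KE/AO); NULL = all.
#' @param alpha Adjusted-p significance threshold.
#' @return data.frame: event_id, type, n_genes, overlap, odds_ratio, p,
#'   adj_p, significant.
#' @export
enrich_event_sets <- function(target_set, annotation,
                              event_type_filter = NULL, alpha = 0.05) {
  ev <- annotation$events
  if (!is.null(event_type_filter)) {
    ev <- ev[vapply(ev, function(e) e$type %in% event_type_filter, TRUE)]
  }
  if (length(ev) == 0L) stop("no events of the requested type")
  rows <- lapply(names(ev), function(id) {
    res <- fisher_overrepresentation(target_set, ev[[id]]$genes,
                                     annotation$universe)
    data.frame(event_id = id, type = ev[[id]]$type,
               n_genes = length(unique(ev[[id]]$genes)),
               overlap = res$table["target", "in_term"],
               odds_ratio = res$odds_ratio, p = res$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- pmin(1, out$p * nrow(out))  # Bonferroni
  out$significant <- out$adj_p < alpha
  out
}

#' AOP-level enrichment with the one-third key-event rule
#'
#' An adverse outcome pathway is reported when (a) the union of its events'
#' genes is enriched for the target set at unadjusted p below `alpha`, and
#' (b) at least one-third of its events individually pass unadjusted
#' `alpha`.
#'
#' @param target_set Character vector of genes.
#' @param annotation An `aop_annotation`.
#' @param alpha Significance threshold for both the gene-level test and the
#'   per-event fraction.
#' @return data.frame: aop_id, n_events, n_significant_events,
#'   event_fraction, gene_level_p, kept; attribute `event_p` holds the
#'   per-event p map.
#' @export
enrich_aops <- function(target_set, annotation, alpha = 0.05) {
  event_p <- vapply(annotation$events, function(e)
    fisher_overrepresentation(target_set, e$genes, annotation$universe)$p, 0)
  rows <- lapply(names(annotation$aops), function(aid) {
    evs <- annotation$aops[[aid]]
    if (length(evs) == 0L) stop("AOP without events: ", aid)
    union_genes <- unique(unlist(lapply(annotation$events[evs], `[[`, "genes")))
    gp <- fisher_overrepresentation(target_set, union_genes,
                                    annotation$universe)$p
    nsig <- sum(event_p[evs] < alpha)
    frac <- nsig / length(evs)
    data.frame(aop_id = aid, n_events = length(evs),
               n_significant_events = nsig, event_fraction = frac,
               gene_level_p = gp,
               kept = gp < alpha && frac >= 1 / 3 - 1e-12,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "event_p") <- event_p
  out
}

#' Read an AOP annotation from two TSV files
#'
#' `events_path`: columns event_id, type, gene_id (one gene per row).
#' `aops_path`: columns aop_id, event_id (ordered).
#'
#' @param events_path,aops_path TSV paths.
#' @param universe Gene universe; defaults to all genes seen in the events.
#' @return An `aop_annotation`.
#' @export
read_aop_annotation <- function(events_path, aops_path, universe = NULL) {
  et <- read_tsv(events_path)
  at <- read_tsv(aops_path)
  events <- lapply(split(et, et$event_id), function(d)
    list(type = d$type[1], genes = unique(d$gene_id)))
  aops <- lapply(split(at, at$aop_id), function(d) d$event_id)
  if (is.null(universe)) universe <- unique(et$gene_id)
  missing <- setdiff(unlist(aops), names(events))
  if (length(missing) > 0)
    stop("AOPs reference unknown events: ", paste(missing, collapse = ", "))
  structure(list(events = events, aops = aops, universe = universe),
            class = "aop_annotation")
}
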