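# Shared fixture builders; everything is generated in code.

# a tiny DE collection with fully controlled p-values
tiny_collection <- function(p, logfc = NULL, systems = NULL,
                            durations = NULL, enm = NULL, n = 6L) {
  G <- nrow(p); D <- ncol(p)
  if (is.null(rownames(p))) rownames(p) <- sprintf("g%02d", seq_len(G))
  if (is.null(colnames(p))) colnames(p) <- sprintf("c%02d", seq_len(D))
  if (is.null(logfc)) logfc <- matrix(1, G, D, dimnames = dimnames(p))
  adj <- apply(p, 2, p.adjust, method = "BH")
  dimnames(adj) <- dimnames(p)
  meta <- data.frame(
    contrast_id = colnames(p),
    system = systems %||% rep(c("in_vitro", "in_vivo"), length.out = D),
    duration_class = durations %||% rep(c("short", "intermediate", "long"),
                                        length.out = D),
    enm_group = enm %||% rep("enmA", D),
    n = n, stringsAsFactors = FALSE)
  de_collection(logfc, p, adj, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force running-sum oracle for the enrichment score
es_oracle <- function(scores, set, exponent = 1) {
  genes <- names(scores)
  running <- 0
  best <- 0; best_i <- 1
  nh <- sum(genes %in% set)
  denom_hit <- sum(abs(scores[genes %in% set])^exponent)
  for (i in seq_along(genes)) {
    if (genes[i] %in% set) {
      running <- running + if (denom_hit > 0)
        unname(abs(scores[i]))^exponent / denom_hit else 1 / nh
    } else {
      running <- running - 1 / (length(genes) - nh)
    }
    if (abs(running) > abs(best)) { best <- running; best_i <- i }
  }
  list(ES = unname(best), peak = best_i)
}

# exhaustive hypergeometric upper-tail oracle for a 2x2 enrichment table
hyper_tail_oracle <- function(overlap, n_target, n_term, n_universe) {
  xs <- overlap:min(n_target, n_term)
  sum(choose(n_target, xs) * choose(n_universe - n_target, n_term - xs)) /
    choose(n_universe, n_term)
}

# minimal AOP annotation with exactly controllable per-event significance:
# significant events are copies of a target subset, null events are drawn
# from the non-target remainder
build_aop <- function(n_events, n_sig, universe, target) {
  non_target <- setdiff(universe, target)
  events <- list()
  for (j in seq_len(n_events)) {
    id <- sprintf("aop1_ev%d", j)
    genes <- if (j <= n_sig) target[seq_len(min(20, length(target)))]
             else non_target[((j * 13) %% 50) + seq_len(20)]
    events[[id]] <- list(type = "KE", genes = genes)
  }
  structure(list(events = events,
                 aops = list(aop1 = names(events)),
                 universe = universe),
            class = "aop_annotation")
}
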