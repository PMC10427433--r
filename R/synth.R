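#' Configuration for the synthetic nanotoxicogenomics collection
#'
#' The generator emulates the statistical structure of a large heterogeneous
#' compendium of ENM exposure contrasts: many contrasts sharing a planted
#' deregulated gene core, exposure-system and duration labels, and a
#' persistent subset that stays strongly deregulated in long-term exposures.
#'
#' Planted genes draw per-contrast z-scores around `effect_size_d` with
#' between-contrast heterogeneity `per_contrast_noise_sd`. A fraction
#' `persistent_frac` of the planted signature is additionally boosted by
#' `persistent_boost` standard deviations in long-duration contrasts: the
#' frequency score thresholds genes at per-contrast BH significance, which at
#' compendium scale requires |z| well above 3, so persistently detectable
#' genes must carry reproducibly strong long-term effects.
#'
#' @param n_genes,n_contrasts Collection dimensions.
#' @param planted_signature Number of planted signature genes.
#' @param effect_size_d Standardized mean difference of planted genes.
#' @param per_contrast_noise_sd SD of the contrast-specific shift added to
#'   planted effects.
#' @param frac_invivo Fraction of contrasts labelled in vivo.
#' @param duration_mix Named proportions for short/intermediate/long
#'   (must sum to 1).
#' @param sig_alpha BH-adjusted significance threshold used downstream.
#' @param persistent_frac Fraction of planted genes that are persistent.
#' @param persistent_boost Extra standardized effect of persistent genes in
#'   long-duration contrasts.
#' @param n_enm_groups Number of distinct ENM groups the contrasts cycle
#'   over.
#' @param enm_effect_sd SD of the ENM-group potency factor shared
#'   (direction-signed) by planted genes; this is the latent structure that
#'   nanodescriptors can correlate with.
#' @param seed Master integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_genes = 2000, n_contrasts = 24,
                         planted_signature = 150, effect_size_d = 1.0,
                         per_contrast_noise_sd = 0.3, frac_invivo = 0.5,
                         duration_mix = c(short = 1/3, intermediate = 1/3,
                                          long = 1/3),
                         sig_alpha = 0.05, persistent_frac = 0.3,
                         persistent_boost = 4.5, n_enm_groups = 8,
                         enm_effect_sd = 0.8, seed = 42) {
  if (n_genes < 1 || n_contrasts < 1) stop("counts must be positive")
  if (planted_signature > n_genes) stop("planted signature larger than n_genes")
  if (abs(sum(duration_mix) - 1) > 1e-8) stop("duration_mix must sum to 1")
  stopifnot(frac_invivo >= 0, frac_invivo <= 1,
            persistent_frac >= 0, persistent_frac <= 1)
  structure(list(n_genes = n_genes, n_contrasts = n_contrasts,
                 planted_signature = planted_signature,
                 effect_size_d = effect_size_d,
                 per_contrast_noise_sd = per_contrast_noise_sd,
                 frac_invivo = frac_invivo, duration_mix = duration_mix,
                 sig_alpha = sig_alpha, persistent_frac = persistent_frac,
                 persistent_boost = persistent_boost,
                 n_enm_groups = n_enm_groups, enm_effect_sd = enm_effect_sd,
                 seed = seed),
            class = "synth_config")
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Generate a synthetic DE collection with planted ground truth
#'
#' Per contrast, null genes draw z ~ N(0, 1); planted genes draw
#' z ~ N(s_g (d + delta_j), 1) where s_g is a fixed per-gene direction and
#' delta_j ~ N(0, per_contrast_noise_sd) a contrast-wide heterogeneity shift.
#' Persistent planted genes get `persistent_boost` added in long-duration
#' contrasts. Two-sided normal p-values; BH adjustment within contrast;
#' log2 fold changes proportional to z (sign-consistent).
#'
#' @param config A [synth_config()].
#' @return List with `collection` (a [de_collection()]) and `truth`
#'   (list: `signature_genes`, `persistent_long_genes` per system,
#'   `directions`).
#' @export
generate_de_collection <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(split_seed(config$seed, 1L))
  G <- config$n_genes; D <- config$n_contrasts
  genes <- gene_ids(G)
  contrasts <- sprintf("c%03d", seq_len(D))
  n_planted <- config$planted_signature
  planted <- genes[seq_len(n_planted)]
  n_pers <- round(config$persistent_frac * n_planted)
  persistent <- planted[seq_len(n_pers)]
  dirs <- stats::setNames(sample(c(-1, 1), n_planted, replace = TRUE), planted)

  n_vivo <- round(config$frac_invivo * D)
  system <- c(rep("in_vivo", n_vivo), rep("in_vitro", D - n_vivo))
  mix <- config$duration_mix[c("short", "intermediate", "long")]
  # deterministic per-system duration assignment following the mix
  duration <- character(D)
  for (s in unique(system)) {
    idx <- which(system == s)
    counts <- diff(round(cumsum(c(0, mix)) * length(idx)))
    duration[idx] <- rep(names(mix), counts)
  }
  n_groups <- min(config$n_enm_groups, D)
  enm_group <- sprintf("enm%02d", (seq_len(D) - 1L) %% n_groups + 1L)

  z <- matrix(stats::rnorm(G * D), G, D, dimnames = list(genes, contrasts))
  if (n_planted > 0) {
    delta <- stats::rnorm(D, 0, config$per_contrast_noise_sd)
    # ENM-group potency factor shared by planted genes (what descriptors
    # can track)
    eta <- stats::setNames(stats::rnorm(n_groups, 0, config$enm_effect_sd),
                           sprintf("enm%02d", seq_len(n_groups)))
    for (j in seq_len(D)) {
      mu <- rep(config$effect_size_d + eta[[enm_group[j]]] + delta[j],
                n_planted)
      if (duration[j] == "long") {
        # the persistent core responds regardless of the ENM's potency:
        # its long-term effect is the boosted baseline without the
        # material-specific factor
        mu[planted %in% persistent] <-
          config$effect_size_d + delta[j] + config$persistent_boost
      }
      z[planted, j] <- z[planted, j] + dirs * mu
    }
  }
  p <- 2 * stats::pnorm(-abs(z))
  p <- pmin(pmax(p, 1e-300), 1)
  adj_p <- apply(p, 2, stats::p.adjust, method = "BH")
  dimnames(adj_p) <- dimnames(p)
  logfc <- z / 2

  meta <- data.frame(contrast_id = contrasts, system = system,
                     duration_class = duration, enm_group = enm_group,
                     n = 6L, stringsAsFactors = FALSE)
  coll <- de_collection(logfc, p, adj_p, meta)
  truth <- list(signature_genes = planted,
                persistent_long_genes = list(in_vitro = persistent,
                                             in_vivo = persistent),
                directions = dirs,
                enm_potency = if (n_planted > 0) eta else NULL)
  list(collection = coll, truth = truth)
}

#' Generate promoter sequences with planted motif instances
#'
#' Background sequences are i.i.d. draws from a 0-order base composition.
#' Each planted gene receives, with probability `insertion_prob`, one motif
#' instance sampled column-wise from the motif's PFM, placed at a uniform
#' position on a uniform strand; non-planted genes receive instances with
#' probability `background_prob`. `motif` may be a single motif or a list of
#' motifs, in which case each planted gene independently receives each motif
#' with the stated probability.
#'
#' @param gene_ids Character vector of promoter names.
#' @param motif A `motif_model` (list with `pfm`, 4 x w, rows ACGT, and
#'   `consensus`) or list thereof.
#' @param planted_genes Genes eligible for insertion at `insertion_prob`.
#' @param insertion_prob Per-motif insertion probability for planted genes.
#' @param length Promoter length (bp).
#' @param seed Integer seed.
#' @param background_prob Insertion probability for non-planted genes.
#' @param base_freq Background base composition (A, C, G, T).
#' @return Named character vector of sequences (a promoter set).
#' @export
generate_promoters <- function(gene_ids, motif, planted_genes,
                               insertion_prob, length = 600, seed = 1,
                               background_prob = 0,
                               base_freq = c(A = 0.25, C = 0.25,
                                             G = 0.25, T = 0.25)) {
  stopifnot(insertion_prob >= 0, insertion_prob <= 1,
            background_prob >= 0, background_prob <= 1)
  motifs <- if (!is.null(motif$pfm)) list(motif) else motif
  for (m in motifs) {
    if (ncol(m$pfm) > length) stop("motif wider than promoter length")
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(gene_ids, function(g) {
    paste(sample(bases, length, replace = TRUE, prob = base_freq),
          collapse = "")
  }, "")
  sample_instance <- function(pfm) {
    pr <- sweep(pfm, 2, colSums(pfm), "/")
    paste(vapply(seq_len(ncol(pr)), function(j)
      sample(bases, 1, prob = pr[, j]), ""), collapse = "")
  }
  for (g in gene_ids) {
    prob <- if (g %in% planted_genes) insertion_prob else background_prob
    if (prob == 0) next
    for (m in motifs) {
      if (stats::runif(1) < prob) {
        inst <- sample_instance(m$pfm)
        if (stats::runif(1) < 0.5) inst <- revcomp(inst)
        w <- nchar(inst)
        pos <- sample.int(length - w + 1L, 1L)
        s <- seqs[[g]]
        seqs[[g]] <- paste0(substr(s, 1, pos - 1L), inst,
                            substr(s, pos + w, length))
      }
    }
  }
  seqs
}

#' Generate a nanodescriptor table correlated with planted gene responses
#'
#' For each descriptor listed in `linked_genes`, the descriptor value of an
#' ENM tracks the mean log2 fold change of that descriptor's linked genes
#' across the ENM's contrasts, plus Gaussian noise; unlinked descriptors are
#' pure noise. Cells go missing independently with `missing_frac`.
#'
#' @param enm_ids ENM identifiers; must match `enm_group` labels of the
#'   collection.
#' @param linked_genes Named list: descriptor name -> character vector of
#'   linked gene ids (may be empty for unlinked descriptors).
#' @param de_collection A [de_collection()].
#' @param noise_sd Noise SD on the standardized linked signal (0 = perfect
#'   correlation).
#' @param seed Integer seed.
#' @param missing_frac Fraction of cells set missing.
#' @return Numeric ENM x descriptor matrix (with NAs).
#' @export
generate_descriptor_table <- function(enm_ids, linked_genes, de_collection,
                                      noise_sd = 0.3, seed = 1,
                                      missing_frac = 0) {
  stopifnot(all(unlist(linked_genes) %in% de_collection$genes))
  set.seed(seed)
  # per-ENM mean logFC profile over contrasts of that ENM group
  prof <- sapply(enm_ids, function(e) {
    idx <- which(de_collection$meta$enm_group == e)
    if (length(idx) == 0L) stop("unknown ENM group: ", e)
    rowMeans(de_collection$logfc[, idx, drop = FALSE])
  })
  out <- matrix(NA_real_, length(enm_ids), length(linked_genes),
                dimnames = list(enm_ids, names(linked_genes)))
  for (d in names(linked_genes)) {
    lg <- linked_genes[[d]]
    base <- if (length(lg) == 0L) stats::rnorm(length(enm_ids)) else {
      # align gene directions before averaging so opposite-sign responders
      # do not cancel
      sgn <- sign(rowMeans(prof[lg, , drop = FALSE]))
      sgn[sgn == 0] <- 1
      v <- colMeans(sgn * prof[lg, , drop = FALSE])
      as.numeric(scale(v)) + stats::rnorm(length(enm_ids), 0, noise_sd)
    }
    out[, d] <- base
  }
  if (missing_frac > 0) {
    miss <- matrix(stats::runif(length(out)) < missing_frac, nrow(out))
    out[miss] <- NA_real_
    if (any(colSums(!is.na(out)) == 0L))
      stop("missing fraction produced an all-missing descriptor column")
  }
  out
}

#' Generate dose-response expression series with known benchmark doses
#'
#' Responsive genes follow a linear (`response = b * dose`) or Hill curve
#' plus constant-variance Gaussian noise; other genes are flat noise. For
#' linear genes the true benchmark dose under the standard-deviation approach
#' is `bmrf * sigma / |b|`, recorded as ground truth.
#'
#' @param gene_ids All gene ids in the series.
#' @param responsive_genes Genes following the dose-response curve.
#' @param doses Distinct dose levels (>= 4).
#' @param model_spec List: `model` ("linear" or "hill") plus parameters
#'   (`b` for linear; `emax`, `k`, `n` for hill).
#' @param sigma Residual SD (constant variance).
#' @param seed Integer seed.
#' @param n_replicates Replicates per dose (>= 2).
#' @param bmrf Benchmark response factor used for the recorded true BMD.
#' @return List with `series` (long data.frame gene/dose/replicate/response)
#'   and `truth` (data.frame gene_id, true_bmd for responsive genes).
#' @export
generate_dose_series <- function(gene_ids, responsive_genes, doses,
                                 model_spec = list(model = "linear", b = 2),
                                 sigma = 1, seed = 1, n_replicates = 3,
                                 bmrf = 1.349) {
  if (length(unique(doses)) < 4) stop("need at least 4 distinct doses")
  if (n_replicates < 2) stop("need at least 2 replicates per dose")
  set.seed(seed)
  grid <- expand.grid(dose = doses, replicate = seq_len(n_replicates))
  curve <- function(x) {
    switch(model_spec$model,
           linear = model_spec$b * x,
           hill = model_spec$emax * x^model_spec$n /
             (model_spec$k^model_spec$n + x^model_spec$n),
           stop("unknown model: ", model_spec$model))
  }
  rows <- lapply(gene_ids, function(g) {
    mu <- if (g %in% responsive_genes) curve(grid$dose) else 0
    data.frame(gene_id = g, dose = grid$dose, replicate = grid$replicate,
               response = mu + stats::rnorm(nrow(grid), 0, sigma),
               stringsAsFactors = FALSE)
  })
  true_bmd <- if (model_spec$model == "linear") {
    rep(bmrf * sigma / abs(model_spec$b), length(responsive_genes))
  } else {
    # numeric inversion of |curve(x)| = bmrf * sigma
    vapply(responsive_genes, function(g) {
      f <- function(x) abs(curve(x)) - bmrf * sigma
      if (f(max(doses)) < 0) return(NA_real_)
      stats::uniroot(f, c(0, max(doses)), tol = 1e-10)$root
    }, 0)
  }
  list(series = do.call(rbind, rows),
       truth = data.frame(gene_id = responsive_genes, true_bmd = true_bmd,
                          stringsAsFactors = FALSE))
}

#' Generate an AOP annotation with planted enriched events
#'
#' Events sample genes uniformly from the universe except designated enriched
#' events, which over-sample the target set at the requested odds ratio.
#' Events are grouped consecutively into AOPs.
#'
#' @param universe Gene universe (character).
#' @param target_set Genes over-represented in enriched events.
#' @param n_aops Number of AOPs.
#' @param events_per_aop Events per AOP.
#' @param genes_per_event Genes per event.
#' @param enriched_events Character vector of event ids to enrich (ids are
#'   `aop<i>_ev<j>`), or an integer count n: the first n events of the first
#'   AOP.
#' @param odds_ratio Sampling odds multiplier for target genes in enriched
#'   events (1 = null).
#' @param seed Integer seed.
#' @return An `aop_annotation`: list with `events` (id -> list(type, genes)),
#'   `aops` (id -> event ids), `universe`.
#' @export
generate_aop_annotation <- function(universe, target_set, n_aops = 3,
                                    events_per_aop = 9, genes_per_event = 40,
                                    enriched_events = 0, odds_ratio = 1,
                                    seed = 1) {
  stopifnot(n_aops > 0, events_per_aop > 0, genes_per_event > 0)
  if (genes_per_event > length(universe)) stop("event larger than universe")
  set.seed(seed)
  ev_ids <- unlist(lapply(seq_len(n_aops), function(i)
    sprintf("aop%d_ev%d", i, seq_len(events_per_aop))))
  if (is.numeric(enriched_events) && length(enriched_events) == 1L) {
    enriched_events <- utils::head(ev_ids, enriched_events)
  }
  in_target <- universe %in% target_set
  w_null <- rep(1, length(universe))
  w_enr <- ifelse(in_target, odds_ratio, 1)
  types <- c("MIE", rep("KE", events_per_aop - 2L), "AO")[seq_len(events_per_aop)]
  events <- list()
  for (i in seq_len(n_aops)) {
    for (j in seq_len(events_per_aop)) {
      id <- sprintf("aop%d_ev%d", i, j)
      w <- if (id %in% enriched_events) w_enr else w_null
      events[[id]] <- list(type = types[j],
                           genes = sample(universe, genes_per_event,
                                          prob = w / sum(w)))
    }
  }
  aops <- stats::setNames(lapply(seq_len(n_aops), function(i)
    sprintf("aop%d_ev%d", i, seq_len(events_per_aop))),
    sprintf("aop%d", seq_len(n_aops)))
  structure(list(events = events, aops = aops, universe = universe),
            class = "aop_annotation")
}

#' A small synthetic PWM library with zinc-finger-family profiles
#'
#' Builds a JASPAR-style library of informative position frequency matrices:
#' `n_family` profiles labelled `C2H2-ZNF` (the first built around the
#' supplied family consensus words, the rest around random GC-rich words) and
#' `n_other` labelled `other` around random words. Serves as the matching
#' background for family-overrepresentation tests on synthetic data.
#'
#' @param family_words Character vector of consensus words for family
#'   profiles.
#' @param n_family,n_other Profile counts.
#' @param seed Integer seed.
#' @param concentration Per-column probability mass on the consensus base.
#' @return A `pwm_library` (see [read_pwm_library()]).
#' @export
synthetic_pwm_library <- function(family_words = character(), n_family = 20,
                                  n_other = 80, seed = 1,
                                  concentration = 0.85) {
  stopifnot(n_family >= length(family_words))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  word_pfm <- function(word) {
    w <- nchar(word)
    pfm <- matrix((1 - concentration) / 3, 4, w, dimnames = list(bases, NULL))
    for (j in seq_len(w)) pfm[substr(word, j, j), j] <- concentration
    round(pfm * 100)
  }
  rand_word <- function(gc = 0.5) {
    n <- sample(6:12, 1)
    paste(sample(bases, n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  }
  lib <- list()
  k <- 0L
  for (wrd in family_words) {
    k <- k + 1L
    lib[[sprintf("MZF%03d", k)]] <- list(pfm = word_pfm(wrd),
                                         name = sprintf("ZNF%03d", k),
                                         family = "C2H2-ZNF")
  }
  while (k < n_family) {
    k <- k + 1L
    lib[[sprintf("MZF%03d", k)]] <- list(pfm = word_pfm(rand_word(0.75)),
                                         name = sprintf("ZNF%03d", k),
                                         family = "C2H2-ZNF")
  }
  for (i in seq_len(n_other)) {
    lib[[sprintf("MOT%03d", i)]] <- list(pfm = word_pfm(rand_word(0.5)),
                                         name = sprintf("TF%03d", i),
                                         family = "other")
  }
  structure(lib, class = "pwm_library")
}

#' Default planted zinc-finger consensus words used by the synthetic pipeline
#'
#' Six GC-rich words in the style of classic C2H2 zinc-finger binding sites
#' (KLF/SP/EGR-like), 8-11 bp, used both to plant promoter instances and to
#' seed family profiles in [synthetic_pwm_library()].
#' @return Character vector of consensus words.
#' @export
znf_consensus_words <- function() {
  c("GGGGCGGGG", "GCGTGGGCG", "GAGGAGGAG", "GACCACCCA",
    "TGCCATGGC", "CACACCCAC")
}

#' Build a motif model from a consensus word
#' @param word Consensus string over ACGT.
#' @param concentration Probability mass on the consensus base per column.
#' @return A `motif_model` list with `pfm` (4 x width) and `consensus`.
#' @export
motif_from_word <- function(word, concentration = 0.9) {
  bases <- c("A", "C", "G", "T")
  w <- nchar(word)
  pfm <- matrix((1 - concentration) / 3, 4, w, dimnames = list(bases, NULL))
  for (j in seq_len(w)) pfm[substr(word, j, j), j] <- concentration
  structure(list(pfm = pfm, consensus = word), class = "motif_model")
}
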