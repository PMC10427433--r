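#' Demo pipeline configuration on synthetic data
#'
#' A modest synthetic study: 500 genes x 24 contrasts with a planted
#' 60-gene signature (40 percent persistent), six planted zinc-finger
#' promoter words, three descriptor-linked descriptors and a small
#' dose-response panel. Sizes are chosen so a full end-to-end run completes
#' in well under a minute while every stage still has recoverable planted
#' structure.
#'
#' @param seed Master integer seed.
#' @param outdir Output directory.
#' @return A `pipeline_config` list understood by [run_pipeline()].
#' @export
demo_config <- function(seed = 42, outdir = tempfile("nanometasig_run_")) {
  list(
    synthetic = list(n_genes = 600, n_contrasts = 24,
                     planted_signature = 150,
                     effect_size_d = 1.0, per_contrast_noise_sd = 0.3,
                     frac_invivo = 0.5, persistent_frac = 0.45,
                     persistent_boost = 4.5, n_enm_groups = 12,
                     enm_effect_sd = 0.8,
                     insertion_prob = 0.4, background_prob = 0.05,
                     n_background_promoters = 80,
                     n_gene_sets = 20, n_signature_sets = 5,
                     descriptor_noise_sd = 0.3,
                     doses = c(0, 0.5, 1, 1.5, 2), dose_sigma = 0.25,
                     n_dose_genes = 30),
    params = list(n_perm = 500, sig_alpha = 0.05, gsea_alpha = 0.05,
                  signature_percentile = 10, n_clusters = 2,
                  persistence_threshold = 40, motif_width_range = c(6, 15),
                  motif_p_threshold = 0.05, min_similarity = 0.8,
                  descriptor_alpha = 0.01, aop_alpha = 0.05,
                  bmrf = 1.349, bmd_conf = 0.90),
    seed = seed,
    outdir = outdir
  )
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML path with the same structure as [demo_config()].
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- demo_config()
  for (blk in c("synthetic", "params")) {
    if (!is.null(cfg[[blk]])) {
      merged <- base[[blk]]
      merged[names(cfg[[blk]])] <- cfg[[blk]]
      cfg[[blk]] <- merged
    } else cfg[[blk]] <- base[[blk]]
  }
  cfg$seed <- cfg$seed %||% base$seed
  cfg$outdir <- cfg$outdir %||% base$outdir
  cfg
}

# generate every synthetic input the pipeline consumes, with ground truth
synthetic_inputs <- function(config) {
  sy <- config$synthetic
  sc <- synth_config(n_genes = sy$n_genes, n_contrasts = sy$n_contrasts,
                     planted_signature = sy$planted_signature,
                     effect_size_d = sy$effect_size_d,
                     per_contrast_noise_sd = sy$per_contrast_noise_sd,
                     frac_invivo = sy$frac_invivo,
                     persistent_frac = sy$persistent_frac,
                     persistent_boost = sy$persistent_boost,
                     n_enm_groups = sy$n_enm_groups %||% 8,
                     enm_effect_sd = sy$enm_effect_sd %||% 0.8,
                     seed = config$seed)
  gen <- generate_de_collection(sc)
  coll <- gen$collection
  truth <- gen$truth
  genes <- coll$genes
  planted <- truth$signature_genes
  persistent <- truth$persistent_long_genes$in_vitro

  # pathway-style gene sets: some enriched in the planted signature, rest null
  set.seed(split_seed(config$seed, 2L))
  sets <- list()
  for (i in seq_len(sy$n_signature_sets)) {
    k <- sample(30:60, 1)
    k_sig <- round(0.6 * k)
    sets[[sprintf("sig_set_%02d", i)]] <-
      c(sample(planted, min(k_sig, length(planted))),
        sample(setdiff(genes, planted), k - min(k_sig, length(planted))))
  }
  for (i in seq_len(sy$n_gene_sets - sy$n_signature_sets)) {
    sets[[sprintf("null_set_%02d", i)]] <- sample(genes, sample(20:80, 1))
  }
  attr(sets, "category") <- stats::setNames(
    ifelse(grepl("^sig", names(sets)), "signature", "null"), names(sets))

  words <- znf_consensus_words()
  motifs <- lapply(words, motif_from_word)
  library <- synthetic_pwm_library(family_words = words, n_family = 10,
                                   n_other = 90,
                                   seed = split_seed(config$seed, 3L))

  set.seed(split_seed(config$seed, 4L))
  bg_genes <- sample(setdiff(genes, persistent), sy$n_background_promoters)
  promoter_genes <- c(persistent, bg_genes)
  promoters <- generate_promoters(promoter_genes, motifs,
                                  planted_genes = persistent,
                                  insertion_prob = sy$insertion_prob,
                                  background_prob = sy$background_prob,
                                  seed = split_seed(config$seed, 5L))

  enm_ids <- unique(coll$meta$enm_group)
  set.seed(split_seed(config$seed, 6L))
  linked <- list(
    desc_linked_1 = sample(planted, min(40, length(planted))),
    desc_linked_2 = sample(planted, min(40, length(planted))),
    desc_linked_3 = sample(planted, min(40, length(planted))),
    desc_null_1 = character(), desc_null_2 = character(),
    desc_null_3 = character(), desc_null_4 = character(),
    desc_null_5 = character()
  )
  descriptors <- generate_descriptor_table(enm_ids, linked, coll,
                                           noise_sd = sy$descriptor_noise_sd,
                                           seed = split_seed(config$seed, 7L))

  set.seed(split_seed(config$seed, 8L))
  dose_gene_pool <- c(sample(persistent, min(10, length(persistent))),
                      sample(setdiff(genes, planted),
                             sy$n_dose_genes - min(10, length(persistent))))
  dose <- generate_dose_series(dose_gene_pool,
                               responsive_genes = dose_gene_pool[
                                 dose_gene_pool %in% persistent],
                               doses = sy$doses,
                               model_spec = list(model = "linear", b = 2),
                               sigma = sy$dose_sigma,
                               seed = split_seed(config$seed, 9L))

  aop <- generate_aop_annotation(genes, target_set = persistent,
                                 n_aops = 3, events_per_aop = 9,
                                 genes_per_event = 40,
                                 enriched_events = 4, odds_ratio = 15,
                                 seed = split_seed(config$seed, 10L))

  list(collection = coll, truth = truth, gene_sets = sets,
       planted_motifs = motifs, pwm_library = library,
       promoters = promoters, descriptor_table = descriptors,
       descriptor_links = linked, dose = dose, aop = aop)
}

write_fasta <- function(seqs, path, tag = NULL) {
  hdr <- if (is.null(tag)) paste0(">", names(seqs))
         else paste0(">", names(seqs), " cfg=", tag)
  writeLines(as.vector(rbind(hdr, unname(seqs))), path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order on synthetic inputs generated from the
#' config: ensemble meta-analysis, GSEA signature cut, frequency-score
#' clustering, promoter motif analysis, descriptor association, AOP
#' enrichment and benchmark-dose analysis. Every intermediate is persisted
#' as plain text (TSV/FASTA/GMT/JSON) stamped with the config hash, and
#' recovery metrics against the planted ground truth are reported.
#'
#' @param config A `pipeline_config` (see [demo_config()] /
#'   [read_pipeline_config()]).
#' @return A `run_report`: list with `outputs` (named file paths),
#'   `summary` (named numeric metrics), `recovery` (AUROC, Jaccard, family
#'   p, ...), `config_hash`.
#' @export
run_pipeline <- function(config) {
  pr <- config$params
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config[c("synthetic", "params", "seed")])
  hdr <- paste0("config_hash: ", hash)
  outputs <- character()
  t0 <- proc.time()[3]
  log_stage <- function(stage, t_start, ...) {
    message(sprintf("[%s] %.2fs %s", stage, proc.time()[3] - t_start,
                    paste(..., collapse = " ")))
  }

  ts <- proc.time()[3]
  inp <- synthetic_inputs(config)
  coll <- inp$collection
  truth <- inp$truth
  write_tsv(data.frame(gene_id = rep(coll$genes, ncol(coll$p)),
                       contrast_id = rep(coll$contrasts, each = nrow(coll$p)),
                       logfc = as.vector(coll$logfc),
                       p = as.vector(coll$p),
                       adj_p = as.vector(coll$adj_p)),
            file.path(outdir, "de_stats.tsv"), header = hdr)
  write_tsv(coll$meta, file.path(outdir, "contrast_meta.tsv"), header = hdr)
  write_gmt(inp$gene_sets, file.path(outdir, "gene_sets.gmt"))
  write_pwm_library(inp$pwm_library, file.path(outdir, "pwm_library.pfm"))
  write_fasta(inp$promoters, file.path(outdir, "promoters.fasta"), tag = hash)
  jsonlite::write_json(
    list(signature_genes = truth$signature_genes,
         persistent_long_genes = truth$persistent_long_genes,
         dose_responsive = inp$dose$truth$gene_id),
    file.path(outdir, "groundtruth.json"), auto_unbox = FALSE)
  outputs["inputs"] <- file.path(outdir, "de_stats.tsv")
  log_stage("simulate", ts)

  ts <- proc.time()[3]
  consensus <- run_meta_analysis(coll, n_perm = pr$n_perm,
                                 seed = split_seed(config$seed, 20L))
  write_consensus_rank(consensus, file.path(outdir, "consensus_rank.tsv"),
                       header = hdr)
  outputs["meta"] <- file.path(outdir, "consensus_rank.tsv")
  rank_auroc <- auroc(-consensus$mean_rank[coll$genes],
                      coll$genes %in% truth$signature_genes)
  log_stage("meta", ts, sprintf("auroc=%.3f", rank_auroc))

  ts <- proc.time()[3]
  scores <- stats::setNames(rev(seq_along(consensus$order)), consensus$order)
  enr <- preranked_gsea(scores, inp$gene_sets, n_perm = pr$n_perm,
                        seed = split_seed(config$seed, 21L),
                        min_size = 15, max_size = 1000)
  sig_enr <- enr[enr$adj_p < pr$gsea_alpha, , drop = FALSE]
  cut <- select_signature_cut(consensus, sig_enr,
                              percentile = pr$signature_percentile)
  write_tsv(as.data.frame(enr), file.path(outdir, "gsea_results.tsv"),
            header = hdr)
  writeLines(c(paste0("# ", hdr), cut$signature_genes),
             file.path(outdir, "signature_genes.txt"))
  outputs["gsea"] <- file.path(outdir, "gsea_results.tsv")
  log_stage("gsea", ts, sprintf("cut=%d", cut$cut_position))

  ts <- proc.time()[3]
  sig_genes <- cut$signature_genes
  profiles <- frequency_scores(coll, sig_genes, alpha = pr$sig_alpha)
  persistent_sets <- list()
  for (sys in names(profiles)) {
    k <- min(pr$n_clusters, nrow(profiles[[sys]]))
    cl <- ward_clusters(profiles[[sys]], n_clusters = k)
    persistent_sets[[sys]] <- suppressWarnings(
      select_persistent_cluster(cl, profiles[[sys]],
                                threshold = pr$persistence_threshold))
    write_tsv(data.frame(gene_id = rownames(profiles[[sys]]),
                         profiles[[sys]], cluster = cl$cluster,
                         check.names = FALSE),
              file.path(outdir, paste0("frequency_", sys, ".tsv")),
              header = hdr)
  }
  ov <- overlap_counts(persistent_sets$in_vitro %||% character(),
                       persistent_sets$in_vivo %||% character())
  persistent <- unique(unlist(persistent_sets))
  outputs["cluster"] <- file.path(outdir, "frequency_in_vitro.tsv")
  jac <- jaccard(persistent, truth$persistent_long_genes$in_vitro)
  log_stage("cluster", ts, sprintf("persistent=%d jaccard=%.3f",
                                   length(persistent), jac))

  ts <- proc.time()[3]
  motifs <- discover_motifs(inp$promoters,
                            width_range = pr$motif_width_range,
                            p_threshold = pr$motif_p_threshold,
                            seed = split_seed(config$seed, 22L))
  matches <- lapply(motifs, match_motif_to_library, library = inp$pwm_library,
                    min_similarity = pr$min_similarity)
  matched_ids <- unique(stats::na.omit(
    vapply(matches, `[[`, "", "profile_id")))
  fam <- family_overrepresentation(matched_ids, inp$pwm_library)
  motif_df <- data.frame(
    consensus = vapply(motifs, `[[`, "", "consensus"),
    width = vapply(motifs, `[[`, 0, "width"),
    p = vapply(motifs, `[[`, 0, "p"),
    matched_profile = vapply(matches, `[[`, "", "profile_id"),
    matched_family = vapply(matches, `[[`, "", "family"),
    similarity = vapply(matches, `[[`, 0, "similarity"),
    stringsAsFactors = FALSE)
  write_tsv(motif_df, file.path(outdir, "motifs.tsv"), header = hdr)
  outputs["promoter"] <- file.path(outdir, "motifs.tsv")
  dens <- if (length(persistent) > 0 &&
              length(persistent) < length(consensus$order)) {
    target_position_density(consensus$order, persistent,
                            window = max(10, length(consensus$order) %/% 20))
  } else list(ks_p = NA_real_)
  log_stage("promoter", ts, sprintf("motifs=%d family_p=%.3g",
                                    length(motifs), fam$p))

  ts <- proc.time()[3]
  enm_ids <- unique(coll$meta$enm_group)
  logfc_by_enm <- sapply(enm_ids, function(e)
    rowMeans(coll$logfc[, coll$meta$enm_group == e, drop = FALSE]))
  cors <- winsorized_cube_correlation(logfc_by_enm, inp$descriptor_table,
                                      min_pairs = 3)
  dgsea <- descriptor_gsea(cors, consensus, top_frac = 0.10,
                           n_perm = pr$n_perm,
                           seed = split_seed(config$seed, 23L),
                           alpha = pr$descriptor_alpha)
  write_tsv(dgsea, file.path(outdir, "descriptor_gsea.tsv"), header = hdr)
  outputs["descriptors"] <- file.path(outdir, "descriptor_gsea.tsv")
  log_stage("descriptors", ts,
            sprintf("selected=%d/%d", sum(dgsea$selected), nrow(dgsea)))

  ts <- proc.time()[3]
  target <- if (length(persistent) > 0) persistent else
    truth$persistent_long_genes$in_vitro
  ev <- enrich_event_sets(target, inp$aop, alpha = pr$aop_alpha)
  ap <- enrich_aops(target, inp$aop, alpha = pr$aop_alpha)
  write_tsv(ev, file.path(outdir, "aop_events.tsv"), header = hdr)
  write_tsv(ap, file.path(outdir, "aop_pathways.tsv"), header = hdr)
  outputs["aop"] <- file.path(outdir, "aop_events.tsv")
  log_stage("aop", ts, sprintf("kept_aops=%d", sum(ap$kept)))

  ts <- proc.time()[3]
  bmd <- bmd_analysis(inp$dose$series, bmrf = pr$bmrf, conf = pr$bmd_conf)
  write_tsv(as.data.frame(bmd), file.path(outdir, "bmd_results.tsv"),
            header = hdr)
  outputs["bmd"] <- file.path(outdir, "bmd_results.tsv")
  dd_genes <- bmd$gene_id[bmd$passed]
  tf <- if (length(dd_genes) > 0) target_fraction(dd_genes, target) else
    NA_real_
  log_stage("bmd", ts, sprintf("dose_dependent=%d target_frac=%.1f",
                               length(dd_genes), tf))

  summary <- c(n_genes = length(coll$genes),
               n_contrasts = length(coll$contrasts),
               signature_size = cut$cut_position,
               n_persistent = length(persistent),
               overlap_shared = unname(ov["shared"]),
               n_motifs = length(motifs),
               n_matched_family = sum(motif_df$matched_family == "C2H2-ZNF",
                                      na.rm = TRUE),
               n_selected_descriptors = sum(dgsea$selected),
               n_significant_events = sum(ev$significant),
               n_kept_aops = sum(ap$kept),
               n_dose_dependent = length(dd_genes),
               dose_target_fraction = tf)
  recovery <- c(consensus_auroc = rank_auroc,
                persistent_jaccard = jac,
                family_fisher_p = fam$p,
                target_density_ks_p = dens$ks_p)
  report <- structure(list(outputs = outputs, summary = summary,
                           recovery = recovery, config_hash = hash,
                           elapsed = proc.time()[3] - t0),
                      class = "run_report")
  write_tsv(data.frame(metric = c(names(summary), names(recovery)),
                       value = unname(c(summary, recovery))),
            file.path(outdir, "run_report.tsv"), header = hdr)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("nanometasig run (", sprintf("%.1fs", x$elapsed), ", config ",
      substr(x$config_hash, 1, 8), ")\n", sep = "")
  cat("stage outputs:\n")
  for (nm in names(x$outputs)) cat(sprintf("  %-12s %s\n", nm, x$outputs[nm]))
  cat("summary:\n")
  for (nm in names(x$summary))
    cat(sprintf("  %-24s %s\n", nm, format(x$summary[[nm]])))
  cat("recovery vs ground truth:\n")
  for (nm in names(x$recovery))
    cat(sprintf("  %-24s %.4g\n", nm, x$recovery[[nm]]))
  invisible(x)
}
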