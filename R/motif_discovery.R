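# Simplified ANR (any-number-of-repetitions) EM motif finder.
#
# Deliberately not a MEME reimplementation: candidate widths are seeded from
# over-represented w-mers, refined by EM against a 0-order background, and
# scored for significance on a held-out half of the sequences so the
# binomial site-count test is independent of the half the model was fitted
# on. Adequate for planted-motif recovery; not bit-compatible with MEME.

BASES <- c("A", "C", "G", "T")

# sequences -> integer matrix (n x L) of base codes 1..4
encode_seqs <- function(seqs) {
  L <- unique(nchar(seqs))
  stopifnot(length(L) == 1L)
  m <- matrix(match(unlist(strsplit(seqs, "")), BASES), nrow = length(seqs),
              ncol = L, byrow = TRUE)
  rownames(m) <- names(seqs)
  m
}

revcomp_codes <- function(enc) {
  m <- 5L - enc[, rev(seq_len(ncol(enc))), drop = FALSE]
  rownames(m) <- rownames(enc)
  m
}

# scan context: per-offset base-code vectors for width-w windows over both
# strands, shared by every candidate of that width
scan_context <- function(enc, w) {
  enc2 <- rbind(enc, revcomp_codes(enc))
  np <- ncol(enc2) - w + 1L
  codes <- lapply(seq_len(w), function(k)
    as.vector(enc2[, k:(k + np - 1L), drop = FALSE]))
  list(enc2 = enc2, np = np, w = w, codes = codes,
       n_pos = nrow(enc2) * np)
}

# per-position log-likelihood-ratio scores (vector, column-major over the
# n2 x np window grid)
scan_scores <- function(ctx, lw) {
  lv <- as.vector(lw)
  sc <- numeric(ctx$n_pos)
  for (k in seq_len(ctx$w)) {
    sc <- sc + lv[(k - 1L) * 4L + ctx$codes[[k]]]
  }
  sc
}

# count w-mers (both strands) and return top distinct seed words by
# background-enrichment ratio
seed_words <- function(seqs, w, bg, n_seeds) {
  L <- nchar(seqs[1])
  both <- c(seqs, revcomp(seqs))
  words <- unlist(lapply(both, function(s)
    substring(s, 1:(L - w + 1L), w:L)), use.names = FALSE)
  tab_full <- table(words)
  # only well-repeated words can seed a motif; shortlist by exact-count
  # enrichment over the 0-order expectation
  tab <- tab_full[tab_full >= 2]
  if (length(tab) > 500) tab <- sort(tab, decreasing = TRUE)[1:500]
  if (length(tab) == 0L) return(character(0))
  exp_p <- vapply(names(tab), function(wd) {
    prod(bg[match(strsplit(wd, "")[[1]], BASES)])
  }, 0)
  ratio <- as.numeric(tab) / (exp_p * length(words))
  short <- names(tab)[order(-ratio, -as.numeric(tab), names(tab))]
  short <- utils::head(short, 200L)
  # re-rank the shortlist by Hamming-1-ball counts: instances of a real
  # motif scatter into one-mismatch words, coincidental repeats do not
  var_list <- lapply(short, function(wd) {
    v <- strsplit(wd, "")[[1]]
    c(wd, unlist(lapply(seq_along(v), function(j) {
      vapply(setdiff(BASES, v[j]), function(b) {
        u <- v; u[j] <- b; paste(u, collapse = "")
      }, "")
    })))
  })
  all_vars <- unlist(var_list)
  cnt_all <- as.numeric(tab_full[match(all_vars, names(tab_full))])
  cnt_all[is.na(cnt_all)] <- 0
  grp <- rep(seq_along(short), lengths(var_list))
  ball_count <- as.numeric(rowsum(cnt_all, grp))
  exp_ball <- exp_p[match(short, names(tab))] * (1 + 3 * w)
  ord <- order(-(ball_count / exp_ball), -ball_count, short)
  tab <- stats::setNames(as.numeric(tab_full[short]), short)
  # skip words that are shifts of an already-picked seed (shared w-2 core,
  # either strand), so one strong motif cannot occupy every seed slot
  core_overlap <- function(a, b) {
    k <- nchar(a) - 2L
    if (k < 4L) return(a == b || a == revcomp(b))
    subs <- function(s) substring(s, 1:(nchar(s) - k + 1L), k:nchar(s))
    any(subs(a) %in% c(subs(b), subs(revcomp(b))))
  }
  picked <- character(0)
  for (i in ord) {
    wd <- names(tab)[i]
    if (any(vapply(picked, core_overlap, TRUE, a = wd))) next
    picked <- c(picked, wd)
    if (length(picked) >= n_seeds) break
  }
  picked
}

pwm_from_word <- function(word, concentration = 0.85) {
  w <- nchar(word)
  pwm <- matrix((1 - concentration) / 3, 4, w, dimnames = list(BASES, NULL))
  for (j in seq_len(w)) pwm[substr(word, j, j), j] <- concentration
  pwm
}

# keep only active positions that are local score maxima within a window
# width on their own sequence row; overlapping shifted windows of one site
# otherwise smear the PWM columns during EM
local_max_filter <- function(idx, sc, n_rows, np, w) {
  keep <- logical(length(idx))
  for (h in seq_along(idx)) {
    i <- idx[h]
    r <- (i - 1L) %% n_rows + 1L
    j <- (i - 1L) %/% n_rows + 1L
    nb <- (max(1L, j - w + 1L):min(np, j + w - 1L))
    nb_i <- (nb - 1L) * n_rows + r
    keep[h] <- sc[i] >= max(sc[nb_i]) - 1e-12
  }
  idx[keep]
}

# EM refinement of the ANR model; the site prior is capped low so the model
# cannot absorb broad background patterns
em_refine <- function(ctx, pwm, bg, n_iter = 10, gamma_cap = 0.005,
                      pseudo = 0.25) {
  w <- ctx$w
  n_rows <- nrow(ctx$enc2)
  gamma <- 1 / (2 * ncol(ctx$enc2))
  for (it in seq_len(n_iter)) {
    lw <- log(pwm) - matrix(log(bg), 4, w)
    sc <- scan_scores(ctx, lw)
    # positions with negligible posterior (z <= 1e-4) carry no motif
    # information, only background blur; identify the active set on the
    # score scale and evaluate the posterior only there
    sc_min <- log(1e-4) - log(gamma / (1 - gamma))
    idx <- which(sc > sc_min)
    idx <- local_max_filter(idx, sc, n_rows, ctx$np, w)
    odds <- exp(pmin(sc[idx], 500)) * gamma / (1 - gamma)
    zi <- odds / (1 + odds)
    counts <- matrix(pseudo, 4, w, dimnames = list(BASES, NULL))
    for (k in seq_len(w)) {
      ck <- ctx$codes[[k]][idx]
      for (b in 1:4) counts[b, k] <- counts[b, k] + sum(zi[ck == b])
    }
    pwm <- sweep(counts, 2, colSums(counts), "/")
    gamma <- min(gamma_cap, max(sum(zi) / ctx$n_pos, 1e-7))
  }
  list(pwm = pwm, gamma = gamma)
}

# exact tail of the PWM llr score distribution under the 0-order
# background, by column-wise convolution on a discretized score grid;
# returns, for each requested tail target, the least stringent attainable
# threshold (sharp matrices reach 1e-6; soft ones only the looser tails)
pwm_score_thresholds <- function(lw, bg, targets = c(1e-6, 1e-5, 1e-4, 1e-3),
                                 step = 0.05) {
  w <- ncol(lw)
  dist <- c(`0` = 1)
  for (k in seq_len(w)) {
    sc <- round(lw[, k] / step)
    new_scores <- outer(as.numeric(names(dist)), sc, "+")
    new_probs <- outer(unname(dist), bg, "*")
    agg <- tapply(as.vector(new_probs), as.vector(new_scores), sum)
    dist <- agg
  }
  s <- as.numeric(names(dist)) * step
  ord <- order(s, decreasing = TRUE)
  tail_p <- cumsum(dist[ord])
  rows <- lapply(targets, function(tg) {
    ok <- which(tail_p <= tg)
    i <- if (length(ok) > 0) max(ok) else 1L
    c(threshold = s[ord][i], p0 = unname(tail_p[i]))
  })
  out <- unique(do.call(rbind, rows))
  as.data.frame(out)
}

#' Discover over-represented motifs in promoter sequences
#'
#' A simplified any-number-of-repetitions EM finder. For each width in
#' `width_range`, candidate position weight matrices are seeded from the
#' most background-enriched w-mers of a training half of the sequences and
#' refined by EM against a 0-order background. Each candidate's significance
#' is a binomial test of its site count on the held-out half (site threshold
#' set where the exact background tail probability of the PWM score drops to
#' ~1e-4), Bonferroni-corrected for the number of width/seed candidates
#' tried. Motifs passing `p_threshold` are re-fitted on all sequences,
#' deduplicated by consensus, and returned sorted by significance.
#'
#' @param promoters Named character vector of equal-length sequences
#'   (>= 10).
#' @param width_range Integer pair; widths must lie in `[6, 15]` unless
#'   `enforce_width_range = FALSE`.
#' @param p_threshold Corrected significance threshold.
#' @param max_motifs Maximum motifs returned.
#' @param seed Integer seed (train/test split).
#' @param seeds_per_width Seed words tried per width.
#' @param em_iters EM iterations per candidate.
#' @param enforce_width_range Error on widths outside `[6, 15]`.
#' @return List of `motif_model`s (fields `pfm` count matrix, `consensus`,
#'   `width`, `p`, `n_sites`, `score_threshold`), sorted by p.
#' @export
discover_motifs <- function(promoters, width_range = c(6, 15),
                            p_threshold = 0.05, max_motifs = 10, seed = 1,
                            seeds_per_width = 6, em_iters = 10,
                            enforce_width_range = TRUE) {
  if (length(promoters) < 10L) stop("need at least 10 sequences")
  widths <- seq(width_range[1], width_range[2])
  if (enforce_width_range && (min(widths) < 6 || max(widths) > 15))
    stop("motif widths must lie in [6, 15]")
  set.seed(seed)
  enc <- encode_seqs(promoters)
  n <- nrow(enc)
  train_idx <- sort(sample.int(n, ceiling(n / 2)))
  test_idx <- setdiff(seq_len(n), train_idx)
  enc_tr <- enc[train_idx, , drop = FALSE]
  enc_te <- enc[test_idx, , drop = FALSE]
  bg <- as.numeric(table(factor(as.vector(enc), levels = 1:4)))
  bg <- (bg + 1) / sum(bg + 4)

  candidates <- list()
  for (w in widths) {
    for (wd in seed_words(promoters[train_idx], w, bg, seeds_per_width)) {
      candidates[[length(candidates) + 1L]] <- list(width = w, word = wd)
    }
  }
  n_trials <- length(candidates)
  ctx_tr <- list(); ctx_te <- list(); ctx_all <- list()
  out <- list()
  for (cand in candidates) {
    wkey <- as.character(cand$width)
    if (is.null(ctx_tr[[wkey]])) {
      ctx_tr[[wkey]] <- scan_context(enc_tr, cand$width)
      ctx_te[[wkey]] <- scan_context(enc_te, cand$width)
    }
    fit <- em_refine(ctx_tr[[wkey]], pwm_from_word(cand$word), bg,
                     n_iter = em_iters)
    lw <- log(fit$pwm) - matrix(log(bg), 4, cand$width)
    # site counting uses the same discretized score scale as the exact
    # background tail, so threshold and scan agree to the last site; the
    # count is tested at every attainable tail level (Bonferroni over
    # levels) because soft matrices only reach the looser tails
    step <- 0.05
    lw <- round(lw / step) * step
    thr <- pwm_score_thresholds(lw, bg, step = step)
    sc_te <- scan_scores(ctx_te[[wkey]], lw)
    p_levels <- vapply(seq_len(nrow(thr)), function(i) {
      n_obs <- sum(sc_te >= thr$threshold[i] - 1e-9)
      stats::pbinom(n_obs - 1L, length(sc_te), thr$p0[i], lower.tail = FALSE)
    }, 0)
    best_lvl <- which.min(p_levels)
    p <- min(1, p_levels[best_lvl] * nrow(thr) * n_trials)
    if (p > p_threshold) next
    thr <- list(threshold = thr$threshold[best_lvl], p0 = thr$p0[best_lvl])
    # refit site counts on all sequences for the reported PFM
    if (is.null(ctx_all[[wkey]])) ctx_all[[wkey]] <- scan_context(enc, cand$width)
    ctx <- ctx_all[[wkey]]
    sc_all <- scan_scores(ctx, lw)
    hit_pos <- which(sc_all >= thr$threshold - 1e-9)
    counts <- matrix(0.25, 4, cand$width, dimnames = list(BASES, NULL))
    for (k in seq_len(cand$width)) {
      ck <- ctx$codes[[k]][hit_pos]
      for (b in 1:4) counts[b, k] <- counts[b, k] + sum(ck == b)
    }
    consensus <- paste(BASES[apply(counts, 2, which.max)], collapse = "")
    out[[length(out) + 1L]] <- structure(
      list(pfm = counts, consensus = consensus, width = cand$width,
           p = p, n_sites = length(hit_pos),
           score_threshold = thr$threshold, seed_word = cand$word),
      class = "motif_model")
  }
  out <- out[order(vapply(out, `[[`, 0, "p"))]
  # collapse shadows: a narrower motif contained in an already-kept one
  # (either strand) is the same discovery at another width
  contained <- function(a, b) {
    if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
    grepl(a, b, fixed = TRUE) || grepl(a, revcomp(b), fixed = TRUE)
  }
  seen <- character()
  keep <- logical(length(out))
  for (i in seq_along(out)) {
    cs <- out[[i]]$consensus
    if (!any(vapply(seen, contained, TRUE, a = cs))) {
      keep[i] <- TRUE
      seen <- c(seen, cs)
    }
  }
  utils::head(out[keep], max_motifs)
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif_model: %s (width %d%s)\n", x$consensus, x$width,
              if (!is.null(x$p)) sprintf(", p = %.3g", x$p) else ""))
  invisible(x)
}
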