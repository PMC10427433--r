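# Avogadro constant (1/mol)
N_AVOGADRO <- 6.02214076e23

#' Liquid-drop-model descriptors of a nanoparticle
#'
#' Treats the ENM as a spherical drop of tightly packed elementary
#' molecules whose cluster density equals the particle mass density:
#' \itemize{
#'   \item Wigner-Seitz radius `r_w = (3 M / (4 pi rho N_A))^(1/3)` (nm) —
#'     the minimum interaction radius between individual molecules;
#'   \item agglomerate count `n = (r0 / r_w)^3`;
#'   \item surface-element ratio `S = 4 n^(-1/3)`;
#'   \item surface-volume ratio `SV = S / (1 - S)` (undefined, flagged NA,
#'     when `S >= 1`);
#'   \item size-dependent interfacial thickness
#'     `h = 0.01 (T - 273) r^0.35` (nm; negative below 273 K, allowed but
#'     flagged).
#' }
#'
#' @param M Molecular weight (g/mol).
#' @param rho Mass density (g/cm^3).
#' @param r0 Nominal particle radius (nm).
#' @param T Temperature (K).
#' @param r Nominal size used by the interfacial-thickness relation (nm);
#'   defaults to `r0`.
#' @return List: `r_w`, `n`, `S`, `SV`, `h`, `flags` (character vector,
#'   possibly empty).
#' @export
liquid_drop_descriptors <- function(M, rho, r0, T = 298, r = r0) {
  stopifnot(M > 0, rho > 0, r0 > 0, T > 0, r > 0)
  # g/mol over g/cm^3 gives cm^3/mol; 1 cm^3 = 1e21 nm^3
  r_w <- (3 * M * 1e21 / (4 * pi * rho * N_AVOGADRO))^(1 / 3)
  n <- (r0 / r_w)^3
  S <- 4 * n^(-1 / 3)
  flags <- character()
  SV <- if (S >= 1) {
    flags <- c(flags, "SV_undefined_S_ge_1")
    NA_real_
  } else S / (1 - S)
  h <- 0.01 * (T - 273) * r^0.35
  if (h < 0) flags <- c(flags, "negative_h_below_273K")
  list(r_w = r_w, n = n, S = S, SV = SV, h = h, flags = flags)
}

#' Per-atom coordination numbers of an atomistic structure
#'
#' Counts, for each atom, the neighbouring atoms lying within the cutoff
#' `R = scale * (r_i + r_j)`, the scaled sum of the two atoms' ionic radii
#' (the standard bonding-cutoff convention for a metal-oxygen pair).
#'
#' @param structure data.frame with columns species, x, y, z.
#' @param radii Named numeric vector of ionic radii per species (same length
#'   unit as the coordinates).
#' @param scale Cutoff scale factor.
#' @return Integer vector of neighbour counts (self excluded).
#' @export
coordination_numbers <- function(structure, radii, scale = 1.2) {
  sp <- structure$species
  if (!all(sp %in% names(radii))) {
    stop("unknown species: ",
         paste(setdiff(unique(sp), names(radii)), collapse = ", "))
  }
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (n == 1L) return(0L)
  d <- as.matrix(stats::dist(xyz))
  rsum <- outer(radii[sp], radii[sp], "+")
  counts <- integer(n)
  for (i in seq_len(n)) {
    counts[i] <- sum(d[i, -i] <= scale * rsum[i, -i])
  }
  counts
}

#' Surface-normal force component per atom
#'
#' The projection of each atom's force vector onto its position vector from
#' the centre of mass: `V = (x fx + y fy + z fz) / d`, with
#' `d = sqrt(x^2 + y^2 + z^2)`. Coordinates are taken relative to the
#' centre of mass (i.e. the origin); atoms at the centre (`d = 0`) raise an
#' error.
#'
#' @param structure data.frame with columns x, y, z, fx, fy, fz.
#' @return Numeric vector `V`.
#' @export
surface_normal_force <- function(structure) {
  d <- sqrt(structure$x^2 + structure$y^2 + structure$z^2)
  if (any(d == 0)) stop("atom at the centre of mass (d = 0)")
  (structure$x * structure$fx + structure$y * structure$fy +
     structure$z * structure$fz) / d
}

#' Winsorized, cube-root-transformed descriptor-gene correlations
#'
#' Per gene, log2 fold changes are winsorized at the stated quantiles (the
#' fold-change layer carries occasional extreme values); descriptor values
#' get a signed cube root. Pearson correlation is then computed per
#' (gene, descriptor) pair on pairwise-complete cases, reported missing when
#' fewer than `min_pairs` complete pairs or either vector is constant.
#'
#' @param logfc_matrix Gene x ENM matrix of log2 fold changes.
#' @param descriptor_table ENM x descriptor matrix (NAs allowed); rows must
#'   align with the columns of `logfc_matrix`.
#' @param winsor_q Winsorization quantile pair.
#' @param min_pairs Minimum complete pairs.
#' @return Gene x descriptor correlation matrix (NAs where undefined).
#' @export
winsorized_cube_correlation <- function(logfc_matrix, descriptor_table,
                                        winsor_q = c(0.05, 0.95),
                                        min_pairs = 3) {
  stopifnot(ncol(logfc_matrix) == nrow(descriptor_table))
  lf <- t(apply(logfc_matrix, 1, winsorize, probs = winsor_q))
  dimnames(lf) <- dimnames(logfc_matrix)
  dt <- cube_root(descriptor_table)
  out <- matrix(NA_real_, nrow(lf), ncol(dt),
                dimnames = list(rownames(lf), colnames(dt)))
  for (j in seq_len(ncol(dt))) {
    v <- dt[, j]
    ok <- !is.na(v)
    if (sum(ok) < min_pairs) next
    if (stats::sd(v[ok]) == 0) next
    sub <- lf[, ok, drop = FALSE]
    r <- suppressWarnings(as.numeric(
      stats::cor(t(sub), v[ok], use = "pairwise.complete.obs")))
    pairs <- rowSums(!is.na(sub))
    r[pairs < min_pairs] <- NA_real_
    r[apply(sub, 1, function(x) stats::sd(x, na.rm = TRUE)) == 0] <- NA_real_
    out[, j] <- r
  }
  out
}

#' Descriptor-signature enrichment on the consensus rank
#'
#' For each descriptor, the top `top_frac` genes by absolute correlation
#' form a gene set that is tested by pre-ranked GSEA against the consensus
#' rank; p-values are BH-adjusted across descriptors and descriptors passing
#' `alpha` are flagged as linked to the exposure signature.
#'
#' @param correlations Gene x descriptor correlation matrix
#'   (from [winsorized_cube_correlation()]).
#' @param consensus_rank A `consensus_rank` or ranked gene-id vector.
#' @param top_frac Fraction of most-correlated genes per descriptor.
#' @param n_perm,seed Passed to the permutation null.
#' @param alpha Adjusted-p selection threshold.
#' @return data.frame: descriptor, set_size, ES, p, adj_p, selected.
#' @export
descriptor_gsea <- function(correlations, consensus_rank, top_frac = 0.10,
                            n_perm = 1000, seed = 1, alpha = 0.01) {
  order <- if (inherits(consensus_rank, "consensus_rank"))
    consensus_rank$order else consensus_rank
  scores <- stats::setNames(rev(seq_along(order)), order)
  k <- max(1L, round(top_frac * length(order)))
  sets <- list()
  for (d in colnames(correlations)) {
    r <- abs(correlations[, d])
    r <- r[!is.na(r) & names(r) %in% order]
    if (length(r) == 0L) next
    sets[[d]] <- names(sort(r, decreasing = TRUE))[seq_len(min(k, length(r)))]
  }
  res <- preranked_gsea(scores, sets, n_perm = n_perm, seed = seed,
                        min_size = 1, max_size = length(order) - 1L)
  data.frame(descriptor = res$set, set_size = res$size, ES = res$ES,
             p = res$p, adj_p = res$adj_p, selected = res$adj_p < alpha,
             stringsAsFactors = FALSE)
}
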