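#' Reverse complement of a DNA string
#' @param x Character vector of sequences over ACGT (case preserved).
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, "", fixed = TRUE), function(v)
    paste(rev(v), collapse = ""), "", USE.NAMES = FALSE)
}

#' Read TSS records from a BED6 file
#'
#' BED is 0-based half-open; the TSS is taken as `start` for plus-strand
#' records and `end - 1` for minus-strand records.
#'
#' @param path BED6 file path.
#' @return data.frame: gene_id, contig, tss (0-based), strand.
#' @export
read_tss_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  names(bed)[1:6] <- c("contig", "start", "end", "gene_id", "score", "strand")
  data.frame(gene_id = bed$gene_id, contig = bed$contig,
             tss = ifelse(bed$strand == "+", bed$start, bed$end - 1L),
             strand = bed$strand, stringsAsFactors = FALSE)
}

#' Extract promoter windows around TSSs
#'
#' Windows are `[TSS - upstream, TSS + downstream)` in 0-based half-open
#' coordinates on the plus strand; for minus-strand genes the mirrored
#' window `[TSS - downstream + 1, TSS + upstream + 1)` is taken and
#' reverse-complemented, so every promoter reads 5' to 3' on the gene's own
#' strand and has length `upstream + downstream` exactly. Windows running
#' off a contig raise an error naming the gene (no padding).
#'
#' @param genome Named character vector of contig sequences, a
#'   `Biostrings::DNAStringSet`, or a FASTA path.
#' @param tss_records data.frame as returned by [read_tss_bed()].
#' @param upstream,downstream Window extents (bp).
#' @return Named character vector of promoter sequences.
#' @export
extract_promoters <- function(genome, tss_records, upstream = 500,
                              downstream = 100) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (!inherits(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  out <- character(nrow(tss_records))
  names(out) <- tss_records$gene_id
  for (i in seq_len(nrow(tss_records))) {
    r <- tss_records[i, ]
    contig <- genome[[r$contig]]
    L <- length(contig)
    if (r$strand == "+") {
      from0 <- r$tss - upstream; to0 <- r$tss + downstream  # half-open
    } else {
      from0 <- r$tss - downstream + 1L; to0 <- r$tss + upstream + 1L
    }
    if (from0 < 0 || to0 > L)
      stop("promoter window off contig for gene ", r$gene_id)
    s <- as.character(Biostrings::subseq(contig, start = from0 + 1L,
                                         end = to0))
    out[i] <- if (r$strand == "+") s else revcomp(s)
  }
  out
}

# --- PFM similarity and family testing ---------------------------------------

normalize_pfm <- function(pfm) sweep(pfm, 2, colSums(pfm), "/")

pfm_revcomp <- function(pfm) {
  m <- pfm[c("T", "G", "C", "A"), rev(seq_len(ncol(pfm))), drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  m
}

# mean column-wise Pearson correlation at one alignment offset
pfm_offset_cor <- function(a, b, offset, min_overlap) {
  ja <- seq_len(ncol(a))
  jb <- ja + offset
  keep <- jb >= 1 & jb <= ncol(b)
  if (sum(keep) < min_overlap) return(-Inf)
  cors <- vapply(which(keep), function(j) {
    va <- a[, j]; vb <- b[, j + offset]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(0)
    stats::cor(va, vb)
  }, 0)
  mean(cors)
}

#' Match a discovered motif against a PWM library
#'
#' Similarity between two profiles is the maximum, over alignment offsets
#' (minimum overlapping columns `min_overlap`) and both strands, of the mean
#' column-wise Pearson correlation of the normalized matrices. Returns the
#' best-scoring library profile when it reaches `min_similarity`.
#'
#' @param motif A `motif_model` (or any list with a 4 x w `pfm`).
#' @param library A `pwm_library`.
#' @param min_similarity Acceptance threshold.
#' @param min_overlap Minimum aligned columns.
#' @return List: `profile_id` (NA when no match), `name`, `family`,
#'   `similarity`, `strand` ("+" or "-").
#' @export
match_motif_to_library <- function(motif, library, min_similarity = 0.8,
                                   min_overlap = 6) {
  if (length(library) == 0L) stop("empty PWM library")
  q <- normalize_pfm(motif$pfm)
  if (ncol(q) == 0L) stop("motif width 0")
  best <- list(profile_id = NA_character_, name = NA_character_,
               family = NA_character_, similarity = -Inf, strand = "+")
  for (id in names(library)) {
    t_fwd <- normalize_pfm(library[[id]]$pfm)
    for (strand in c("+", "-")) {
      t <- if (strand == "+") t_fwd else pfm_revcomp(t_fwd)
      ov <- min(min_overlap, ncol(q), ncol(t))
      for (off in seq(-(ncol(q) - ov), ncol(t) - ov)) {
        s <- pfm_offset_cor(q, t, off, ov)
        if (s > best$similarity) {
          best <- list(profile_id = id, name = library[[id]]$name,
                       family = library[[id]]$family, similarity = s,
                       strand = strand)
        }
      }
    }
  }
  if (best$similarity < min_similarity) {
    return(list(profile_id = NA_character_, name = NA_character_,
                family = NA_character_, similarity = best$similarity,
                strand = best$strand))
  }
  best
}

#' Overrepresentation of a TF family among matched profiles
#'
#' One-sided Fisher exact test of the 2 x 2 table (matched vs unmatched
#' library profiles x family vs other). An empty matched set returns
#' OR = 0, p = 1 rather than raising.
#'
#' @param matched_profiles Character vector of matched library profile ids
#'   (unique; subset of the library).
#' @param library A `pwm_library` with a `family` label per profile.
#' @param family Family label tested (default the Cys2-His2 zinc-finger
#'   class).
#' @return List: `odds_ratio`, `p`, `table` (2 x 2 counts).
#' @export
family_overrepresentation <- function(matched_profiles, library,
                                      family = "C2H2-ZNF") {
  matched_profiles <- unique(matched_profiles)
  stopifnot(all(matched_profiles %in% names(library)))
  fams <- vapply(library, function(e) identical(e$family, family), TRUE)
  m <- names(library) %in% matched_profiles
  tab <- matrix(c(sum(m & fams), sum(m & !fams),
                  sum(!m & fams), sum(!m & !fams)), 2, 2,
                dimnames = list(c("family", "other"),
                                c("matched", "unmatched")))
  if (length(matched_profiles) == 0L)
    return(list(odds_ratio = 0, p = 1, table = tab))
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab)
}

#' Positional density of target genes along a ranking
#'
#' Sliding-window fraction of target genes along the gene order, plus a
#' one-sided Kolmogorov-Smirnov test that target positions are shifted
#' toward the top of the ranking.
#'
#' @param gene_order Character vector (best gene first).
#' @param target_set Non-empty strict subset of the order.
#' @param window Sliding-window width (genes).
#' @return List: `density` (data.frame position/density), `ks_p`.
#' @export
target_position_density <- function(gene_order, target_set, window = 100) {
  target_set <- unique(target_set)
  if (length(target_set) == 0L) stop("empty target set")
  if (!all(target_set %in% gene_order)) stop("targets outside the universe")
  N <- length(gene_order)
  if (length(target_set) == N)
    stop("target set equals the universe; positional test degenerate")
  is_t <- as.numeric(gene_order %in% target_set)
  cs <- cumsum(is_t)
  window <- min(window, N)
  pos <- seq_len(N - window + 1L)
  dens <- (cs[pos + window - 1L] - c(0, cs)[pos]) / window
  u <- which(is_t == 1) / N  # normalized positions in (0, 1]
  ks <- suppressWarnings(stats::ks.test(u, "punif",
                                        alternative = "greater"))
  list(density = data.frame(position = pos, density = dens),
       ks_p = ks$p.value)
}
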