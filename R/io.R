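#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids. The description field is kept as an optional category label.
#'
#' @param path File path.
#' @return Named list of character vectors with attribute `category`
#'   (named character vector of the description column).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  attr(sets, "category") <- stats::setNames(vapply(parts, `[`, "", 2L), names(sets))
  sets
}

#' Write a gene-set collection to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param category Optional character vector of descriptions (recycled "NA").
#' @export
write_gmt <- function(sets, path, category = NULL) {
  if (is.null(category)) category <- attr(sets, "category") %||% rep("NA", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], category[[i]], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a PWM library in JASPAR PFM text format
#'
#' Accepts the JASPAR 2016-style flat format: a `>ID NAME` header followed by
#' four lines `A [ counts ]` ... `T [ counts ]` (brackets optional). TF-family
#' labels are supplied separately (tab-separated `id<TAB>family` file) or read
#' from a third header token when present.
#'
#' @param path PFM file path.
#' @param family_path Optional TSV path mapping profile id to family label.
#' @return A `pwm_library`: named list of elements with `pfm` (4 x width
#'   matrix, rows ACGT), `name`, `family`.
#' @export
read_pwm_library <- function(path, family_path = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  idx <- grep("^>", lines)
  stopifnot(length(idx) > 0L)
  fam_map <- NULL
  if (!is.null(family_path)) {
    ft <- utils::read.table(family_path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    fam_map <- stats::setNames(ft[[2]], ft[[1]])
  }
  lib <- vector("list", length(idx))
  ids <- character(length(idx))
  for (k in seq_along(idx)) {
    hdr <- strsplit(sub("^>\\s*", "", lines[idx[k]]), "\\s+")[[1]]
    id <- hdr[1]
    nm <- if (length(hdr) >= 2) hdr[2] else id
    fam <- if (length(hdr) >= 3) hdr[3] else NA_character_
    rows <- lines[(idx[k] + 1):(idx[k] + 4)]
    mat <- t(vapply(rows, function(r) {
      r <- gsub("^[ACGTacgt]\\s*", "", r)
      r <- gsub("[\\[\\]]", " ", r, perl = TRUE)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }, numeric(length(strsplit(trimws(gsub("[\\[\\]]", " ",
      gsub("^[ACGTacgt]\\s*", "", rows[1]), perl = TRUE)), "\\s+")[[1]]))))
    rownames(mat) <- c("A", "C", "G", "T")
    if (!is.null(fam_map) && id %in% names(fam_map)) fam <- fam_map[[id]]
    lib[[k]] <- list(pfm = mat, name = nm, family = fam)
    ids[k] <- id
  }
  names(lib) <- ids
  structure(lib, class = "pwm_library")
}

#' Write a PWM library in JASPAR PFM text format
#' @param library A `pwm_library` (see [read_pwm_library()]).
#' @param path Output path.
#' @export
write_pwm_library <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(library)) {
    e <- library[[id]]
    writeLines(sprintf(">%s %s %s", id, e$name, e$family), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(e$pfm[b, ], trim = TRUE), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read an atomistic structure from an extended XYZ file
#'
#' Plain XYZ (count line, comment line, then `species x y z` rows) with an
#' extended dialect carrying three extra force columns `fx fy fz` in the same
#' units as the coordinates. Coordinates are taken relative to the structure's
#' origin (assumed to be the centre of mass).
#'
#' @param path File path.
#' @return data.frame with columns species, x, y, z and (when present)
#'   fx, fy, fz.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  ncol <- length(rows[[1]])
  out <- data.frame(
    species = vapply(rows, `[`, "", 1L),
    x = as.numeric(vapply(rows, `[`, "", 2L)),
    y = as.numeric(vapply(rows, `[`, "", 3L)),
    z = as.numeric(vapply(rows, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  if (ncol >= 7) {
    out$fx <- as.numeric(vapply(rows, `[`, "", 5L))
    out$fy <- as.numeric(vapply(rows, `[`, "", 6L))
    out$fz <- as.numeric(vapply(rows, `[`, "", 7L))
  }
  out
}

# write a TSV with an optional "# key: value" header comment block
write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
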