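# Readers and writers for the plain-text formats used by the pipeline:
# pooled allele-count TSVs (1-based positions), site-classification TSVs,
# window BED files (0-based half-open), chromosome-size and recruitment
# tables, and JSON reports. All readers accept '#'-prefixed comment lines
# and both LF and CRLF line endings.

POOLED_COUNT_COLS <- c("CHROM", "POS", "REF",
                       paste0(c("A", "C", "G", "T"), "_m"),
                       paste0(c("A", "C", "G", "T"), "_f"))

.read_lines_clean <- function(path) {
  ln <- readLines(path, warn = FALSE)
  sub("\r$", "", ln)
}

#' Read a pooled allele-count table
#'
#' Parses the pooled-counts TSV dialect: one row per site with columns
#' `CHROM`, `POS` (1-based), `REF`, and per-nucleotide read counts
#' `A_m,C_m,G_m,T_m` for the male pool and `A_f,...,T_f` for the female
#' pool. A header line is required; `#` comment lines are ignored.
#' Malformed rows (wrong column count, non-integer or negative counts)
#' raise an error naming the offending file line. Positions out of order
#' within a chromosome only produce a warning.
#'
#' @param path path to a TSV file.
#' @return `data.frame` with the eleven dialect columns.
#' @seealso [write_pooled_counts()], [classify_sites()]
#' @export
read_pooled_counts <- function(path) {
  ln <- .read_lines_clean(path)
  keep <- which(!grepl("^#", ln) & nzchar(ln))
  if (!length(keep)) stop("no content in ", path)
  header <- strsplit(ln[keep[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(header, POOLED_COUNT_COLS))
    stop("header does not match the pooled-counts dialect: ",
         paste(header, collapse = ","))
  rows <- keep[-1]
  if (!length(rows))
    return(stats::setNames(
      data.frame(character(), integer(), character(),
                 integer(), integer(), integer(), integer(),
                 integer(), integer(), integer(), integer()),
      POOLED_COUNT_COLS))
  parts <- strsplit(ln[rows], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != length(POOLED_COUNT_COLS))
  if (length(bad))
    stop("line ", rows[bad[1]], ": expected ",
         length(POOLED_COUNT_COLS), " columns, found ",
         lengths(parts)[bad[1]])
  m <- do.call(rbind, parts)
  out <- data.frame(CHROM = m[, 1], POS = NA_integer_, REF = m[, 3],
                    stringsAsFactors = FALSE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos) || any(pos < 1))
    stop("line ", rows[which(is.na(pos) | pos < 1)[1]],
         ": POS must be a positive integer")
  out$POS <- pos
  for (j in 4:11) {
    v <- suppressWarnings(as.numeric(m[, j]))
    badv <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(badv))
      stop("line ", rows[badv[1]], ": column ", POOLED_COUNT_COLS[j],
           " must be a non-negative integer (got '", m[badv[1], j], "')")
    out[[POOLED_COUNT_COLS[j]]] <- as.integer(v)
  }
  unsorted <- unlist(tapply(out$POS, out$CHROM, function(p) any(diff(p) < 0)))
  if (any(unsorted))
    warning("positions not sorted within chromosome(s): ",
            paste(names(unsorted)[unsorted], collapse = ", "))
  out
}

#' Write a pooled allele-count table
#'
#' @param x data.frame in the pooled-counts dialect (see
#'   [read_pooled_counts()]).
#' @param path output path.
#' @param comment optional character vector written as `#` header lines
#'   (provenance: producing command, configuration hash, ...).
#' @return `path`, invisibly.
#' @export
write_pooled_counts <- function(x, path, comment = NULL) {
  stopifnot(all(POOLED_COUNT_COLS %in% names(x)))
  .write_tsv(x[POOLED_COUNT_COLS], path, comment)
}

.write_tsv <- function(x, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write site classifications
#'
#' One row per evaluated allele: `CHROM, POS, ALLELE, FREQ_M, FREQ_F, FST,
#' LABEL` with `LABEL` in `XY`/`ZW`/`none`.
#'
#' @inheritParams write_pooled_counts
#' @export
write_site_classifications <- function(x, path, comment = NULL) {
  cols <- c("CHROM", "POS", "ALLELE", "FREQ_M", "FREQ_F", "FST", "LABEL")
  stopifnot(all(cols %in% names(x)))
  .write_tsv(x[cols], path, comment)
}

#' Read a chromosome-size table
#'
#' TSV with columns `chrom`, `length` and an optional logical `anchored`
#' column (defaults to `TRUE`); unanchored sequences are tiled into windows
#' but excluded from the top-percent denominator.
#'
#' @param path path to a TSV file.
#' @return `data.frame` with columns `chrom`, `length`, `anchored`.
#' @export
read_chrom_sizes <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "length") %in% names(x)))
  if (!"anchored" %in% names(x)) x$anchored <- TRUE
  x$anchored <- as.logical(x$anchored)
  if (any(x$length <= 0)) stop("chromosome lengths must be positive")
  x[c("chrom", "length", "anchored")]
}

#' Read a recruitment table
#'
#' TSV with columns `chrom` and `count`: how many times each chromosome has
#' been independently recruited as a sex chromosome.
#'
#' @param path path to a TSV file.
#' @return `data.frame` with columns `chrom`, `count`.
#' @export
read_recruitment_table <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "count") %in% names(x)))
  if (any(x$count < 0) || any(x$count != floor(x$count)))
    stop("recruitment counts must be non-negative integers")
  x$count <- as.integer(x$count)
  x[c("chrom", "count")]
}

#' Write window statistics as BED
#'
#' Columns: `chrom`, `start` (0-based), `end` (exclusive), `n_xy`, `n_zw`,
#' `log2_ratio` and, when present, the `top1` flag. Coordinates follow the
#' BED standard, unlike the 1-based site TSVs.
#'
#' @inheritParams write_pooled_counts
#' @export
write_windows_bed <- function(x, path, comment = NULL) {
  cols <- c("chrom", "start", "end", "n_xy", "n_zw", "log2_ratio")
  if ("top1" %in% names(x)) cols <- c(cols, "top1")
  stopifnot(all(cols %in% names(x)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(x[cols], con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a JSON report
#'
#' Serialises a (possibly nested) list of results with scalars unboxed and
#' full numeric precision, the form consumed by downstream tooling.
#'
#' @param x list of results.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# --- bundled fixtures ------------------------------------------------------

.extdata <- function(file)
  system.file("extdata", file, package = "poolsex", mustWork = TRUE)

#' Published recruitment counts for East African cichlids
#'
#' The bundled tally of independent sex chromosome origins per linkage
#' group (LG1-LG23 without LG21, plus the unpaired B chromosome): 51
#' events over 23 categories, with maxima of 7 on LG5 and 6 on LG7.
#'
#' @return `data.frame` with columns `chrom`, `count`.
#' @export
cichlid_recruitments <- function()
  read_recruitment_table(.extdata("recruitment_table1.tsv"))

#' Synthetic cichlid chromosome-size table
#'
#' A synthetic approximation of the cichlid reference karyotype: 22
#' anchored linkage groups totalling 780 Mb (7,800 windows of 100 kb) with
#' LG7 about twice the mean size of the rest, plus an unanchored B
#' chromosome carrying the mean size. Intended for the size-weighted Monte
#' Carlo null and for tests; supply real assembly lengths via
#' [read_chrom_sizes()] for real data.
#'
#' @return `data.frame` with columns `chrom`, `length`, `anchored`.
#' @export
cichlid_chrom_sizes <- function()
  read_chrom_sizes(.extdata("chrom_sizes_synthetic.tsv"))

#' Synthetic basal-haplochromine time tree
#'
#' A synthetic nine-tip phylogeny (seven *Pseudocrenilabrus* populations
#' plus *Lufubuchromis* and *Thoracochromis*) with branch lengths in
#' million years, calibrated so the whole tree sums to 26 MY and the
#' *Pseudocrenilabrus* subtree to 10 MY. Used as input for turnover-rate
#' estimation; it is not an estimated phylogeny.
#'
#' @return an [ape] `phylo` object.
#' @export
basal_haplochromine_tree <- function()
  ape::read.tree(.extdata("basal_haplochromine_tree_synthetic.nwk"))
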