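# Sex-specific k-mer analysis: canonical k-mer tabulation at desk scale,
# sex-specific k-mer lists per pool, cross-population intersection, and
# exact-match placement on a reference. Everything is strand-agnostic
# through canonicalisation (lexicographic min of a k-mer and its reverse
# complement).

.as_seq_chr <- function(x) {
  if (inherits(x, "DNAStringSet") || inherits(x, "XStringSet"))
    x <- as.character(x)
  nm <- names(x)
  stats::setNames(toupper(as.character(x)), nm)
}

.revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonicalise k-mers
#'
#' Returns, for each k-mer, the lexicographically smaller of itself and
#' its reverse complement. Idempotent; k-mer counts built on canonical
#' k-mers are identical for a sequence and its reverse complement.
#'
#' @param x character vector of k-mers over A/C/G/T.
#' @return character vector of the same length.
#' @export
canonical_kmers <- function(x) {
  rc <- .revcomp(x)
  swap <- rc < x
  x[swap] <- rc[swap]
  x
}

#' Count canonical k-mers in a sequence set
#'
#' Tabulates every k-long window of every sequence, canonicalised.
#' Windows containing a non-ACGT character (e.g. `N`) are skipped;
#' sequences shorter than `k` contribute nothing (with a message). This
#' is a plain in-memory tabulation intended for simulated pools and small
#' references, not for full sequencing runs.
#'
#' @param seqs character vector or `DNAStringSet`.
#' @param k k-mer length (default 22).
#' @return named integer vector of counts, names sorted; total count
#'   equals the number of valid k-mer windows.
#' @export
count_kmers <- function(seqs, k = 22) {
  stopifnot(k >= 1)
  seqs <- .as_seq_chr(seqs)
  acc <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    len <- nchar(seqs[i])
    if (len < k) {
      message("sequence ", i, " shorter than k = ", k, "; skipped")
      next
    }
    km <- substring(seqs[i], 1:(len - k + 1), k:len)
    acc[[i]] <- km[!grepl("[^ACGT]", km)]
  }
  km <- unlist(acc)
  if (!length(km))
    return(stats::setNames(integer(0), character(0)))
  tab <- table(canonical_kmers(km))
  stats::setNames(as.integer(tab), names(tab))
}

#' Sex-specific k-mers
#'
#' k-mers seen at least `min_count` times in the focal-sex pool and never
#' in the other pool. The default `min_count = 2` guards against
#' sequencing-error k-mers, which are overwhelmingly singletons.
#'
#' @param focal,other k-mer count tables from [count_kmers()] built with
#'   the same `k` (focal = the heterogametic sex's pool for Y/W-specific
#'   k-mers).
#' @param min_count minimum count in the focal pool (default 2).
#' @return sorted character vector of k-mers.
#' @export
sex_specific_kmers <- function(focal, other, min_count = 2) {
  cand <- names(focal)[focal >= min_count]
  sort(setdiff(cand, names(other)))
}

#' Intersection of two k-mer sets
#'
#' Exact, symmetric intersection; used across populations to test for a
#' shared origin of syntenic sex systems (a shared sex-limited haplotype
#' leaves thousands of identical sex-specific k-mers, independent origins
#' next to none).
#'
#' @param a,b k-mer sets (character vectors) or count tables (their names
#'   are used) built with the same `k`.
#' @return sorted character vector of shared k-mers.
#' @export
shared_kmers <- function(a, b) {
  if (!is.null(names(a))) a <- names(a)
  if (!is.null(names(b))) b <- names(b)
  sort(intersect(a, b))
}

#' Place k-mers on a reference by exact match
#'
#' Reports every locus at which a query k-mer matches the reference
#' exactly (match is canonical, hence strand-agnostic), per-chromosome
#' placement totals and the number of query k-mers with no locus.
#' `max_mismatch = 1` additionally matches all single-substitution
#' neighbours of each query (neighbour enumeration), a desk-scale stand-in
#' for short-read alignment of near-identical queries.
#'
#' @param kmers character vector of query k-mers (all the same length).
#' @param reference character vector or `DNAStringSet` of reference
#'   sequences; unnamed sequences are labelled `seq1`, `seq2`, ...
#' @param max_mismatch 0 (exact, default) or 1.
#' @return list with `placements` (data.frame `kmer`, `chrom`, `start`
#'   1-based, `end`), `chrom_counts` (named placement totals) and
#'   `n_unplaced`.
#' @export
place_kmers <- function(kmers, reference, max_mismatch = 0) {
  stopifnot(length(kmers) >= 1, max_mismatch %in% c(0, 1))
  k <- unique(nchar(kmers))
  if (length(k) != 1) stop("query k-mers must share one length")
  ref <- .as_seq_chr(reference)
  if (is.null(names(ref)))
    names(ref) <- paste0("seq", seq_along(ref))
  q <- unique(canonical_kmers(kmers))
  if (max_mismatch == 1) {
    qmap <- .mismatch_neighbours(q, k)
  } else {
    qmap <- stats::setNames(q, q)  # variant -> query
  }
  hits <- vector("list", length(ref))
  for (i in seq_along(ref)) {
    len <- nchar(ref[i])
    if (len < k) next
    km <- substring(ref[i], 1:(len - k + 1), k:len)
    valid <- !grepl("[^ACGT]", km)
    can <- canonical_kmers(km[valid])
    pos <- which(valid)
    m <- match(can, names(qmap))
    found <- !is.na(m)
    if (!any(found)) next
    hits[[i]] <- data.frame(kmer = unname(qmap[m[found]]),
                            chrom = names(ref)[i],
                            start = pos[found], end = pos[found] + k - 1,
                            stringsAsFactors = FALSE)
  }
  placements <- do.call(rbind, hits)
  if (is.null(placements))
    placements <- data.frame(kmer = character(), chrom = character(),
                             start = integer(), end = integer())
  chrom_counts <- table(factor(placements$chrom, levels = names(ref)))
  chrom_counts <- stats::setNames(as.integer(chrom_counts),
                                  names(ref))
  list(placements = placements, chrom_counts = chrom_counts,
       n_unplaced = length(q) - length(unique(placements$kmer)))
}

# All canonical single-substitution neighbours (plus the queries
# themselves), as a named vector: variant -> originating query.
.mismatch_neighbours <- function(q, k) {
  var <- q
  org <- q
  for (pos in seq_len(k)) {
    for (b in NUCS) {
      v <- q
      substr(v, pos, pos) <- b
      new <- v != q
      var <- c(var, v[new])
      org <- c(org, q[new])
    }
  }
  var <- canonical_kmers(var)
  first <- !duplicated(var)
  stats::setNames(org[first], var[first])
}
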