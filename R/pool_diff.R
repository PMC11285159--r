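# Per-site differentiation between the male and female DNA pools, and
# classification of sex-patterned SNPs. Frequencies are read-count
# frequencies (pool-seq), not genotype frequencies.

#' Per-allele pool frequencies at a single site
#'
#' For every nucleotide with a nonzero combined read count, returns its
#' frequency in the male pool and in the female pool (count / pool depth).
#' Frequencies within a pool sum to 1. A site with zero depth in either
#' pool yields a zero-row result with a message rather than an error, so
#' streaming callers can skip and log it.
#'
#' @param counts_male,counts_female length-4 non-negative integer vectors
#'   of read counts in A,C,G,T order.
#' @return `data.frame` with columns `allele`, `freq_male`, `freq_female`.
#' @examples
#' allele_frequencies(c(10, 0, 10, 0), c(20, 0, 0, 0))
#' @export
allele_frequencies <- function(counts_male, counts_female) {
  stopifnot(length(counts_male) == 4, length(counts_female) == 4,
            all(counts_male >= 0), all(counts_female >= 0))
  dm <- sum(counts_male)
  df <- sum(counts_female)
  if (dm == 0 || df == 0) {
    message("site skipped: zero read depth in ",
            if (dm == 0) "male" else "female", " pool")
    return(data.frame(allele = character(), freq_male = numeric(),
                      freq_female = numeric()))
  }
  keep <- (counts_male + counts_female) > 0
  data.frame(allele = NUCS[keep],
             freq_male = counts_male[keep] / dm,
             freq_female = counts_female[keep] / df,
             stringsAsFactors = FALSE)
}

#' Wright's FST between two pools from allele frequencies
#'
#' FST = (H_T - mean(H_S)) / H_T with H = 2p(1-p), the two pools weighted
#' equally; defined as 0 when the total heterozygosity H_T is 0. The
#' statistic is symmetric in its arguments, 0 for equal frequencies and 1
#' for a fixed difference. Vectorised.
#'
#' @param freq_a,freq_b allele frequencies in `[0, 1]`.
#' @return numeric vector of FST values in `[0, 1]`.
#' @examples
#' site_fst(0.5, 0.0)  # 1/3
#' @export
site_fst <- function(freq_a, freq_b) {
  stopifnot(all(freq_a >= 0 & freq_a <= 1),
            all(freq_b >= 0 & freq_b <= 1))
  p_bar <- (freq_a + freq_b) / 2
  h_t <- 2 * p_bar * (1 - p_bar)
  h_s <- freq_a * (1 - freq_a) + freq_b * (1 - freq_b)  # mean of 2p(1-p)
  fst <- ifelse(h_t > 0, (h_t - h_s) / h_t, 0)
  pmin(pmax(fst, 0), 1)
}

#' Classify an allele as XY-patterned, ZW-patterned or neither
#'
#' An allele is *XY-patterned* when it is effectively absent from the
#' female pool (frequency `< t_fix`) and at intermediate frequency in the
#' male pool (within `[t_lo, t_hi]`, closed interval): the signature of a
#' Y-limited haplotype carried by half the males. *ZW* is the mirror
#' pattern. Everything else is `none`. Vectorised.
#'
#' @param freq_male,freq_female allele frequencies in `[0, 1]`.
#' @param t_fix "fixed" threshold: the sex in which the allele is absent
#'   must have frequency strictly below this (default 0.1).
#' @param t_lo,t_hi closed polymorphism interval for the other sex
#'   (default `[0.3, 0.7]`).
#' @return character vector over `"XY"`, `"ZW"`, `"none"`.
#' @examples
#' classify_site(c(0.5, 0.05, 0.2), c(0.05, 0.5, 0.2))
#' @export
classify_site <- function(freq_male, freq_female,
                          t_fix = 0.1, t_lo = 0.3, t_hi = 0.7) {
  stopifnot(all(freq_male >= 0 & freq_male <= 1),
            all(freq_female >= 0 & freq_female <= 1))
  xy <- freq_female < t_fix & freq_male >= t_lo & freq_male <= t_hi
  zw <- freq_male < t_fix & freq_female >= t_lo & freq_female <= t_hi
  out <- rep("none", length(xy))
  out[xy] <- "XY"
  out[zw] <- "ZW"
  out
}

#' Classify all sites of a pooled-count table
#'
#' Applies the depth filter, evaluates every allele with a nonzero
#' combined count at each variable site, computes per-pool frequencies and
#' per-allele FST, and labels XY/ZW-patterned alleles. Each alternate
#' allele is evaluated independently, but a site contributes at most one
#' XY and one ZW record: if several alleles at one site match the same
#' pattern, only the highest-FST one keeps the label (ties broken by
#' allele order).
#'
#' Sites are skipped (and recorded in the `"skipped"` attribute with a
#' reason) when either pool is below `min_depth`, has zero depth, or the
#' site is not variable (fewer than two alleles with nonzero combined
#' count).
#'
#' @param counts data.frame in the pooled-counts dialect
#'   ([read_pooled_counts()]).
#' @param min_depth minimum read depth required in *each* pool (default 4;
#'   zero-depth sites are always skipped).
#' @inheritParams classify_site
#' @return `data.frame` with columns `CHROM, POS, ALLELE, FREQ_M, FREQ_F,
#'   FST, LABEL`, ordered by position; attribute `"skipped"` is a
#'   data.frame of excluded sites with reasons.
#' @export
classify_sites <- function(counts, min_depth = 4,
                           t_fix = 0.1, t_lo = 0.3, t_hi = 0.7) {
  mcols <- paste0(NUCS, "_m")
  fcols <- paste0(NUCS, "_f")
  stopifnot(all(c("CHROM", "POS", mcols, fcols) %in% names(counts)))
  mm <- as.matrix(counts[mcols])
  mf <- as.matrix(counts[fcols])
  if (any(mm < 0) || any(mf < 0)) stop("negative allele counts")
  dm <- rowSums(mm)
  dfp <- rowSums(mf)
  min_depth <- max(min_depth, 1)
  low <- dm < min_depth | dfp < min_depth
  variable <- rowSums((mm + mf) > 0) >= 2
  use <- which(!low & variable)

  skipped <- data.frame(
    CHROM = counts$CHROM[!(!low & variable)],
    POS = counts$POS[!(!low & variable)],
    reason = ifelse(pmin(dm, dfp)[!(!low & variable)] == 0, "zero_depth",
             ifelse(low[!(!low & variable)], "low_depth", "not_variable")),
    stringsAsFactors = FALSE)

  out <- do.call(rbind, lapply(seq_along(NUCS), function(j) {
    r <- use[(mm[use, j] + mf[use, j]) > 0]
    if (!length(r)) return(NULL)
    data.frame(CHROM = counts$CHROM[r], POS = counts$POS[r],
               ALLELE = NUCS[j],
               FREQ_M = mm[r, j] / dm[r], FREQ_F = mf[r, j] / dfp[r],
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(CHROM = character(), POS = integer(),
                      ALLELE = character(), FREQ_M = numeric(),
                      FREQ_F = numeric())
  out$FST <- site_fst(out$FREQ_M, out$FREQ_F)
  out$LABEL <- classify_site(out$FREQ_M, out$FREQ_F, t_fix, t_lo, t_hi)

  # at most one XY and one ZW record per site
  for (lab in c("XY", "ZW")) {
    i <- which(out$LABEL == lab)
    if (length(i) > 1) {
      o <- i[order(out$CHROM[i], out$POS[i], -out$FST[i], out$ALLELE[i])]
      dup <- duplicated(paste(out$CHROM[o], out$POS[o]))
      out$LABEL[o[dup]] <- "none"
    }
  }
  out <- out[order(out$CHROM, out$POS, out$ALLELE), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
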