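# Seeded generators for every input the pipeline consumes: pooled
# allele-count tables with plantable sex-determining regions (plus truth
# tables), pool sequence sets with a sex-limited haplotype for the k-mer
# module, and recruitment tables drawn from the size-weighted null.
# Counts are generated directly (two-stage binomial sampling of pool
# chromosomes, then reads); there is no read-mapping or coalescent model.

#' Describe a planted sex-determining region
#'
#' A sex system is a chromosome interval carrying sex-linked SNPs: on the
#' sex-limited haplotype (Y or W) the linked allele is fixed, so its
#' expected pool frequency is `0.5 * system_frequency` in the
#' heterogametic sex and 0 in the other. `strata` subdivides the region
#' into intervals of differing sex-linked SNP density, emulating
#' evolutionary strata; by default the whole region is one stratum at
#' 1 SNP/kb (100 per 100-kb window, mid-range for a moderately
#' differentiated system).
#'
#' @param chrom chromosome carrying the region.
#' @param start,end region bounds, 1-based inclusive bp.
#' @param heterogamety `"XY"` (male heterogametic) or `"ZW"`.
#' @param system_frequency fraction of the heterogametic sex governed by
#'   this system, in `(0, 1]`; below 1 emulates a sex system segregating
#'   at reduced frequency in the population.
#' @param strata optional `data.frame` with `start`, `end`, `density`
#'   (sex-linked SNPs per bp); intervals must lie inside the region and
#'   not overlap.
#' @return an object of class `sex_system_spec`.
#' @export
sex_system_spec <- function(chrom, start, end,
                            heterogamety = c("XY", "ZW"),
                            system_frequency = 1, strata = NULL) {
  heterogamety <- match.arg(heterogamety)
  stopifnot(start >= 1, end > start,
            system_frequency > 0, system_frequency <= 1)
  if (is.null(strata))
    strata <- data.frame(start = start, end = end, density = 0.001)
  stopifnot(all(c("start", "end", "density") %in% names(strata)))
  strata <- strata[order(strata$start), , drop = FALSE]
  if (any(strata$start < start) || any(strata$end > end))
    stop("strata must lie within the region")
  if (nrow(strata) > 1 &&
      any(strata$start[-1] <= strata$end[-nrow(strata)]))
    stop("strata must not overlap")
  structure(list(chrom = chrom, start = start, end = end,
                 heterogamety = heterogamety,
                 system_frequency = system_frequency, strata = strata),
            class = "sex_system_spec")
}

#' @export
print.sex_system_spec <- function(x, ...) {
  cat(sprintf("%s system on %s:%d-%d (frequency %.2f, %d stratum/a)\n",
              x$heterogamety, x$chrom, x$start, x$end,
              x$system_frequency, nrow(x$strata)))
  invisible(x)
}

# Move each read to a random other nucleotide with probability `rate`
# (uniform substitution error), column-wise on an n x 4 count matrix.
.scatter_errors <- function(mat, rate) {
  if (rate <= 0) return(mat)
  out <- mat
  for (j in 1:4) {
    e <- stats::rbinom(nrow(mat), mat[, j], rate)
    if (!any(e > 0)) next
    out[, j] <- out[, j] - e
    others <- setdiff(1:4, j)
    a <- stats::rbinom(length(e), e, 1 / 3)
    b <- stats::rbinom(length(e), e - a, 1 / 2)
    out[, others[1]] <- out[, others[1]] + a
    out[, others[2]] <- out[, others[2]] + b
    out[, others[3]] <- out[, others[3]] + (e - a - b)
  }
  out
}

#' Simulate a pooled allele-count table with planted sex systems
#'
#' Background SNPs get one population frequency per site (uniform on
#' `maf_range`), shared in expectation between the sexes; the realised
#' pool frequency of each sex is a binomial draw over its `2N` pooled
#' chromosomes. Sex-linked sites carry the linked allele on the
#' sex-limited haplotype, so the heterogametic pool frequency is
#' `n_governed / (2N)` with `n_governed ~ Bin(N, system_frequency)`
#' (expectation `0.5 * system_frequency`) and 0 in the other pool. Read
#' counts are binomial at Poisson-distributed depth, then uniform
#' substitution error at `error_rate` is applied. A truth table records
#' each site's class, so downstream sensitivity and specificity are
#' exactly computable.
#'
#' @param chrom_sizes data.frame (`chrom`, `length`) or named vector, bp.
#' @param sex_systems a [sex_system_spec()] or list of them (several on
#'   one chromosome are allowed, e.g. an XY and a ZW system); `NULL`
#'   plants nothing.
#' @param n_males,n_females individuals per pool (defaults 25/24, a
#'   typical full-sib family design).
#' @param depth mean reads per site per pool (Poisson; default 50).
#' @param error_rate per-base substitution error (default 0.002).
#' @param background_density background SNPs per bp (default 0.001).
#' @param maf_range range of background population allele frequencies
#'   (default `c(0.05, 0.95)`).
#' @param seed mandatory RNG seed.
#' @return list with `counts` (pooled-counts dialect) and `truth`
#'   (`CHROM, POS, CLASS, ALT, P_M, P_F` with `CLASS` in
#'   `background`/`XY`/`ZW` and `P_M`/`P_F` the realised pool
#'   frequencies of the ALT allele).
#' @export
simulate_pooled_counts <- function(chrom_sizes, sex_systems = NULL,
                                   n_males = 25, n_females = 24,
                                   depth = 50, error_rate = 0.002,
                                   background_density = 0.001,
                                   maf_range = c(0.05, 0.95), seed) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  set.seed(seed)
  cs <- .norm_chrom_sizes(chrom_sizes)
  stopifnot(n_males >= 1, n_females >= 1, depth > 0)
  if (inherits(sex_systems, "sex_system_spec"))
    sex_systems <- list(sex_systems)
  for (ss in sex_systems) {
    len <- cs$length[match(ss$chrom, cs$chrom)]
    if (is.na(len) || ss$end > len)
      stop("sex system region outside the genome: ", ss$chrom, ":",
           ss$start, "-", ss$end)
  }

  sites <- list()
  for (i in seq_len(nrow(cs))) {
    n <- stats::rpois(1, cs$length[i] * background_density)
    n <- min(n, cs$length[i])
    if (n > 0)
      sites[[length(sites) + 1]] <- data.frame(
        chrom = cs$chrom[i], pos = sample.int(cs$length[i], n),
        class = "background", sys = 0L, stringsAsFactors = FALSE)
  }
  for (s in seq_along(sex_systems)) {
    ss <- sex_systems[[s]]
    for (r in seq_len(nrow(ss$strata))) {
      len <- ss$strata$end[r] - ss$strata$start[r] + 1
      n <- min(stats::rpois(1, len * ss$strata$density[r]), len)
      if (n > 0)
        sites[[length(sites) + 1]] <- data.frame(
          chrom = ss$chrom,
          pos = ss$strata$start[r] + sample.int(len, n) - 1L,
          class = ss$heterogamety, sys = s, stringsAsFactors = FALSE)
    }
  }
  if (!length(sites)) stop("no sites generated; increase densities")
  all <- do.call(rbind, sites)
  # linked sites win position collisions
  all <- all[order(all$chrom, all$pos, all$class == "background"), ,
             drop = FALSE]
  all <- all[!duplicated(all[c("chrom", "pos")]), , drop = FALSE]
  n <- nrow(all)

  p_m <- numeric(n)
  p_f <- numeric(n)
  bg <- all$class == "background"
  if (any(bg)) {
    pop <- stats::runif(sum(bg), maf_range[1], maf_range[2])
    p_m[bg] <- stats::rbinom(sum(bg), 2 * n_males, pop) / (2 * n_males)
    p_f[bg] <- stats::rbinom(sum(bg), 2 * n_females, pop) / (2 * n_females)
  }
  for (s in seq_along(sex_systems)) {
    ss <- sex_systems[[s]]
    rows <- all$sys == s
    if (ss$heterogamety == "XY") {
      n_gov <- stats::rbinom(1, n_males, ss$system_frequency)
      p_m[rows] <- n_gov / (2 * n_males)
      p_f[rows] <- 0
    } else {
      n_gov <- stats::rbinom(1, n_females, ss$system_frequency)
      p_f[rows] <- n_gov / (2 * n_females)
      p_m[rows] <- 0
    }
  }

  d_m <- stats::rpois(n, depth)
  d_f <- stats::rpois(n, depth)
  alt_m <- stats::rbinom(n, d_m, p_m)
  alt_f <- stats::rbinom(n, d_f, p_f)
  ref_idx <- sample.int(4, n, replace = TRUE)
  alt_idx <- ((ref_idx - 1 + sample.int(3, n, replace = TRUE)) %% 4) + 1
  idx <- seq_len(n)
  cm <- matrix(0L, n, 4)
  cf <- matrix(0L, n, 4)
  cm[cbind(idx, ref_idx)] <- d_m - alt_m
  cm[cbind(idx, alt_idx)] <- alt_m
  cf[cbind(idx, ref_idx)] <- d_f - alt_f
  cf[cbind(idx, alt_idx)] <- alt_f
  cm <- .scatter_errors(cm, error_rate)
  cf <- .scatter_errors(cf, error_rate)

  counts <- data.frame(CHROM = all$chrom, POS = all$pos,
                       REF = NUCS[ref_idx], stringsAsFactors = FALSE)
  for (j in 1:4) counts[[paste0(NUCS[j], "_m")]] <- cm[, j]
  for (j in 1:4) counts[[paste0(NUCS[j], "_f")]] <- cf[, j]
  truth <- data.frame(CHROM = all$chrom, POS = all$pos,
                      CLASS = all$class, ALT = NUCS[alt_idx],
                      P_M = p_m, P_F = p_f, stringsAsFactors = FALSE)
  rownames(counts) <- rownames(truth) <- NULL
  list(counts = counts, truth = truth)
}

.rand_seq <- function(n)
  paste(sample(NUCS, n, replace = TRUE), collapse = "")

.mutate_seq <- function(s, rate) {
  if (rate <= 0 || !nchar(s)) return(s)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  i <- which(stats::runif(length(v)) < rate)
  if (!length(i)) return(s)
  v[i] <- vapply(v[i], function(b) sample(setdiff(NUCS, b), 1), "")
  paste(v, collapse = "")
}

.emit_reads <- function(seqs, read_length, coverage, error_rate) {
  out <- list()
  for (i in seq_along(seqs)) {
    len <- nchar(seqs[i])
    if (len == 0) next
    rl <- min(read_length, len)
    n_reads <- ceiling(coverage * len / rl)
    starts <- sample.int(len - rl + 1, n_reads, replace = TRUE)
    rd <- substring(seqs[i], starts, starts + rl - 1)
    if (error_rate > 0)
      rd <- vapply(rd, .mutate_seq, "", rate = error_rate,
                   USE.NAMES = FALSE)
    out[[i]] <- stats::setNames(
      rd, paste0(names(seqs)[i], "_read", seq_along(rd)))
  }
  unlist(out)
}

#' Simulate male/female pool sequence sets with a sex-limited haplotype
#'
#' Builds a random reference and two pool sequence sets in which the
#' heterogametic sex carries a sex-limited haplotype at half the
#' sex-chromosome dose. Two layouts are available:
#'
#' * `mode = "contig"`: the sex-limited sequence is a standalone contig
#'   of length `region_length` present only in the heterogametic pool
#'   (a hemizygous insertion whose flanks are not modelled). Its
#'   sex-specific k-mer count is analytically `region_length - k + 1`.
#' * `mode = "embedded"`: the reference (a heterogametic-sex assembly)
#'   contains the region at `region` on `sex_chrom`; the homogametic
#'   haplotype replaces it with an unrelated sequence of the same
#'   length. Sex-specific k-mers then place back onto the region.
#'
#' With `emit = "haplotypes"` each haplotype is emitted `n_copies` times
#' (so real k-mers clear a `min_count = 2` guard deterministically);
#' `emit = "reads"` samples read-like fragments at `coverage` with
#' substitution errors at `error_rate`.
#'
#' A second population with a **shared origin** of the system is
#' simulated by passing the first population's result as `template`: the
#' sex-limited sequence is reused identically (identity by descent) while
#' the genomic background is redrawn. Omitting `template` gives an
#' independent origin.
#'
#' @param chrom_sizes named vector of chromosome lengths in bp (small;
#'   this generator is for desk-scale validation).
#' @param sex_chrom chromosome carrying the system.
#' @param region `c(start, end)` (1-based) for `mode = "embedded"`.
#' @param region_length sex-limited contig length for `mode = "contig"`.
#' @param heterogamety `"XY"` or `"ZW"`.
#' @param mode `"contig"` or `"embedded"` (see above).
#' @param emit `"haplotypes"` or `"reads"`.
#' @param n_copies copies per haplotype when emitting haplotypes.
#' @param read_length,coverage,error_rate read simulation parameters.
#' @param template previous result for a shared-origin population.
#' @param seed mandatory RNG seed.
#' @return list with `reference`, `male`, `female` (named character
#'   vectors of sequences), `sex_sequence`, `region` (data.frame), plus
#'   the layout parameters.
#' @export
simulate_pool_sequences <- function(chrom_sizes =
                                      c(chr1 = 20000, chr2 = 20000,
                                        chr3 = 40000),
                                    sex_chrom = "chr3", region = NULL,
                                    region_length = 1000,
                                    heterogamety = c("XY", "ZW"),
                                    mode = c("contig", "embedded"),
                                    emit = c("haplotypes", "reads"),
                                    n_copies = 2, read_length = 150,
                                    coverage = 10, error_rate = 0,
                                    template = NULL, seed) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  set.seed(seed)
  heterogamety <- match.arg(heterogamety)
  mode <- match.arg(mode)
  emit <- match.arg(emit)
  stopifnot(!is.null(names(chrom_sizes)), sex_chrom %in% names(chrom_sizes))

  chroms <- vapply(chrom_sizes, .rand_seq, "")
  if (mode == "embedded") {
    if (is.null(region)) stop("mode 'embedded' needs region = c(start, end)")
    stopifnot(region[1] >= 1, region[2] <= chrom_sizes[[sex_chrom]])
    reg_len <- region[2] - region[1] + 1
    sex_seq <- substring(chroms[[sex_chrom]], region[1], region[2])
    if (!is.null(template)) sex_seq <- template$sex_sequence
    stopifnot(nchar(sex_seq) == reg_len)
    y_chrom <- paste0(substring(chroms[[sex_chrom]], 1, region[1] - 1),
                      sex_seq,
                      substring(chroms[[sex_chrom]], region[2] + 1))
    x_chrom <- paste0(substring(chroms[[sex_chrom]], 1, region[1] - 1),
                      .rand_seq(reg_len),
                      substring(chroms[[sex_chrom]], region[2] + 1))
    chroms[[sex_chrom]] <- y_chrom  # reference carries the region
    het <- c(chroms[names(chroms) != sex_chrom],
             stats::setNames(c(y_chrom, x_chrom),
                             paste0(sex_chrom, c("_lim", "_alt"))))
    hom <- c(chroms[names(chroms) != sex_chrom],
             stats::setNames(c(x_chrom, x_chrom),
                             paste0(sex_chrom, c("_alt1", "_alt2"))))
    region_df <- data.frame(chrom = sex_chrom, start = region[1],
                            end = region[2], stringsAsFactors = FALSE)
  } else {
    sex_seq <- .rand_seq(region_length)
    if (!is.null(template)) sex_seq <- template$sex_sequence
    het <- chroms
    if (nchar(sex_seq) > 0)
      het <- c(het, stats::setNames(sex_seq, "sexlimited"))
    hom <- chroms
    region_df <- data.frame(chrom = "sexlimited", start = 1L,
                            end = nchar(sex_seq),
                            stringsAsFactors = FALSE)
  }

  male <- if (heterogamety == "XY") het else hom
  female <- if (heterogamety == "XY") hom else het
  expand <- function(seqs) {
    if (emit == "reads")
      return(.emit_reads(seqs, read_length, coverage, error_rate))
    out <- rep(seqs, each = n_copies)
    names(out) <- paste0(rep(names(seqs), each = n_copies), "_copy",
                         seq_len(n_copies))
    if (error_rate > 0)
      out <- vapply(out, .mutate_seq, "", rate = error_rate)
    out
  }
  list(reference = chroms, male = expand(male), female = expand(female),
       sex_sequence = sex_seq, region = region_df, mode = mode,
       heterogamety = heterogamety)
}

#' Draw a recruitment table from the size-weighted null
#'
#' Multinomial draw of `n_events` recruitment events over the chromosomes
#' of `sizes`, each event landing with probability proportional to
#' chromosome size. Deterministic given `seed`.
#'
#' @param n_events number of recruitment events.
#' @param sizes chromosome-size table or named vector.
#' @param seed mandatory RNG seed.
#' @return `data.frame` with columns `chrom`, `count` summing to
#'   `n_events`.
#' @export
simulate_recruitments <- function(n_events, sizes, seed) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  sz <- .named_counts(sizes, value_col = "length")
  stopifnot(all(sz > 0), n_events >= 0)
  set.seed(seed)
  x <- as.integer(stats::rmultinom(1, n_events, sz / sum(sz)))
  data.frame(chrom = names(sz), count = x, stringsAsFactors = FALSE)
}
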