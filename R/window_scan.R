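# Windowed genome scan: tile the genome into fixed-width windows, count
# XY/ZW-patterned SNPs per window, select the top 1% of anchored windows,
# test heterogeneity of the log2(XY:ZW) ratio among chromosomes, and call
# the sex system. Window coordinates are 0-based half-open (BED
# convention); site positions are 1-based.

.norm_chrom_sizes <- function(chrom_sizes) {
  if (is.data.frame(chrom_sizes)) {
    stopifnot(all(c("chrom", "length") %in% names(chrom_sizes)))
    out <- chrom_sizes
    if (!"anchored" %in% names(out))
      out$anchored <- rep(TRUE, nrow(out))
    return(out[c("chrom", "length", "anchored")])
  }
  if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes)))
    return(data.frame(chrom = names(chrom_sizes),
                      length = unname(chrom_sizes), anchored = TRUE,
                      stringsAsFactors = FALSE))
  stop("chrom_sizes must be a data.frame (chrom, length[, anchored]) ",
       "or a named numeric vector")
}

#' Tile chromosomes into fixed-width windows
#'
#' Produces `ceiling(length / width)` non-overlapping windows per
#' sequence; the last window of each sequence may be short. Coordinates
#' are 0-based half-open.
#'
#' @param chrom_sizes data.frame with `chrom`, `length` (bp) and optional
#'   logical `anchored`, or a named numeric vector of lengths.
#' @param width window width in bp (default 100 kb).
#' @return `data.frame` with columns `chrom`, `start`, `end`, `anchored`.
#' @examples
#' make_windows(c(chr1 = 250000), width = 100000)  # 3 windows, last 50 kb
#' @export
make_windows <- function(chrom_sizes, width = 100000) {
  cs <- .norm_chrom_sizes(chrom_sizes)
  if (nrow(cs) == 0) stop("empty chromosome size table")
  stopifnot(all(cs$length > 0), width >= 1)
  out <- do.call(rbind, lapply(seq_len(nrow(cs)), function(i) {
    n <- ceiling(cs$length[i] / width)
    start <- (seq_len(n) - 1) * width
    data.frame(chrom = cs$chrom[i], start = start,
               end = pmin(start + width, cs$length[i]),
               anchored = cs$anchored[i], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Count sex-patterned SNPs in windows
#'
#' Assigns every XY- and ZW-labelled record to the window containing its
#' (1-based) position and computes per-window totals and the
#' `log2((n_xy + pseudocount) / (n_zw + pseudocount))` ratio, finite for
#' all windows. Records on chromosomes absent from the window set (or
#' beyond the tiled length) are counted as unplaced, reported via a
#' message and the `"n_unplaced"` attribute.
#'
#' @param classifications output of [classify_sites()] (only `XY`/`ZW`
#'   rows are used).
#' @param windows output of [make_windows()].
#' @param pseudocount added to both counts in the log ratio (default 1).
#' @return `windows` with columns `n_xy`, `n_zw`, `n_total`,
#'   `log2_ratio` appended.
#' @export
count_in_windows <- function(classifications, windows, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  w <- windows
  w$n_xy <- 0L
  w$n_zw <- 0L
  cl <- classifications[classifications$LABEL %in% c("XY", "ZW"), ,
                        drop = FALSE]
  unplaced <- 0L
  for (ch in unique(cl$CHROM)) {
    wi <- which(w$chrom == ch)
    sub <- cl[cl$CHROM == ch, , drop = FALSE]
    if (!length(wi)) {
      unplaced <- unplaced + nrow(sub)
      next
    }
    pos0 <- sub$POS - 1  # to 0-based
    j <- findInterval(pos0, w$start[wi])
    ok <- j >= 1
    ok[ok] <- pos0[ok] < w$end[wi][j[ok]]
    unplaced <- unplaced + sum(!ok)
    w$n_xy[wi] <- w$n_xy[wi] +
      tabulate(j[ok & sub$LABEL == "XY"], nbins = length(wi))
    w$n_zw[wi] <- w$n_zw[wi] +
      tabulate(j[ok & sub$LABEL == "ZW"], nbins = length(wi))
  }
  if (unplaced > 0)
    message(unplaced, " sex-patterned record(s) fell outside the window ",
            "set and were counted as unplaced")
  w$n_total <- w$n_xy + w$n_zw
  w$log2_ratio <- log2((w$n_xy + pseudocount) / (w$n_zw + pseudocount))
  attr(w, "n_unplaced") <- unplaced
  w
}

#' Flag the top fraction of windows by sex-patterned SNP count
#'
#' Flags exactly `ceiling(fraction * N)` windows, where `N` is the number
#' of anchored windows (unanchored sequences never receive the flag and do
#' not enter the denominator). Selection is by descending `n_total`; ties
#' are broken deterministically by `(chrom, start)` ascending.
#'
#' @param stats output of [count_in_windows()].
#' @param fraction fraction of anchored windows to flag (default 0.01).
#' @param anchored_only restrict both the denominator and the selection to
#'   anchored windows (default `TRUE`).
#' @return `stats` with a logical `top1` column appended.
#' @export
top_percent_windows <- function(stats, fraction = 0.01,
                                anchored_only = TRUE) {
  anc <- if (anchored_only) stats$anchored else rep(TRUE, nrow(stats))
  n_anc <- sum(anc)
  if (n_anc < 1) stop("no anchored windows")
  n_flag <- ceiling(fraction * n_anc)
  if (all(stats$n_total[anc] == 0))
    warning("all windows have zero sex-patterned SNPs; ",
            "top fraction selected by coordinate only")
  o <- order(-stats$n_total, stats$chrom, stats$start)
  o <- o[anc[o]]
  stats$top1 <- FALSE
  stats$top1[o[seq_len(n_flag)]] <- TRUE
  stats
}

#' Kruskal-Wallis test of the log2(XY:ZW) ratio among chromosomes
#'
#' Rank-based heterogeneity test of a per-window statistic among
#' chromosomes, with tie correction, p-value from the chi-square
#' approximation with `k - 1` degrees of freedom. The degenerate
#' all-values-identical case returns `H = 0`, `p = 1`.
#'
#' @param stats output of [count_in_windows()].
#' @param value column to test (default `"log2_ratio"`).
#' @param anchored_only use anchored windows only (default `TRUE`).
#' @return list with `statistic` (H), `df`, `p.value`.
#' @export
kruskal_wallis_by_chrom <- function(stats, value = "log2_ratio",
                                    anchored_only = TRUE) {
  d <- if (anchored_only) stats[stats$anchored, , drop = FALSE] else stats
  g <- factor(d$chrom)
  if (nlevels(g) < 2)
    stop("Kruskal-Wallis test needs at least 2 chromosomes with windows")
  x <- d[[value]]
  if (length(unique(x)) == 1)
    return(list(statistic = 0, df = nlevels(g) - 1, p.value = 1))
  kt <- stats::kruskal.test(x, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value)
}

#' Dunn's post hoc test with multiplicity correction
#'
#' Pairwise follow-up to the Kruskal-Wallis test: for each pair of groups,
#' `z` is the difference in mean ranks (ranking done over all
#' observations) divided by its standard error from the pooled rank
#' variance `N(N+1)/12 - sum(t^3 - t) / (12(N-1))` (tie-corrected).
#' Two-sided p-values are adjusted with Benjamini-Hochberg by default.
#' Groups with no observations are dropped with a message.
#'
#' @param x numeric values, or a window-stats data.frame (in which case
#'   `value` is tested across its `chrom` column, anchored windows only).
#' @param g grouping vector (ignored when `x` is a data.frame).
#' @param value column tested when `x` is a data.frame.
#' @param p_adjust_method method for [stats::p.adjust()] (default `"BH"`).
#' @return `data.frame` with columns `group1`, `group2`, `z`, `p`,
#'   `p_adj`.
#' @export
dunn_posthoc <- function(x, g = NULL, value = "log2_ratio",
                         p_adjust_method = "BH") {
  if (is.data.frame(x)) {
    d <- if ("anchored" %in% names(x)) x[x$anchored, , drop = FALSE] else x
    g <- d$chrom
    x <- d[[value]]
  }
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]
  g <- factor(g[keep])
  if (any(tabulate(g, nbins = nlevels(g)) == 0)) {
    message("dropping empty group(s): ",
            paste(levels(g)[tabulate(g, nbins = nlevels(g)) == 0],
                  collapse = ", "))
    g <- droplevels(g)
  }
  if (nlevels(g) < 2) stop("Dunn's test needs at least 2 groups")
  n <- length(x)
  r <- rank(x)
  ties <- table(r)
  v <- n * (n + 1) / 12 - sum(ties^3 - ties) / (12 * (n - 1))
  mr <- tapply(r, g, mean)
  ng <- tapply(r, g, length)
  pr <- utils::combn(levels(g), 2)
  z <- vapply(seq_len(ncol(pr)), function(i) {
    a <- pr[1, i]
    b <- pr[2, i]
    se2 <- v * (1 / ng[[a]] + 1 / ng[[b]])
    if (se2 <= 0) return(0)
    (mr[[a]] - mr[[b]]) / sqrt(se2)
  }, numeric(1))
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pr[1, ], group2 = pr[2, ], z = z, p = p,
             p_adj = stats::p.adjust(p, p_adjust_method),
             stringsAsFactors = FALSE)
}

#' Call the sex system from a window scan
#'
#' Automates the by-inspection call: among top-flagged windows whose SNP
#' count clears a genome-wide background threshold, the chromosome holding
#' the plurality of supporting windows is the candidate sex chromosome. It
#' is called `XY` when more than `majority` of its supporting windows have
#' `n_xy > n_zw`, `ZW` for the mirror, otherwise `mixed` (both signals on
#' one chromosome do occur). The call is `none` when no top window clears
#' the background threshold or the plurality chromosome holds less than
#' `plurality_floor` of the supporting windows.
#'
#' The background threshold is
#' `max(min_snps, qpois(1 - tail_q, lambda) + 1)` with `lambda` the median
#' `n_total` over anchored windows: a window must carry more sex-patterned
#' SNPs than background misclassification plausibly produces.
#'
#' @param stats output of [count_in_windows()]; the `top1` flag is
#'   computed with defaults if absent.
#' @param plurality_floor minimum share of supporting windows the best
#'   chromosome must hold (default 0.10).
#' @param majority fraction of supporting windows that must agree on the
#'   heterogamety (default 2/3).
#' @param min_snps floor on the background threshold (default 5).
#' @param tail_q Poisson tail probability for the background threshold
#'   (default 1e-4).
#' @param fraction passed to [top_percent_windows()] when `top1` is
#'   missing.
#' @return list with `chrom`, `heterogamety` (`XY`/`ZW`/`mixed`/`none`),
#'   `n_top_windows_on_chrom`, `support_threshold`, and `intervals` (the
#'   supporting windows on the called chromosome).
#' @export
call_sex_system <- function(stats, plurality_floor = 0.10,
                            majority = 2 / 3, min_snps = 5,
                            tail_q = 1e-4, fraction = 0.01) {
  if (!"top1" %in% names(stats))
    stats <- suppressWarnings(top_percent_windows(stats, fraction))
  lam <- stats::median(stats$n_total[stats$anchored])
  thr <- max(min_snps, stats::qpois(1 - tail_q, lam) + 1)
  none <- list(chrom = NA_character_, heterogamety = "none",
               n_top_windows_on_chrom = 0L, support_threshold = thr,
               intervals = stats[0, c("chrom", "start", "end",
                                      "n_xy", "n_zw")])
  sup <- stats[stats$top1 & stats$n_total >= thr, , drop = FALSE]
  if (nrow(sup) == 0) return(none)
  tab <- sort(table(sup$chrom), decreasing = TRUE)
  if (tab[1] / nrow(sup) < plurality_floor) return(none)
  best <- names(tab)[1]
  on_best <- sup[sup$chrom == best, , drop = FALSE]
  f_xy <- mean(on_best$n_xy > on_best$n_zw)
  f_zw <- mean(on_best$n_zw > on_best$n_xy)
  het <- "mixed"
  if (f_xy > majority) het <- "XY"
  if (f_zw > majority) het <- "ZW"
  list(chrom = best, heterogamety = het,
       n_top_windows_on_chrom = nrow(on_best), support_threshold = thr,
       intervals = on_best[c("chrom", "start", "end", "n_xy", "n_zw")])
}

#' Run the full pool-seq sex scan
#'
#' Convenience pipeline: classify sites, tile windows, count sex-patterned
#' SNPs, flag the top fraction, run the Kruskal-Wallis test (and Dunn's
#' post hoc when it rejects at `alpha`), and call the sex system.
#'
#' @param counts pooled-count table ([read_pooled_counts()] or
#'   [simulate_pooled_counts()]).
#' @param chrom_sizes chromosome sizes ([read_chrom_sizes()] or a named
#'   vector).
#' @param width,fraction,pseudocount window width, top fraction and log
#'   pseudocount.
#' @param alpha significance level gating the post hoc test.
#' @param ... passed to [classify_sites()] (thresholds, `min_depth`).
#' @return list with elements `classifications`, `windows`, `kruskal`,
#'   `dunn` (or `NULL`), `call`.
#' @export
sex_scan <- function(counts, chrom_sizes, width = 100000,
                     fraction = 0.01, pseudocount = 1, alpha = 0.05,
                     ...) {
  cl <- classify_sites(counts, ...)
  w <- make_windows(chrom_sizes, width)
  st <- count_in_windows(cl, w, pseudocount)
  st <- suppressWarnings(top_percent_windows(st, fraction))
  kw <- tryCatch(kruskal_wallis_by_chrom(st), error = function(e) NULL)
  dn <- if (!is.null(kw) && is.finite(kw$p.value) && kw$p.value < alpha)
    dunn_posthoc(st) else NULL
  list(classifications = cl, windows = st, kruskal = kw, dunn = dn,
       call = call_sex_system(st, fraction = fraction))
}

#' Plot the per-chromosome scan tracks
#'
#' Three stacked panels in the style of a pool-seq sex scan figure:
#' per-allele FST, the male-pool frequency of XY-patterned alleles, and
#' the female-pool frequency of ZW-patterned alleles, along one
#' chromosome.
#'
#' @param classifications output of [classify_sites()].
#' @param chrom chromosome to plot.
#' @param file optional PNG path; when given the plot is written there.
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_sex_scan <- function(classifications, chrom, file = NULL) {
  d <- classifications[classifications$CHROM == chrom, , drop = FALSE]
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 800, res = 120)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op), add = TRUE)
  mb <- d$POS / 1e6
  graphics::plot(mb, d$FST, pch = 16, cex = 0.4, col = "grey30",
                 xlab = "", ylab = "FST", main = chrom, ylim = c(0, 1))
  xy <- d[d$LABEL == "XY", ]
  graphics::plot(xy$POS / 1e6, xy$FREQ_M, pch = 16, cex = 0.4,
                 col = "steelblue", xlab = "", ylab = "Y allele freq (M)",
                 xlim = range(mb), ylim = c(0, 1))
  zw <- d[d$LABEL == "ZW", ]
  graphics::plot(zw$POS / 1e6, zw$FREQ_F, pch = 16, cex = 0.4,
                 col = "firebrick", xlab = "position (Mb)",
                 ylab = "W allele freq (F)", xlim = range(mb),
                 ylim = c(0, 1))
  invisible(file)
}
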