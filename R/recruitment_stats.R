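# Clade-level statistics of sex chromosome recruitment: Poisson fit with
# chi-square goodness of fit, chromosome-size-weighted Monte Carlo null
# with Bonferroni correction, and turnover-rate estimation from branch
# lengths.

# Accepts a recruitment/size table as a data.frame (chrom + count/length)
# or a (named) numeric vector; returns a named numeric vector.
.named_counts <- function(x, value_col = c("count", "length")) {
  if (is.data.frame(x)) {
    col <- intersect(value_col, names(x))
    if (!length(col) || !"chrom" %in% names(x))
      stop("expected columns 'chrom' and one of ",
           paste(value_col, collapse = "/"))
    return(stats::setNames(as.numeric(x[[col[1]]]), x$chrom))
  }
  stats::setNames(as.numeric(x), names(x))
}

#' Mean recruitments per chromosome
#'
#' Total number of independent sex chromosome origins divided by the
#' number of chromosome categories; the mean of the fitted Poisson
#' distribution.
#'
#' @param x recruitment table (`data.frame` with `chrom`, `count`, e.g.
#'   [cichlid_recruitments()]) or a numeric vector of counts.
#' @return events per chromosome (numeric scalar).
#' @examples
#' poisson_mean(cichlid_recruitments())  # 51 / 23
#' @export
poisson_mean <- function(x) {
  cnt <- .named_counts(x)
  if (!length(cnt)) stop("empty recruitment table")
  sum(cnt) / length(cnt)
}

#' Expected Poisson category counts per occurrence class
#'
#' `expected[j] = n_categories * exp(-mean) * mean^j / j!` for occurrence
#' classes `0 .. max_count-1`, with a final class `>= max_count` absorbing
#' the remaining tail mass, so the expectations sum exactly to
#' `n_categories`.
#'
#' @param mean Poisson mean (events per category).
#' @param n_categories number of chromosome categories.
#' @param max_count first occurrence class of the absorbing tail.
#' @return named numeric vector of expected category counts.
#' @export
poisson_expected <- function(mean, n_categories, max_count) {
  stopifnot(mean >= 0, n_categories > 0, max_count >= 1)
  j <- 0:(max_count - 1)
  out <- c(n_categories * stats::dpois(j, mean),
           n_categories * stats::ppois(max_count - 1, mean,
                                       lower.tail = FALSE))
  stats::setNames(out, c(as.character(j), paste0(">=", max_count)))
}

# Chi-square on pre-binned observed/expected class counts with tail
# pooling: the topmost bins are merged downward until the top expected
# count reaches pool_min. df = bins - 1 - est_params (one estimated
# parameter, the mean, in the Poisson fit).
.chisq_pooled <- function(obs, expd, pool_min = 1, est_params = 1) {
  stopifnot(length(obs) == length(expd))
  while (length(expd) > 2 && expd[length(expd)] < pool_min) {
    n <- length(expd)
    expd[n - 1] <- expd[n - 1] + expd[n]
    obs[n - 1] <- obs[n - 1] + obs[n]
    names(expd)[n - 1] <- paste0(">=", sub("^>=", "", names(expd)[n - 1]))
    expd <- expd[-n]
    obs <- obs[-n]
  }
  if (length(expd) < 2) stop("fewer than 2 bins after pooling")
  stat <- sum((obs - expd)^2 / expd)
  df <- length(expd) - 1 - est_params
  p <- if (df >= 1) {
    stats::pchisq(stat, df, lower.tail = FALSE)
  } else {
    warning("no residual degrees of freedom after pooling; p undefined")
    NA_real_
  }
  list(statistic = stat, df = df, p.value = p, observed = obs,
       expected = expd)
}

#' Chi-square goodness of fit of recruitment counts to a Poisson
#'
#' Bins chromosomes by their occurrence count (0, 1, 2, ...), compares
#' the observed number of chromosomes in each class with the Poisson
#' expectation for `mean`, pools the upper tail until the top expected
#' count reaches `pool_min` (default 1), and tests with
#' `df = bins - 2` (one df lost to the estimated mean). Returns the
#' statistic, df and p-value together, since the binning policy affects
#' all three.
#'
#' @param x recruitment table or numeric vector of per-chromosome counts.
#' @param mean Poisson mean; estimated with [poisson_mean()] when `NULL`.
#' @param pool_min minimum expected count in the top bin (default 1).
#' @return list with `statistic`, `df`, `p.value`, `observed`,
#'   `expected` (class counts after pooling).
#' @examples
#' chisq_gof(cichlid_recruitments())
#' @export
chisq_gof <- function(x, mean = NULL, pool_min = 1) {
  cnt <- .named_counts(x)
  if (!length(cnt)) stop("empty recruitment table")
  if (is.null(mean)) mean <- poisson_mean(cnt)
  maxc <- max(cnt)
  if (maxc < 1) stop("all recruitment counts are zero")
  obs <- tabulate(cnt + 1, nbins = maxc + 1)
  names(obs) <- c(as.character(0:(maxc - 1)), paste0(">=", maxc))
  expd <- poisson_expected(mean, length(cnt), maxc)
  .chisq_pooled(obs, expd, pool_min = pool_min, est_params = 1)
}

#' Size-weighted Monte Carlo test of chromosome recruitment
#'
#' Simulates `n_reps` replicates of `n_events` recruitment events, each
#' event landing on a chromosome with probability proportional to its
#' size, and for each focal chromosome reports the upper-tail p-value:
#' the proportion of replicates in which the focal chromosome is hit at
#' least as often as observed. Bonferroni correction multiplies by
#' `n_tests` (capped at 1).
#'
#' The plain proportion keeps `p = 1` exact for an observed count of 0;
#' `add_one = TRUE` switches to the `(r + 1) / (n_reps + 1)` estimator.
#'
#' @param observed recruitment table or named count vector.
#' @param sizes chromosome-size table (`chrom`, `length`) or named
#'   vector; must cover every focal chromosome.
#' @param focal chromosomes to test (default: all categories in
#'   `sizes`).
#' @param n_events events per replicate (default `sum(observed)`).
#' @param n_reps Monte Carlo replicates (default 1000).
#' @param n_tests Bonferroni multiplicity (default `length(focal)`).
#' @param seed mandatory RNG seed for reproducibility.
#' @param add_one use the add-one p estimator (default `FALSE`).
#' @return `data.frame` with `chrom`, `observed`, `raw_p`,
#'   `bonferroni_p`; attributes `seed`, `n_reps`, `n_events`.
#' @export
monte_carlo_recruitment <- function(observed, sizes, focal = NULL,
                                    n_events = NULL, n_reps = 1000,
                                    n_tests = NULL, seed,
                                    add_one = FALSE) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  obs <- .named_counts(observed)
  sz <- .named_counts(sizes, value_col = "length")
  stopifnot(all(sz > 0), n_reps >= 1)
  if (is.null(focal)) focal <- names(sz)
  missing_sz <- setdiff(focal, names(sz))
  if (length(missing_sz))
    stop("focal chromosome(s) absent from the size table: ",
         paste(missing_sz, collapse = ", "))
  if (is.null(n_events)) n_events <- sum(obs)
  if (is.null(n_tests)) n_tests <- length(focal)
  set.seed(seed)
  draws <- stats::rmultinom(n_reps, n_events, sz / sum(sz))
  rownames(draws) <- names(sz)
  obs_f <- ifelse(is.na(obs[focal]), 0, obs[focal])
  raw <- vapply(seq_along(focal), function(i) {
    r <- sum(draws[focal[i], ] >= obs_f[i])
    if (add_one) (r + 1) / (n_reps + 1) else r / n_reps
  }, numeric(1))
  out <- data.frame(chrom = focal, observed = as.numeric(obs_f),
                    raw_p = raw,
                    bonferroni_p = pmin(1, raw * n_tests),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "seed") <- seed
  attr(out, "n_reps") <- n_reps
  attr(out, "n_events") <- n_events
  out
}

#' Sum of branch lengths of a tree or subtree
#'
#' Sums the edge lengths of a phylogeny (in whatever unit the tree
#' carries, here million years), optionally after pruning to the subtree
#' spanned by `tips`. The root edge is never included. Trees with a
#' missing edge length raise an error naming the edge.
#'
#' @param tree an [ape] `phylo` object or a path to a Newick file.
#' @param tips optional tip labels selecting a subtree.
#' @return total branch length (numeric scalar).
#' @export
sum_branch_lengths <- function(tree, tips = NULL) {
  if (is.character(tree) && length(tree) == 1)
    tree <- ape::read.tree(tree)
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tips)) tree <- ape::keep.tip(tree, tips)
  el <- tree$edge.length
  if (is.null(el))
    stop("tree has no branch lengths")
  if (anyNA(el))
    stop("missing branch length on edge(s) ",
         paste(which(is.na(el)), collapse = ", "),
         " (child nodes ",
         paste(tree$edge[is.na(el), 2], collapse = ", "), ")")
  sum(el)
}

#' Sex chromosome turnover rate
#'
#' Number of turnovers divided by the summed branch length over which
#' they occurred, in turnovers per million years when branch lengths are
#' in MY. Conventionally reported to two decimals.
#'
#' @param n_turnovers number of observed turnovers.
#' @param branch_length_sum summed branch length (must be positive).
#' @return turnovers per unit branch length (full precision).
#' @examples
#' turnover_rate(6, 26)  # ~0.23 per MY
#' @export
turnover_rate <- function(n_turnovers, branch_length_sum) {
  stopifnot(n_turnovers >= 0)
  if (branch_length_sum <= 0)
    stop("branch_length_sum must be positive")
  n_turnovers / branch_length_sum
}
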