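# Window tiling, per-window counting, top-percent selection, rank tests
# and the automated sex-system call.

test_that("windows tile each sequence without overlap, last may be short", {
  w <- make_windows(c(chr1 = 250000), width = 100000)
  expect_equal(nrow(w), 3)
  expect_equal(w$start, c(0, 100000, 200000))
  expect_equal(w$end, c(100000, 200000, 250000))
  expect_error(make_windows(data.frame(chrom = character(),
                                       length = numeric())), "empty")
})

test_that("window tiling matches the brute-force oracle on random sizes", {
  set.seed(5)
  sizes <- setNames(sample(1e5:1e6, 6), paste0("s", 1:6))
  width <- 73000  # deliberately not a divisor
  w <- make_windows(sizes, width)
  o <- do.call(rbind, lapply(names(sizes),
                             function(ch) oracle_tile(ch, sizes[[ch]],
                                                      width)))
  expect_equal(w[c("chrom", "start", "end")], o,
               ignore_attr = TRUE)
})

test_that("sex-patterned SNPs are assigned to the window containing them", {
  w <- make_windows(c(c1 = 100000))
  cl <- data.frame(CHROM = "c1", POS = 1:5, LABEL = "XY")
  st <- count_in_windows(cl, w)
  expect_equal(st$n_xy, 5L)
  expect_equal(st$n_zw, 0L)

  # 1-based position 100,000 is the last base of the first 0-based
  # half-open window; 100,001 opens the second
  w2 <- make_windows(c(c1 = 300000))
  cl2 <- data.frame(CHROM = "c1", POS = c(100000L, 100001L),
                    LABEL = c("XY", "ZW"))
  st2 <- count_in_windows(cl2, w2)
  expect_equal(oracle_window_index(100000, 1e5), 1)
  expect_equal(oracle_window_index(100001, 1e5), 2)
  expect_equal(st2$n_xy, c(1L, 0L, 0L))
  expect_equal(st2$n_zw, c(0L, 1L, 0L))

  empty <- count_in_windows(cl2[0, ], w2)
  expect_true(all(empty$n_total == 0))
  expect_true(all(is.finite(empty$log2_ratio)))
})

test_that("records on unknown chromosomes are logged as unplaced", {
  w <- make_windows(c(c1 = 1e5))
  cl <- data.frame(CHROM = c("c1", "cX"), POS = c(10L, 10L),
                   LABEL = "XY")
  expect_message(st <- count_in_windows(cl, w), "unplaced")
  expect_equal(attr(st, "n_unplaced"), 1L)
  expect_equal(sum(st$n_xy), 1L)
})

test_that("window counts conserve the classified records", {
  set.seed(11)
  sizes <- c(a = 5e5, b = 7e5)
  cl <- data.frame(
    CHROM = sample(names(sizes), 500, replace = TRUE),
    POS = NA_integer_,
    LABEL = sample(c("XY", "ZW", "none"), 500, replace = TRUE))
  cl$POS <- vapply(cl$CHROM, function(ch) sample.int(sizes[[ch]], 1),
                   integer(1))
  st <- count_in_windows(cl, make_windows(sizes))
  expect_equal(sum(st$n_xy), sum(cl$LABEL == "XY"))
  expect_equal(sum(st$n_zw), sum(cl$LABEL == "ZW"))
  expect_equal(st$n_total, st$n_xy + st$n_zw)
})

test_that("exactly ceiling(fraction * N_anchored) windows are flagged", {
  set.seed(21)
  for (n in c(1, 9, 100, 937)) {
    st <- data.frame(chrom = "c1", start = (seq_len(n) - 1) * 100,
                     end = seq_len(n) * 100, anchored = TRUE,
                     n_xy = rpois(n, 2), n_zw = rpois(n, 2))
    st$n_total <- st$n_xy + st$n_zw
    st$log2_ratio <- log2((st$n_xy + 1) / (st$n_zw + 1))
    out <- suppressWarnings(top_percent_windows(st, 0.01))
    expect_equal(sum(out$top1), ceiling(0.01 * n))
  }
})

test_that("top-window ties break deterministically by coordinate", {
  st <- data.frame(chrom = rep(c("b", "a"), each = 50),
                   start = rep((0:49) * 100, 2), end = rep((1:50) * 100, 2),
                   anchored = TRUE, n_xy = 3L, n_zw = 0L, n_total = 3L,
                   log2_ratio = 2)
  out <- top_percent_windows(st, 0.01)  # 1 of 100, all tied
  expect_equal(out[out$top1, c("chrom", "start")],
               data.frame(chrom = "a", start = 0), ignore_attr = TRUE)
  expect_warning(
    top_percent_windows(transform(st, n_total = 0L)), "zero")
})

test_that("unanchored windows are excluded from the top-percent set", {
  st <- data.frame(chrom = rep(c("c1", "ctg"), each = 100),
                   start = rep((0:99) * 100, 2),
                   end = rep((1:100) * 100, 2),
                   anchored = rep(c(TRUE, FALSE), each = 100),
                   n_xy = c(rpois(100, 1), rep(50L, 100)), n_zw = 0L)
  st$n_total <- st$n_xy + st$n_zw
  st$log2_ratio <- 0
  out <- suppressWarnings(top_percent_windows(st))
  expect_equal(sum(out$top1), 1L)  # 1% of the 100 anchored
  expect_false(any(out$top1 & !out$anchored))
})

test_that("Kruskal-Wallis handles ties, degenerate and textbook cases", {
  st <- data.frame(chrom = rep(c("a", "b"), each = 5), anchored = TRUE,
                   log2_ratio = 1)
  kw <- kruskal_wallis_by_chrom(st)
  expect_equal(kw$statistic, 0)
  expect_equal(kw$p.value, 1)

  st2 <- data.frame(chrom = rep(c("a", "b"), each = 3), anchored = TRUE,
                    log2_ratio = c(1, 2, 3, 4, 5, 6))
  kw2 <- kruskal_wallis_by_chrom(st2)
  expect_equal(kw2$statistic, oracle_kw_h(st2$log2_ratio, st2$chrom))
  expect_equal(kw2$df, 1)

  expect_error(kruskal_wallis_by_chrom(
    data.frame(chrom = "a", anchored = TRUE, log2_ratio = 1:3)),
    "at least 2")
})

test_that("rank statistics equal brute-force oracles on small instances", {
  set.seed(31)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    n <- sample(k:12, 1)
    g <- as.character(sample(seq_len(k), n, replace = TRUE))
    if (length(unique(g)) < 2) next
    x <- sample(1:6, n, replace = TRUE)  # forces ties
    if (length(unique(x)) == 1) next
    st <- data.frame(chrom = g, anchored = TRUE, log2_ratio = x)
    kw <- kruskal_wallis_by_chrom(st)
    expect_equal(kw$statistic, oracle_kw_h(x, g), tolerance = 1e-12)
    dn <- dunn_posthoc(x, g)
    for (i in seq_len(nrow(dn)))
      expect_equal(dn$z[i],
                   oracle_dunn_z(x, g, dn$group1[i], dn$group2[i]),
                   tolerance = 1e-12)
  }
})

test_that("Dunn post hoc: identical groups give z = 0, p = 1; BH >= raw", {
  dn <- dunn_posthoc(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(dn$z, 0)
  expect_equal(dn$p, 1)

  set.seed(41)
  x <- rnorm(60)
  g <- rep(letters[1:4], each = 15)
  dn2 <- dunn_posthoc(x, g)
  expect_true(all(dn2$p_adj >= dn2$p - 1e-15))
  # BH adjustment preserves the raw-p ordering
  expect_true(all(diff(dn2$p_adj[order(dn2$p)]) >= -1e-15))
})

test_that("the sex-system call follows plurality and majority rules", {
  mk <- function(n_xy, n_zw, chrom, n = length(n_xy)) {
    st <- data.frame(chrom = chrom, start = (seq_len(n) - 1) * 1e5,
                     end = seq_len(n) * 1e5, anchored = TRUE,
                     n_xy = n_xy, n_zw = n_zw)
    st$n_total <- st$n_xy + st$n_zw
    st$log2_ratio <- log2((st$n_xy + 1) / (st$n_zw + 1))
    st
  }
  # 100 windows, the 1 top window strongly XY on chr2
  st <- mk(c(rep(0L, 50), 80L, rep(0L, 49)), 0L,
           rep(c("chr1", "chr2"), each = 50))
  cal <- call_sex_system(st)
  expect_equal(cal$chrom, "chr2")
  expect_equal(cal$heterogamety, "XY")

  # nothing above the background threshold -> none
  st0 <- mk(rpois(100, 0.2), rpois(100, 0.2),
            rep(c("chr1", "chr2"), each = 50))
  expect_equal(call_sex_system(st0)$heterogamety, "none")

  # top windows spread thinly over many chromosomes -> plurality floor
  n_xy3 <- rep(0L, 2000)
  n_xy3[seq(1, by = 50, length.out = 20)] <- 20L  # 1 hot window on each
  st3 <- mk(n_xy3, 0L, rep(paste0("c", sprintf("%02d", 1:40)), each = 50))
  cal3 <- call_sex_system(st3)
  expect_equal(cal3$heterogamety, "none")
})

test_that("a planted ZW system is recovered end to end", {
  sizes <- c(chr1 = 5e6, chr2 = 5e6, chr3 = 5e6)
  for (seed in c(301, 302, 303)) {
    sim <- simulate_pooled_counts(
      sizes, sex_system_spec("chr3", 2e6, 3e6 - 1, "ZW"), seed = seed)
    sc <- sex_scan(sim$counts, sizes)
    expect_equal(sc$call$chrom, "chr3")
    expect_equal(sc$call$heterogamety, "ZW")
    # conservation through the whole pipeline
    expect_equal(sum(sc$windows$n_xy),
                 sum(sc$classifications$LABEL == "XY"))
  }
})
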