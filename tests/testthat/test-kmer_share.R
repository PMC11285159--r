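# Canonical k-mer counting, sex-specific k-mer extraction, cross-population
# sharing and reference placement.

test_that("k-mer position arithmetic and canonicalisation are exact", {
  s <- paste(rep("ACGT", 11), collapse = "")  # 44 bp
  tab <- count_kmers(s, k = 22)
  expect_equal(sum(tab), 23)          # 44 - 22 + 1 windows
  expect_lte(length(tab), 23)

  set.seed(7)
  r <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  rc <- poolsex:::.revcomp(r)
  expect_identical(count_kmers(r, 22), count_kmers(rc, 22))

  km <- names(count_kmers(r, 22))
  expect_identical(canonical_kmers(canonical_kmers(km)),
                   canonical_kmers(km))
})

test_that("k-mer tables equal the naive sliding-window oracle", {
  set.seed(13)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  expect_identical(count_kmers(s, 22), oracle_count_kmers(s, 22))
  # and on a short sequence with an N
  sn <- "ACGTNACGTACGTACGTACGTACGTACG"
  expect_identical(count_kmers(sn, 22), oracle_count_kmers(sn, 22))
})

test_that("sequences shorter than k are skipped with a message", {
  expect_message(tab <- count_kmers(c("ACGT", paste(rep("A", 25),
                                                    collapse = "")), 22),
                 "shorter than k")
  expect_equal(sum(tab), 4)
})

test_that("sex-specific k-mers need min_count in one pool, zero in the other", {
  pool <- count_kmers(paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                            collapse = ""), 22)
  expect_length(sex_specific_kmers(pool, pool), 0)

  # a 1,000-bp sex-limited insertion yields L - k + 1 specific 22-mers
  sim <- simulate_pool_sequences(region_length = 1000, mode = "contig",
                                 seed = 5)
  male <- count_kmers(sim$male, 22)
  female <- count_kmers(sim$female, 22)
  expect_length(sex_specific_kmers(male, female), 979)
})

test_that("min_count = 2 suppresses singleton error k-mers", {
  set.seed(17)
  base <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  err_read <- poolsex:::.mutate_seq(substr(base, 50, 120), 0.05)
  male <- count_kmers(c(base, base, err_read), 22)
  female <- count_kmers(c(base, base), 22)
  leak1 <- sex_specific_kmers(male, female, min_count = 1)
  leak2 <- sex_specific_kmers(male, female, min_count = 2)
  expect_gt(length(leak1), 0)   # error k-mers leak at min_count = 1
  expect_length(leak2, 0)
})

test_that("shared k-mer sets are exact symmetric intersections", {
  a <- c("AAAA", "CCCC", "GGGG")
  b <- c("TTTT", "ACGT")
  expect_length(shared_kmers(a, b), 0)
  expect_equal(shared_kmers(a, c(a, b)), sort(a))  # A subset of B -> |A|
  set.seed(19)
  x <- names(count_kmers(paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                               collapse = ""), 22))
  y <- names(count_kmers(paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                               collapse = ""), 22))
  expect_identical(shared_kmers(x, y), shared_kmers(y, x))
  expect_lte(length(shared_kmers(x, y)), min(length(x), length(y)))
})

test_that("shared-origin populations share the sex-limited k-mers, independent ones do not", {
  p1 <- simulate_pool_sequences(region_length = 1000, seed = 5)
  p2 <- simulate_pool_sequences(region_length = 1000, seed = 6,
                                template = p1)   # identical by descent
  p3 <- simulate_pool_sequences(region_length = 1000, seed = 7)
  ms <- lapply(list(p1, p2, p3), function(p)
    sex_specific_kmers(count_kmers(p$male, 22),
                       count_kmers(p$female, 22)))
  expect_gte(length(shared_kmers(ms[[1]], ms[[2]])), 970)
  expect_lt(length(shared_kmers(ms[[1]], ms[[3]])),
            0.01 * length(ms[[1]])) # < 1% random convergence
})

test_that("k-mers place at every exact locus; absent k-mers are unplaced", {
  ref <- c(chr7 = "ACGTACGTACGTACGTACGTACGTAC",
           chr8 = "TTTTTTTTTTTTTTTTTTTTTTTTTT")
  q <- substr(ref[["chr7"]], 2, 23)
  pl <- place_kmers(c(q, paste(rep("G", 22), collapse = "")), ref)
  expect_gte(pl$chrom_counts[["chr7"]], 1)
  expect_equal(pl$chrom_counts[["chr8"]], 0)
  expect_equal(pl$n_unplaced, 1L)
  expect_true(all(pl$placements$end - pl$placements$start == 21))

  # reverse-complement queries place too (canonical matching)
  pl2 <- place_kmers(poolsex:::.revcomp(q), ref)
  expect_equal(pl2$n_unplaced, 0L)
})

test_that("1-mismatch placement finds single-substitution neighbours", {
  set.seed(23)
  ref <- c(c1 = paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                      collapse = ""))
  q <- substr(ref[["c1"]], 100, 121)
  substr(q, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                             substr(q, 5, 5))[1]
  expect_equal(place_kmers(q, ref)$n_unplaced, 1L)
  expect_equal(place_kmers(q, ref, max_mismatch = 1)$n_unplaced, 0L)
})

test_that("shared k-mers from an embedded region place back onto it", {
  p <- simulate_pool_sequences(mode = "embedded",
                               region = c(15001, 25000),
                               sex_chrom = "chr3", seed = 11)
  ms <- sex_specific_kmers(count_kmers(p$male, 22),
                           count_kmers(p$female, 22))
  pl <- place_kmers(ms, p$reference)
  inreg <- pl$placements$chrom == "chr3" &
    pl$placements$end >= 15001 & pl$placements$start <= 25000
  expect_gt(mean(inreg), 0.9)
})
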