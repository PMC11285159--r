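# Independent brute-force oracles. These are deliberately naive (loops,
# direct formulas) and share no code with the package implementation.

# Wright's fixation index from two pool frequencies, written out directly.
oracle_fst <- function(p1, p2) {
  pb <- (p1 + p2) / 2
  ht <- 2 * pb * (1 - pb)
  if (ht == 0) return(0)
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  (ht - hs) / ht
}

# Tile one chromosome at a time with an explicit while loop.
oracle_tile <- function(chrom, len, width) {
  out <- NULL
  s <- 0
  while (s < len) {
    out <- rbind(out, data.frame(chrom = chrom, start = s,
                                 end = min(s + width, len)))
    s <- s + width
  }
  out
}

# 1-based index of the width-bp window containing a 1-based position.
oracle_window_index <- function(pos, width) ((pos - 1) %/% width) + 1

# Kruskal-Wallis H with tie correction, from the textbook formula.
oracle_kw_h <- function(x, g) {
  g <- as.character(g)
  n <- length(x)
  r <- rank(x)
  h <- 0
  for (gr in unique(g)) {
    ri <- sum(r[g == gr])
    ni <- sum(g == gr)
    h <- h + ri^2 / ni
  }
  h <- 12 / (n * (n + 1)) * h - 3 * (n + 1)
  tt <- table(x)
  h / (1 - sum(tt^3 - tt) / (n^3 - n))
}

# Dunn z for one pair of groups, from the mean-rank formula.
oracle_dunn_z <- function(x, g, a, b) {
  g <- as.character(g)
  n <- length(x)
  r <- rank(x)
  tt <- table(x)
  v <- n * (n + 1) / 12 - sum(tt^3 - tt) / (12 * (n - 1))
  na <- sum(g == a)
  nb <- sum(g == b)
  (mean(r[g == a]) - mean(r[g == b])) / sqrt(v * (1 / na + 1 / nb))
}

# Canonical k-mer counts via an explicit position loop and a hand-rolled
# reverse complement.
oracle_count_kmers <- function(s, k) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  kms <- character(0)
  for (i in seq_len(nchar(s) - k + 1)) {
    km <- substr(s, i, i + k - 1)
    if (grepl("[^ACGT]", km)) next
    rc <- paste(rev(unname(comp[strsplit(km, "")[[1]]])), collapse = "")
    kms <- c(kms, if (rc < km) rc else km)
  }
  tab <- table(kms)
  setNames(as.integer(tab), names(tab))
}

# Small hand-rollable pooled-counts table builder.
make_counts <- function(chrom, pos, male, female, ref = "A") {
  stopifnot(is.matrix(male), is.matrix(female))
  out <- data.frame(CHROM = chrom, POS = pos,
                    REF = rep_len(ref, length(pos)),
                    stringsAsFactors = FALSE)
  for (j in 1:4) out[[paste0(c("A", "C", "G", "T")[j], "_m")]] <- male[, j]
  for (j in 1:4) out[[paste0(c("A", "C", "G", "T")[j], "_f")]] <- female[, j]
  out
}
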