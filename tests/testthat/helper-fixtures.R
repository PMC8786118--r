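# Shared fixtures: the audited guide, printed table rows, and the
# brute-force alignment oracle used to cross-check the banded DP.

paper_guide <- function() {
  guide_rna("GCTCTAGGCCGAAGTGTCGC", name = "IDUA-W402X")
}

ungap <- function(x) gsub("-", "", x, fixed = TRUE)

# Independent alignment oracle. Any alignment of an n-nt target spacer to
# the 20-nt guide satisfies (#ins - #del) = n - 20, so the lexicographic
# (I, M) optimum always has I = |n - 20| realized by a pure
# insertion-only or deletion-only placement; enumerate them all and count
# mismatches directly.
brute_force_align <- function(guide, raw_seq) {
  L <- nchar(raw_seq)
  stopifnot(L >= 21, L <= 25)
  g <- strsplit(guide$spacer, "")[[1]]
  t <- strsplit(substr(raw_seq, 1, L - 3), "")[[1]]
  n <- length(t)
  k <- abs(n - 20L)
  ham <- function(a, b) sum(a != b | b == "N")
  if (n == 20L) {
    return(list(M = ham(g, t), I = 0L))
  }
  best <- Inf
  if (n > 20L) {
    for (idx in utils::combn(n, k, simplify = FALSE)) {
      best <- min(best, ham(g, t[-idx]))
    }
  } else {
    for (idx in utils::combn(20L, k, simplify = FALSE)) {
      best <- min(best, ham(g[-idx], t))
    }
  }
  list(M = as.integer(best), I = k)
}

# Random candidate sequences biased toward guide-like structure so the
# oracle comparison exercises realistic mismatch counts as well as noise.
random_candidates <- function(guide, n, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  g <- strsplit(guide$spacer, "")[[1]]
  out <- character(n)
  for (i in seq_len(n)) {
    t <- g
    nmut <- sample(0:7, 1)
    if (nmut > 0) {
      pos <- sample(20, nmut)
      t[pos] <- sample(bases, nmut, replace = TRUE)
    }
    ndel <- sample(0:2, 1)
    if (ndel > 0) t <- t[-sample(length(t), ndel)]
    nins <- sample(0:2, 1)
    if (nins > 0) {
      for (j in seq_len(nins)) {
        at <- sample(0:length(t), 1)
        t <- append(t, sample(bases, 1), after = at)
      }
    }
    len <- length(t)
    if (len < 18) t <- c(t, sample(bases, 18 - len, replace = TRUE))
    if (len > 22) t <- t[1:22]
    out[i] <- paste0(paste(t, collapse = ""),
                     sample(bases, 1), "GG")
  }
  out
}

# Table 1 rows used across tests: id, printed sequence, M, I
table1_rows <- function() {
  data.frame(
    id = c("0", "1", "2", "3", "4", "5", "75", "81"),
    sequence = c(
      "GCTCTAGGCCGAAGTGTCGCAGG",
      "GCTCTGGGCCGAAGTGTCGCAGG",
      "GCTCTGGGCTGGGGTGTCGCTGG",
      "TCTCTAGGCAGAAGTGATGCTGG",
      "GCTCTAGGCTGAAGTGCTTCTGG",
      "CCACTAGGCCAAAGTGTAGCTGG",
      "GCTC-AGGCTGAAGGGTCGCAGG",
      "ACT-GAGGTCGAAGTGTCGCTGG"),
    M = c(0L, 1L, 4L, 4L, 4L, 4L, 2L, 3L),
    I = c(0L, 0L, 0L, 0L, 0L, 0L, 1L, 1L),
    stringsAsFactors = FALSE)
}

# A small five-site candidate table on a toy chromosome, in the unified
# schema, sequences taken from the printed rows.
toy_candidates <- function() {
  t1 <- table1_rows()
  n <- nrow(t1)
  data.frame(
    id = t1$id, chrom = "chrT",
    start = seq(1000, by = 100, length.out = n),
    end = seq(1000, by = 100, length.out = n) +
      nchar(gsub("-", "", t1$sequence)),
    strand = "+",
    sequence = t1$sequence,
    source = "toolA",
    annotation = "unknown",
    stringsAsFactors = FALSE)
}
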