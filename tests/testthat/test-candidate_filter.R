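test_that("read_candidates validates the unified schema", {
  df <- toy_candidates()
  out <- read_candidates(df)
  expect_equal(nrow(out), nrow(df))
  bad <- df; bad$end[1] <- bad$end[1] + 5L
  expect_error(read_candidates(bad), "disagrees")
  bad2 <- df; bad2$sequence[2] <- "GCTCTAGGCCGAAGTGTCGCAGQ"
  expect_error(read_candidates(bad2), "invalid characters")
  expect_error(read_candidates(df[, -3]), "lacks columns")
})

test_that("merge_predictions unions sources and rejects locus conflicts", {
  df <- toy_candidates()
  a <- df[1:4, ]
  b <- df[3:6, ]; b$source <- "toolB"
  m <- merge_predictions(list(a, b))
  expect_equal(nrow(m), 6L)
  expect_equal(m$source[m$id == "3"], "toolA,toolB")
  expect_equal(m$source[m$id == "0"], "toolA")
  # disjoint loci concatenate, count preserved
  m2 <- merge_predictions(list(df[1:3, ], df[4:6, ]))
  expect_equal(nrow(m2), 6L)
  # same locus, different sequence -> error
  conflict <- df[3, ]
  conflict$sequence <- "GCTCTGGGCTGGGGTGTCGCAGG"
  expect_error(merge_predictions(list(df[3, ], conflict)),
               "conflicting sequences")
})

test_that("synthetic multi-predictor fixture merges to known intersections", {
  df <- toy_candidates()
  # three predictors with a known overlap structure
  pa <- df[c(1, 2, 3), ]; pa$source <- "A"
  pb <- df[c(2, 3, 4), ]; pb$source <- "B"
  pc <- df[c(3, 5), ]; pc$source <- "C"
  m <- merge_predictions(list(pa, pb, pc))
  expect_equal(nrow(m), 5L)
  srcs <- strsplit(m$source, ",")
  names(srcs) <- m$id
  # fixture truth: "0" only in A; "1" in A,B; "2" in all three;
  # "3" only in B; "4" only in C
  expect_equal(srcs[["0"]], "A")
  expect_equal(sort(srcs[["1"]]), c("A", "B"))
  expect_equal(sort(srcs[["2"]]), c("A", "B", "C"))
  expect_equal(srcs[["3"]], "B")
  expect_equal(srcs[["4"]], "C")
  pairwise_AB <- sum(vapply(srcs, function(s) all(c("A", "B") %in% s),
                            logical(1)))
  expect_equal(pairwise_AB, 2L)
})

test_that("apply_filters enforces the 6/2/SEED/PAM policy with reasons", {
  g <- paper_guide()
  df <- toy_candidates()
  res <- apply_filters(df, g)
  expect_equal(nrow(res$retained) + nrow(res$rejected), nrow(df))
  expect_true("2" %in% res$retained$id)          # 4/0, TGG, seed intact
  expect_equal(res$retained$M[res$retained$id == "2"], 4L)

  # M over the cap
  gs <- strsplit(g$spacer, "")[[1]]
  gs[c(1, 2, 3, 4, 6, 7, 10)] <- c("T", "A", "A", "A", "C", "A", "A")
  over <- data.frame(id = "m7", chrom = "chrT", start = 1, end = 24,
                     strand = "+",
                     sequence = paste0(paste(gs, collapse = ""), "AGG"),
                     source = "x", annotation = "unknown",
                     stringsAsFactors = FALSE)
  r2 <- apply_filters(over, g)
  expect_equal(nrow(r2$retained), 0L)
  expect_match(r2$rejected$reason, "M=7 exceeds 6")

  # seed-broken site is rejected with its reason
  broken <- over
  broken$id <- "seedless"
  broken$sequence <- "GCTCTAGGCCGAAGTGTCGTAGG"
  broken$end <- broken$start + 23
  r3 <- apply_filters(broken, g)
  expect_match(r3$rejected$reason, "SEED")

  # unalignable sequences are rejected, not fatal
  junk <- over; junk$id <- "junk"; junk$sequence <- "GCTCTAG-CCGAAGTGTCG-AG-"
  junk$end <- junk$start + 20
  r4 <- apply_filters(junk, g)
  expect_equal(nrow(r4$retained), 0L)
  expect_match(r4$rejected$reason, "unalignable")
})

test_that("apply_filters is idempotent and monotone under tightening", {
  g <- paper_guide()
  df <- toy_candidates()
  r1 <- apply_filters(df, g)
  r2 <- apply_filters(r1$retained[, names(df)], g)
  expect_equal(r2$retained$id, r1$retained$id)
  tight <- filter_policy(max_mismatches = 2L)
  r3 <- apply_filters(df, g, tight)
  expect_true(all(r3$retained$id %in% r1$retained$id))
  expect_lte(nrow(r3$retained), nrow(r1$retained))
})

test_that("merge then filter commutes with filter then merge on disjoint inputs", {
  g <- paper_guide()
  df <- toy_candidates()
  a <- df[1:3, ]; b <- df[4:6, ]
  mf <- apply_filters(merge_predictions(list(a, b)), g)$retained$id
  fa <- apply_filters(a, g)$retained
  fb <- apply_filters(b, g)$retained
  fm <- merge_predictions(list(fa[, names(df)], fb[, names(df)]))$id
  expect_setequal(mf, fm)
})

test_that("annotate_genic classifies overlap, boundary and unknown chrom", {
  df <- toy_candidates()
  genes <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(start = c(950, 1210), end = c(1100, 1500)),
    name = c("GENE1", "GENE2"))
  ann <- annotate_genic(df, genes)
  expect_equal(ann$annotation[1], "genic")       # 1000-1023 inside GENE1
  expect_equal(ann$gene[1], "GENE1")
  expect_equal(ann$annotation[2], "intergenic")  # 1100-1123 overlaps GENE1?
  # straddling a boundary still counts as genic (any-overlap rule)
  strad <- df[1, ]; strad$start <- 1090L; strad$end <- 1113L
  expect_equal(annotate_genic(strad, genes)$annotation, "genic")
  # unknown chromosome -> unknown, with a warning
  off <- df[1, ]; off$chrom <- "chrZ"
  expect_warning(res <- annotate_genic(off, genes), "absent")
  expect_equal(res$annotation, "unknown")
  # pseudogene biotype honoured
  pg <- GenomicRanges::GRanges("chrT", IRanges::IRanges(990, 1100),
                               name = "PSG1",
                               gene_biotype = "processed_pseudogene")
  expect_equal(annotate_genic(df[1, ], pg)$annotation, "pseudogene")
})

test_that("find_duplicate_sequences groups identical sequences across loci", {
  df <- toy_candidates()
  # plant the Table 3 trio: same sequence at three loci
  trio <- df[1:3, ]
  trio$id <- c("15", "16", "18")
  trio$sequence <- "AATCCAGGTCGAAGGGTCGCCGG"
  trio$chrom <- c("chr16", "chr10", "chr6")
  trio$start <- c(3131029, 81735283, 67041122)
  trio$end <- trio$start + 23
  all <- rbind(df[4:6, ], trio)
  dup <- find_duplicate_sequences(all)
  expect_equal(nrow(dup), 3L)
  expect_equal(length(unique(dup$dup_group)), 1L)
  expect_setequal(dup$id, c("15", "16", "18"))
  # all-unique input -> empty report
  expect_equal(nrow(find_duplicate_sequences(df)), 0L)
  # k planted duplicate pairs -> exactly k groups
  k <- 3L
  pairs <- do.call(rbind, lapply(seq_len(k), function(i) {
    r <- df[rep(i + 1, 2), ]
    r$id <- paste0("dup", i, c("a", "b"))
    r$start <- r$start + c(0L, 5000L * i)
    r$end <- r$end + c(0L, 5000L * i)
    r
  }))
  expect_equal(length(unique(find_duplicate_sequences(pairs)$dup_group)), k)
})

test_that("flag_repeats distinguishes inside / near / none", {
  df <- toy_candidates()[1:3, ]
  reps <- GenomicRanges::GRanges(
    "chrT",
    IRanges::IRanges(start = c(995, 1175), end = c(1030, 1180)),
    name = c("ERV_classII", "L1"))
  fl <- flag_repeats(df, reps, flank = 200L)
  expect_equal(fl$repeat_status[1], "inside")    # 1000-1023 in 995-1030
  expect_equal(fl$repeat_element[1], "ERV_classII")
  expect_equal(fl$repeat_status[2], "near")      # 1100-1123, repeat 50bp away
  nochr <- df; nochr$chrom <- "chrZ"
  expect_true(all(flag_repeats(nochr, reps)$repeat_status == "none"))
})

test_that("RepeatMasker .out ingestion yields usable intervals", {
  out_lines <- c(
    "   SW   perc perc perc  query      position in query     matching repeat",
    "score   div. del. ins.  sequence   begin end (left)      repeat class/family",
    "",
    "  463   1.3  0.6  1.7  chrT        995  1030 (100) + MER4  ERV_classII  1 36 (0) 1",
    "  239  29.4  1.9  1.0  chrT       5000  5120 (20) C L1M2  LINE/L1  2 120 (5) 2")
  p <- tempfile(fileext = ".out")
  writeLines(out_lines, p)
  gr <- read_repeatmasker_out(p)
  expect_equal(length(gr), 2L)
  expect_equal(S4Vectors::mcols(gr)$name, c("ERV_classII", "LINE/L1"))
  fl <- flag_repeats(toy_candidates()[1, ], p)
  expect_equal(fl$repeat_status, "inside")
})
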