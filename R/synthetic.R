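## Deterministic synthetic data: genomes, planted off-target sites,
## population VCFs with known truth. Everything derives from one integer
## seed so each stage of the audit is testable without downloads.

#' Generate a random genome
#'
#' I.i.d. background sequence at a requested GC content. Reproducible for
#' a fixed seed; the observed GC fraction converges on the request (within
#' 2 percentage points for lengths >= 10 kb).
#'
#' @param seed integer seed controlling all randomness
#' @param length sequence length in bp (>= 1000)
#' @param gc target GC fraction, strictly inside (0, 1)
#' @param chrom sequence name (default "chrS1")
#' @return a \code{DNAStringSet} of one sequence
#' @export
make_genome <- function(seed, length, gc = 0.41, chrom = "chrS1") {
  if (length < 1000L) stop("genome length must be >= 1000")
  if (gc <= 0 || gc >= 1) stop("degenerate gc content rejected")
  bases <- with_seed(seed, sample(DNA_BASES, length, replace = TRUE,
                                  prob = c((1 - gc) / 2, gc / 2,
                                           gc / 2, (1 - gc) / 2)))
  g <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(g) <- chrom
  g
}

#' Specify a site to plant
#'
#' Describes one off-target to be written into a genome: which guide
#' positions are mutated (and to what), where bases are deleted or
#' inserted, the PAM trinucleotide, the locus and the strand. The truth
#' M/I follow directly from the spec.
#'
#' @param chrom,start locus (0-based start of the site on the plus strand)
#' @param strand "+" or "-"
#' @param mismatches named character vector: names are guide positions
#'   1-20, values the substituted target base
#' @param deletions integer vector of guide positions deleted in the target
#' @param insertions named character vector: names are guide positions
#'   after which the extra base is inserted (0 = before position 1), values
#'   the inserted base
#' @param pam PAM trinucleotide planted after the protospacer
#' @return a \code{plant_spec}
#' @export
plant_spec <- function(chrom, start, strand = "+",
                       mismatches = character(0),
                       deletions = integer(0),
                       insertions = character(0),
                       pam = "AGG") {
  structure(list(chrom = chrom, start = as.integer(start), strand = strand,
                 mismatches = mismatches, deletions = as.integer(deletions),
                 insertions = insertions, pam = toupper(pam)),
            class = "plant_spec")
}

## realize the guide-oriented planted sequence and its truth counts
build_planted <- function(guide, spec) {
  g <- strsplit(guide$spacer, "")[[1]]
  t <- g
  mpos <- as.integer(names(spec$mismatches))
  if (length(mpos)) {
    if (any(mpos < 1L | mpos > 20L)) stop("mismatch position out of range")
    if (any(spec$mismatches == g[mpos])) {
      stop("mismatch spec equals the guide base")
    }
    t[mpos] <- spec$mismatches
  }
  if (any(duplicated(c(mpos, spec$deletions)))) {
    stop("overlapping mismatch/deletion positions")
  }
  keep <- setdiff(seq_len(20L), spec$deletions)
  t <- t[keep]
  ipos <- as.integer(names(spec$insertions))
  if (length(ipos)) {
    ## insert after guide position k, walking right-to-left so earlier
    ## offsets stay valid
    ord <- order(ipos, decreasing = TRUE)
    for (j in ord) {
      at <- sum(keep <= ipos[j])
      t <- append(t, spec$insertions[j], after = at)
    }
  }
  seqn <- paste0(paste(t, collapse = ""), spec$pam)
  if (nchar(seqn) < 21L || nchar(seqn) > 25L) {
    stop("planted sequence length ", nchar(seqn), " outside [21, 25]")
  }
  list(sequence = seqn,
       M = length(mpos),
       I = length(spec$deletions) + length(ipos),
       seed_conserved = all(c(mpos, spec$deletions, ipos) <= 15L))
}

#' Plant off-target sites into a genome
#'
#' Writes each specified site into the genome (reverse-complemented for
#' minus-strand loci) and returns the modified genome plus a truth table.
#' Scanning or aligning the modified genome recovers each site with
#' exactly the truth M, I, SEED and PAM.
#'
#' @param genome a \code{DNAStringSet}
#' @param guide a \code{guide_rna}
#' @param specs list of \code{\link{plant_spec}}
#' @return list: \code{genome} (modified), \code{truth} (data.frame with
#'   id, chrom, start, end, strand, sequence, M, I, pam, seed_conserved)
#' @export
plant_sites <- function(genome, guide, specs) {
  stopifnot(inherits(genome, "DNAStringSet"))
  rows <- list()
  for (k in seq_along(specs)) {
    spec <- specs[[k]]
    built <- build_planted(guide, spec)
    w <- nchar(built$sequence)
    rows[[k]] <- data.frame(
      id = paste0("planted_", k), chrom = spec$chrom, start = spec$start,
      end = spec$start + w, strand = spec$strand,
      sequence = built$sequence, M = built$M, I = built$I,
      pam = spec$pam, seed_conserved = built$seed_conserved,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  for (ch in unique(truth$chrom)) {
    sub <- truth[truth$chrom == ch, ]
    o <- order(sub$start)
    if (any(sub$start[o][-1] < sub$end[o][-nrow(sub)])) {
      stop("overlapping plant loci on ", ch)
    }
    if (any(sub$end > length(genome[[ch]])) || any(sub$start < 0L)) {
      stop("plant locus outside genome bounds on ", ch)
    }
  }
  for (k in seq_len(nrow(truth))) {
    plus_seq <- if (truth$strand[k] == "+") truth$sequence[k] else
      revcomp(truth$sequence[k])
    genome[[truth$chrom[k]]] <- Biostrings::replaceLetterAt(
      genome[[truth$chrom[k]]],
      seq.int(truth$start[k] + 1L, truth$end[k]),
      strsplit(plus_seq, "")[[1]])
  }
  list(genome = genome, truth = truth)
}

#' Random plant specifications emulating the audited candidate set
#'
#' Draws sites with 4-6 mismatches and 0-2 indels confined to the 15
#' PAM-distal positions (so SEED stays conserved), canonical NGG PAMs,
#' random strands, and non-overlapping loci.
#'
#' @param n number of sites
#' @param guide a \code{guide_rna}
#' @param genome_length available genome length
#' @param seed RNG seed
#' @param m_range,i_range inclusive ranges for mismatch / indel counts
#' @return list of \code{plant_spec}
#' @export
random_plant_specs <- function(n, guide, genome_length, seed,
                               m_range = c(4L, 6L), i_range = c(0L, 2L)) {
  g <- strsplit(guide$spacer, "")[[1]]
  with_seed(seed, {
    gap <- (genome_length - 200L) %/% n
    if (gap < 40L) stop("genome too short for ", n, " sites")
    lapply(seq_len(n), function(k) {
      start <- 100L + (k - 1L) * gap + sample.int(gap - 30L, 1L)
      for (attempt in 1:100) {
        nm <- sample(seq.int(m_range[1], m_range[2]), 1L)
        ni <- sample(seq.int(i_range[1], i_range[2]), 1L)
        ndel <- if (ni > 0L) sample.int(ni + 1L, 1L) - 1L else 0L
        nins <- ni - ndel
        ## deletions stay off guide position 1: a bulge there has no
        ## published activity (it is indistinguishable from a shorter
        ## window), so the penalty tables carry positions 2-20 only
        pos <- sample.int(14L, nm + ndel) + 1L
        mpos <- sort(pos[seq_len(nm)])
        dpos <- sort(pos[nm + seq_len(ndel)])
        mb <- vapply(mpos, function(p) sample(setdiff(DNA_BASES, g[p]),
                                              1L), character(1))
        ins <- character(0)
        if (nins > 0L) {
          iat <- sample(setdiff(1:14, dpos), nins)
          ins <- setNames(sample(DNA_BASES, nins, replace = TRUE),
                          as.character(iat))
        }
        spec <- plant_spec(
          chrom = "chrS1", start = start,
          strand = sample(c("+", "-"), 1L),
          mismatches = setNames(mb, as.character(mpos)),
          deletions = dpos, insertions = ins,
          pam = paste0(sample(DNA_BASES, 1L), "GG"))
        ## keep only specs whose DP-optimal alignment equals the planted
        ## truth, so generator truth tables stay exact
        built <- build_planted(guide, spec)
        a <- align_candidate(guide, built$sequence)
        if (a$M == built$M && a$I == built$I &&
            seed_conserved(a) == built$seed_conserved) {
          return(spec)
        }
      }
      stop("could not draw a canonical plant spec after 100 attempts")
    })
  })
}

#' Generate a genome with verified planted off-targets
#'
#' Draws random plant specifications, writes each site into the genome and
#' verifies in genomic context that the anchored scan recovers it with
#' exactly the planted truth (a site is redrawn when a competing window
#' interpretation would shadow it — e.g. a PAM-distal insertion that the
#' scanner could also explain as a shifted mismatch-only window).
#' Deterministic for a fixed seed.
#'
#' @param guide a \code{guide_rna}
#' @param n number of sites
#' @param length genome length
#' @param seed integer seed for the genome and all draws
#' @param gc background GC fraction
#' @param m_range,i_range inclusive mismatch / indel count ranges
#' @return list: \code{genome}, \code{truth} (as \code{\link{plant_sites}})
#' @export
synthesize_offtarget_genome <- function(guide, n, length, seed, gc = 0.41,
                                        m_range = c(4L, 6L),
                                        i_range = c(0L, 2L)) {
  genome <- make_genome(seed, length, gc)
  rows <- vector("list", n)
  gap <- (length - 200L) %/% n
  if (gap < 60L) stop("genome too short for ", n, " sites")
  for (k in seq_len(n)) {
    base_start <- 100L + (k - 1L) * gap
    for (attempt in 1:50) {
      spec <- random_plant_specs(1L, guide, 400L, seed = seed + k * 100L +
                                   attempt, m_range = m_range,
                                 i_range = i_range)[[1]]
      spec$start <- base_start + attempt  # keep loci disjoint across draws
      trial <- plant_sites(genome, guide, list(spec))
      tr <- trial$truth
      tr$id <- paste0("planted_", k)
      ## verify recovery on a local slice around the planted locus
      lo <- max(1L, tr$start - 30L)
      hi <- min(length, tr$end + 30L)
      slice <- Biostrings::DNAStringSet(
        Biostrings::subseq(trial$genome[[tr$chrom]], lo, hi))
      names(slice) <- tr$chrom
      hits <- scan_offtargets(slice, guide,
                              filter_policy(max_mismatches = m_range[2],
                                            max_indels = i_range[2]))
      ok <- nrow(hits) == 1L &&
        hits$start == tr$start - (lo - 1L) &&
        hits$M == tr$M && hits$I == tr$I &&
        hits$sequence == tr$sequence
      if (ok) {
        genome <- trial$genome
        rows[[k]] <- tr
        break
      }
      if (attempt == 50L) {
        stop("could not verify a planted site after 50 attempts")
      }
    }
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  list(genome = genome, truth = truth)
}

#' Write a population VCF with per-population AF INFO keys
#'
#' REF alleles are read from (and verified against) the genome. The INFO
#' keys follow the 1000 Genomes dialect: AF (worldwide), EUR_AF, AMR_AF,
#' AFR_AF, all Number=A.
#'
#' @param specs data.frame with columns chrom, pos (1-based), ref, alt and
#'   optional af_E, af_LA, af_A, af_W columns (NA = absent)
#' @param genome a \code{DNAStringSet}
#' @param path output VCF path
#' @param seed recorded in the header for provenance
#' @return \code{path}, invisibly
#' @export
make_vcf <- function(specs, genome, path, seed = NA) {
  stopifnot(inherits(genome, "DNAStringSet"))
  keymap <- c(af_W = "AF", af_E = "EUR_AF", af_LA = "AMR_AF",
              af_A = "AFR_AF")
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=crisprAudit-synthetic(seed=%s)", seed),
    sprintf("##INFO=<ID=%s,Number=A,Type=Float,Description=\"%s\">",
            keymap, names(keymap)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  specs <- specs[order(specs$chrom, specs$pos), , drop = FALSE]
  for (k in seq_len(nrow(specs))) {
    s <- specs[k, ]
    obs <- as.character(Biostrings::subseq(
      genome[[s$chrom]], s$pos, s$pos + nchar(s$ref) - 1L))
    if (obs != toupper(s$ref)) {
      stop(sprintf("spec REF inconsistent with genome at %s:%d (%s vs %s)",
                   s$chrom, s$pos, s$ref, obs))
    }
    info <- character(0)
    for (cc in names(keymap)) {
      if (cc %in% names(s) && !is.na(s[[cc]])) {
        info <- c(info, sprintf("%s=%s", keymap[[cc]],
                                format(s[[cc]], scientific = FALSE)))
      }
    }
    lines <- c(lines, paste(s$chrom, s$pos, ".", toupper(s$ref),
                            toupper(s$alt), ".", "PASS",
                            if (length(info)) paste(info, collapse = ";")
                            else ".",
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Derive a variant spec realizing an intended effect at a planted site
#'
#' Builds a genomic SNV that, overlaid on the given truth row, produces the
#' requested effect class: more/fewer mismatches, a broken SEED, a broken
#' PAM, or (at an NGN/NNG site) a created PAM.
#'
#' @param truth_row one row of a \code{\link{plant_sites}} truth table
#' @param guide a \code{guide_rna}
#' @param effect one of increase_mismatches, decrease_mismatches,
#'   seed_disrupted, pam_disrupted, pam_created
#' @param genome the planted genome (REF read from it)
#' @param af named allele frequencies (af_E, af_LA, af_A, af_W)
#' @return one-row data.frame usable with \code{\link{make_vcf}} and
#'   \code{\link{reevaluate}}
#' @export
variant_for_effect <- function(truth_row, guide, effect, genome,
                               af = c(af_A = 0.05)) {
  site_seq <- truth_row$sequence
  L <- nchar(site_seq)
  a <- align_candidate(guide, site_seq)
  cc <- a$columns
  pick_offset <- function(col) {
    ## offset of an alignment column inside the ungapped site sequence
    sum(cc$target_base[seq_len(col)] != "-")
  }
  if (effect == "increase_mismatches") {
    cand <- cc[cc$op == "match" & !is.na(cc$guide_pos) &
                 cc$guide_pos <= 15L, ]
    if (!nrow(cand)) stop("no match column available")
    col <- cand$column[1L]
    from <- cand$target_base[1L]
    to <- setdiff(DNA_BASES, c(from, cand$guide_base[1L]))[1L]
    off <- pick_offset(col)
  } else if (effect == "decrease_mismatches") {
    cand <- cc[cc$op == "mismatch", ]
    if (!nrow(cand)) stop("site has no mismatch to revert")
    col <- cand$column[1L]
    from <- cand$target_base[1L]
    to <- cand$guide_base[1L]
    off <- pick_offset(col)
  } else if (effect == "seed_disrupted") {
    cand <- cc[cc$op == "match" & !is.na(cc$guide_pos) &
                 cc$guide_pos >= 16L, ]
    if (!nrow(cand)) stop("seed already broken")
    col <- cand$column[1L]
    from <- cand$target_base[1L]
    to <- setdiff(DNA_BASES, c(from, cand$guide_base[1L]))[1L]
    off <- pick_offset(col)
  } else if (effect == "pam_disrupted") {
    if (!iupac_match(truth_row$pam, "NGG")) stop("PAM not canonical")
    from <- substr(truth_row$pam, 2L, 2L)
    to <- "T"
    off <- (L - 3L) + 2L
  } else if (effect == "pam_created") {
    pam <- truth_row$pam
    if (iupac_match(pam, "NGG")) stop("PAM already canonical")
    miss <- if (substr(pam, 2L, 2L) != "G") 2L else 3L
    from <- substr(pam, miss, miss)
    to <- "G"
    off <- (L - 3L) + miss
  } else {
    stop("unknown effect class: ", effect)
  }
  ## map site-oriented offset to a genomic plus-strand SNV
  if (truth_row$strand == "+") {
    pos <- truth_row$start + off
    ref <- from; alt <- to
  } else {
    pos <- truth_row$end - off + 1L
    ref <- revcomp(from); alt <- revcomp(to)
  }
  obs <- as.character(Biostrings::subseq(genome[[truth_row$chrom]],
                                         pos, pos))
  if (obs != ref) {
    stop("derived REF inconsistent with genome (internal error)")
  }
  row <- data.frame(chrom = truth_row$chrom, pos = pos, ref = ref,
                    alt = alt, source = "synthetic",
                    intended_effect = effect, stringsAsFactors = FALSE)
  for (nm in names(af)) row[[nm]] <- af[[nm]]
  row
}

#' Write a genome to FASTA
#'
#' @param genome a \code{DNAStringSet}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Write candidates in the unified TSV schema
#'
#' @param sites candidate data.frame
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_candidates <- function(sites, path) {
  cols <- intersect(c(CANDIDATE_COLUMNS, "flank5", "flank3"),
                    names(sites))
  write.table(sites[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Truth table -> unified candidate TSV records
#'
#' @param truth a \code{\link{plant_sites}} truth table
#' @param genome the planted genome (used to fill flanks)
#' @param source predictor label
#' @param flank flank length captured on each side (default 30)
#' @return candidate data.frame in the unified schema
#' @export
truth_to_candidates <- function(truth, genome, source = "synthetic",
                                flank = 30L) {
  out <- truth
  out$source <- source
  out$annotation <- "unknown"
  n <- nrow(out)
  out$flank5 <- out$flank3 <- ""
  for (k in seq_len(n)) {
    L <- length(genome[[out$chrom[k]]])
    lo <- max(1L, out$start[k] - flank + 1L)
    if (out$start[k] >= 1L) {
      out$flank5[k] <- as.character(Biostrings::subseq(
        genome[[out$chrom[k]]], lo, out$start[k]))
    }
    hi <- min(L, out$end[k] + flank)
    if (out$end[k] < L) {
      out$flank3[k] <- as.character(Biostrings::subseq(
        genome[[out$chrom[k]]], out$end[k] + 1L, hi))
    }
  }
  out[, c(CANDIDATE_COLUMNS[CANDIDATE_COLUMNS %in% names(out)],
          "flank5", "flank3")]
}
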