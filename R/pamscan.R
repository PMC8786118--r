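## Genome scans: canonical off-target search (seed + PAM anchored,
## bulge-aware) and the near-PAM search for NNG/NGN sites that a variant
## could convert into canonical NGG.

as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L) {
    return(Biostrings::readDNAStringSet(genome))
  }
  stop("genome must be a DNAStringSet or a FASTA path")
}

pam_class_of <- function(tri) {
  if (iupac_match(tri, "NGG")) "NGG"
  else if (iupac_match(tri, "NGN")) "NGN"
  else if (iupac_match(tri, "NNG")) "NNG"
  else "other"
}

count_mismatches <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  sum(x != y | y == "N")
}

#' Scan a genome for mismatch-only sites with an NNG or NGN pre-PAM
#'
#' Finds every 20-mer, on both strands, with at most \code{max_mm}
#' mismatches to the spacer, no indels, a conserved SEED, followed by a
#' trinucleotide matching NNG or NGN but not NGG. These are the sites a
#' single substitution in the PAM could turn into canonical cleavable
#' sites. Exhaustive; intended for desk-scale genomes.
#'
#' @param genome DNAStringSet or FASTA path
#' @param guide a \code{guide_rna}
#' @param max_mm maximum mismatch count (default 6)
#' @param seed_len SEED length (default 5)
#' @return data.frame: chrom, start, end (0-based half-open, spacer + PAM),
#'   strand, sequence (guide-oriented 23-mer), M, pam_observed, pam_class
#' @export
scan_near_pam <- function(genome, guide, max_mm = 6L, seed_len = 5L) {
  genome <- as_genome(genome)
  spacer <- Biostrings::DNAString(guide$spacer)
  out <- list()
  for (chrom in names(genome)) {
    subj <- genome[[chrom]]
    L <- length(subj)
    for (strand in c("+", "-")) {
      seqv <- if (strand == "+") subj else
        Biostrings::reverseComplement(subj)
      hits <- Biostrings::matchPattern(spacer, seqv,
                                       max.mismatch = max_mm)
      for (k in seq_along(hits)) {
        s <- Biostrings::start(hits)[k]
        if (s + 22L > length(seqv)) next
        prot <- as.character(Biostrings::subseq(seqv, s, s + 19L))
        if (substr(prot, 21L - seed_len, 20L) !=
            guide_seed(guide, seed_len)) next
        tri <- as.character(Biostrings::subseq(seqv, s + 20L, s + 22L))
        cls <- pam_class_of(tri)
        if (!cls %in% c("NNG", "NGN")) next
        m <- count_mismatches(guide$spacer, prot)
        if (m > max_mm) next
        start0 <- if (strand == "+") s - 1L else L - (s + 22L)
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = start0, end = start0 + 23L,
          strand = strand, sequence = paste0(prot, tri),
          M = m, pam_observed = tri, pam_class = cls,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      sequence = character(0), M = integer(0),
                      pam_observed = character(0),
                      pam_class = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Seed-and-PAM-anchored bulge-aware off-target scan
#'
#' Finds candidate sites with up to \code{policy$max_mismatches}
#' mismatches and up to \code{policy$max_indels} indels whose SEED is
#' conserved and whose PAM matches the policy pattern. The scan anchors on
#' exact SEED + PAM occurrences and extends PAM-distal windows of every
#' supported length with the banded aligner, so it can only recover sites
#' with a conserved SEED (which the inclusion filters require anyway).
#'
#' @param genome DNAStringSet or FASTA path
#' @param guide a \code{guide_rna}
#' @param policy a \code{\link{filter_policy}}
#' @return data.frame like \code{\link{scan_near_pam}} plus an I column
#' @export
scan_offtargets <- function(genome, guide, policy = filter_policy()) {
  genome <- as_genome(genome)
  seed <- guide_seed(guide, policy$seed_len)
  anchor <- Biostrings::DNAString(paste0(seed, policy$pam_pattern))
  out <- list()
  for (chrom in names(genome)) {
    subj <- genome[[chrom]]
    L <- length(subj)
    for (strand in c("+", "-")) {
      seqv <- if (strand == "+") subj else
        Biostrings::reverseComplement(subj)
      hits <- Biostrings::matchPattern(anchor, seqv, fixed = FALSE)
      for (k in seq_along(hits)) {
        pam_end <- Biostrings::end(hits)[k]       # end of PAM
        ## among windows of every supported length that pass the policy,
        ## keep the lexicographically best (fewest indels, then fewest
        ## mismatches); a PAM position yields at most one site
        best <- NULL
        for (tlen in (18:22)) {                   # target spacer lengths
          st <- pam_end - 2L - tlen               # window start
          if (st < 1L) next
          cand <- as.character(Biostrings::subseq(seqv, st, pam_end))
          a <- align_candidate(guide, cand)
          if (a$M > policy$max_mismatches || a$I > policy$max_indels) next
          if (policy$require_seed &&
              !seed_conserved(a, policy$seed_len)) next
          if (is.null(best) ||
              (a$I * 1024L + a$M) < (best$a$I * 1024L + best$a$M)) {
            best <- list(a = a, st = st)
          }
        }
        if (is.null(best)) next
        a <- best$a
        wlen <- nchar(a$target_raw)
        start0 <- if (strand == "+") best$st - 1L else
          L - (best$st - 1L) - wlen
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = start0, end = start0 + wlen,
          strand = strand, sequence = a$target_raw,
          M = a$M, I = a$I, pam_observed = a$pam_observed,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      sequence = character(0), M = integer(0),
                      I = integer(0), pam_observed = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[!duplicated(paste(res$chrom, res$start, res$end,
                               res$strand)), , drop = FALSE]
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Variants that create a canonical PAM
#'
#' For each site (normally from \code{\link{scan_near_pam}}) and each
#' variant falling inside its PAM trinucleotide, checks whether
#' substituting ALT turns the observed PAM into NGG.
#'
#' @param sites data.frame with chrom, start, end, strand, pam_observed
#' @param variants frequency data.frame (genomic plus-strand records)
#' @return data.frame of (site, variant) pairs with the created PAM and the
#'   variant's frequency columns
#' @export
pam_creation_check <- function(sites, variants) {
  out <- list()
  af_cols <- grep("^af_", names(variants), value = TRUE)
  for (k in seq_len(nrow(sites))) {
    site <- sites[k, , drop = FALSE]
    ## genomic plus-strand span of the PAM trinucleotide (0-based)
    pam_lo <- if (site$strand == "+") site$end - 3L else site$start
    pam_hi <- pam_lo + 3L
    touch <- variants$chrom == site$chrom &
      variants$pos <= pam_hi &
      (variants$pos + nchar(variants$ref) - 1L) >= pam_lo + 1L
    for (vi in which(touch)) {
      v <- variants[vi, , drop = FALSE]
      if (nchar(v$ref) != nchar(v$alt)) next  # PAM must stay 3 bp
      ## build the plus-strand PAM, substitute, re-orient
      pam_plus <- if (site$strand == "+") site$pam_observed else
        revcomp(site$pam_observed)
      off <- v$pos - 1L - pam_lo
      lo <- max(0L, off); hi <- min(3L, off + nchar(v$ref))
      if (lo >= hi) next
      ref_in <- substr(v$ref, lo - off + 1L, hi - off)
      alt_in <- substr(v$alt, lo - off + 1L, hi - off)
      if (substr(pam_plus, lo + 1L, hi) != ref_in) {
        stop(sprintf("REF mismatch in PAM at %s:%d (stored %s, REF %s)",
                     v$chrom, v$pos, substr(pam_plus, lo + 1L, hi),
                     ref_in))
      }
      new_plus <- paste0(substr(pam_plus, 1L, lo), alt_in,
                         substr(pam_plus, hi + 1L, 3L))
      new_pam <- if (site$strand == "+") new_plus else revcomp(new_plus)
      if (!iupac_match(site$pam_observed, "NGG") &&
          iupac_match(new_pam, "NGG")) {
        row <- data.frame(
          site$chrom, site$start, site$end, site$strand,
          sequence = site$sequence, pam_before = site$pam_observed,
          created_pam = new_pam, pos = v$pos, ref = v$ref, alt = v$alt,
          stringsAsFactors = FALSE)
        names(row)[1:4] <- c("chrom", "start", "end", "strand")
        for (cc in af_cols) row[[cc]] <- v[[cc]]
        out[[length(out) + 1L]] <- row
      }
    }
  }
  if (!length(out)) {
    base <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), strand = character(0),
                       sequence = character(0), pam_before = character(0),
                       created_pam = character(0), pos = integer(0),
                       ref = character(0), alt = character(0),
                       stringsAsFactors = FALSE)
    for (cc in af_cols) base[[cc]] <- numeric(0)
    return(base)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
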