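## Bulge-aware alignment of a candidate off-target to the guide.
##
## A guide_alignment holds a per-column correspondence between the 20-nt
## spacer and the candidate protospacer, plus the observed PAM. Column ops:
##   match / mismatch         spacer base paired with a target base
##   deletion_in_target       spacer base with no target partner ('-')
##   insertion_in_target      extra target base with no spacer partner
## The PAM trinucleotide is carried separately and may never be gapped.

new_guide_alignment <- function(guide, columns, pam_observed, target_raw) {
  m <- sum(columns$op == "mismatch")
  i <- sum(columns$op %in% c("insertion_in_target", "deletion_in_target"))
  structure(
    list(
      guide = guide,
      columns = columns,
      pam_observed = pam_observed,
      M = m,
      I = i,
      target_raw = target_raw
    ),
    class = "guide_alignment"
  )
}

#' @export
print.guide_alignment <- function(x, ...) {
  cat(sprintf("guide_alignment M=%d I=%d PAM=%s seed=%s\n", x$M, x$I,
              x$pam_observed, seed_conserved(x)))
  cat(" guide : ", gapped_guide(x), "\n", sep = "")
  cat(" target: ", gapped_target(x), "|", x$pam_observed, "\n", sep = "")
  invisible(x)
}

#' Gapped guide / target strings of an alignment
#'
#' \code{gapped_target} includes the PAM; removing gaps from it
#' reconstructs the input sequence exactly.
#'
#' @param a a \code{guide_alignment}
#' @return character scalar
#' @export
gapped_target <- function(a) {
  paste0(paste(a$columns$target_base, collapse = ""), a$pam_observed)
}

#' @rdname gapped_target
#' @export
gapped_guide <- function(a) {
  paste(ifelse(is.na(a$columns$guide_base), "-", a$columns$guide_base),
        collapse = "")
}

validate_candidate_chars <- function(seq, allow_gap = TRUE) {
  pat <- if (allow_gap) "[^ACGTN-]" else "[^ACGTN]"
  if (grepl(pat, seq)) {
    stop("invalid character in candidate sequence: ", seq, call. = FALSE)
  }
}

#' Parse a gapped candidate sequence against a guide
#'
#' Interprets predictor-style gapped notation: the final three columns are
#' the PAM (never gapped), '-' in the spacer region marks a deletion in the
#' target, and ungapped sequences longer than 23 nt imply insertions in the
#' target whose placement is re-derived with the banded aligner. Sequences
#' that combine explicit gaps with implied insertions are rejected as
#' unsupported notation.
#'
#' @param guide a \code{guide_rna}
#' @param gapped_seq candidate sequence, 21-25 characters counting gaps,
#'   alphabet A/C/G/T/N plus '-'
#' @return a \code{guide_alignment}
#' @examples
#' g <- guide_rna("GCTCTAGGCCGAAGTGTCGC")
#' a <- parse_gapped(g, "GCTC-AGGCTGAAGGGTCGCAGG")
#' c(a$M, a$I)  # 2 mismatches, 1 indel
#' @export
parse_gapped <- function(guide, gapped_seq) {
  stopifnot(inherits(guide, "guide_rna"))
  gapped_seq <- toupper(gapped_seq)
  validate_candidate_chars(gapped_seq)
  L <- nchar(gapped_seq)
  if (L < 21L || L > 25L) {
    stop("candidate length must be in [21, 25] counting gaps, got ", L)
  }
  pam <- substr(gapped_seq, L - 2L, L)
  if (grepl("-", pam, fixed = TRUE)) {
    stop("gap inside PAM trinucleotide: ", gapped_seq)
  }
  spacer_part <- substr(gapped_seq, 1L, L - 3L)
  if (!grepl("-", spacer_part, fixed = TRUE)) {
    return(align_candidate(guide, gapped_seq))
  }
  cols <- strsplit(spacer_part, "")[[1]]
  ndel <- sum(cols == "-")
  n_ins <- (length(cols) - ndel) - 20L + ndel
  if (n_ins != 0L) {
    stop("gapped sequence implies both deletions and insertions; ",
         "this notation is unsupported, supply the raw sequence instead")
  }
  gb <- strsplit(guide$spacer, "")[[1]]
  columns <- data.frame(
    column = seq_along(cols),
    guide_pos = seq_along(cols),
    guide_base = gb,
    target_base = cols,
    op = ifelse(cols == "-", "deletion_in_target",
                ifelse(cols == gb & cols %in% DNA_BASES, "match", "mismatch")),
    stringsAsFactors = FALSE
  )
  new_guide_alignment(guide, columns, pam, ungap(gapped_seq))
}

#' Align a raw candidate sequence to the guide
#'
#' Banded dynamic programming (band width 2 around the diagonal) between
#' the 20-nt spacer and the candidate minus its final three PAM bases.
#' The objective is lexicographic: minimise the indel count first, then
#' the mismatch count; ties are broken by pushing indels PAM-distal
#' (toward guide position 1). N bases in the target always count as
#' mismatches.
#'
#' @param guide a \code{guide_rna}
#' @param raw_seq ungapped candidate sequence, 21-25 nt including the PAM
#' @return a \code{guide_alignment}
#' @examples
#' g <- guide_rna("GCTCTAGGCCGAAGTGTCGC")
#' a <- align_candidate(g, "GCTCAGGCTGAAGGGTCGCAGG")
#' c(a$M, a$I)  # 2, 1
#' @export
align_candidate <- function(guide, raw_seq) {
  stopifnot(inherits(guide, "guide_rna"))
  raw_seq <- toupper(raw_seq)
  validate_candidate_chars(raw_seq, allow_gap = FALSE)
  L <- nchar(raw_seq)
  if (L < 21L || L > 25L) {
    stop("unsupported candidate length ", L, " (must be 21-25)")
  }
  pam <- substr(raw_seq, L - 2L, L)
  tsp <- substr(raw_seq, 1L, L - 3L)
  g <- strsplit(guide$spacer, "")[[1]]
  t <- strsplit(tsp, "")[[1]]
  n <- length(t)

  ## cost packs (indels, mismatches) into one integer for lexicographic
  ## comparison; indel unit dwarfs any attainable mismatch count
  IND <- 1024L
  BIG <- .Machine$integer.max %/% 4L
  band <- 2L
  D <- matrix(BIG, nrow = 21L, ncol = n + 1L)
  D[1L, 1L] <- 0L
  for (j in seq_len(min(band, n))) D[1L, j + 1L] <- j * IND
  for (i in seq_len(min(band, 20L))) D[i + 1L, 1L] <- i * IND
  for (i in seq_len(20L)) {
    jlo <- max(1L, i - band)
    jhi <- min(n, i + band)
    if (jlo > jhi) next
    for (j in jlo:jhi) {
      sub <- D[i, j] + (if (g[i] == t[j] && t[j] != "N") 0L else 1L)
      del <- if (abs((i - 1L) - j) <= band) D[i, j + 1L] + IND else BIG
      ins <- if (abs(i - (j - 1L)) <= band) D[i + 1L, j] + IND else BIG
      D[i + 1L, j + 1L] <- min(sub, del, ins)
    }
  }
  if (D[21L, n + 1L] >= BIG) {
    stop("no alignment within band for candidate: ", raw_seq)
  }

  ## traceback from the PAM end; preferring the diagonal on ties pushes
  ## indel columns toward guide position 1 (PAM-distal)
  i <- 20L; j <- n
  ops <- character(0); gpos <- integer(0); gbase <- character(0)
  tbase <- character(0)
  while (i > 0L || j > 0L) {
    cur <- D[i + 1L, j + 1L]
    if (i > 0L && j > 0L &&
        cur == D[i, j] + (if (g[i] == t[j] && t[j] != "N") 0L else 1L)) {
      ops <- c(if (g[i] == t[j] && t[j] != "N") "match" else "mismatch", ops)
      gpos <- c(i, gpos); gbase <- c(g[i], gbase); tbase <- c(t[j], tbase)
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && cur == D[i, j + 1L] + IND) {
      ops <- c("deletion_in_target", ops)
      gpos <- c(i, gpos); gbase <- c(g[i], gbase); tbase <- c("-", tbase)
      i <- i - 1L
    } else if (j > 0L && cur == D[i + 1L, j] + IND) {
      ops <- c("insertion_in_target", ops)
      gpos <- c(NA_integer_, gpos); gbase <- c(NA_character_, gbase)
      tbase <- c(t[j], tbase)
      j <- j - 1L
    } else {
      stop("internal error: traceback failed")
    }
  }
  columns <- data.frame(
    column = seq_along(ops), guide_pos = gpos, guide_base = gbase,
    target_base = tbase, op = ops, stringsAsFactors = FALSE
  )
  new_guide_alignment(guide, columns, pam, raw_seq)
}

## Build an alignment from an explicit gapped guide/target pair (both
## spacer-region only, equal length; PAM supplied separately). Used to
## reproduce alignments chosen by external predictors when they differ
## from the DP optimum.
pair_alignment <- function(guide, gapped_guide_str, gapped_target_str, pam) {
  gg <- strsplit(toupper(gapped_guide_str), "")[[1]]
  tt <- strsplit(toupper(gapped_target_str), "")[[1]]
  stopifnot(length(gg) == length(tt))
  if (paste(gg[gg != "-"], collapse = "") != guide$spacer) {
    stop("gapped guide does not reconstruct the spacer")
  }
  if (any(gg == "-" & tt == "-")) stop("double-gap column")
  gpos <- ifelse(gg == "-", NA_integer_, cumsum(gg != "-"))
  op <- ifelse(gg == "-", "insertion_in_target",
        ifelse(tt == "-", "deletion_in_target",
        ifelse(gg == tt & tt %in% DNA_BASES, "match", "mismatch")))
  columns <- data.frame(
    column = seq_along(gg), guide_pos = as.integer(gpos),
    guide_base = ifelse(gg == "-", NA_character_, gg),
    target_base = tt, op = op, stringsAsFactors = FALSE
  )
  new_guide_alignment(guide, columns,
                      toupper(pam),
                      paste0(paste(tt[tt != "-"], collapse = ""),
                             toupper(pam)))
}

#' Is the SEED region conserved?
#'
#' TRUE iff the \code{seed_len} PAM-proximal guide positions (16-20 for the
#' default) are all match columns, with no indel column among or between
#' them (including insertions between position 20 and the PAM).
#'
#' @param a a \code{guide_alignment}
#' @param seed_len number of PAM-proximal positions checked (default 5)
#' @return logical
#' @export
seed_conserved <- function(a, seed_len = 5L) {
  stopifnot(inherits(a, "guide_alignment"))
  if (seed_len < 1L || seed_len > 20L) {
    stop("seed_len must be in [1, 20]")
  }
  first_pos <- 21L - seed_len
  idx <- which(!is.na(a$columns$guide_pos) &
               a$columns$guide_pos >= first_pos)
  if (length(idx) == 0L) return(FALSE)
  span <- min(idx):nrow(a$columns)
  all(a$columns$op[span] == "match")
}

#' Does the observed PAM match a pattern?
#'
#' @param a a \code{guide_alignment}
#' @param pattern IUPAC trinucleotide (default "NGG")
#' @return logical
#' @export
pam_check <- function(a, pattern = "NGG") {
  stopifnot(inherits(a, "guide_alignment"))
  iupac_match(a$pam_observed, pattern)
}

#' Positional mismatch/indel profile over a set of alignments
#'
#' Counts, for each aligned column position 1-25, how many alignments carry
#' a mismatch, an insertion or a deletion there. The PAM occupies the final
#' three columns of each alignment, anywhere between positions 19 and 25
#' depending on candidate length.
#'
#' @param alignments a list of \code{guide_alignment} objects
#' @return a 25 x 3 integer matrix with columns mismatch/insertion/deletion
#' @export
position_profile <- function(alignments) {
  if (length(alignments) == 0L) stop("empty alignment list")
  prof <- matrix(0L, nrow = 25L, ncol = 3L,
                 dimnames = list(position = 1:25,
                                 op = c("mismatch", "insertion", "deletion")))
  opcol <- c(mismatch = 1L, insertion_in_target = 2L,
             deletion_in_target = 3L)
  for (a in alignments) {
    stopifnot(inherits(a, "guide_alignment"))
    cc <- a$columns
    for (k in which(cc$op != "match")) {
      j <- opcol[[cc$op[k]]]
      prof[cc$column[k], j] <- prof[cc$column[k], j] + 1L
    }
  }
  prof
}
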