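## CFD (cutting frequency determination) scoring.
##
## The mismatch and PAM activity fractions are the published empirical
## values of Doench et al. (2016), bundled as a plain-text resource
## (inst/extdata/cfd_penalties.tsv) together with per-position bulge
## activities. Keys:
##   mismatch  (guide position 1-20 from the 5' end, guide base, target base)
##   pam       (observed trinucleotide; only the last two bases matter)
##   insertion (gapped-guide coordinate of the gap column, inserted base)
##   deletion  (guide position of the deleted base, deleted guide base)
## The insertion/deletion key convention was fixed empirically against the
## worked examples the indel extension was published with; see the methods
## vignette.

#' Load CFD penalty tables
#'
#' @param resource path to a penalty TSV with columns
#'   \code{kind, position, guide_base, target_base, activity}; by default the
#'   bundled Doench activity resource.
#' @return an object of class \code{penalty_tables}: lookup vectors for
#'   mismatch, PAM, insertion and deletion penalties plus the resource
#'   checksum (md5, logged into audit reports for provenance).
#' @examples
#' pt <- load_penalties()
#' pt$pam[["AGG"]]  # canonical PAM, activity 1
#' @export
load_penalties <- function(resource = NULL) {
  if (is.null(resource)) {
    resource <- system.file("extdata", "cfd_penalties.tsv",
                            package = "crisprAudit", mustWork = TRUE)
  }
  df <- read.delim(resource, stringsAsFactors = FALSE,
                   colClasses = c("character", "integer", "character",
                                  "character", "numeric"))
  need <- c("kind", "position", "guide_base", "target_base", "activity")
  if (!identical(names(df), need)) {
    stop("malformed penalty resource: expected columns ",
         paste(need, collapse = ", "))
  }
  if (any(is.na(df$activity)) || any(df$activity < 0) ||
      any(df$activity > 1)) {
    stop("penalty activities must all lie in [0, 1]")
  }
  bad <- setdiff(unique(df$kind), c("mismatch", "pam", "insertion",
                                    "deletion"))
  if (length(bad)) stop("unknown penalty kind: ", paste(bad, collapse = ","))

  mm <- df[df$kind == "mismatch", ]
  mismatch <- setNames(mm$activity,
                       paste0(mm$position, ":", mm$guide_base, ">",
                              mm$target_base))
  ## completeness: all 20 positions x 12 ordered base pairs
  pairs <- expand.grid(g = DNA_BASES, t = DNA_BASES, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$g != pairs$t, ]
  expect <- as.vector(outer(1:20, paste0(pairs$g, ">", pairs$t),
                            paste, sep = ":"))
  missing <- setdiff(expect, names(mismatch))
  if (length(missing)) {
    stop("penalty resource lacks mismatch entries: ",
         paste(head(missing, 5), collapse = ", "))
  }

  pam_df <- df[df$kind == "pam", ]
  pam <- setNames(pam_df$activity, pam_df$target_base)
  ins <- df[df$kind == "insertion", ]
  del <- df[df$kind == "deletion", ]
  structure(
    list(
      mismatch = mismatch,
      pam = pam,
      insertion = setNames(ins$activity,
                           paste0(ins$position, ":", ins$target_base)),
      deletion = setNames(del$activity,
                          paste0(del$position, ":", del$guide_base)),
      checksum = unname(tools::md5sum(resource)),
      resource = resource
    ),
    class = "penalty_tables"
  )
}

#' Uniform penalty tables for property testing
#'
#' Every mismatch, insertion and deletion entry takes the given value; PAM
#' entries are 1 for NGG trinucleotides and \code{value} otherwise. Under
#' this table \code{cfd_mismatch} has the closed form
#' \code{value^M * pam}.
#'
#' @param value activity assigned to every non-match event (default 0.5)
#' @return a \code{penalty_tables}
#' @export
uniform_penalties <- function(value = 0.5) {
  stopifnot(value >= 0, value <= 1)
  pairs <- expand.grid(g = DNA_BASES, t = DNA_BASES,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$g != pairs$t, ]
  mm_keys <- as.vector(outer(1:20, paste0(pairs$g, ">", pairs$t),
                             paste, sep = ":"))
  tri <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste0,
               collapse = "")
  pam <- setNames(ifelse(substr(tri, 2, 3) == "GG", 1, value), tri)
  pos <- 1:25
  structure(
    list(
      mismatch = setNames(rep(value, length(mm_keys)), mm_keys),
      pam = pam,
      insertion = setNames(rep(value, length(pos) * 4),
                           as.vector(outer(pos, DNA_BASES, paste,
                                           sep = ":"))),
      deletion = setNames(rep(value, length(pos) * 4),
                          as.vector(outer(pos, DNA_BASES, paste,
                                          sep = ":"))),
      checksum = NA_character_,
      resource = sprintf("uniform(%s)", format(value))
    ),
    class = "penalty_tables"
  )
}

lookup_penalty <- function(tab, key, what) {
  v <- tab[key]
  if (any(is.na(v))) {
    stop("no ", what, " penalty for key ",
         paste(key[is.na(v)], collapse = ", "))
  }
  unname(v)
}

#' CFD mismatch score
#'
#' Product over mismatch columns of the per-position activity fractions,
#' times the PAM activity of the observed trinucleotide. Indel columns are
#' ignored here (they are priced by \code{\link{cfd_indel}}).
#'
#' @param a a \code{guide_alignment}
#' @param tables a \code{penalty_tables}
#' @return numeric in [0, 1]
#' @export
cfd_mismatch <- function(a, tables) {
  stopifnot(inherits(a, "guide_alignment"),
            inherits(tables, "penalty_tables"))
  cc <- a$columns[a$columns$op == "mismatch", ]
  s <- 1
  if (nrow(cc)) {
    tb <- cc$target_base
    tb[tb == "N"] <- NA  # N never scored as a concrete base
    if (any(is.na(tb))) {
      stop("cannot score mismatch against N base at guide position ",
           paste(cc$guide_pos[is.na(tb)], collapse = ","))
    }
    keys <- paste0(cc$guide_pos, ":", cc$guide_base, ">", tb)
    s <- prod(lookup_penalty(tables$mismatch, keys, "mismatch"))
  }
  s * lookup_penalty(tables$pam, a$pam_observed, "PAM")
}

#' CFD indel score
#'
#' Not applicable (NA, rendered "-") when the alignment has no indel
#' columns. Otherwise the product over indel columns of the bulge
#' activities: insertions are indexed by the gapped-guide coordinate of the
#' gap column and the inserted target base; deletions by the guide position
#' and identity of the deleted guide base. Mismatch columns are ignored.
#'
#' @inheritParams cfd_mismatch
#' @return numeric in [0, 1], or \code{NA_real_} when I = 0
#' @export
cfd_indel <- function(a, tables) {
  stopifnot(inherits(a, "guide_alignment"),
            inherits(tables, "penalty_tables"))
  if (a$I == 0L) return(NA_real_)
  cc <- a$columns
  s <- 1
  ins <- cc[cc$op == "insertion_in_target", ]
  if (nrow(ins)) {
    ## gapped-guide coordinate = column index minus preceding target-only
    ## columns... the alignment column index IS the gapped guide coordinate
    keys <- paste0(ins$column, ":", ins$target_base)
    s <- s * prod(lookup_penalty(tables$insertion, keys, "insertion"))
  }
  del <- cc[cc$op == "deletion_in_target", ]
  if (nrow(del)) {
    keys <- paste0(del$guide_pos, ":", del$guide_base)
    s <- s * prod(lookup_penalty(tables$deletion, keys, "deletion"))
  }
  s
}

#' Final cleavage-probability score and tier
#'
#' Multiplies the independent mismatch and indel event probabilities.
#' Tier thresholds (0.2 and 0.023) are applied to the unrounded value;
#' three-decimal rounding is display-only.
#'
#' @param mm CFD mismatch score
#' @param indel CFD indel score or NA when not applicable
#' @param thresholds numeric length-2: the upper and lower cleavage
#'   probability cut-offs
#' @return a \code{score_result} with fields \code{cfd_mm},
#'   \code{cfd_indel}, \code{cfd_final}, \code{tier}
#' @examples
#' cfd_final(0.419, 0.328)$cfd_final  # 0.138 at 3 dp
#' @export
cfd_final <- function(mm, indel = NA_real_, thresholds = c(0.2, 0.023)) {
  stopifnot(mm >= 0, mm <= 1, is.na(indel) || (indel >= 0 && indel <= 1))
  final <- mm * (if (is.na(indel)) 1 else indel)
  tier <- if (final >= thresholds[1]) "above_0.2"
          else if (final >= thresholds[2]) "between_0.023_and_0.2"
          else "below_0.023"
  structure(list(cfd_mm = mm, cfd_indel = indel, cfd_final = final,
                 tier = tier),
            class = "score_result")
}

#' Score one alignment end-to-end
#'
#' @param a a \code{guide_alignment}
#' @param tables a \code{penalty_tables}
#' @inheritParams cfd_final
#' @return a \code{score_result}
#' @export
score_alignment <- function(a, tables, thresholds = c(0.2, 0.023)) {
  cfd_final(cfd_mismatch(a, tables), cfd_indel(a, tables), thresholds)
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("CFD %s  INDEL %s  FINAL %s %s\n",
              format_cfd(x$cfd_mm), format_cfd(x$cfd_indel),
              format_cfd(x$cfd_final), tier_marker(x$tier)))
  invisible(x)
}

#' Render a CFD value the way reports print it
#'
#' Three decimal places; "-" for a not-applicable indel score.
#'
#' @param x numeric (possibly NA)
#' @return character
#' @export
format_cfd <- function(x) {
  ifelse(is.na(x), "-", sprintf("%.3f", x))
}

#' Tier marker used in score tables
#'
#' "**" for final scores at or above the upper threshold, "*" for scores
#' between the thresholds, "" below.
#'
#' @param tier a tier string from \code{\link{cfd_final}}
#' @return character
#' @export
tier_marker <- function(tier) {
  c(above_0.2 = "**", between_0.023_and_0.2 = "*",
    below_0.023 = "")[tier]
}
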