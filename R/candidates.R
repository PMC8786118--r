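## Candidate off-target tables: ingest, merge, filter, annotate.
##
## The unified candidate schema (one TSV per predictor) has columns
##   id, chrom, start, end, strand, sequence, source, annotation
## and optionally flank5, flank3. Coordinates are 0-based half-open
## (BED-like); sequences are guide-oriented, '-' gaps allowed; flank5 and
## flank3 are genomic plus-strand context immediately left/right of the
## interval. Reports render coordinates 1-based inclusive.

CANDIDATE_COLUMNS <- c("id", "chrom", "start", "end", "strand", "sequence",
                       "source", "annotation")

#' Read a unified candidate table
#'
#' @param path TSV path (or a data.frame already in the schema)
#' @return a validated candidate data.frame
#' @export
read_candidates <- function(path) {
  df <- if (is.data.frame(path)) path else {
    read.delim(path, stringsAsFactors = FALSE,
               colClasses = "character")
  }
  missing <- setdiff(CANDIDATE_COLUMNS, names(df))
  if (length(missing)) {
    stop("candidate table lacks columns: ", paste(missing, collapse = ", "))
  }
  df$id <- as.character(df$id)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$sequence <- toupper(df$sequence)
  if (!all(df$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  if (!"flank5" %in% names(df)) df$flank5 <- character(nrow(df))
  if (!"flank3" %in% names(df)) df$flank3 <- character(nrow(df))
  df$flank5 <- toupper(ifelse(is.na(df$flank5), "", df$flank5))
  df$flank3 <- toupper(ifelse(is.na(df$flank3), "", df$flank3))
  bad <- grepl("[^ACGTN-]", df$sequence)
  if (any(bad)) {
    stop("invalid characters in sequence for id ",
         paste(df$id[bad], collapse = ", "))
  }
  lens <- nchar(ungap(df$sequence))
  off <- df$end - df$start != lens
  if (any(off)) {
    stop("interval width disagrees with ungapped sequence length for id ",
         paste(df$id[off], collapse = ", "))
  }
  df[, c(CANDIDATE_COLUMNS, "flank5", "flank3")]
}

#' Merge predictor outputs into one candidate set
#'
#' One record is kept per (chrom, start, end, strand); the source sets are
#' unioned. Two predictors reporting different sequences at the same locus
#' is a data error.
#'
#' @param tables list of TSV paths or data.frames in the unified schema
#' @return merged candidate data.frame
#' @export
merge_predictions <- function(tables) {
  dfs <- lapply(tables, read_candidates)
  all <- do.call(rbind, dfs)
  key <- paste(all$chrom, all$start, all$end, all$strand, sep = "\r")
  out <- do.call(rbind, lapply(split(all, factor(key, levels = unique(key))),
                               function(g) {
    if (length(unique(ungap(g$sequence))) != 1L) {
      stop("conflicting sequences reported at locus ",
           render_locus(g$chrom[1], g$start[1], g$end[1]))
    }
    r <- g[1L, , drop = FALSE]
    r$source <- paste(sort(unique(unlist(strsplit(g$source, ",")))),
                      collapse = ",")
    known <- g$annotation[!g$annotation %in% c("", "unknown", NA)]
    r$annotation <- if (length(known)) known[1] else "unknown"
    ## keep the most informative notation (gapped beats raw)
    gapped <- g$sequence[grepl("-", g$sequence, fixed = TRUE)]
    if (length(gapped)) r$sequence <- gapped[1]
    r
  }))
  rownames(out) <- NULL
  out
}

#' Filtering policy
#'
#' Defaults reproduce the inclusion criteria of the audit: up to 6
#' mismatches, up to 2 indels, conserved 5-nt SEED, canonical NGG PAM.
#'
#' @param max_mismatches maximum mismatch count M
#' @param max_indels maximum indel count I
#' @param require_seed require SEED conservation
#' @param pam_pattern IUPAC PAM pattern candidates must match
#' @param seed_len SEED length in nt
#' @return a \code{filter_policy}
#' @export
filter_policy <- function(max_mismatches = 6L, max_indels = 2L,
                          require_seed = TRUE, pam_pattern = "NGG",
                          seed_len = 5L) {
  structure(list(max_mismatches = as.integer(max_mismatches),
                 max_indels = as.integer(max_indels),
                 require_seed = isTRUE(require_seed),
                 pam_pattern = pam_pattern,
                 seed_len = as.integer(seed_len)),
            class = "filter_policy")
}

#' Align every candidate to the guide
#'
#' Gapped sequences go through \code{\link{parse_gapped}}, raw sequences
#' through \code{\link{align_candidate}}. Unalignable records yield NULL
#' with the error recorded.
#'
#' @param sites candidate data.frame
#' @param guide a \code{guide_rna}
#' @return list with \code{alignments} (named by id) and \code{errors}
#' @export
align_candidates <- function(sites, guide) {
  alignments <- vector("list", nrow(sites))
  names(alignments) <- sites$id
  errors <- character(0)
  for (k in seq_len(nrow(sites))) {
    a <- tryCatch(parse_gapped(guide, sites$sequence[k]),
                  error = function(e) conditionMessage(e))
    if (is.character(a)) {
      errors[sites$id[k]] <- a
    } else {
      alignments[[k]] <- a
    }
  }
  list(alignments = alignments, errors = errors)
}

#' Apply the inclusion filters
#'
#' A candidate is retained iff M <= max_mismatches, I <= max_indels, the
#' SEED is conserved (when required) and the PAM matches the policy
#' pattern. Unalignable records are rejected with a reason, never fatal.
#'
#' @param sites candidate data.frame
#' @param guide a \code{guide_rna}
#' @param policy a \code{\link{filter_policy}}
#' @return list: \code{retained} (data.frame with M, I, seed, pam columns),
#'   \code{alignments} (named list for retained ids), \code{rejected}
#'   (data.frame with a reason column)
#' @export
apply_filters <- function(sites, guide, policy = filter_policy()) {
  al <- align_candidates(sites, guide)
  keep <- logical(nrow(sites))
  reason <- character(nrow(sites))
  M <- I <- rep(NA_integer_, nrow(sites))
  seed <- pam <- rep(NA, nrow(sites))
  pam_obs <- rep(NA_character_, nrow(sites))
  for (k in seq_len(nrow(sites))) {
    a <- al$alignments[[k]]
    if (is.null(a)) {
      reason[k] <- paste0("unalignable: ", al$errors[[sites$id[k]]])
      next
    }
    M[k] <- a$M; I[k] <- a$I
    seed[k] <- seed_conserved(a, policy$seed_len)
    pam[k] <- pam_check(a, policy$pam_pattern)
    pam_obs[k] <- a$pam_observed
    if (a$M > policy$max_mismatches) {
      reason[k] <- sprintf("M=%d exceeds %d", a$M, policy$max_mismatches)
    } else if (a$I > policy$max_indels) {
      reason[k] <- sprintf("I=%d exceeds %d", a$I, policy$max_indels)
    } else if (policy$require_seed && !seed[k]) {
      reason[k] <- "SEED not conserved"
    } else if (!pam[k]) {
      reason[k] <- paste0("PAM ", pam_obs[k], " does not match ",
                          policy$pam_pattern)
    } else {
      keep[k] <- TRUE
    }
  }
  res <- cbind(sites, M = M, I = I, seed_conserved = seed,
               pam_ok = pam, pam_observed = pam_obs,
               stringsAsFactors = FALSE)
  retained <- res[keep, , drop = FALSE]
  rejected <- cbind(res[!keep, , drop = FALSE],
                    reason = reason[!keep], stringsAsFactors = FALSE)
  rownames(retained) <- rownames(rejected) <- NULL
  list(retained = retained,
       alignments = al$alignments[retained$id],
       rejected = rejected)
}

sites_granges <- function(sites) {
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$start + 1L, end = sites$end),
    strand = sites$strand
  )
}

read_intervals <- function(x) {
  if (inherits(x, "GRanges")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (grepl("\\.out$", x)) return(read_repeatmasker_out(x))
    return(rtracklayer::import(x))
  }
  stop("expected a GRanges, a BED/GFF path, or a RepeatMasker .out path")
}

#' Annotate candidates as genic / intergenic / pseudogene
#'
#' Any overlap with an annotated gene body counts as genic; a feature whose
#' type or biotype says pseudogene yields the pseudogene class. Sites on
#' chromosomes absent from the annotation get class "unknown" with a
#' warning.
#'
#' @param sites candidate data.frame
#' @param genes GRanges, BED or GFF3 path of gene bodies; a \code{name}
#'   (BED), \code{Name}/\code{gene_name}/\code{ID} (GFF) column supplies
#'   gene names, a \code{type}/\code{gene_biotype} column may flag
#'   pseudogenes
#' @return the sites data.frame with \code{annotation} and \code{gene}
#'   columns filled
#' @export
annotate_genic <- function(sites, genes) {
  gr <- read_intervals(genes)
  gr <- GenomicRanges::sort(gr)
  sgr <- sites_granges(sites)
  known <- as.character(GenomicRanges::seqnames(sgr)) %in%
    GenomeInfoDb::seqlevels(gr)
  if (!all(known)) {
    warning("chromosome(s) absent from gene annotation: ",
            paste(unique(sites$chrom[!known]), collapse = ", "))
  }
  mc <- S4Vectors::mcols(gr)
  namecol <- intersect(c("name", "Name", "gene_name", "ID"), names(mc))[1]
  typecol <- intersect(c("gene_biotype", "biotype", "type"), names(mc))[1]
  gname <- if (!is.na(namecol)) as.character(mc[[namecol]]) else
    rep(NA_character_, length(gr))
  gtype <- if (!is.na(typecol)) as.character(mc[[typecol]]) else
    rep("", length(gr))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(sgr, gr, ignore.strand = TRUE))
  sites$annotation <- ifelse(known, "intergenic", "unknown")
  sites$gene <- NA_character_
  if (length(hits)) {
    for (q in unique(S4Vectors::queryHits(hits))) {
      subj <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == q]
      pseudo <- grepl("pseudogene", gtype[subj], ignore.case = TRUE)
      pick <- if (any(!pseudo)) subj[!pseudo][1] else subj[1]
      sites$annotation[q] <- if (all(pseudo)) "pseudogene" else "genic"
      sites$gene[q] <- gname[pick]
    }
  }
  sites
}

#' Groups of identical sequences at distinct loci
#'
#' Groups are keyed by the ungapped, guide-oriented sequence; only groups
#' with at least two distinct loci are reported.
#'
#' @param sites candidate data.frame (normally the retained set)
#' @return data.frame of the member sites with a \code{dup_group} column,
#'   empty when no sequence repeats
#' @export
find_duplicate_sequences <- function(sites) {
  key <- ungap(sites$sequence)
  tab <- table(key)
  dup <- names(tab)[tab >= 2L]
  out <- sites[key %in% dup, , drop = FALSE]
  if (nrow(out)) {
    out$dup_group <- match(ungap(out$sequence), dup)
    out <- out[order(out$dup_group, out$chrom, out$start), , drop = FALSE]
  } else {
    out$dup_group <- integer(0)
  }
  rownames(out) <- NULL
  out
}

#' Flag overlap with repetitive elements
#'
#' "inside" when the site interval itself overlaps a repeat, "near" when
#' only the +/- \code{flank} bp window does, else "none".
#'
#' @param sites candidate data.frame
#' @param repeats GRanges, BED path, or RepeatMasker .out path
#' @param flank window in bp used for the "near" class (default 200)
#' @return sites with \code{repeat_status} and \code{repeat_element}
#' @export
flag_repeats <- function(sites, repeats, flank = 200L) {
  rr <- read_intervals(repeats)
  mc <- S4Vectors::mcols(rr)
  namecol <- intersect(c("name", "Name", "repeat_class", "ID"), names(mc))[1]
  rname <- if (!is.na(namecol)) as.character(mc[[namecol]]) else
    rep(NA_character_, length(rr))
  sgr <- sites_granges(sites)
  inside <- suppressWarnings(
    GenomicRanges::findOverlaps(sgr, rr, ignore.strand = TRUE))
  wide <- suppressWarnings(GenomicRanges::findOverlaps(
    sgr + flank, rr, ignore.strand = TRUE))
  sites$repeat_status <- "none"
  sites$repeat_element <- NA_character_
  for (q in seq_along(sgr)) {
    ih <- S4Vectors::subjectHits(inside)[S4Vectors::queryHits(inside) == q]
    wh <- S4Vectors::subjectHits(wide)[S4Vectors::queryHits(wide) == q]
    if (length(ih)) {
      sites$repeat_status[q] <- "inside"
      sites$repeat_element[q] <- paste(unique(rname[ih]), collapse = "/")
    } else if (length(wh)) {
      sites$repeat_status[q] <- "near"
      sites$repeat_element[q] <- paste(unique(rname[wh]), collapse = "/")
    }
  }
  sites
}

#' Parse a RepeatMasker .out file into GRanges
#'
#' @param path RepeatMasker annotation output
#' @return GRanges with a \code{name} column (repeat class/family)
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  lines <- lines[-seq_len(min(3L, length(lines)))]  # banner + header
  lines <- trimws(lines[nzchar(trimws(lines))])
  if (!length(lines)) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines, "[ \t]+")
  chrom <- vapply(fields, `[[`, "", 5L)
  start <- as.integer(vapply(fields, `[[`, "", 6L))
  end <- as.integer(vapply(fields, `[[`, "", 7L))
  fam <- vapply(fields, `[[`, "", 11L)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  S4Vectors::mcols(gr)$name <- fam
  gr
}
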