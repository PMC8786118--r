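## Population variants: ingest, polymorphic-site calling, overlay.
##
## A variant record is genomic plus-strand: chrom, pos (1-based), ref, alt,
## one allele-frequency column per configured population (af_E, af_LA, ...).
## NA frequency means "absent from that population's database", never zero.

#' Read population variant frequencies
#'
#' Supports two dialects: VCF 4.x with per-population AF INFO keys (the
#' 1000 Genomes style), and a long TSV with columns
#' \code{chrom, pos, ref, alt, population, af} (the auxiliary
#' frequency-table style). Multi-allelic VCF records are split into one
#' biallelic record per ALT; Number=A INFO fields are split along with
#' them.
#'
#' @param path VCF or TSV file
#' @param population_map named character vector mapping population labels
#'   to INFO keys, e.g. \code{c(E = "EUR_AF", LA = "AMR_AF", A = "AFR_AF",
#'   W = "AF")}; ignored for the TSV dialect
#' @param source label recorded on each record (defaults to the file name)
#' @return data.frame: chrom, pos, ref, alt, source and one \code{af_*}
#'   column per population
#' @export
read_frequencies <- function(path, population_map = NULL, source = NULL) {
  first <- readLines(path, n = 1L)
  src <- source %||% basename(path)
  if (grepl("^##fileformat=VCF", first)) {
    if (is.null(population_map) || is.null(names(population_map)) ||
        any(!nzchar(names(population_map)))) {
      stop("population_map with named entries is required for VCF input")
    }
    return(read_frequencies_vcf(path, population_map, src))
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "population", "af")
  if (!all(need %in% names(df))) {
    stop("frequency TSV needs columns: ", paste(need, collapse = ", "))
  }
  df$af <- suppressWarnings(as.numeric(df$af))
  bad <- is.na(df$af) | df$af < 0 | df$af > 1
  if (any(bad)) {
    warning(sum(bad), " record(s) with malformed AF skipped")
    df <- df[!bad, , drop = FALSE]
  }
  pops <- unique(df$population)
  key <- paste(df$chrom, df$pos, df$ref, df$alt, sep = "\r")
  out <- df[!duplicated(key), c("chrom", "pos", "ref", "alt")]
  out$source <- src
  for (p in pops) {
    v <- rep(NA_real_, nrow(out))
    sub <- df[df$population == p, ]
    v[match(paste(sub$chrom, sub$pos, sub$ref, sub$alt, sep = "\r"),
            key[!duplicated(key)])] <- sub$af
    out[[paste0("af_", p)]] <- v
  }
  out$pos <- as.integer(out$pos)
  rownames(out) <- NULL
  out
}

read_frequencies_vcf <- function(path, population_map, src) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  recs <- list()
  nskip <- 0L
  for (ln in body) {
    f <- strsplit(ln, "\t")[[1]]
    if (length(f) < 8L) { nskip <- nskip + 1L; next }
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    info <- strsplit(f[8], ";", fixed = TRUE)[[1]]
    kv <- strsplit(info, "=", fixed = TRUE)
    keys <- vapply(kv, `[[`, "", 1L)
    vals <- vapply(kv, function(x) if (length(x) > 1L) x[2] else "", "")
    afs <- matrix(NA_real_, nrow = length(alts),
                  ncol = length(population_map),
                  dimnames = list(NULL, names(population_map)))
    ok <- TRUE
    for (p in names(population_map)) {
      k <- population_map[[p]]
      if (!k %in% keys) next  # absent population: absent key, not zero
      raw <- strsplit(vals[match(k, keys)], ",", fixed = TRUE)[[1]]
      if (length(raw) != length(alts)) { ok <- FALSE; break }
      num <- suppressWarnings(as.numeric(raw))
      if (any(is.na(num) | num < 0 | num > 1)) { ok <- FALSE; break }
      afs[, p] <- num
    }
    if (!ok) { nskip <- nskip + 1L; next }
    for (ai in seq_along(alts)) {
      recs[[length(recs) + 1L]] <- c(
        list(chrom = f[1], pos = as.integer(f[2]), ref = toupper(f[4]),
             alt = toupper(alts[ai]), source = src),
        as.list(setNames(afs[ai, ], paste0("af_", names(population_map))))
      )
    }
  }
  if (nskip > 0L) {
    warning(nskip, " malformed VCF record(s) skipped")
  }
  if (!length(recs)) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      source = character(0), stringsAsFactors = FALSE)
    for (p in names(population_map)) out[[paste0("af_", p)]] <- numeric(0)
    return(out)
  }
  do.call(rbind, lapply(recs, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
}

#' Flag polymorphic sites
#'
#' A record is polymorphic when its allele frequency is >= \code{threshold}
#' in at least one of the trigger populations. The worldwide frequency is
#' reported but, by default, never triggers the rule.
#'
#' @param records frequency data.frame from \code{\link{read_frequencies}}
#' @param threshold allele-frequency cut-off (default 0.01)
#' @param populations trigger population labels (default E, LA, A)
#' @return records with \code{polymorphic} (logical) and
#'   \code{populations_over_threshold} (comma string) columns
#' @export
polymorphic_filter <- function(records, threshold = 0.01,
                               populations = c("E", "LA", "A")) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  if (!length(populations)) stop("empty population set")
  cols <- paste0("af_", populations)
  have <- cols %in% names(records)
  over <- vapply(seq_len(nrow(records)), function(i) {
    hit <- populations[have][vapply(cols[have], function(cc) {
      v <- records[[cc]][i]
      !is.na(v) && v >= threshold
    }, logical(1))]
    paste(hit, collapse = ",")
  }, character(1))
  records$polymorphic <- nzchar(over)
  records$populations_over_threshold <- over
  records
}

#' Private and shared polymorphic sites per population
#'
#' A site is private to population p iff its frequency is over threshold in
#' p and under threshold (or absent) in every other configured population.
#'
#' @inheritParams polymorphic_filter
#' @return list: \code{private} (named integer vector), \code{shared},
#'   \code{total} (= sum(private) + shared), \code{patterns} (counts per
#'   over-threshold population combination)
#' @export
population_privacy <- function(records, populations = c("E", "LA", "A"),
                               threshold = 0.01) {
  records <- polymorphic_filter(records, threshold, populations)
  poly <- records[records$polymorphic, , drop = FALSE]
  pats <- poly$populations_over_threshold
  private <- setNames(integer(length(populations)), populations)
  shared <- 0L
  for (p in pats) {
    hit <- strsplit(p, ",", fixed = TRUE)[[1]]
    if (length(hit) == 1L) {
      private[hit] <- private[hit] + 1L
    } else {
      shared <- shared + 1L
    }
  }
  list(private = private, shared = shared,
       total = nrow(poly), patterns = table(pats))
}

#' Apply a variant to a candidate site
#'
#' The variant is genomic plus-strand. The site sequence (guide-oriented)
#' is re-oriented to the genome, the REF allele is verified against it and
#' replaced by ALT, and the result is re-oriented back. For
#' length-changing variants the REF must lie fully inside the site
#' interval; the window is then re-derived from the stored flanks on the
#' PAM-distal side so the candidate keeps an alignable length (21-25 nt).
#'
#' @param site one-row candidate data.frame (with flank5/flank3 columns)
#' @param variant one-row frequency data.frame (chrom, pos, ref, alt)
#' @return list: \code{new_seq} (guide-oriented, NA when skipped),
#'   \code{skipped}, \code{reason}
#' @export
apply_variant <- function(site, variant) {
  stopifnot(nrow(site) == 1L, nrow(variant) == 1L)
  if (site$chrom != variant$chrom) {
    return(list(new_seq = NA_character_, skipped = TRUE,
                reason = "variant on a different chromosome"))
  }
  ref <- toupper(variant$ref); alt <- toupper(variant$alt)
  if (!nzchar(ref)) stop("empty REF allele")
  site_seq <- ungap(site$sequence)
  plus_site <- if (site$strand == "+") site_seq else revcomp(site_seq)
  window <- paste0(site$flank5, plus_site, site$flank3)
  wstart0 <- site$start - nchar(site$flank5)   # 0-based window start
  voff <- variant$pos - 1L - wstart0           # 0-based offset in window
  if (voff < 0L || voff + nchar(ref) > nchar(window)) {
    return(list(new_seq = NA_character_, skipped = TRUE,
                reason = "REF extends beyond site and available flanks"))
  }
  obs <- substr(window, voff + 1L, voff + nchar(ref))
  if (obs != ref) {
    stop(sprintf(
      "REF mismatch at %s:%d for site %s: stored '%s', variant REF '%s'",
      variant$chrom, variant$pos, site$id, obs, ref))
  }
  delta <- nchar(alt) - nchar(ref)
  in_site0 <- variant$pos - 1L - site$start
  if (delta != 0L &&
      (in_site0 < 0L || in_site0 + nchar(ref) > nchar(plus_site))) {
    return(list(new_seq = NA_character_, skipped = TRUE,
                reason = "length-changing REF crosses the site boundary"))
  }
  new_window <- paste0(substr(window, 1L, voff),
                       alt,
                       substr(window, voff + nchar(ref) + 1L,
                              nchar(window)))
  a <- nchar(site$flank5) + 1L                 # site start in window
  b <- nchar(site$flank5) + nchar(plus_site) + delta
  lo <- a; hi <- b
  len <- hi - lo + 1L
  pam_right <- site$strand == "+"  # genomic side holding the PAM
  if (len < 21L) {
    need <- 21L - len
    if (pam_right) lo <- lo - need else hi <- hi + need
  } else if (len > 25L) {
    drop <- len - 25L
    if (pam_right) lo <- lo + drop else hi <- hi - drop
  }
  if (lo < 1L || hi > nchar(new_window)) {
    return(list(new_seq = NA_character_, skipped = TRUE,
                reason = "insufficient flank to restore alignable length"))
  }
  new_plus <- substr(new_window, lo, hi)
  new_seq <- if (site$strand == "+") new_plus else revcomp(new_plus)
  list(new_seq = new_seq, skipped = FALSE, reason = "")
}

#' Re-evaluate a candidate under a variant
#'
#' Aligns and scores the candidate before and after applying the variant
#' and classifies the effect by comparing M, I, SEED conservation and PAM
#' state.
#'
#' @param site one-row candidate data.frame
#' @param variant one-row frequency data.frame (may carry af_* columns and
#'   polymorphic flags)
#' @param guide a \code{guide_rna}
#' @param tables a \code{penalty_tables}
#' @param policy a \code{filter_policy} (supplies PAM pattern and seed
#'   length)
#' @return an \code{overlay_result} list, or an \code{overlay_skip} (with a
#'   reason) when the variant could not be applied
#' @export
reevaluate <- function(site, variant, guide, tables = NULL,
                       policy = filter_policy()) {
  av <- apply_variant(site, variant)
  if (av$skipped) {
    return(structure(list(site_id = site$id, variant = variant,
                          reason = av$reason),
                     class = "overlay_skip"))
  }
  before <- parse_gapped(guide, site$sequence)
  after <- align_candidate(guide, av$new_seq)
  effects <- character(0)
  if (after$M > before$M) effects <- c(effects, "increase_mismatches")
  if (after$M < before$M) effects <- c(effects, "decrease_mismatches")
  if (after$I > before$I) effects <- c(effects, "increase_indels")
  seed_b <- seed_conserved(before, policy$seed_len)
  seed_a <- seed_conserved(after, policy$seed_len)
  if (seed_b && !seed_a) effects <- c(effects, "seed_disrupted")
  pam_b <- pam_check(before, policy$pam_pattern)
  pam_a <- pam_check(after, policy$pam_pattern)
  if (pam_b && !pam_a) effects <- c(effects, "pam_disrupted")
  if (!pam_b && pam_a) effects <- c(effects, "pam_created")
  identical_aln <- identical(before$columns, after$columns) &&
    before$pam_observed == after$pam_observed
  if (identical_aln) effects <- "no_change"
  ## a re-alignment can park a bulge at a coordinate with no published
  ## activity (e.g. guide position 1); the effect classes stand either
  ## way, so such scores are reported as NA with the reason kept
  safe_score <- function(a) {
    tryCatch(score_alignment(a, tables), error = function(e) {
      structure(list(cfd_mm = NA_real_, cfd_indel = NA_real_,
                     cfd_final = NA_real_, tier = NA_character_,
                     note = conditionMessage(e)),
                class = "score_result")
    })
  }
  score_b <- if (!is.null(tables)) safe_score(before) else NULL
  score_a <- if (!is.null(tables)) safe_score(after) else NULL
  poly <- if ("polymorphic" %in% names(variant)) variant$polymorphic else NA
  pops <- if ("populations_over_threshold" %in% names(variant)) {
    variant$populations_over_threshold
  } else NA_character_
  structure(
    list(site_id = site$id, variant = variant, new_seq = av$new_seq,
         m_i_before = c(M = before$M, I = before$I),
         m_i_after = c(M = after$M, I = after$I),
         before = before, after = after,
         score_before = score_b, score_after = score_a,
         effects = effects, polymorphic = poly,
         populations_over_threshold = pops),
    class = "overlay_result"
  )
}

#' @export
print.overlay_result <- function(x, ...) {
  cat(sprintf(
    "overlay %s %s:%d %s>%s  M/I %d/%d -> %d/%d  [%s]\n",
    x$site_id, x$variant$chrom, x$variant$pos, x$variant$ref,
    x$variant$alt, x$m_i_before["M"], x$m_i_before["I"],
    x$m_i_after["M"], x$m_i_after["I"],
    paste(x$effects, collapse = ",")))
  invisible(x)
}

#' Overlay every variant on every candidate it touches
#'
#' @param sites candidate data.frame
#' @param records frequency data.frame (after
#'   \code{\link{polymorphic_filter}})
#' @param guide a \code{guide_rna}
#' @param tables optional \code{penalty_tables}
#' @param policy a \code{filter_policy}
#' @return list of \code{overlay_result}; skipped pairs are reported in the
#'   \code{skipped} attribute (site id, variant, reason)
#' @export
overlay_variants <- function(sites, records, guide, tables = NULL,
                             policy = filter_policy()) {
  out <- list()
  skipped <- list()
  for (k in seq_len(nrow(sites))) {
    site <- sites[k, , drop = FALSE]
    ## any overlap between the REF span and the 1-based site interval
    touch <- records$chrom == site$chrom &
      records$pos <= site$end &
      (records$pos + nchar(records$ref) - 1L) >= site$start + 1L
    for (vi in which(touch)) {
      v <- records[vi, , drop = FALSE]
      r <- reevaluate(site, v, guide, tables, policy)
      if (inherits(r, "overlay_skip")) {
        skipped[[length(skipped) + 1L]] <- r
      } else {
        out[[length(out) + 1L]] <- r
      }
    }
  }
  attr(out, "skipped") <- skipped
  out
}
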