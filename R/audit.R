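## End-to-end audit orchestration and report rendering.

#' Build / validate a run configuration
#'
#' @param guide_spacer 20-nt spacer
#' @param guide_name guide label
#' @param candidates character vector of candidate TSV paths (or a list of
#'   data.frames)
#' @param genome optional FASTA path or DNAStringSet (enables the PAM
#'   discovery scan)
#' @param genes optional gene annotation (BED/GFF3 path or GRanges)
#' @param repeats optional repeat annotation (BED/.out path or GRanges)
#' @param variants optional list of variant sources; each element a list
#'   with \code{path}, optional \code{population_map}, optional
#'   \code{source}
#' @param policy a \code{\link{filter_policy}}
#' @param score_thresholds upper/lower cleavage-probability cut-offs
#' @param af_threshold polymorphic-site allele-frequency cut-off
#' @param populations trigger populations for the polymorphic rule
#' @param penalty_resource optional penalty TSV path (default bundled)
#' @param seed integer recorded in the run log
#' @param json path to a JSON config file; when given, its fields override
#'   the other arguments
#' @return a validated \code{run_config}
#' @export
run_config <- function(guide_spacer = NULL, guide_name = "guide",
                       candidates = character(0), genome = NULL,
                       genes = NULL, repeats = NULL, variants = list(),
                       policy = filter_policy(),
                       score_thresholds = c(0.2, 0.023),
                       af_threshold = 0.01,
                       populations = c("E", "LA", "A"),
                       penalty_resource = NULL, seed = 1L,
                       json = NULL) {
  if (!is.null(json)) {
    cfg <- jsonlite::read_json(json, simplifyVector = TRUE)
    for (nm in c("guide_spacer", "guide_name", "candidates", "genome",
                 "genes", "repeats", "af_threshold", "populations",
                 "penalty_resource", "seed")) {
      if (!is.null(cfg[[nm]])) assign(nm, cfg[[nm]])
    }
    if (!is.null(cfg$score_thresholds)) {
      score_thresholds <- as.numeric(cfg$score_thresholds)
    }
    if (!is.null(cfg$policy)) policy <- do.call(filter_policy, cfg$policy)
    if (!is.null(cfg$variants)) {
      variants <- lapply(seq_len(nrow(as.data.frame(cfg$variants))),
                         function(i) as.list(as.data.frame(
                           cfg$variants)[i, , drop = FALSE]))
      if (is.list(cfg$variants) && !is.data.frame(cfg$variants)) {
        variants <- cfg$variants
      }
    }
  }
  if (is.null(guide_spacer)) stop("guide_spacer is required")
  thr <- c(score_thresholds, af_threshold)
  if (any(thr <= 0 | thr >= 1)) stop("thresholds must lie in (0, 1)")
  for (p in c(if (is.character(candidates)) candidates,
              if (is.character(genome)) genome,
              if (is.character(genes)) genes,
              if (is.character(repeats)) repeats,
              vapply(variants, function(v) v$path %||% "", ""))) {
    if (nzchar(p) && !file.exists(p)) stop("missing input file: ", p)
  }
  structure(list(
    guide = guide_rna(guide_spacer, name = guide_name,
                      pam_pattern = policy$pam_pattern),
    candidates = candidates, genome = genome, genes = genes,
    repeats = repeats, variants = variants, policy = policy,
    score_thresholds = score_thresholds, af_threshold = af_threshold,
    populations = populations, penalty_resource = penalty_resource,
    seed = as.integer(seed)), class = "run_config")
}

#' Run the full off-target audit
#'
#' Merge -> filter -> score -> annotate -> duplicates -> repeats ->
#' variant overlay -> PAM discovery -> privacy summary -> position
#' profile. Deterministic for fixed inputs; every input record lands
#' either in a report table or in the rejected-with-reason log.
#'
#' @param config a \code{\link{run_config}}
#' @return an \code{audit_bundle} list of report tables and the run log
#' @export
run_audit <- function(config) {
  stopifnot(inherits(config, "run_config"))
  guide <- config$guide
  tables <- load_penalties(config$penalty_resource)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("audit stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  merged <- stage("merge", {
    if (length(config$candidates)) {
      merge_predictions(as.list(config$candidates))
    } else {
      read_candidates(data.frame(
        id = character(0), chrom = character(0), start = integer(0),
        end = integer(0), strand = character(0), sequence = character(0),
        source = character(0), annotation = character(0)))
    }
  })
  filt <- stage("filter", apply_filters(merged, guide, config$policy))
  retained <- filt$retained

  if (!is.null(config$genes) && nrow(retained)) {
    retained <- stage("annotate", annotate_genic(retained, config$genes))
  } else {
    retained$gene <- rep(NA_character_, nrow(retained))
  }
  if (!is.null(config$repeats) && nrow(retained)) {
    retained <- stage("repeats", flag_repeats(retained, config$repeats))
  }

  scores <- stage("score", {
    if (nrow(retained)) {
      do.call(rbind, lapply(retained$id, function(id) {
        sr <- score_alignment(filt$alignments[[id]], tables,
                              config$score_thresholds)
        data.frame(id = id, cfd_mm = sr$cfd_mm, cfd_indel = sr$cfd_indel,
                   cfd_final = sr$cfd_final, tier = sr$tier,
                   stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(id = character(0), cfd_mm = numeric(0),
                 cfd_indel = numeric(0), cfd_final = numeric(0),
                 tier = character(0), stringsAsFactors = FALSE)
    }
  })

  dup <- stage("duplicates", find_duplicate_sequences(retained))

  records <- NULL
  overlay <- list()
  privacy <- NULL
  if (length(config$variants)) {
    records <- stage("variants", {
      do.call(rbind, lapply(config$variants, function(v) {
        pm <- v$population_map
        if (!is.null(pm)) pm <- unlist(pm)
        read_frequencies(v$path, population_map = pm,
                         source = v$source %||% NULL)
      }))
    })
    records <- stage("polymorphic", polymorphic_filter(
      records, config$af_threshold, config$populations))
    overlay <- stage("overlay", overlay_variants(
      retained, records, guide, tables, config$policy))
    privacy <- stage("privacy", population_privacy(
      records[records$polymorphic, , drop = FALSE],
      config$populations, config$af_threshold))
  }

  pam_sites <- NULL
  pam_created <- NULL
  if (!is.null(config$genome)) {
    pam_sites <- stage("pamscan", scan_near_pam(
      config$genome, guide, config$policy$max_mismatches,
      config$policy$seed_len))
    if (!is.null(records) && nrow(pam_sites)) {
      pam_created <- stage("pamcreate", pam_creation_check(
        pam_sites, records[records$polymorphic, , drop = FALSE]))
    }
  }

  profile <- if (length(filt$alignments)) {
    position_profile(filt$alignments)
  } else {
    matrix(0L, 25L, 3L, dimnames = list(position = 1:25,
                                        op = c("mismatch", "insertion",
                                               "deletion")))
  }

  input_checksums <- local({
    paths <- c(config$candidates[is.character(config$candidates)],
               if (is.character(config$genome)) config$genome,
               if (is.character(config$genes)) config$genes,
               if (is.character(config$repeats)) config$repeats,
               vapply(config$variants, function(v) v$path %||% "", ""))
    paths <- paths[nzchar(paths) & file.exists(paths)]
    as.list(tools::md5sum(paths))
  })

  if (nrow(merged) == 0L) {
    warning("empty candidate table: producing an empty bundle")
  }

  structure(list(
    config = config,
    candidates = retained,
    alignments = filt$alignments,
    rejected = filt$rejected,
    scores = scores,
    duplicates = dup,
    variant_records = records,
    overlay = overlay,
    privacy = privacy,
    pam_sites = pam_sites,
    pam_created = pam_created,
    profile = profile,
    log = list(
      package_version = as.character(packageVersion("crisprAudit")),
      seed = config$seed,
      guide = guide$spacer,
      penalty_checksum = load_penalties(config$penalty_resource)$checksum,
      input_checksums = input_checksums,
      n_input = nrow(merged), n_retained = nrow(retained),
      n_rejected = nrow(filt$rejected))
  ), class = "audit_bundle")
}

#' Summarise an audit bundle
#'
#' Headline counts: candidates retained, mismatch-only candidates,
#' candidates in each score tier, genic/intergenic split, duplicate
#' groups, polymorphic sites, privacy counts.
#'
#' @param bundle an \code{audit_bundle}
#' @return a named list of counts
#' @export
audit_summary <- function(bundle) {
  cand <- bundle$candidates
  list(
    n_candidates = nrow(cand),
    n_mismatch_only = sum(cand$I == 0L),
    n_with_indels = sum(cand$I > 0L),
    n_genic = if ("annotation" %in% names(cand))
      sum(cand$annotation == "genic") else NA_integer_,
    n_intergenic = if ("annotation" %in% names(cand))
      sum(cand$annotation == "intergenic") else NA_integer_,
    n_above_upper = sum(bundle$scores$tier == "above_0.2"),
    n_above_lower = sum(bundle$scores$tier != "below_0.023"),
    n_duplicate_groups = if (nrow(bundle$duplicates))
      length(unique(bundle$duplicates$dup_group)) else 0L,
    n_polymorphic = if (!is.null(bundle$variant_records))
      sum(bundle$variant_records$polymorphic) else NA_integer_,
    privacy = bundle$privacy[c("private", "shared", "total")]
  )
}

#' Render the report bundle to files
#'
#' Writes TSV tables (scores at 3 decimal places, "-" for not-applicable
#' indel scores, **(/*) tier markers, 1-based inclusive loci) and JSON
#' summaries. Output is byte-stable for identical input.
#'
#' @param bundle an \code{audit_bundle}
#' @param dir output directory (created if needed)
#' @param format "tsv" (tables + JSON summaries) or "json" (whole bundle)
#' @return invisible character vector of files written
#' @export
render_tables <- function(bundle, dir, format = c("tsv", "json")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "-")
    files <<- c(files, p)
  }
  cand <- bundle$candidates
  if (format == "json") {
    p <- file.path(dir, "bundle.json")
    jsonlite::write_json(list(
      candidates = cand, scores = bundle$scores,
      summary = audit_summary(bundle), log = bundle$log),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    return(invisible(p))
  }
  if (nrow(cand)) {
    tab1 <- data.frame(
      ID = cand$id, SEQUENCE = cand$sequence,
      `M.I` = paste0(cand$M, "/", cand$I),
      LOCALIZATION = render_locus(cand$chrom, cand$start, cand$end),
      ANNOTATION = ifelse(!is.na(cand$gene) & nzchar(cand$gene %||% ""),
                          cand$gene, cand$annotation),
      stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    tab1 <- data.frame(ID = character(0), SEQUENCE = character(0),
                       `M.I` = character(0), LOCALIZATION = character(0),
                       ANNOTATION = character(0), check.names = FALSE)
  }
  wr(tab1, "candidates.tsv")
  sc <- bundle$scores
  wr(data.frame(ID = sc$id,
                CFD = format_cfd(sc$cfd_mm),
                CFD_INDEL = format_cfd(sc$cfd_indel),
                CFD_FINAL = paste0(format_cfd(sc$cfd_final),
                                   ifelse(nzchar(tier_marker(sc$tier)),
                                          paste0(" ",
                                                 tier_marker(sc$tier)),
                                          "")),
                stringsAsFactors = FALSE),
     "scores.tsv")
  if (length(bundle$overlay)) {
    ov <- do.call(rbind, lapply(bundle$overlay, function(r) {
      data.frame(
        ID = r$site_id, POS = r$variant$pos, REF = r$variant$ref,
        ALT = r$variant$alt,
        NO_VARIANT = paste0(r$m_i_before["M"], "/", r$m_i_before["I"]),
        VARIANT = paste0(r$m_i_after["M"], "/", r$m_i_after["I"]),
        EFFECTS = paste(r$effects, collapse = ","),
        PAM_AFTER = r$after$pam_observed,
        stringsAsFactors = FALSE)
    }))
    wr(ov, "overlay.tsv")
  } else {
    wr(data.frame(ID = character(0), POS = integer(0), REF = character(0),
                  ALT = character(0), NO_VARIANT = character(0),
                  VARIANT = character(0), EFFECTS = character(0),
                  PAM_AFTER = character(0)), "overlay.tsv")
  }
  if (!is.null(bundle$pam_created)) {
    wr(bundle$pam_created, "pam_created.tsv")
  }
  if (nrow(bundle$duplicates)) {
    wr(bundle$duplicates[, c("dup_group", "id", "sequence", "chrom",
                             "start", "end")], "duplicates.tsv")
  }
  prof <- as.data.frame(bundle$profile)
  prof <- data.frame(position = 1:25, prof, check.names = FALSE)
  wr(prof, "position_profile.tsv")
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(audit_summary(bundle), p, auto_unbox = TRUE,
                       digits = NA, na = "null")
  files <- c(files, p)
  p2 <- file.path(dir, "run_log.json")
  jsonlite::write_json(bundle$log, p2, auto_unbox = TRUE, na = "null")
  files <- c(files, p2)
  invisible(files)
}
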