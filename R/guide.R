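#' Construct a guide RNA
#'
#' A single SpCas9 guide: a 20-nt spacer in 5'->3' orientation plus an
#' IUPAC PAM pattern (NGG for wild-type SpCas9). Every alignment and every
#' CFD score in the package is taken relative to one of these objects.
#'
#' @param spacer 20-nt spacer sequence, alphabet A/C/G/T
#' @param name optional label
#' @param pam_pattern IUPAC trinucleotide the PAM must match (default "NGG")
#' @return an object of class \code{guide_rna}
#' @examples
#' g <- guide_rna("GCTCTAGGCCGAAGTGTCGC", name = "IDUA-W402X")
#' gc_fraction(g)
#' @export
guide_rna <- function(spacer, name = "guide", pam_pattern = "NGG") {
  spacer <- toupper(spacer)
  if (nchar(spacer) != 20L) {
    stop("spacer must be exactly 20 nt, got ", nchar(spacer))
  }
  if (grepl("[^ACGT]", spacer)) {
    stop("spacer alphabet must be A/C/G/T")
  }
  pam_pattern <- toupper(pam_pattern)
  if (nchar(pam_pattern) != 3L || grepl("[^ACGTRYSWKMBDHVN]", pam_pattern)) {
    stop("pam_pattern must be an IUPAC trinucleotide")
  }
  structure(
    list(name = name, spacer = spacer, pam_pattern = pam_pattern),
    class = "guide_rna"
  )
}

#' GC fraction of a guide spacer
#'
#' @param guide a \code{guide_rna}
#' @return fraction of spacer bases that are G or C, in [0, 1]
#' @export
gc_fraction <- function(guide) {
  stopifnot(inherits(guide, "guide_rna"))
  b <- strsplit(guide$spacer, "")[[1]]
  mean(b %in% c("G", "C"))
}

#' @export
print.guide_rna <- function(x, ...) {
  cat(sprintf("guide_rna '%s': %s + %s (GC %.0f%%)\n",
              x$name, x$spacer, x$pam_pattern, 100 * gc_fraction(x)))
  invisible(x)
}

## spacer + PAM pattern length; candidate windows are this +/- 2
guide_site_width <- function(guide) nchar(guide$spacer) + 3L

guide_seed <- function(guide, seed_len = 5L) {
  substr(guide$spacer, nchar(guide$spacer) - seed_len + 1L,
         nchar(guide$spacer))
}
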