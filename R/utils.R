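#' @importFrom utils read.delim write.table head tail packageVersion
#' @importFrom stats setNames
NULL

DNA_BASES <- c("A", "C", "G", "T")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

## Match a concrete base string against an IUPAC pattern of equal length.
## Ambiguity codes are honoured on the pattern side only; an N in the
## observed sequence never matches (conservative rule used throughout).
iupac_match <- function(observed, pattern) {
  if (nchar(observed) != nchar(pattern)) return(FALSE)
  obs <- strsplit(toupper(observed), "")[[1]]
  pat <- strsplit(toupper(pattern), "")[[1]]
  for (i in seq_along(obs)) {
    allowed <- IUPAC_SETS[[pat[i]]]
    if (is.null(allowed)) {
      stop("invalid IUPAC code in pattern: ", pat[i])
    }
    if (!obs[i] %in% allowed) return(FALSE)
  }
  TRUE
}

revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

ungap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Render a genomic interval the way the field prints it
#'
#' Internal coordinates are 0-based half-open; reports use 1-based
#' inclusive intervals (e.g. \code{"chr4:996530-996552"}).
#'
#' @param chrom chromosome name
#' @param start 0-based start
#' @param end half-open end
#' @return character vector of rendered loci
#' @export
render_locus <- function(chrom, start, end) {
  paste0(chrom, ":", start + 1L, "-", end)
}

## deterministic per-call RNG scope; never leaks state into the session
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
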