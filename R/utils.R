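# Internal helpers shared across modules.

END5 <- "5"
END3 <- "3"
FORWARD <- "+"
REVERSE <- "-"

CLASS_CP <- "CP"
CLASS_MT <- "MT"
CLASS_NUCLEAR <- "NUCLEAR"
CLASS_REPEAT <- "REPEAT"   # unresolved repeat: exempt from plain thresholding

opposite_end <- function(end) ifelse(end == END5, END3, END5)

# end at which an oriented traversal enters / leaves a contig
entry_end <- function(orient) ifelse(orient == FORWARD, END5, END3)
exit_end <- function(orient) ifelse(orient == FORWARD, END3, END5)
flip_orient <- function(orient) ifelse(orient == FORWARD, REVERSE, FORWARD)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a nucleotide string
#'
#' Thin wrapper over [Biostrings::reverseComplement()] accepting and returning
#' plain character scalars (A/C/G/T/N alphabet).
#'
#' @param x Nucleotide string.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# vectorised reverse complement for many short strings (k-mers)
revcomp_many <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# uppercase + alphabet check; other characters are an error
normalize_sequence <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside A/C/G/T/N", what), call. = FALSE)
  }
  x
}

# run code with a fixed RNG seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# weighted median: smallest x whose cumulative weight reaches half the total
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), length(x) > 0L)
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w)
  x[which(cw >= cw[length(cw)] / 2)[1L]]
}
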