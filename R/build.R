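# Sequence reconstruction and assembly reporting.

#' Reconstruct the circular genome sequence from a finished circle
#'
#' Concatenates the oriented contig sequences along the closed walk
#' (reverse steps contribute the reverse complement).  Most joins are
#' zero-gap by the contig-graph construction; a join may insert a single
#' gap/insert base, taken from `gap_policy` or, failing that, from the
#' graph edge's own gap annotation.
#'
#' @param graph A [contig_graph] whose circle contigs carry sequences.
#' @param circle A closed [circle_path].
#' @param gap_policy Optional named character vector of single bases; names
#'   are ordered joins `"from|to"` (the step traversing `from` immediately
#'   precedes the step traversing `to`).  Naming a join the circle does not
#'   make is an error.
#' @return The circular genome sequence (character scalar) with a
#'   `"gaps_filled"` attribute (data frame of joins with inserted bases).
#' @export
reconstruct_sequence <- function(graph, circle, gap_policy = NULL) {
  stopifnot(inherits(graph, "contig_graph"), inherits(circle, "circle_path"))
  if (!circle$closed) stop("reconstruct_sequence: circle is not closed")
  steps <- circle$steps
  n <- nrow(steps)
  ni <- match(steps$contig_id, graph$nodes$contig_id)
  if (any(is.na(ni))) stop("reconstruct_sequence: circle step not in graph")
  seqs <- graph$nodes$sequence[ni]
  if (any(is.na(seqs))) {
    stop("reconstruct_sequence: missing sequence on contig(s): ",
         paste(unique(steps$contig_id[is.na(seqs)]), collapse = ", "))
  }
  oriented <- ifelse(steps$orient == FORWARD, seqs,
                     vapply(seqs, revcomp, character(1)))

  join_keys <- vapply(seq_len(n), function(i) {
    paste(steps$contig_id[i], steps$contig_id[(i %% n) + 1L], sep = "|")
  }, character(1))
  if (!is.null(gap_policy)) {
    bad <- setdiff(names(gap_policy), join_keys)
    if (length(bad)) {
      stop("reconstruct_sequence: gap_policy references non-circle join(s): ",
           paste(bad, collapse = ", "))
    }
  }
  edge_gap_base <- function(i) {
    j <- (i %% n) + 1L
    a <- steps$contig_id[i]; b <- steps$contig_id[j]
    ea <- exit_end(steps$orient[i]); eb <- entry_end(steps$orient[j])
    e <- graph$edges
    hit <- (e$a_id == a & e$a_end == ea & e$b_id == b & e$b_end == eb) |
      (e$a_id == b & e$a_end == eb & e$b_id == a & e$b_end == ea)
    if (any(hit) && e$gap[which(hit)[1L]] >= 1L) e$gap_base[which(hit)[1L]]
    else NA_character_
  }
  inserts <- vapply(seq_len(n), function(i) {
    k <- join_keys[i]
    if (!is.null(gap_policy) && k %in% names(gap_policy)) {
      normalize_sequence(gap_policy[[k]], "gap base")
    } else {
      gb <- edge_gap_base(i)
      if (is.na(gb)) "" else gb
    }
  }, character(1))

  seq_out <- paste0(paste0(oriented, inserts), collapse = "")
  filled <- which(nzchar(inserts))
  attr(seq_out, "gaps_filled") <- data.frame(
    after_step = filled,
    join = join_keys[filled],
    base = inserts[filled],
    stringsAsFactors = FALSE
  )
  seq_out
}

# index (1-based) of the lexicographically least rotation of an integer
# vector; simultaneous candidate refinement, vectorised per round
min_rotation_idx <- function(v) {
  n <- length(v)
  if (n == 1L) return(1L)
  w <- c(v, v)
  cand <- which(v == min(v))
  k <- 1L
  while (length(cand) > 1L && k < n) {
    ch <- w[cand + k]
    cand <- cand[ch == min(ch)]
    k <- k + 1L
  }
  cand[1L]
}

#' Canonical form of a circular sequence
#'
#' The lexicographically smallest string among all rotations of the sequence
#' and all rotations of its reverse complement.  Two circular assemblies are
#' the same molecule iff their canonical forms are identical, regardless of
#' chosen origin or strand.
#'
#' @param sequence Non-empty nucleotide string over A/C/G/T/N.
#' @return The canonical string.
#' @export
canonical_form <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- normalize_sequence(sequence)
  if (!nzchar(sequence)) stop("canonical_form: empty sequence")
  best_rot <- function(s) {
    v <- utf8ToInt(s)
    i <- min_rotation_idx(v)
    if (i == 1L) v else c(v[i:length(v)], v[seq_len(i - 1L)])
  }
  r1 <- best_rot(sequence)
  r2 <- best_rot(revcomp(sequence))
  d <- which(r1 != r2)
  pick <- if (!length(d) || r1[d[1L]] < r2[d[1L]]) r1 else r2
  intToUtf8(pick)
}

#' GC content of a nucleotide sequence
#'
#' `100 * (G + C) / (A + C + G + T)`; ambiguous N bases are excluded from
#' the denominator so unplaced ambiguity does not bias composition.
#' Internal value is unrounded; reports round to 2 decimals.
#'
#' @param sequence Non-empty nucleotide string.
#' @return GC percentage (numeric scalar, unrounded).
#' @export
gc_content <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  sequence <- normalize_sequence(sequence)
  f <- Biostrings::letterFrequency(Biostrings::DNAString(sequence),
                                   letters = c("A", "C", "G", "T"))
  denom <- sum(f)
  if (denom == 0) stop("gc_content: sequence contains only N")
  100 * (f[["C"]] + f[["G"]]) / denom
}

#' Assembly report for a finished circular genome
#'
#' Collects genome length, GC percentage (2 decimals), contig statistics --
#' counting repeat contigs once, the circle-graph reporting convention, with
#' the per-traversal statistics alongside -- the quadripartite annotation if
#' present, and the gap bases inserted during reconstruction.
#'
#' @param sequence Reconstructed genome sequence (from
#'   [reconstruct_sequence()]).
#' @param circle The closed [circle_path] it came from.
#' @param graph The [contig_graph].
#' @param annotation Optional `structure_annotation`.
#' @return An `assembly_report` list.
#' @export
assembly_report <- function(sequence, circle, graph, annotation = NULL) {
  stopifnot(inherits(circle, "circle_path"), inherits(graph, "contig_graph"))
  steps <- circle$steps
  ni <- match(steps$contig_id, graph$nodes$contig_id)
  if (any(is.na(ni))) stop("assembly_report: circle step not in graph")
  gaps <- attr(sequence, "gaps_filled") %||%
    data.frame(after_step = integer(0), join = character(0),
               base = character(0), stringsAsFactors = FALSE)
  expect_len <- sum(graph$nodes$length[ni]) + nrow(gaps)
  if (nchar(sequence) != expect_len) {
    stop(sprintf(
      "assembly_report: sequence length %d != traversed contig lengths + gaps (%d)",
      nchar(sequence), expect_len))
  }
  uniq <- unique(steps$contig_id)
  ustats <- graph_stats(graph$nodes[match(uniq, graph$nodes$contig_id), ,
                                    drop = FALSE])
  mult <- table(steps$contig_id)
  tstats <- graph_stats(
    graph$nodes[match(uniq, graph$nodes$contig_id), , drop = FALSE],
    count_repeats_once = FALSE,
    multiplicity = stats::setNames(as.integer(mult), names(mult))
  )
  structure(list(
    genome_length = nchar(sequence),
    gc_percent = round(gc_content(sequence), 2L),
    n_contigs = ustats$n_contigs,
    n50 = ustats$n50,
    total_bp_once = ustats$total_bp,
    total_bp_traversed = tstats$total_bp,
    structure = annotation,
    gaps_filled = gaps
  ), class = "assembly_report")
}

#' @export
print.assembly_report <- function(x, ...) {
  cat(sprintf("circular assembly: %s bp, GC %.2f%%\n",
              format(x$genome_length, big.mark = ","), x$gc_percent))
  cat(sprintf("  %d contigs, %s bp counting repeats once (N50 %s bp); %s bp traversed\n",
              x$n_contigs, format(x$total_bp_once, big.mark = ","),
              format(x$n50, big.mark = ","),
              format(x$total_bp_traversed, big.mark = ",")))
  if (!is.null(x$structure)) print(x$structure)
  if (nrow(x$gaps_filled)) {
    cat(sprintf("  gap bases inserted: %s\n",
                paste(sprintf("%s (%s)", x$gaps_filled$base, x$gaps_filled$join),
                      collapse = ", ")))
  }
  invisible(x)
}
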