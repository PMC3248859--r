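# Depth-based contig classification.
#
# Plant cells carry many copies of the organellar genomes, so in a
# whole-genome shotgun assembly the mean read depth of a contig is roughly
# proportional to the copy number of the genome it came from.  With class
# mean depths around 87x (chloroplast), 43x (mitochondrion) and 9x (nuclear),
# two thresholds separate the three classes; repeat-containing contigs sit at
# integer multiples of their class depth and are exempted from plain
# thresholding.

#' Depth histogram diagnostic
#'
#' Bins contigs by mean read depth, reporting both contig counts and
#' base-weighted counts per bin.  Used to eyeball the depth separation
#' between the organellar and nuclear classes before choosing thresholds.
#'
#' @param graph A [contig_graph].
#' @param bin_width Bin width in fold-coverage (> 0).
#' @return A `depth_histogram` data frame with columns `bin_start`,
#'   `bin_end`, `n_contigs`, `total_bp`.
#' @export
depth_histogram <- function(graph, bin_width = 10) {
  stopifnot(inherits(graph, "contig_graph"))
  if (!is.numeric(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  if (nrow(graph$nodes) == 0L) stop("depth_histogram: empty graph")
  bin <- floor(graph$nodes$depth / bin_width)
  counts <- tapply(rep(1L, nrow(graph$nodes)), bin, sum)
  bases <- tapply(graph$nodes$length, bin, sum)
  b <- as.numeric(names(counts))
  out <- data.frame(
    bin_start = b * bin_width,
    bin_end = (b + 1) * bin_width,
    n_contigs = as.integer(counts),
    total_bp = as.numeric(bases)
  )
  out <- out[order(out$bin_start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "bin_width") <- bin_width
  class(out) <- c("depth_histogram", "data.frame")
  out
}

#' @export
#' @method plot depth_histogram
plot.depth_histogram <- function(x, weighted = FALSE, ...) {
  h <- if (weighted) x$total_bp else x$n_contigs
  graphics::barplot(h, names.arg = x$bin_start, space = 0,
                    xlab = "read depth (fold-coverage)",
                    ylab = if (weighted) "bases" else "contigs", ...)
  invisible(x)
}

#' Classify contigs by read depth
#'
#' Labels each contig CP (`depth >= t_high`), MT (`t_low < depth < t_high`,
#' the open interval) or NUCLEAR (`depth <= t_low`).  Contigs listed in
#' `repeat_flags` are labelled REPEAT instead: their depth is a multiple of
#' their class depth, so plain thresholding would misplace them; they are
#' adopted into a class during component extraction.
#'
#' @param graph A [contig_graph].
#' @param t_low,t_high Fold-coverage thresholds, `t_low < t_high`.
#'   Defaults 20 and 60.
#' @param repeat_flags Character vector of contig ids exempt from
#'   thresholding.
#' @return A `depth_partition`: list with `labels` (named character vector
#'   over all contigs), `t_low`, `t_high`, `repeat_flags`.
#' @export
classify_by_depth <- function(graph, t_low = 20, t_high = 60,
                              repeat_flags = character(0)) {
  stopifnot(inherits(graph, "contig_graph"))
  if (!(t_low < t_high)) stop("t_low must be < t_high")
  d <- graph$nodes$depth
  labels <- ifelse(d >= t_high, CLASS_CP,
                   ifelse(d > t_low, CLASS_MT, CLASS_NUCLEAR))
  names(labels) <- graph$nodes$contig_id
  repeat_flags <- intersect(repeat_flags, graph$nodes$contig_id)
  labels[repeat_flags] <- CLASS_REPEAT
  structure(list(labels = labels, t_low = t_low, t_high = t_high,
                 repeat_flags = repeat_flags),
            class = "depth_partition")
}

#' @export
print.depth_partition <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c(CLASS_CP, CLASS_MT, CLASS_NUCLEAR,
                                           CLASS_REPEAT)))
  cat(sprintf("depth_partition (t_low = %g, t_high = %g): ", x$t_low, x$t_high))
  cat(paste(sprintf("%s %d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  invisible(x)
}

# shared k-mer machinery -----------------------------------------------------

seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

canonical_kmers <- function(seq, k) {
  km <- unique(seq_kmers(seq, k))
  km <- km[!grepl("N", km, fixed = TRUE)]
  if (!length(km)) return(character(0))
  rc <- revcomp_many(km)
  unique(ifelse(km <= rc, km, rc))
}

#' Find seed contigs by shared k-mer content with a reference set
#'
#' A dependency-free stand-in for read-mapping or conserved-gene search: a
#' contig is a seed if it shares at least `min_hits` distinct canonical
#' k-mers (the lexicographic minimum of a k-mer and its reverse complement)
#' with any single reference record.  Typical references are conserved
#' mitochondrial genes or complete chloroplast genomes of related species.
#'
#' @param graph A [contig_graph] whose contigs carry sequences.
#' @param reference_fasta Path to a nucleotide FASTA of reference records.
#' @param k K-mer size (>= 11; default 31).
#' @param min_hits Minimum shared distinct canonical k-mers (default 5).
#' @return Character vector of seed contig ids.
#' @export
find_seed_contigs <- function(graph, reference_fasta, k = 31L, min_hits = 5L) {
  stopifnot(inherits(graph, "contig_graph"))
  if (k < 11L) stop("k must be >= 11")
  has_seq <- !is.na(graph$nodes$sequence)
  if (!any(has_seq)) stop("find_seed_contigs: no contig carries a sequence")
  refs <- Biostrings::readDNAStringSet(reference_fasta)
  if (!length(refs)) stop("find_seed_contigs: empty reference FASTA")
  ref_sets <- lapply(seq_along(refs), function(i) {
    canonical_kmers(normalize_sequence(as.character(refs[[i]]), "reference"), k)
  })
  seeds <- character(0)
  for (i in which(has_seq)) {
    ck <- canonical_kmers(graph$nodes$sequence[i], k)
    if (!length(ck)) next
    for (rs in ref_sets) {
      if (sum(ck %in% rs) >= min_hits) {
        seeds <- c(seeds, graph$nodes$contig_id[i])
        break
      }
    }
  }
  seeds
}

# core multiplicity-from-depth rule, shared by flag_repeats and
# infer_multiplicity: base depth is the length-weighted median of the
# single-copy candidates; a contig gets multiplicity m = round(depth/base)
# when m >= 2 and the relative deviation |depth - m*base|/base is within
# tolerance.  One refinement pass re-estimates the base from contigs that
# first-pass assigned m = 1 (robust when repeats carry substantial mass).
depth_multiplicities <- function(lengths, depths, tolerance = 0.35) {
  base <- weighted_median(depths, lengths)
  for (pass in 1:2) {
    m <- pmax(1L, as.integer(round(depths / base)))
    ok <- m >= 2L & abs(depths - m * base) / base <= tolerance
    m[!ok] <- 1L
    if (pass == 1L && any(m == 1L)) {
      base <- weighted_median(depths[m == 1L], lengths[m == 1L])
    }
  }
  list(multiplicity = m, base_depth = base)
}

#' Flag repeat contigs by depth multiplicity within a class
#'
#' A collapsed repeat is assembled as one contig whose depth is (about) an
#' integer multiple of the class's single-copy depth -- the plastid inverted
#' repeat sequences at roughly twice the depth of the LSC/SSC regions.  The
#' single-copy base depth is estimated as the length-weighted median of the
#' class depths (refined once on the contigs consistent with one copy), and a
#' contig is flagged with multiplicity `m = round(depth/base)` when `m >= 2`
#' and `|depth - m*base|/base <= tolerance`.
#'
#' @param graph A [contig_graph].
#' @param partition A `depth_partition` covering the graph.
#' @param class_label `"CP"` or `"MT"`.
#' @param tolerance Maximum relative deviation from an integer multiple
#'   (default 0.35: collapsed-repeat depth ratios are near, not exactly,
#'   integral).
#' @return Named integer vector (contig_id -> multiplicity >= 2) over the
#'   flagged contigs; empty when none qualify.
#' @export
flag_repeats <- function(graph, partition, class_label, tolerance = 0.35) {
  stopifnot(inherits(graph, "contig_graph"),
            inherits(partition, "depth_partition"))
  ids <- names(partition$labels)[partition$labels %in% c(class_label, CLASS_REPEAT)]
  ids <- intersect(ids, graph$nodes$contig_id)
  if (length(ids) < 3L) {
    stop("flag_repeats: fewer than 3 contigs in class ", class_label,
         "; set multiplicities manually")
  }
  idx <- match(ids, graph$nodes$contig_id)
  res <- depth_multiplicities(graph$nodes$length[idx], graph$nodes$depth[idx],
                              tolerance)
  m <- res$multiplicity
  names(m) <- ids
  out <- m[m >= 2L]
  attr(out, "base_depth") <- res$base_depth
  out
}

#' Candidate repeat contigs for a class, searched over the whole graph
#'
#' Like [flag_repeats()] but considers every contig in the graph, not just
#' those already labelled with the class: a collapsed two-copy mitochondrial
#' repeat sequences at ~2x the MT depth and is therefore thresholded into the
#' CP class.  Candidates are contigs whose depth is consistent with an
#' integer multiple (>= 2) of the class base depth; graph reachability then
#' decides which candidates actually belong to the class.
#'
#' @inheritParams flag_repeats
#' @return Character vector of candidate contig ids (may include contigs of
#'   other classes whose depth is coincidentally consistent; extraction
#'   discards those).
#' @export
repeat_candidates <- function(graph, partition, class_label, tolerance = 0.35) {
  stopifnot(inherits(graph, "contig_graph"),
            inherits(partition, "depth_partition"))
  in_class <- names(partition$labels)[partition$labels == class_label]
  in_class <- intersect(in_class, graph$nodes$contig_id)
  if (length(in_class) < 3L) return(character(0))
  idx <- match(in_class, graph$nodes$contig_id)
  base <- depth_multiplicities(graph$nodes$length[idx],
                               graph$nodes$depth[idx], tolerance)$base_depth
  d <- graph$nodes$depth
  m <- pmax(1L, as.integer(round(d / base)))
  ok <- m >= 2L & abs(d - m * base) / base <= tolerance
  graph$nodes$contig_id[ok]
}

#' Extract the class subgraph reachable from seed contigs
#'
#' Breadth-first reachability from the seeds through contigs labelled with
#' the class or REPEAT (repeat-flagged contigs are adopted into the class
#' they are reached from).  For mitochondrial extraction, chloroplast-labelled
#' contigs *internal* to mitochondrial paths (connected to at least two
#' already-reached contigs) are retained, because fragments of the cp genome
#' are frequently transferred into the mt genome; cp contigs hanging off the
#' component on full cp paths are not adopted.
#'
#' @param graph A [contig_graph].
#' @param seeds Non-empty character vector of seed contig ids.
#' @param partition A `depth_partition`.
#' @param class_label `"CP"` or `"MT"`.
#' @return The induced [contig_graph]; its `"adopted"` attribute lists
#'   contigs whose label was not `class_label` (REPEAT-flagged, or internal
#'   CP contigs during MT extraction).
#' @export
extract_component <- function(graph, seeds, partition, class_label) {
  stopifnot(inherits(graph, "contig_graph"),
            inherits(partition, "depth_partition"))
  if (!length(seeds)) stop("extract_component: no seeds given")
  missing_seeds <- setdiff(seeds, graph$nodes$contig_id)
  if (length(missing_seeds)) {
    stop("extract_component: seed absent from graph: ",
         paste(missing_seeds, collapse = ", "))
  }
  labels <- partition$labels
  allowed <- names(labels)[labels %in% c(class_label, CLASS_REPEAT)]
  allowed <- union(allowed, seeds)

  # neighbour lists over the node projection
  proj <- node_projection(graph)
  reach_from <- function(permitted) {
    sub <- igraph::induced_subgraph(proj, intersect(permitted, graph$nodes$contig_id))
    present <- intersect(seeds, igraph::V(sub)$name)
    if (!length(present)) return(character(0))
    unique(unlist(lapply(present, function(s) {
      igraph::V(sub)$name[igraph::subcomponent(sub, s)]
    })))
  }
  reached <- reach_from(allowed)

  if (class_label == CLASS_MT) {
    # adopt cp contigs bridging >= 2 reached mt contigs, to a fixpoint
    repeat {
      cp_ids <- names(labels)[labels == CLASS_CP]
      cp_ids <- setdiff(intersect(cp_ids, graph$nodes$contig_id), reached)
      if (!length(cp_ids)) break
      nb <- function(id) {
        e <- graph$edges
        unique(c(e$b_id[e$a_id == id], e$a_id[e$b_id == id]))
      }
      internal <- cp_ids[vapply(cp_ids, function(id) {
        length(intersect(nb(id), reached)) >= 2L
      }, logical(1))]
      if (!length(internal)) break
      allowed <- union(allowed, internal)
      reached <- reach_from(allowed)
    }
  }

  if (!length(reached)) {
    stop("extract_component: no contigs reachable from seeds within class ",
         class_label)
  }
  out <- induced_subgraph_contigs(graph, reached)
  attr(out, "adopted") <- setdiff(
    reached, names(labels)[labels == class_label])
  out
}
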