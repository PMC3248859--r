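# End-to-end assembly pipeline: classify -> extract -> prune -> circle ->
# build, for one organellar class at a time.

#' Assemble one organellar genome from a mixed contig graph
#'
#' Runs the full procedure for the chosen class:
#' \enumerate{
#'   \item classify contigs by read depth (unless a partition is supplied);
#'   \item flag repeat candidates -- contigs whose depth is an integer
#'     multiple of the class's single-copy depth, which plain thresholding
#'     would misplace (a collapsed two-copy mt repeat sequences at ~2x the
#'     mt depth, in cp territory);
#'   \item drop edges below `min_support` (single chimeric reads), then take
#'     the subgraph reachable from the class seeds
#'     ([extract_component()]), remove remaining out-of-class contigs
#'     ([remove_false_links()]), and keep the largest connected component
#'     (the organellar circle dominates; stray same-depth contigs from
#'     other genomes are isolated once their own class is removed);
#'   \item resolve forks by depth agreement ([resolve_forks()]);
#'   \item infer traversal multiplicities and search for closed walks
#'     ([find_circular_path()]); when dispersed repeats leave several walks
#'     and a mate-pair link table is given, select the major links and
#'     expand the repeats into wired copies ([select_major_links()],
#'     [apply_major_links()]), then search again;
#'   \item reconstruct the sequence of each remaining walk and report the
#'     one with the smallest canonical form (for a quadripartite plastid the
#'     surviving walks are the two inversion isomers of the same molecule);
#'   \item annotate the quadripartite structure (CP class) and build the
#'     assembly report.
#' }
#'
#' @param graph A [contig_graph] with contig sequences attached.
#' @param class_label `"CP"` or `"MT"`.
#' @param partition Optional precomputed `depth_partition`; by default
#'   [classify_by_depth()] with thresholds `t_low`/`t_high`.
#' @param link_table Optional mate-pair `link_table` for repeat resolution;
#'   its `repeat_id` values must be repeat contig ids.
#' @param seeds Optional seed contig ids (e.g. from [find_seed_contigs()]);
#'   default: all contigs the partition labels with the class.
#' @param t_low,t_high Depth thresholds (defaults 20/60).
#' @param min_support Minimum edge spanning-read support (default 2).
#' @param tolerance Repeat-multiplicity tolerance (default 0.35).
#' @param max_solutions Walk-search cap (default 16).
#' @return An `organelle_assembly` list: `class_label`, `circle`, `sequence`
#'   (reconstructed, smallest canonical form among walks),
#'   `canonical_sequence`, `alternates` (canonical sequences of the other
#'   walks, e.g. the flip-flop isomer), `report`, `structure`, `graph` (the
#'   pruned graph), `multiplicity`, `partition`.
#' @export
assemble_genome <- function(graph, class_label = c("CP", "MT"),
                            partition = NULL, link_table = NULL,
                            seeds = NULL, t_low = 20, t_high = 60,
                            min_support = 2L, tolerance = 0.35,
                            max_solutions = 16L) {
  class_label <- match.arg(class_label)
  stopifnot(inherits(graph, "contig_graph"))
  if (is.null(partition)) {
    partition <- classify_by_depth(graph, t_low = t_low, t_high = t_high)
  }
  if (is.null(seeds)) {
    seeds <- names(partition$labels)[partition$labels == class_label]
  }
  if (!length(seeds)) {
    stop("assemble_genome: no seed contigs for class ", class_label)
  }

  cands <- repeat_candidates(graph, partition, class_label, tolerance)
  labels <- partition$labels
  labels[setdiff(cands, seeds)] <- CLASS_REPEAT
  part2 <- structure(list(labels = labels, t_low = partition$t_low,
                          t_high = partition$t_high,
                          repeat_flags = setdiff(cands, seeds)),
                     class = "depth_partition")

  g1 <- filter_low_support_edges(graph, min_support)
  g2 <- extract_component(g1, seeds, part2, class_label)
  # adopted contigs now belong to the class
  labels[attr(g2, "adopted")] <- CLASS_REPEAT
  part3 <- structure(list(labels = labels, t_low = part2$t_low,
                          t_high = part2$t_high,
                          repeat_flags = attr(g2, "adopted")),
                     class = "depth_partition")
  g3 <- remove_false_links(g2, part3, class_label, min_support)

  # the organellar circle is the dominant component; drop stray contigs of
  # matching depth that lost their own genome's neighbours
  comp <- igraph::components(node_projection(g3))
  sizes <- tapply(g3$nodes$length, comp$membership[g3$nodes$contig_id], sum)
  keep <- names(comp$membership)[comp$membership ==
                                   as.integer(names(which.max(sizes)))]
  g3 <- induced_subgraph_contigs(g3, keep)

  g4 <- resolve_forks(g3, part3)
  mult <- infer_multiplicity(g4, tolerance)
  walks <- find_circular_path(g4, mult, max_solutions = max_solutions)

  if (length(walks) > 1L && !is.null(link_table)) {
    sel <- select_major_links(link_table)
    rep_ids <- intersect(names(sel), g4$nodes$contig_id)
    if (length(rep_ids)) {
      g4 <- apply_major_links(g4, stats::setNames(rep_ids, rep_ids), sel)
      mult <- stats::setNames(rep(1L, nrow(g4$nodes)), g4$nodes$contig_id)
      expanded_mult <- infer_multiplicity(g4, tolerance)
      mult[names(expanded_mult)] <- expanded_mult
      walks <- find_circular_path(g4, mult, max_solutions = max_solutions)
    }
  }

  seqs <- lapply(walks, function(w) reconstruct_sequence(g4, w))
  canon <- vapply(seqs, function(s) canonical_form(s), character(1))
  best <- order(canon)[1L]
  circle <- walks[[best]]

  annotation <- NULL
  if (class_label == CLASS_CP && any(mult[circle$steps$contig_id] >= 2L)) {
    annotation <- annotate_quadripartite(circle, mult, g4)
  }
  report <- assembly_report(seqs[[best]], circle, g4, annotation)

  structure(list(
    class_label = class_label,
    circle = circle,
    sequence = seqs[[best]],
    canonical_sequence = canon[best],
    alternates = canon[-best],
    report = report,
    structure = annotation,
    graph = g4,
    multiplicity = mult,
    partition = part3
  ), class = "organelle_assembly")
}

#' @export
print.organelle_assembly <- function(x, ...) {
  cat(sprintf("%s assembly\n", x$class_label))
  print(x$report)
  if (length(x$alternates)) {
    cat(sprintf("  %d alternative walk(s) (e.g. inversion isomers) not reported\n",
                length(x$alternates)))
  }
  invisible(x)
}
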