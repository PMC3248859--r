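# Contig-graph data model.
#
# A contig graph is the connection structure an overlap assembler reports:
# contigs are nodes (with length and mean read depth), and reads spanning
# from one contig into another are edges.  Every edge joins a specific *end*
# of each contig (5' or 3'), because a spanning read tells you which ends are
# adjacent; walks through the graph decide orientation, so edges are stored
# unordered (an edge between end X of c1 and end Y of c2 equals its reverse).

#' Construct a contig graph
#'
#' @param nodes Data frame with columns `contig_id` (unique character),
#'   `length` (bases, >= 1), `depth` (mean fold-coverage, > 0), and optionally
#'   `sequence` (IUPAC nucleotide text, `NA` when absent) and `num_reads`.
#' @param edges Data frame with columns `a_id`, `a_end`, `b_id`, `b_end`
#'   (ends are `"5"` or `"3"`), and optionally `support` (spanning-read count,
#'   default 0), `gap` (bases inserted at the join, default 0) and `gap_base`
#'   (single nucleotide, required iff `gap >= 1`). Duplicate unordered edges
#'   with identical ends are merged with summed support.
#' @return An object of class `contig_graph` with elements `nodes` and
#'   `edges` (edges canonically ordered so that `(a_id, a_end) <= (b_id,
#'   b_end)`).
#' @export
contig_graph <- function(nodes = NULL, edges = NULL) {
  nodes <- normalize_nodes(nodes)
  edges <- normalize_edges(edges, nodes$contig_id)
  structure(list(nodes = nodes, edges = edges), class = "contig_graph")
}

normalize_nodes <- function(nodes) {
  if (is.null(nodes) || nrow(as.data.frame(nodes)) == 0L) {
    return(data.frame(
      contig_id = character(0), length = integer(0), depth = numeric(0),
      sequence = character(0), num_reads = integer(0),
      stringsAsFactors = FALSE
    ))
  }
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  req <- c("contig_id", "length", "depth")
  miss <- setdiff(req, names(nodes))
  if (length(miss)) stop("nodes is missing columns: ", paste(miss, collapse = ", "))
  nodes$contig_id <- as.character(nodes$contig_id)
  if (anyDuplicated(nodes$contig_id)) {
    stop("duplicate contig_id in nodes: ",
         paste(unique(nodes$contig_id[duplicated(nodes$contig_id)]), collapse = ", "))
  }
  nodes$length <- as.integer(nodes$length)
  nodes$depth <- as.numeric(nodes$depth)
  if (any(is.na(nodes$length)) || any(nodes$length < 1L)) {
    stop("contig length must be a positive integer")
  }
  if (any(is.na(nodes$depth)) || any(nodes$depth <= 0)) {
    stop("contig depth must be positive")
  }
  if (is.null(nodes$sequence)) nodes$sequence <- NA_character_
  nodes$sequence <- as.character(nodes$sequence)
  has_seq <- !is.na(nodes$sequence)
  if (any(has_seq)) {
    nodes$sequence[has_seq] <- normalize_sequence(nodes$sequence[has_seq],
                                                  "contig sequence")
    bad <- has_seq & nchar(nodes$sequence) != nodes$length
    if (any(bad)) {
      stop("sequence length differs from stated contig length for: ",
           paste(nodes$contig_id[bad], collapse = ", "))
    }
  }
  if (is.null(nodes$num_reads)) nodes$num_reads <- NA_integer_
  nodes$num_reads <- as.integer(nodes$num_reads)
  rownames(nodes) <- NULL
  nodes[c("contig_id", "length", "depth", "sequence", "num_reads")]
}

empty_edges <- function() {
  data.frame(
    a_id = character(0), a_end = character(0),
    b_id = character(0), b_end = character(0),
    support = integer(0), gap = integer(0), gap_base = character(0),
    stringsAsFactors = FALSE
  )
}

normalize_edges <- function(edges, ids) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) return(empty_edges())
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  req <- c("a_id", "a_end", "b_id", "b_end")
  miss <- setdiff(req, names(edges))
  if (length(miss)) stop("edges is missing columns: ", paste(miss, collapse = ", "))
  for (col in req) edges[[col]] <- as.character(edges[[col]])
  if (!all(edges$a_end %in% c(END5, END3)) || !all(edges$b_end %in% c(END5, END3))) {
    stop("edge ends must be \"5\" or \"3\"")
  }
  unknown <- setdiff(c(edges$a_id, edges$b_id), ids)
  if (length(unknown)) {
    stop("edge references unknown contig: ", paste(unique(unknown), collapse = ", "))
  }
  if (is.null(edges$support)) edges$support <- 0L
  edges$support <- as.integer(edges$support)
  if (any(is.na(edges$support)) || any(edges$support < 0L)) {
    stop("edge support must be a non-negative integer")
  }
  if (is.null(edges$gap)) edges$gap <- 0L
  edges$gap <- as.integer(edges$gap)
  if (any(is.na(edges$gap)) || any(edges$gap < 0L)) stop("edge gap must be >= 0")
  if (is.null(edges$gap_base)) edges$gap_base <- NA_character_
  edges$gap_base <- as.character(edges$gap_base)
  bad_gap <- xor(edges$gap >= 1L, !is.na(edges$gap_base))
  if (any(bad_gap)) stop("gap_base must be present iff gap >= 1")

  # canonical endpoint order: (a_id, a_end) <= (b_id, b_end)
  swap <- edges$a_id > edges$b_id |
    (edges$a_id == edges$b_id & edges$a_end > edges$b_end)
  if (any(swap)) {
    tmp_id <- edges$a_id[swap]; tmp_end <- edges$a_end[swap]
    edges$a_id[swap] <- edges$b_id[swap]; edges$a_end[swap] <- edges$b_end[swap]
    edges$b_id[swap] <- tmp_id; edges$b_end[swap] <- tmp_end
  }
  key <- edge_keys(edges)
  if (anyDuplicated(key)) {
    agg <- tapply(edges$support, key, sum)
    keep <- !duplicated(key)
    edges <- edges[keep, , drop = FALSE]
    edges$support <- as.integer(agg[edge_keys(edges)])
  }
  edges <- edges[order(edges$a_id, edges$a_end, edges$b_id, edges$b_end), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  edges[c("a_id", "a_end", "b_id", "b_end", "support", "gap", "gap_base")]
}

edge_keys <- function(edges) {
  paste(edges$a_id, edges$a_end, edges$b_id, edges$b_end, sep = "\r")
}

#' @export
print.contig_graph <- function(x, ...) {
  cat(sprintf("contig_graph: %d contigs (%s bp), %d edges\n",
              nrow(x$nodes), format(sum(x$nodes$length), big.mark = ","),
              nrow(x$edges)))
  if (nrow(x$nodes)) {
    cat(sprintf("  depth range: %.1f-%.1f; %d contigs carry sequence\n",
                min(x$nodes$depth), max(x$nodes$depth),
                sum(!is.na(x$nodes$sequence))))
  }
  invisible(x)
}

# induced subgraph on a set of contig ids
induced_subgraph_contigs <- function(graph, ids) {
  keep_n <- graph$nodes$contig_id %in% ids
  keep_e <- graph$edges$a_id %in% ids & graph$edges$b_id %in% ids
  contig_graph(graph$nodes[keep_n, , drop = FALSE],
               graph$edges[keep_e, , drop = FALSE])
}

# node projection as an igraph object (ends dropped); used for
# reachability/component queries only, never for walk search
node_projection <- function(graph) {
  igraph::graph_from_data_frame(
    d = graph$edges[, c("a_id", "b_id"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = graph$nodes$contig_id)
  )
}

# edge crossings incident to each (contig, end); self-paired ends count twice
end_degrees <- function(graph) {
  ids <- graph$nodes$contig_id
  deg <- matrix(0L, nrow = length(ids), ncol = 2L,
                dimnames = list(ids, c(END5, END3)))
  e <- graph$edges
  for (i in seq_len(nrow(e))) {
    deg[e$a_id[i], e$a_end[i]] <- deg[e$a_id[i], e$a_end[i]] + 1L
    deg[e$b_id[i], e$b_end[i]] <- deg[e$b_id[i], e$b_end[i]] + 1L
  }
  deg
}

#' Assembly summary statistics (contig count, total bases, N50)
#'
#' N50 is the smallest contig length L such that contigs of length >= L sum
#' to at least half of the total bases.  Repeat contigs can be counted once
#' (the convention used for circle-graph reporting) or once per traversal via
#' `multiplicity`.
#'
#' @param contigs A `contig_graph`, a nodes data frame, or a numeric vector of
#'   contig lengths.
#' @param count_repeats_once If `TRUE` (default) each contig's length is
#'   counted once regardless of multiplicity.
#' @param multiplicity Optional named integer vector (contig_id -> copy
#'   count); when given and `count_repeats_once = FALSE`, each contig length
#'   is counted `multiplicity` times.
#' @return A `stats_record` list with `n_contigs`, `total_bp`, `n50`.
#' @export
graph_stats <- function(contigs, count_repeats_once = TRUE, multiplicity = NULL) {
  if (inherits(contigs, "contig_graph")) contigs <- contigs$nodes
  if (is.data.frame(contigs)) {
    lengths <- contigs$length
    ids <- contigs$contig_id
  } else {
    lengths <- contigs
    ids <- names(contigs)
  }
  if (length(lengths) == 0L) stop("graph_stats: empty contig collection")
  n_contigs <- length(lengths)
  if (!count_repeats_once && !is.null(multiplicity)) {
    if (is.null(ids)) stop("multiplicity weighting needs contig ids")
    m <- rep(1L, length(ids))
    hit <- ids %in% names(multiplicity)
    m[hit] <- as.integer(multiplicity[ids[hit]])
    lengths <- rep(lengths, m)
  }
  total_bp <- sum(as.numeric(lengths))
  sl <- sort(lengths, decreasing = TRUE)
  n50 <- sl[which(cumsum(as.numeric(sl)) >= total_bp / 2)[1L]]
  structure(list(n_contigs = n_contigs, total_bp = total_bp, n50 = n50),
            class = "stats_record")
}

#' @export
print.stats_record <- function(x, ...) {
  cat(sprintf("%d contigs, %s bp, N50 %s bp\n", x$n_contigs,
              format(x$total_bp, big.mark = ","),
              format(x$n50, big.mark = ",")))
  invisible(x)
}
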