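# Circular traversal of the pruned organellar graph.
#
# After pruning, the organellar contig graph should admit a closed walk that
# traverses each contig once per genomic copy (repeat contigs are collapsed
# by the assembler, so they must be traversed multiple times).  The walk
# search is exhaustive backtracking: organellar graphs at this stage are
# small, so completeness is preferred over heuristics.  When dispersed
# repeats leave more than one closed walk, mate-pair link counts across each
# repeat decide the flank pairing (major links) and the master circle.

#' Construct a circle path
#'
#' @param steps Data frame with columns `contig_id` and `orient`
#'   (`"+"` forward, `"-"` reverse), in traversal order.
#' @param multiplicity Named integer vector of per-contig copy counts.
#' @param closed Whether the last step joins back to the first.
#' @return A `circle_path` object.
#' @export
circle_path <- function(steps, multiplicity, closed = TRUE) {
  steps <- as.data.frame(steps, stringsAsFactors = FALSE)
  stopifnot(all(c("contig_id", "orient") %in% names(steps)),
            all(steps$orient %in% c(FORWARD, REVERSE)))
  cnt <- table(steps$contig_id)
  for (id in names(cnt)) {
    m <- if (id %in% names(multiplicity)) multiplicity[[id]] else 1L
    if (cnt[[id]] != m) {
      stop(sprintf("circle_path: %s traversed %d times, multiplicity %d",
                   id, cnt[[id]], m))
    }
  }
  structure(list(steps = steps[c("contig_id", "orient")],
                 closed = isTRUE(closed),
                 multiplicity = multiplicity),
            class = "circle_path")
}

#' @export
print.circle_path <- function(x, ...) {
  cat(sprintf("circle_path: %d steps (%s), %d distinct contigs\n",
              nrow(x$steps), if (x$closed) "closed" else "open",
              length(unique(x$steps$contig_id))))
  cat(" ", paste0(x$steps$contig_id,
                  ifelse(x$steps$orient == FORWARD, "(+)", "(-)"),
                  collapse = " -> "), "\n")
  invisible(x)
}

# canonical key of a closed walk: minimum over all rotations of the step
# string and all rotations of the reversed walk (reverse order, flipped
# orientation).  Used to deduplicate walks and make output invariant to the
# starting contig.
canonical_walk_key <- function(steps) {
  n <- nrow(steps)
  lab <- paste0(steps$contig_id, steps$orient)
  rev_lab <- paste0(rev(steps$contig_id), flip_orient(rev(steps$orient)))
  best <- NULL
  for (v in list(lab, rev_lab)) {
    for (r in seq_len(n)) {
      rot <- paste(c(v[r:n], v[seq_len(r - 1L)]), collapse = "|")
      if (is.null(best) || rot < best) best <- rot
    }
  }
  best
}

# rotate a closed walk so the canonical representation starts first
canonicalize_walk <- function(steps) {
  n <- nrow(steps)
  key <- canonical_walk_key(steps)
  for (v in list(steps, data.frame(contig_id = rev(steps$contig_id),
                                   orient = flip_orient(rev(steps$orient)),
                                   stringsAsFactors = FALSE))) {
    lab <- paste0(v$contig_id, v$orient)
    for (r in seq_len(n)) {
      idx <- c(r:n, seq_len(r - 1L))
      if (paste(lab[idx], collapse = "|") == key) {
        out <- v[idx, , drop = FALSE]
        rownames(out) <- NULL
        return(out)
      }
    }
  }
  steps
}

#' Infer per-contig traversal multiplicity on a pruned graph
#'
#' Recomputes the depth-ratio repeat flags of [flag_repeats()] on the pruned
#' single-class graph (all contigs treated as one class); unflagged contigs
#' get multiplicity 1.
#'
#' @param graph A pruned, single-class [contig_graph].
#' @param tolerance Relative-deviation tolerance, as in [flag_repeats()].
#' @return Named integer vector contig_id -> copy count (>= 1) over all
#'   contigs.
#' @export
infer_multiplicity <- function(graph, tolerance = 0.35) {
  stopifnot(inherits(graph, "contig_graph"))
  if (nrow(graph$nodes) < 3L) {
    stop("infer_multiplicity: fewer than 3 contigs; set multiplicities manually")
  }
  res <- depth_multiplicities(graph$nodes$length, graph$nodes$depth, tolerance)
  m <- res$multiplicity
  names(m) <- graph$nodes$contig_id
  attr(m, "base_depth") <- res$base_depth
  m
}

#' Find all circular traversals of a contig graph
#'
#' Exhaustive backtracking for closed walks that traverse each contig exactly
#' `multiplicity` times and realize every edge at least once.  Each traversal
#' of a contig crosses each of its ends exactly once, so the number of edge
#' crossings at an end equals the contig's multiplicity; an end with more
#' incident edges than multiplicity (or none at all) is reported as a
#' degree violation.  Walks are returned up to rotation and full reversal
#' (canonicalized, deterministic order).  More than one walk means the
#' repeat layout is ambiguous and must be resolved with mate-pair links.
#'
#' @param graph A pruned [contig_graph].
#' @param multiplicity Named integer vector contig_id -> copy count;
#'   contigs not named get multiplicity 1.
#' @param max_solutions Stop after this many distinct walks, with a warning
#'   (default 16).
#' @return List of closed [circle_path] objects (possibly of length > 1).
#' @export
find_circular_path <- function(graph, multiplicity = NULL, max_solutions = 16L) {
  stopifnot(inherits(graph, "contig_graph"))
  ids <- graph$nodes$contig_id
  if (!length(ids)) stop("find_circular_path: empty graph")
  mult <- rep(1L, length(ids))
  names(mult) <- ids
  if (!is.null(multiplicity)) {
    hit <- intersect(names(multiplicity), ids)
    mult[hit] <- as.integer(multiplicity[hit])
  }

  deg <- end_degrees(graph)
  viol <- character(0)
  for (id in ids) {
    for (end in c(END5, END3)) {
      d <- deg[id, end]
      if (d == 0L || d > mult[[id]]) {
        viol <- c(viol, sprintf("%s %s' end: degree %d, multiplicity %d",
                                id, end, d, mult[[id]]))
      }
    }
  }
  if (length(viol)) {
    stop("find_circular_path: no closed walk exists; end-degree violations:\n  ",
         paste(viol, collapse = "\n  "))
  }

  e <- graph$edges
  n_edges <- nrow(e)
  idx <- incidence_index(graph)
  total_steps <- sum(mult)

  # prefer a single-copy start contig: with the first traversal fixed
  # forward, rotation and reversal symmetry is quotiented out directly
  singles <- ids[mult == 1L]
  start <- if (length(singles)) min(singles) else min(ids)

  cap <- new.env(parent = emptyenv()) # remaining crossings per (id, end)
  for (id in ids) {
    assign(paste(id, END5, sep = "\r"), mult[[id]], envir = cap)
    assign(paste(id, END3, sep = "\r"), mult[[id]], envir = cap)
  }
  usage <- integer(n_edges)
  trav <- mult # remaining traversals per contig
  seen_keys <- character(0)
  solutions <- list()
  hit_cap <- FALSE

  cap_get <- function(id, end) get(paste(id, end, sep = "\r"), envir = cap)
  cap_add <- function(id, end, v) {
    key <- paste(id, end, sep = "\r")
    assign(key, get(key, envir = cap) + v, envir = cap)
  }

  steps_id <- character(total_steps)
  steps_or <- character(total_steps)

  dfs <- function(depth_i, cur_id, cur_exit) {
    if (hit_cap) return()
    inc <- incident(idx, cur_id, cur_exit)
    if (is.null(inc)) return()
    if (cap_get(cur_id, cur_exit) < 1L) return()
    for (r in seq_len(nrow(inc))) {
      if (hit_cap) return()
      ei <- inc$edge[r]
      t_id <- inc$other_id[r]
      t_end <- inc$other_end[r]
      if (cap_get(t_id, t_end) < 1L) next
      if (depth_i == total_steps) {
        # closing edge: must return to the start contig's entry end
        if (t_id == start && t_end == END5) {
          cap_add(cur_id, cur_exit, -1L); cap_add(t_id, t_end, -1L)
          usage[ei] <<- usage[ei] + 1L
          if (all(usage >= 1L)) {
            st <- data.frame(contig_id = steps_id, orient = steps_or,
                             stringsAsFactors = FALSE)
            key <- canonical_walk_key(st)
            if (!key %in% seen_keys) {
              seen_keys <<- c(seen_keys, key)
              solutions[[length(solutions) + 1L]] <<-
                canonicalize_walk(st)
              if (length(solutions) >= max_solutions) hit_cap <<- TRUE
            }
          }
          usage[ei] <<- usage[ei] - 1L
          cap_add(cur_id, cur_exit, 1L); cap_add(t_id, t_end, 1L)
        }
        next
      }
      if (trav[[t_id]] < 1L) next
      orient <- if (t_end == END5) FORWARD else REVERSE
      cap_add(cur_id, cur_exit, -1L); cap_add(t_id, t_end, -1L)
      usage[ei] <<- usage[ei] + 1L
      trav[[t_id]] <<- trav[[t_id]] - 1L
      steps_id[depth_i + 1L] <<- t_id
      steps_or[depth_i + 1L] <<- orient
      dfs(depth_i + 1L, t_id, opposite_end(t_end))
      trav[[t_id]] <<- trav[[t_id]] + 1L
      usage[ei] <<- usage[ei] - 1L
      cap_add(cur_id, cur_exit, 1L); cap_add(t_id, t_end, 1L)
    }
  }

  steps_id[1L] <- start
  steps_or[1L] <- FORWARD
  trav[[start]] <- trav[[start]] - 1L
  dfs(1L, start, END3)

  if (hit_cap) {
    warning(sprintf(
      "find_circular_path: stopped after %d walks; repeat layout is ambiguous, resolve with mate-pair links",
      as.integer(max_solutions)))
  }
  if (!length(solutions)) {
    stop("find_circular_path: end degrees are consistent but no closed walk covers the graph (is it connected?)")
  }
  ord <- order(vapply(solutions, function(s) canonical_walk_key(s), character(1)))
  lapply(solutions[ord], function(s) circle_path(s, mult, closed = TRUE))
}

#' Annotate the quadripartite plastid structure of a circle
#'
#' The contigs traversed twice form the collapsed inverted repeat (IR); the
#' two single-copy arcs between the IR's two traversals are the large and
#' small single-copy regions, the longer arc labelled LSC.  Segment lengths
#' are in bases (sum of contig lengths).  With no multiplicity-2 contig the
#' annotation degenerates to one LSC segment with a warning; more than one
#' distinct repeat run is an error (an mt-style dispersed-repeat layout, to
#' be resolved with mate-pair links instead).
#'
#' @param circle A closed [circle_path].
#' @param multiplicity Named integer vector contig_id -> copy count.
#' @param graph The [contig_graph] the circle traverses.
#' @return A `structure_annotation`: list with `segments` (data frame of
#'   region, step indices into the circle, and length) and `lsc_len`,
#'   `ssc_len`, `ir_len`.
#' @export
annotate_quadripartite <- function(circle, multiplicity, graph) {
  stopifnot(inherits(circle, "circle_path"), circle$closed,
            inherits(graph, "contig_graph"))
  steps <- circle$steps
  n <- nrow(steps)
  mult <- rep(1L, n)
  hit <- steps$contig_id %in% names(multiplicity)
  mult[hit] <- as.integer(multiplicity[steps$contig_id[hit]])
  len <- graph$nodes$length[match(steps$contig_id, graph$nodes$contig_id)]
  if (any(is.na(len))) stop("annotate_quadripartite: circle step not in graph")

  is_rep <- mult >= 2L
  if (any(mult > 2L)) {
    stop("annotate_quadripartite: contig with multiplicity > 2; use mate-pair repeat resolution")
  }
  if (!any(is_rep)) {
    warning("annotate_quadripartite: no repeat contig; annotating a single LSC segment")
    segments <- data.frame(region = "LSC", step_from = 1L, step_to = n,
                           length_bp = sum(len), stringsAsFactors = FALSE)
    return(structure(list(segments = segments, lsc_len = sum(len),
                          ssc_len = 0L, ir_len = 0L),
                     class = "structure_annotation"))
  }
  if (all(is_rep)) {
    stop("annotate_quadripartite: every contig is a repeat; no single-copy arcs")
  }

  # rotate so position 1 starts a single-copy arc right after a repeat run
  off <- which(is_rep & !is_rep[c(2:n, 1L)])[1L]
  rot <- ((off + seq_len(n) - 1L) %% n) + 1L
  r_rep <- is_rep[rot]
  runs <- rle(r_rep)
  rep_runs <- which(runs$values)
  if (length(rep_runs) != 2L) {
    stop("annotate_quadripartite: found ", length(rep_runs),
         " repeat runs; expected 2 traversals of one IR run (mt-style repeats need mate-pair resolution)")
  }
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  seg_idx <- lapply(seq_along(runs$lengths), function(i) rot[starts[i]:ends[i]])
  # rotation guarantees layout: arc1, IR(first), arc2, IR(second)
  if (!(length(runs$lengths) == 4L && !runs$values[1L])) {
    stop("annotate_quadripartite: unexpected arc layout")
  }
  ira <- seg_idx[[2L]]; irb <- seg_idx[[4L]]
  if (!setequal(steps$contig_id[ira], steps$contig_id[irb])) {
    stop("annotate_quadripartite: the two repeat runs traverse different contigs")
  }
  arc1 <- seg_idx[[1L]]; arc2 <- seg_idx[[3L]]
  len1 <- sum(len[arc1]); len2 <- sum(len[arc2])
  ir_len <- sum(len[ira])
  if (len1 == len2) {
    message("annotate_quadripartite: equal single-copy arcs; first-traversed arc labelled LSC")
  }
  if (len1 >= len2) {
    lsc <- arc1; ssc <- arc2; lsc_len <- len1; ssc_len <- len2
    order_idx <- list(LSC = arc1, IRa = ira, SSC = arc2, IRb = irb)
  } else {
    lsc <- arc2; ssc <- arc1; lsc_len <- len2; ssc_len <- len1
    order_idx <- list(LSC = arc2, IRa = irb, SSC = arc1, IRb = ira)
  }
  segments <- data.frame(
    region = names(order_idx),
    step_from = vapply(order_idx, function(ix) ix[1L], integer(1)),
    step_to = vapply(order_idx, function(ix) ix[length(ix)], integer(1)),
    length_bp = vapply(order_idx, function(ix) sum(len[ix]), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(segments) <- NULL
  structure(list(segments = segments, steps = order_idx,
                 lsc_len = lsc_len, ssc_len = ssc_len, ir_len = ir_len),
            class = "structure_annotation")
}

#' @export
print.structure_annotation <- function(x, ...) {
  cat(sprintf("quadripartite structure: LSC %s bp, SSC %s bp, IR %s bp (x2)\n",
              format(x$lsc_len, big.mark = ","),
              format(x$ssc_len, big.mark = ","),
              format(x$ir_len, big.mark = ",")))
  invisible(x)
}

#' Select major mate-pair links per repeat
#'
#' For each repeat, the candidate rows pair flanking contigs with a
#' mate-pair link count.  The major links are the set of rows of maximum
#' total link count in which every flanking contig occurs exactly once --
#' a maximum-weight perfect matching over the candidate rows.  All other
#' rows are the minor links and are reported, never assembled.  A tie in
#' total weight, or the absence of any perfect matching, is an error that
#' demands a manual decision.
#'
#' @param table A `link_table` (see [read_link_table()]).
#' @return A `major_link_selection`: per repeat (in order of first
#'   appearance), `selected` and `rejected` row subsets and `total_support`.
#' @export
select_major_links <- function(table) {
  table <- link_table(table)
  out <- list()
  for (rid in unique(table$repeat_id)) {
    rows <- table[table$repeat_id == rid, , drop = FALSE]
    n <- nrow(rows)
    if (n > 16L) stop("select_major_links: more than 16 candidate rows for repeat ", rid)
    contigs <- sort(unique(c(rows$five_prime_contig, rows$three_prime_contig)))
    occ <- factor(c(rows$five_prime_contig, rows$three_prime_contig),
                  levels = contigs)
    occ_mat <- matrix(0L, nrow = n, ncol = length(contigs))
    for (i in seq_len(n)) {
      occ_mat[i, match(rows$five_prime_contig[i], contigs)] <-
        occ_mat[i, match(rows$five_prime_contig[i], contigs)] + 1L
      occ_mat[i, match(rows$three_prime_contig[i], contigs)] <-
        occ_mat[i, match(rows$three_prime_contig[i], contigs)] + 1L
    }
    best_w <- -Inf
    best_masks <- integer(0)
    for (mask in seq_len(2^n) - 1L) {
      sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
      if (!length(sel)) next
      cover <- colSums(occ_mat[sel, , drop = FALSE])
      if (any(cover != 1L)) next
      w <- sum(rows$link_count[sel])
      if (w > best_w) {
        best_w <- w
        best_masks <- mask
      } else if (w == best_w) {
        best_masks <- c(best_masks, mask)
      }
    }
    if (!length(best_masks)) {
      stop("select_major_links: no perfect flank matching exists for repeat ", rid)
    }
    if (length(best_masks) > 1L) {
      stop("select_major_links: tied matchings (total ", best_w,
           ") for repeat ", rid, "; choose manually")
    }
    sel <- which(bitwAnd(best_masks, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    out[[rid]] <- list(
      repeat_id = rid,
      selected = rows[sel, , drop = FALSE],
      rejected = rows[-sel, , drop = FALSE],
      total_support = sum(rows$link_count[sel])
    )
  }
  structure(out, class = "major_link_selection")
}

#' @export
print.major_link_selection <- function(x, ...) {
  for (sel in x) {
    cat(sprintf("%s: major links (total %d)\n", sel$repeat_id,
                sel$total_support))
    for (i in seq_len(nrow(sel$selected))) {
      cat(sprintf("  %s -- %s (%d links)\n",
                  sel$selected$five_prime_contig[i],
                  sel$selected$three_prime_contig[i],
                  sel$selected$link_count[i]))
    }
  }
  invisible(x)
}

#' Apply major-link selections: expand repeats into wired copies
#'
#' Replaces each repeat contig by one copy per selected link, wiring every
#' copy between its selected flank pair using the ends of the original
#' repeat-flank edges.  Sequence content is conserved (`length x
#' multiplicity` before equals the summed copy lengths after) and each
#' copy's depth is the original divided by the copy number.  With all
#' repeats expanded, the graph should admit a unique circular walk -- the
#' master circle.
#'
#' @param graph A [contig_graph].
#' @param repeats Named character vector, repeat_id -> repeat contig id.
#' @param selection A `major_link_selection` from [select_major_links()].
#' @return The expanded [contig_graph].
#' @export
apply_major_links <- function(graph, repeats, selection) {
  stopifnot(inherits(graph, "contig_graph"),
            inherits(selection, "major_link_selection"))
  for (rid in names(repeats)) {
    if (!rid %in% names(selection)) {
      stop("apply_major_links: no selection for repeat ", rid)
    }
    r_contig <- repeats[[rid]]
    if (!r_contig %in% graph$nodes$contig_id) {
      stop("apply_major_links: repeat contig ", r_contig, " not in graph")
    }
    sel <- selection[[rid]]$selected
    m <- nrow(sel)
    node <- graph$nodes[graph$nodes$contig_id == r_contig, , drop = FALSE]
    inc_a <- graph$edges$a_id == r_contig
    inc_b <- graph$edges$b_id == r_contig
    flank_edge <- function(flank) {
      i <- which((inc_a & graph$edges$b_id == flank) |
                   (inc_b & graph$edges$a_id == flank))
      if (!length(i)) {
        stop("apply_major_links: selected link references non-neighbour ",
             flank, " of repeat contig ", r_contig)
      }
      i[1L]
    }
    new_nodes <- NULL
    new_edges <- NULL
    for (i in seq_len(m)) {
      copy_id <- sprintf("%s#%d", r_contig, i)
      nd <- node
      nd$contig_id <- copy_id
      nd$depth <- node$depth / m
      new_nodes <- rbind(new_nodes, nd)
      for (flank in c(sel$five_prime_contig[i], sel$three_prime_contig[i])) {
        ei <- flank_edge(flank)
        ed <- graph$edges[ei, , drop = FALSE]
        if (ed$a_id == r_contig) ed$a_id <- copy_id else ed$b_id <- copy_id
        new_edges <- rbind(new_edges, ed)
      }
    }
    keep_nodes <- graph$nodes[graph$nodes$contig_id != r_contig, , drop = FALSE]
    keep_edges <- graph$edges[!(inc_a | inc_b), , drop = FALSE]
    graph <- contig_graph(rbind(keep_nodes, new_nodes),
                          rbind(keep_edges, new_edges))
  }
  graph
}
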