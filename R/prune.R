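# Graph pruning: removal of false links (contigs and edges that do not
# belong to the class being assembled) and resolution of forks (alternative
# internal paths between the same pair of contig ends).  After pruning, a
# clean organellar graph should admit a circular traversal.

removal_log <- function(type = character(0), target = character(0),
                        reason = character(0)) {
  data.frame(type = type, target = target, reason = reason,
             stringsAsFactors = FALSE)
}

#' Remove false links from a class-restricted assembly graph
#'
#' Deletes every contig not labelled `class_label` or REPEAT (false links
#' between genomes normally join contigs of different depth classes), then
#' deletes surviving edges whose spanning-read support is below
#' `min_support` (single-read joins are likely chimeric).  Every removal is
#' recorded with its reason in the `"removals"` attribute; replaying that log
#' with [apply_removal_log()] on the input reproduces the output exactly.
#'
#' @param graph A [contig_graph].
#' @param partition A `depth_partition` covering the graph.
#' @param class_label `"CP"` or `"MT"`.
#' @param min_support Minimum spanning-read support for an edge to survive
#'   (default 2).
#' @return The pruned [contig_graph] with a `"removals"` attribute.
#' @export
remove_false_links <- function(graph, partition, class_label, min_support = 2L) {
  stopifnot(inherits(graph, "contig_graph"),
            inherits(partition, "depth_partition"))
  labels <- partition$labels[graph$nodes$contig_id]
  keep <- labels %in% c(class_label, CLASS_REPEAT)
  log <- removal_log(
    type = rep("node", sum(!keep)),
    target = graph$nodes$contig_id[!keep],
    reason = sprintf("label %s outside class %s", labels[!keep], class_label)
  )
  nodes <- graph$nodes[keep, , drop = FALSE]
  edges <- graph$edges[graph$edges$a_id %in% nodes$contig_id &
                         graph$edges$b_id %in% nodes$contig_id, , drop = FALSE]
  weak <- edges$support < min_support
  if (any(weak)) {
    log <- rbind(log, removal_log(
      type = rep("edge", sum(weak)),
      target = edge_keys(edges)[weak],
      reason = sprintf("support %d < min_support %d",
                       edges$support[weak], as.integer(min_support))
    ))
    edges <- edges[!weak, , drop = FALSE]
  }
  if (nrow(nodes) == 0L) {
    stop("remove_false_links: no contigs of class ", class_label, " remain")
  }
  out <- contig_graph(nodes, edges)
  attr(out, "removals") <- log
  out
}

# drop edges below a support threshold without touching nodes; used by the
# pipeline before reachability so single-read chimeric joins cannot bridge
# genomes during component extraction
filter_low_support_edges <- function(graph, min_support = 2L) {
  keep <- graph$edges$support >= min_support
  log <- removal_log(
    type = rep("edge", sum(!keep)),
    target = edge_keys(graph$edges)[!keep],
    reason = sprintf("support %d < min_support %d",
                     graph$edges$support[!keep], as.integer(min_support))
  )
  out <- contig_graph(graph$nodes, graph$edges[keep, , drop = FALSE])
  attr(out, "removals") <- log
  out
}

#' Replay a removal log
#'
#' Applies the `"removals"` log produced by the pruning operations to a
#' graph: node removals delete the contig and all incident edges; edge
#' removals delete the canonical edge.
#'
#' @param graph A [contig_graph].
#' @param log A removal-log data frame (`type`, `target`, `reason`).
#' @return The [contig_graph] after the removals.
#' @export
apply_removal_log <- function(graph, log) {
  stopifnot(inherits(graph, "contig_graph"))
  drop_nodes <- log$target[log$type == "node"]
  nodes <- graph$nodes[!graph$nodes$contig_id %in% drop_nodes, , drop = FALSE]
  edges <- graph$edges[graph$edges$a_id %in% nodes$contig_id &
                         graph$edges$b_id %in% nodes$contig_id, , drop = FALSE]
  drop_edges <- log$target[log$type == "edge"]
  edges <- edges[!edge_keys(edges) %in% drop_edges, , drop = FALSE]
  contig_graph(nodes, edges)
}

# adjacency index: "id\r end" -> data.frame(edge, other_id, other_end)
incidence_index <- function(graph) {
  e <- graph$edges
  idx <- new.env(parent = emptyenv())
  add <- function(id, end, i, oid, oend) {
    key <- paste(id, end, sep = "\r")
    cur <- if (exists(key, envir = idx, inherits = FALSE)) get(key, envir = idx) else NULL
    assign(key, rbind(cur, data.frame(edge = i, other_id = oid,
                                      other_end = oend,
                                      stringsAsFactors = FALSE)),
           envir = idx)
  }
  for (i in seq_len(nrow(e))) {
    add(e$a_id[i], e$a_end[i], i, e$b_id[i], e$b_end[i])
    add(e$b_id[i], e$b_end[i], i, e$a_id[i], e$a_end[i])
  }
  idx
}

incident <- function(idx, id, end) {
  key <- paste(id, end, sep = "\r")
  if (exists(key, envir = idx, inherits = FALSE)) get(key, envir = idx) else NULL
}

# enumerate simple branch paths out of one contig end.  A path crosses an
# edge into a contig, traverses it to its other end, crosses the next edge,
# ... and may terminate at any reached contig end whose contig is not
# already internal to the path.  Internal contigs are distinct and never
# the start contig; at most max_internal of them.
branch_paths_from <- function(graph, idx, sid, send, max_internal) {
  paths <- list()
  walk <- function(id, end, internal, edges_used) {
    inc <- incident(idx, id, end)
    if (is.null(inc)) return()
    for (r in seq_len(nrow(inc))) {
      ei <- inc$edge[r]
      if (ei %in% edges_used) next
      t_id <- inc$other_id[r]
      t_end <- inc$other_end[r]
      if (t_id %in% internal) next
      paths[[length(paths) + 1L]] <<- list(
        terminal = c(t_id, t_end), internal = internal,
        edges = c(edges_used, ei)
      )
      if (t_id != sid && length(internal) < max_internal) {
        walk(t_id, opposite_end(t_end), c(internal, t_id), c(edges_used, ei))
      }
    }
  }
  walk(sid, send, character(0), integer(0))
  paths
}

#' Detect forks in a contig graph
#'
#' A fork is a pair of contig ends joined by two or more alternative paths
#' with different (pairwise disjoint) internal contigs -- typically a genuine
#' organellar path shadowed by a spurious detour through another genome's
#' contig.  Branches with up to `max_branch_len` internal contigs are
#' enumerated; forks in pruned organellar graphs are short detours, so the
#' cap bounds enumeration without losing real cases.
#'
#' @param graph A [contig_graph].
#' @param max_branch_len Maximum internal contigs per branch (default 5).
#' @return List of forks, each a list with `start` and `end`
#'   (`c(contig_id, end)`) and `branches` (list of `list(internal, edges)`;
#'   internal may be empty for a direct edge).
#' @export
detect_forks <- function(graph, max_branch_len = 5L) {
  stopifnot(inherits(graph, "contig_graph"))
  if (nrow(graph$edges) == 0L) return(list())
  idx <- incidence_index(graph)
  all_paths <- list()
  for (i in seq_len(nrow(graph$nodes))) {
    for (end in c(END5, END3)) {
      sid <- graph$nodes$contig_id[i]
      ps <- branch_paths_from(graph, idx, sid, end, max_branch_len)
      for (p in ps) {
        p$start <- c(sid, end)
        all_paths[[length(all_paths) + 1L]] <- p
      }
    }
  }
  if (!length(all_paths)) return(list())
  ends_key <- function(p) {
    a <- paste(p$start, collapse = "\r")
    b <- paste(p$terminal, collapse = "\r")
    paste(sort(c(a, b)), collapse = "\n")
  }
  keys <- vapply(all_paths, ends_key, character(1))
  forks <- list()
  for (k in sort(unique(keys))) {
    grp <- all_paths[keys == k]
    # orient every path from the lexicographically first endref and dedupe
    # (each path is found once from each of its two ends)
    sig <- vapply(grp, function(p) paste(sort(p$edges), collapse = ","),
                  character(1))
    grp <- grp[!duplicated(sig)]
    if (length(grp) < 2L) next
    disjoint <- TRUE
    for (a in seq_along(grp)) {
      for (b in seq_along(grp)) {
        if (a < b && length(intersect(grp[[a]]$internal, grp[[b]]$internal))) {
          disjoint <- FALSE
        }
      }
    }
    if (!disjoint) next
    refs <- strsplit(k, "\n", fixed = TRUE)[[1L]]
    forks[[length(forks) + 1L]] <- list(
      start = strsplit(refs[1L], "\r", fixed = TRUE)[[1L]],
      end = strsplit(refs[2L], "\r", fixed = TRUE)[[1L]],
      branches = lapply(grp, function(p) list(internal = p$internal,
                                              edges = p$edges))
    )
  }
  forks
}

#' Resolve forks by depth agreement with the unique paths
#'
#' For each fork, keeps the branch whose length-weighted mean depth is
#' closest to the reference depth -- the length-weighted mean depth of the
#' unique contigs that sit on no fork branch -- and deletes the internal
#' contigs (or, for a direct-edge branch, the edge) of the losing branches.
#' Ties are broken by higher total edge support, then by lexicographically
#' smallest internal contig ids.  A branch with no internal contigs scores
#' the reference depth itself (a direct join carries no depth evidence
#' against the unique paths).
#'
#' Forks touching repeat contigs -- as a branch-internal contig or as a fork
#' endpoint -- are left alone: around a collapsed multi-copy repeat the
#' apparent branches (the direct flank edge and the loop back through the
#' repeat, or the two inter-copy segments hanging off a repeat's ends) are
#' all used by the true circular walk.  Repeat contigs are those the
#' partition labels REPEAT plus those whose depth is an integer multiple
#' (>= 2) of the graph's single-copy depth.
#'
#' @param graph A [contig_graph] (already class-restricted).
#' @param partition Optional `depth_partition`; when given, reference depth
#'   is computed from contigs not labelled NUCLEAR.
#' @param max_branch_len Passed to [detect_forks()].
#' @return The resolved [contig_graph] with a `"removals"` attribute.
#' @export
resolve_forks <- function(graph, partition = NULL, max_branch_len = 5L) {
  stopifnot(inherits(graph, "contig_graph"))
  forks <- detect_forks(graph, max_branch_len)
  log <- removal_log()
  if (!length(forks)) {
    attr(graph, "removals") <- log
    return(graph)
  }
  repeat_ids <- character(0)
  if (!is.null(partition)) {
    repeat_ids <- names(partition$labels)[partition$labels == CLASS_REPEAT]
  }
  if (nrow(graph$nodes) >= 3L) {
    m <- depth_multiplicities(graph$nodes$length, graph$nodes$depth)$multiplicity
    repeat_ids <- union(repeat_ids, graph$nodes$contig_id[m >= 2L])
  }
  touches_repeat <- vapply(forks, function(f) {
    any(c(f$start[1L], f$end[1L],
          unlist(lapply(f$branches, `[[`, "internal"))) %in% repeat_ids)
  }, logical(1))
  forks <- forks[!touches_repeat]
  if (!length(forks)) {
    attr(graph, "removals") <- log
    return(graph)
  }
  fork_internal <- unique(unlist(lapply(forks, function(f) {
    unlist(lapply(f$branches, `[[`, "internal"))
  })))
  ref_ids <- setdiff(graph$nodes$contig_id, fork_internal)
  if (!is.null(partition)) {
    lab <- partition$labels[ref_ids]
    ref_ids <- ref_ids[!is.na(lab) & lab != CLASS_NUCLEAR]
  }
  if (!length(ref_ids)) ref_ids <- graph$nodes$contig_id
  ridx <- match(ref_ids, graph$nodes$contig_id)
  ref_depth <- stats::weighted.mean(graph$nodes$depth[ridx],
                                    graph$nodes$length[ridx])

  cur <- graph
  # deterministic fork order: by endref key
  ord <- order(vapply(forks, function(f) {
    paste(c(f$start, f$end), collapse = "\r")
  }, character(1)))
  for (f in forks[ord]) {
    # skip forks invalidated by earlier removals
    intact <- vapply(f$branches, function(b) {
      all(b$internal %in% cur$nodes$contig_id) &&
        all(graph$edges$a_id[b$edges] %in% cur$nodes$contig_id) &&
        all(edge_keys(graph$edges[b$edges, , drop = FALSE]) %in%
              edge_keys(cur$edges))
    }, logical(1))
    if (sum(intact) < 2L) next
    branches <- f$branches[intact]
    score <- vapply(branches, function(b) {
      if (!length(b$internal)) return(0)
      bi <- match(b$internal, cur$nodes$contig_id)
      bd <- stats::weighted.mean(cur$nodes$depth[bi], cur$nodes$length[bi])
      abs(bd - ref_depth)
    }, numeric(1))
    supp <- vapply(branches, function(b) {
      sum(graph$edges$support[b$edges])
    }, numeric(1))
    idstr <- vapply(branches, function(b) {
      paste(b$internal, collapse = ",")
    }, character(1))
    keep <- order(score, -supp, idstr)[1L]
    for (bi in seq_along(branches)) {
      if (bi == keep) next
      b <- branches[[bi]]
      if (length(b$internal)) {
        log <- rbind(log, removal_log(
          type = rep("node", length(b$internal)),
          target = b$internal,
          reason = sprintf("fork branch depth off reference %.1f", ref_depth)
        ))
        cur_keep <- !cur$nodes$contig_id %in% b$internal
        cur <- contig_graph(
          cur$nodes[cur_keep, , drop = FALSE],
          cur$edges[cur$edges$a_id %in% cur$nodes$contig_id[cur_keep] &
                      cur$edges$b_id %in% cur$nodes$contig_id[cur_keep], ,
                    drop = FALSE])
      } else {
        key <- edge_keys(graph$edges[b$edges, , drop = FALSE])
        log <- rbind(log, removal_log("edge", key, "losing direct fork branch"))
        cur <- contig_graph(cur$nodes,
                            cur$edges[!edge_keys(cur$edges) %in% key, ,
                                      drop = FALSE])
      }
    }
  }
  attr(cur, "removals") <- log
  cur
}
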