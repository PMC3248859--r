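# Graph builders and independent brute-force oracles used across the suite.
# Oracles are deliberately naive re-derivations from first principles; they
# never share code with the implementation paths they check.

# --- builders ---------------------------------------------------------------

simple_cycle_graph <- function(ids = c("a", "b", "c"), depth = 43,
                               len = 1000L, support = 30L) {
  n <- length(ids)
  nodes <- data.frame(contig_id = ids, length = len, depth = depth)
  edges <- data.frame(
    a_id = ids, a_end = "3",
    b_id = ids[c(2:n, 1L)], b_end = "5",
    support = support
  )
  contig_graph(nodes, edges)
}

# single-contig quadripartite toy: LSC - IR - SSC - IR(rev)
cp_toy_graph <- function(with_seqs = FALSE) {
  nodes <- data.frame(
    contig_id = c("L", "I", "S"),
    length = c(800L, 300L, 200L),
    depth = c(87, 174, 87)
  )
  if (with_seqs) {
    set.seed(99)
    nodes$sequence <- vapply(nodes$length, function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }, character(1))
  }
  edges <- data.frame(
    a_id = c("L", "I", "S", "I"),
    a_end = c("3", "3", "3", "5"),
    b_id = c("I", "S", "I", "L"),
    b_end = c("5", "5", "3", "5"),
    support = 80L
  )
  contig_graph(nodes, edges)
}

diamond_graph <- function(depth_b = 43, depth_c = 9) {
  nodes <- data.frame(
    contig_id = c("a", "b", "c", "d", "e"),
    length = c(1000L, 500L, 500L, 1000L, 2000L),
    depth = c(43, depth_b, depth_c, 43, 43)
  )
  edges <- data.frame(
    a_id = c("a", "a", "b", "c", "d", "e"),
    a_end = c("3", "3", "3", "3", "3", "3"),
    b_id = c("b", "c", "d", "d", "e", "a"),
    b_end = c("5", "5", "5", "5", "5", "5"),
    support = 40L
  )
  contig_graph(nodes, edges)
}

random_valid_graph <- function(seed, n = 6L, with_seq_prob = 0.5) {
  set.seed(seed)
  ids <- sprintf("ctg%02d", seq_len(n))
  len <- sample(50:500, n, replace = TRUE)
  seqs <- ifelse(runif(n) < with_seq_prob,
                 vapply(len, function(L) {
                   paste(sample(c("A", "C", "G", "T", "N"), L,
                                replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
                         collapse = "")
                 }, character(1)),
                 NA_character_)
  nodes <- data.frame(
    contig_id = ids, length = len, depth = round(runif(n, 1, 200), 3),
    sequence = seqs,
    num_reads = ifelse(runif(n) < 0.5, sample.int(1e4, n), NA_integer_)
  )
  ne <- sample(1:(2L * n), 1L)
  gap <- ifelse(runif(ne) < 0.2, 1L, 0L)
  edges <- data.frame(
    a_id = sample(ids, ne, replace = TRUE), a_end = sample(c("5", "3"), ne, TRUE),
    b_id = sample(ids, ne, replace = TRUE), b_end = sample(c("5", "3"), ne, TRUE),
    support = rpois(ne, 20), gap = gap,
    gap_base = ifelse(gap == 1L, sample(c("A", "C", "G", "T"), ne, TRUE),
                      NA_character_)
  )
  contig_graph(nodes, edges)
}

expect_graph_equal <- function(g1, g2) {
  o1 <- g1$nodes[order(g1$nodes$contig_id), ]; rownames(o1) <- NULL
  o2 <- g2$nodes[order(g2$nodes$contig_id), ]; rownames(o2) <- NULL
  expect_identical(o1, o2)
  expect_identical(g1$edges, g2$edges)
}

# --- oracles ----------------------------------------------------------------

# N50: sort descending, accumulate until half the total
brute_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  tot <- sum(s)
  acc <- 0
  for (x in s) {
    acc <- acc + x
    if (acc >= tot / 2) return(x)
  }
}

# canonical circular form by full enumeration of all 2L rotations
brute_canonical <- function(s) {
  rotations <- function(x) {
    n <- nchar(x)
    vapply(seq_len(n), function(i) {
      paste0(substr(x, i, n), substr(x, 1, i - 1))
    }, character(1))
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  sort(c(rotations(s), rotations(rc)), method = "radix")[1L]
}

# maximum-weight set of rows pairing every flanking contig exactly once,
# by recursive pairing of the first unmatched contig
brute_matching <- function(rows) {
  contigs <- sort(unique(c(rows$five_prime_contig, rows$three_prime_contig)))
  best <- list(weight = -Inf, sets = list())
  recurse <- function(remaining, chosen, weight) {
    if (!length(remaining)) {
      if (weight > best$weight) {
        best <<- list(weight = weight, sets = list(sort(chosen)))
      } else if (weight == best$weight) {
        best$sets[[length(best$sets) + 1L]] <<- sort(chosen)
      }
      return()
    }
    c1 <- remaining[1L]
    for (i in seq_len(nrow(rows))) {
      pair <- c(rows$five_prime_contig[i], rows$three_prime_contig[i])
      if (!c1 %in% pair) next
      other <- setdiff(pair, c1)
      if (length(other) != 1L || !other %in% remaining) next
      recurse(setdiff(remaining, pair), c(chosen, i), weight + rows$link_count[i])
    }
  }
  recurse(contigs, integer(0), 0)
  best
}

# independent canonicalizer for closed walks (rotation + reversal quotient)
oracle_walk_key <- function(steps) {
  lab <- paste0(steps$contig_id, steps$orient)
  flip <- function(o) ifelse(o == "+", "-", "+")
  rlab <- paste0(rev(steps$contig_id), flip(rev(steps$orient)))
  n <- length(lab)
  cands <- character(0)
  for (v in list(lab, rlab)) {
    for (r in seq_len(n)) {
      cands <- c(cands, paste(c(v[r:n], v[seq_len(r - 1L)]), collapse = "|"))
    }
  }
  sort(cands, method = "radix")[1L]
}

# exhaustive enumeration of closed walks directly over step sequences:
# each contig appears exactly its multiplicity, consecutive steps (and the
# wrap-around) are joined by an existing edge, every edge realized >= once
brute_circular_walks <- function(graph, multiplicity) {
  ids <- graph$nodes$contig_id
  mult <- setNames(rep(1L, length(ids)), ids)
  hit <- intersect(names(multiplicity), ids)
  mult[hit] <- as.integer(multiplicity[hit])
  total <- sum(mult)
  e <- graph$edges
  exit_of <- function(o) ifelse(o == "+", "3", "5")
  entry_of <- function(o) ifelse(o == "+", "5", "3")
  join_ok <- function(a, ea, b, eb) {
    any((e$a_id == a & e$a_end == ea & e$b_id == b & e$b_end == eb) |
          (e$a_id == b & e$a_end == eb & e$b_id == a & e$b_end == ea))
  }
  edge_used_somewhere <- function(steps) {
    n <- nrow(steps)
    for (i in seq_len(nrow(e))) {
      found <- FALSE
      for (j in seq_len(n)) {
        k <- (j %% n) + 1L
        a <- steps$contig_id[j]; ea <- exit_of(steps$orient[j])
        b <- steps$contig_id[k]; eb <- entry_of(steps$orient[k])
        if ((e$a_id[i] == a && e$a_end[i] == ea &&
             e$b_id[i] == b && e$b_end[i] == eb) ||
            (e$a_id[i] == b && e$a_end[i] == eb &&
             e$b_id[i] == a && e$b_end[i] == ea)) {
          found <- TRUE
          break
        }
      }
      if (!found) return(FALSE)
    }
    TRUE
  }
  keys <- character(0)
  start <- sort(ids)[1L]
  extend <- function(steps) {
    if (nrow(steps) == total) {
      last <- nrow(steps)
      if (join_ok(steps$contig_id[last], exit_of(steps$orient[last]),
                  steps$contig_id[1L], entry_of(steps$orient[1L])) &&
          edge_used_somewhere(steps)) {
        keys <<- unique(c(keys, oracle_walk_key(steps)))
      }
      return()
    }
    prev <- nrow(steps)
    for (id in ids) {
      if (sum(steps$contig_id == id) >= mult[[id]]) next
      for (o in c("+", "-")) {
        if (join_ok(steps$contig_id[prev], exit_of(steps$orient[prev]),
                    id, entry_of(o))) {
          extend(rbind(steps, data.frame(contig_id = id, orient = o,
                                         stringsAsFactors = FALSE)))
        }
      }
    }
  }
  extend(data.frame(contig_id = start, orient = "+", stringsAsFactors = FALSE))
  sort(keys)
}

# fork signatures from a detect_forks() result: unordered endpoint pair plus
# the sorted internal contig sets of the branches
fork_signatures <- function(forks) {
  sort(vapply(forks, function(f) {
    ends <- sort(c(paste(f$start, collapse = ","), paste(f$end, collapse = ",")))
    br <- sort(vapply(f$branches, function(b) {
      paste(sort(b$internal), collapse = "+")
    }, character(1)))
    paste(c(ends, br), collapse = ";")
  }, character(1)), method = "radix")
}

# independent fork enumeration: all ordered tuples of (contig, entry end)
# validated edge-by-edge, grouped by endpoint pair, >= 2 pairwise disjoint
# internal sets
brute_forks <- function(graph, max_internal = 3L) {
  ids <- graph$nodes$contig_id
  e <- graph$edges
  opp <- function(x) ifelse(x == "5", "3", "5")
  join_ok <- function(a, ea, b, eb) {
    any((e$a_id == a & e$a_end == ea & e$b_id == b & e$b_end == eb) |
          (e$a_id == b & e$a_end == eb & e$b_id == a & e$b_end == ea))
  }
  endrefs <- expand.grid(id = ids, end = c("5", "3"), stringsAsFactors = FALSE)
  paths <- list() # key: endpoint pair -> list of internal sets
  add_path <- function(s, e2, internal) {
    key <- paste(sort(c(paste(s, collapse = ","), paste(e2, collapse = ","))),
                 collapse = ";")
    paths[[key]] <<- c(paths[[key]], list(sort(internal)))
  }
  tuples <- list(character(0))
  for (k in seq_len(max_internal)) {
    new <- list()
    for (tp in tuples[lengths(tuples) == (k - 1L) * 2L]) {
      tp_ids <- if (length(tp)) tp[seq(1L, length(tp), by = 2L)] else character(0)
      for (i in seq_len(nrow(endrefs))) {
        id <- endrefs$id[i]
        if (id %in% tp_ids) next
        new[[length(new) + 1L]] <- c(tp, id, endrefs$end[i])
      }
    }
    tuples <- c(tuples, new)
  }
  for (si in seq_len(nrow(endrefs))) {
    s <- c(endrefs$id[si], endrefs$end[si])
    for (ei in seq_len(nrow(endrefs))) {
      e2 <- c(endrefs$id[ei], endrefs$end[ei])
      for (tp in tuples) {
        k <- length(tp) / 2L
        internals <- if (k > 0) tp[seq(1L, length(tp), by = 2L)] else character(0)
        if (s[1L] %in% internals || e2[1L] %in% internals) next
        ok <- TRUE
        cur <- s
        if (k > 0) {
          for (j in seq_len(k)) {
            nid <- tp[2L * j - 1L]; nend <- tp[2L * j]
            if (!join_ok(cur[1L], cur[2L], nid, nend)) { ok <- FALSE; break }
            cur <- c(nid, opp(nend))
          }
        }
        if (ok && join_ok(cur[1L], cur[2L], e2[1L], e2[2L])) {
          add_path(s, e2, internals)
        }
      }
    }
  }
  sigs <- character(0)
  for (key in names(paths)) {
    brs <- unique(paths[[key]])
    if (length(brs) < 2L) next
    disjoint <- TRUE
    for (a in seq_along(brs)) {
      for (b in seq_along(brs)) {
        if (a < b && length(intersect(brs[[a]], brs[[b]]))) disjoint <- FALSE
      }
    }
    if (!disjoint) next
    br_sig <- sort(vapply(brs, paste, character(1), collapse = "+"))
    sigs <- c(sigs, paste(c(sort(strsplit(key, ";")[[1L]]), br_sig),
                          collapse = ";"))
  }
  sort(sigs, method = "radix")
}
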