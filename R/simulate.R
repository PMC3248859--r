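# Synthetic planted genomes and in-silico experiments.
#
# The generator plants a chloroplast-like quadripartite circle (LSC + IRa +
# SSC + IRb), a mitochondrion-like circle with dispersed multi-copy repeats,
# and low-depth nuclear background fragments; shreds them into a
# depth-annotated contig graph with collapsed repeats (identical repeat
# copies become one contig at a multiple of the single-copy depth, the way
# an overlap assembler collapses them); simulates mate-pair candidate-link
# tables; and runs the minimal-sequencing-data subsampling experiment.
# Everything is deterministic under a fixed seed.

#' Genome specifications for the simulator
#'
#' Scaled-down defaults exercise every code path of the assembly pipeline at
#' desk scale: a 16 kb quadripartite cp-like genome (8k/2k/3k x 2), a 40 kb
#' mt-like genome with two dispersed 2-copy repeats, and 200 kb of nuclear
#' background in 20 fragments.  Copy depths default to 87x / 43x / 9x, the
#' regime where organellar and nuclear contigs separate cleanly by depth.
#'
#' @param lsc_len,ssc_len,ir_len CP region lengths in bases.
#' @param total_len Genome (or summed fragment) length in bases.
#' @param repeats Data frame with columns `repeat_len`, `n_copies` (>= 2),
#'   `inverted` describing the mt dispersed repeats.
#' @param n_fragments Number of nuclear fragments.
#' @param copy_depth Per-copy fold-coverage of the genome.
#' @param gc GC fraction of generated bases.
#' @return A `genome_spec` list.
#' @name genome_specs
NULL

#' @rdname genome_specs
#' @export
cp_genome_spec <- function(lsc_len = 8000L, ssc_len = 2000L, ir_len = 3000L,
                           copy_depth = 87, gc = 0.37) {
  stopifnot(lsc_len >= 1L, ssc_len >= 1L, ir_len >= 1L, copy_depth > 0,
            gc > 0, gc < 1)
  structure(list(kind = CLASS_CP, lsc_len = as.integer(lsc_len),
                 ssc_len = as.integer(ssc_len), ir_len = as.integer(ir_len),
                 copy_depth = copy_depth, gc = gc),
            class = "genome_spec")
}

#' @rdname genome_specs
#' @export
mt_genome_spec <- function(total_len = 40000L,
                           repeats = data.frame(repeat_len = c(1600L, 1200L),
                                                n_copies = 2L,
                                                inverted = FALSE),
                           copy_depth = 43, gc = 0.43) {
  repeats <- as.data.frame(repeats)
  stopifnot(total_len >= 1L, copy_depth > 0, gc > 0, gc < 1,
            all(repeats$repeat_len >= 1L), all(repeats$n_copies >= 2L))
  structure(list(kind = CLASS_MT, total_len = as.integer(total_len),
                 repeats = repeats, copy_depth = copy_depth, gc = gc),
            class = "genome_spec")
}

#' @rdname genome_specs
#' @export
nuclear_genome_spec <- function(total_len = 200000L, n_fragments = 20L,
                                copy_depth = 9, gc = 0.36) {
  stopifnot(total_len >= n_fragments, n_fragments >= 1L, copy_depth > 0)
  structure(list(kind = CLASS_NUCLEAR, total_len = as.integer(total_len),
                 n_fragments = as.integer(n_fragments),
                 copy_depth = copy_depth, gc = gc),
            class = "genome_spec")
}

random_sequence <- function(n, gc) {
  bases <- utf8ToInt("ACGT")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  intToUtf8(sample(bases, n, replace = TRUE, prob = p))
}

planted_genome <- function(name, kind, sequence, copy_depth, blocks,
                           circular = TRUE) {
  structure(list(name = name, kind = kind, sequence = sequence,
                 copy_depth = copy_depth, blocks = blocks,
                 circular = circular),
            class = "planted_genome")
}

blocks_frame <- function(type, repeat_id, copy, inverted, start, end,
                         cut_internal) {
  data.frame(type = type, repeat_id = repeat_id, copy = copy,
             inverted = inverted, start = start, end = end,
             cut_internal = cut_internal, stringsAsFactors = FALSE)
}

#' Plant a chloroplast-like quadripartite genome
#'
#' Generates `LSC + IRa + SSC + IRb` with `IRb` the reverse complement of
#' `IRa`.  Because the two inversion isomers of a plastid genome (SSC in
#' either orientation) are the same molecule -- and indistinguishable in a
#' collapsed contig graph -- the planted sequence is reported as the
#' canonical representative of its isomer pair (the isomer with the smaller
#' [canonical_form()]), which is also the representative the assembly
#' pipeline reports.
#'
#' @param spec A [cp_genome_spec()].
#' @param seed Integer seed; the same seed gives a byte-identical genome.
#' @return A `planted_genome` (name `"cp"`); positions are 0-based
#'   half-open.
#' @export
make_cp_genome <- function(spec, seed) {
  stopifnot(inherits(spec, "genome_spec"), spec$kind == CLASS_CP)
  with_seed(seed, {
    lsc <- random_sequence(spec$lsc_len, spec$gc)
    ira <- random_sequence(spec$ir_len, spec$gc)
    ssc <- random_sequence(spec$ssc_len, spec$gc)
    iso1 <- paste0(lsc, ira, ssc, revcomp(ira))
    iso2 <- paste0(lsc, ira, revcomp(ssc), revcomp(ira))
    genome <- if (canonical_form(iso1) <= canonical_form(iso2)) iso1 else iso2
    b0 <- c(0L, spec$lsc_len, spec$lsc_len + spec$ir_len,
            spec$lsc_len + spec$ir_len + spec$ssc_len)
    b1 <- c(b0[-1L], nchar(genome))
    blocks <- blocks_frame(
      type = c("unique", "repeat", "unique", "repeat"),
      repeat_id = c(NA, "IR", NA, "IR"),
      copy = c(NA, 1L, NA, 2L),
      inverted = c(NA, FALSE, NA, TRUE),
      start = b0, end = b1,
      cut_internal = c(TRUE, TRUE, TRUE, TRUE)
    )
    planted_genome("cp", CLASS_CP, genome, spec$copy_depth, blocks)
  })
}

#' Plant a mitochondrion-like genome with dispersed repeats
#'
#' Generates a random circular backbone and overwrites dispersed,
#' non-overlapping positions with identical repeat copies (reverse
#' complemented where the repeat is inverted).  Placements keep a safety
#' margin from each other and from the origin so each copy has distinct
#' flanking sequence.
#'
#' @param spec An [mt_genome_spec()].
#' @param seed Integer seed.
#' @param margin Minimum bases between planted regions (default 1500).
#' @return A `planted_genome` (name `"mt"`).
#' @export
make_mt_genome <- function(spec, seed, margin = 1500L) {
  stopifnot(inherits(spec, "genome_spec"), spec$kind == CLASS_MT)
  with_seed(seed, {
    genome <- random_sequence(spec$total_len, spec$gc)
    placements <- NULL
    taken <- matrix(numeric(0), ncol = 2L) # occupied [start, end) + margin
    for (ri in seq_len(nrow(spec$repeats))) {
      rlen <- spec$repeats$repeat_len[ri]
      ncop <- spec$repeats$n_copies[ri]
      inv <- isTRUE(spec$repeats$inverted[ri])
      rid <- sprintf("R%d", ri)
      rseq <- random_sequence(rlen, spec$gc)
      for (cp in seq_len(ncop)) {
        placed <- FALSE
        for (try in 1:2000) {
          s <- sample.int(spec$total_len - rlen - margin, 1L) + margin %/% 2L
          e <- s + rlen
          if (s < margin || e > spec$total_len - margin %/% 2L) next
          clash <- nrow(taken) > 0L &&
            any(s - margin < taken[, 2L] & e + margin > taken[, 1L])
          if (!clash) {
            taken <- rbind(taken, c(s, e))
            placements <- rbind(placements, data.frame(
              repeat_id = rid, copy = cp, inverted = inv && cp > 1L,
              start = s, end = e, seq = rseq, stringsAsFactors = FALSE))
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("make_mt_genome: repeats overlap; cannot place ", rid,
               " copy ", cp, " without collision")
        }
      }
    }
    # overwrite backbone with the repeat copies
    gvec <- strsplit(genome, "", fixed = TRUE)[[1L]]
    for (i in seq_len(nrow(placements))) {
      p <- placements[i, ]
      s <- if (p$inverted) revcomp(p$seq) else p$seq
      gvec[(p$start + 1L):p$end] <- strsplit(s, "", fixed = TRUE)[[1L]]
    }
    genome <- paste0(gvec, collapse = "")

    placements <- placements[order(placements$start), , drop = FALSE]
    blocks <- NULL
    pos <- 0L
    for (i in seq_len(nrow(placements))) {
      p <- placements[i, ]
      if (p$start > pos) {
        blocks <- rbind(blocks, blocks_frame("unique", NA, NA, NA,
                                             pos, p$start, TRUE))
      }
      blocks <- rbind(blocks, blocks_frame("repeat", p$repeat_id, p$copy,
                                           p$inverted, p$start, p$end, FALSE))
      pos <- p$end
    }
    if (pos < spec$total_len) {
      blocks <- rbind(blocks, blocks_frame("unique", NA, NA, NA,
                                           pos, spec$total_len, TRUE))
    }
    planted_genome("mt", CLASS_MT, genome, spec$copy_depth, blocks)
  })
}

#' Plant low-depth nuclear background fragments
#'
#' @param spec A [nuclear_genome_spec()].
#' @param seed Integer seed.
#' @return List of linear `planted_genome` fragments (`nuc01`, `nuc02`, ...).
#' @export
make_nuclear_background <- function(spec, seed) {
  stopifnot(inherits(spec, "genome_spec"), spec$kind == CLASS_NUCLEAR)
  with_seed(seed, {
    frag_len <- diff(round(seq(0L, spec$total_len,
                               length.out = spec$n_fragments + 1L)))
    lapply(seq_len(spec$n_fragments), function(i) {
      seqi <- random_sequence(frag_len[i], spec$gc)
      planted_genome(sprintf("nuc%02d", i), CLASS_NUCLEAR, seqi,
                     spec$copy_depth,
                     blocks_frame("unique", NA, NA, NA, 0L, frag_len[i], TRUE),
                     circular = FALSE)
    })
  })
}

#' Bundle planted genomes into a synthetic truth object
#'
#' @param genomes A list of `planted_genome` objects (nested lists are
#'   flattened); names are taken from the genomes.
#' @return A `synthetic_truth` object; [shred_to_graph()] augments it with
#'   contig labels, multiplicities and planted link pairings.
#' @export
synthetic_truth <- function(genomes) {
  flat <- list()
  collect <- function(x) {
    if (inherits(x, "planted_genome")) {
      flat[[x$name]] <<- x
    } else if (is.list(x)) {
      lapply(x, collect)
    } else stop("synthetic_truth: not a planted_genome")
  }
  collect(genomes)
  structure(list(genomes = flat), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  kinds <- vapply(x$genomes, `[[`, character(1), "kind")
  lens <- vapply(x$genomes, function(g) nchar(g$sequence), numeric(1))
  cat(sprintf("synthetic_truth: %d genomes (%s), %s bp total\n",
              length(x$genomes),
              paste(sprintf("%s %d", names(table(kinds)), table(kinds)),
                    collapse = ", "),
              format(sum(lens), big.mark = ",")))
  if (!is.null(x$contigs)) {
    cat(sprintf("  shredded: %d contigs\n", nrow(x$contigs)))
  }
  invisible(x)
}

# random cut positions inside (0, len) with minimum spacing from each other
# and from both boundaries; exponential spacing with the given mean
sample_cuts <- function(len, mean_len, min_len = 200L) {
  cuts <- integer(0)
  pos <- 0L
  repeat {
    pos <- pos + max(min_len, as.integer(round(stats::rexp(1L, 1 / mean_len))))
    if (pos > len - min_len) break
    cuts <- c(cuts, pos)
  }
  cuts
}

#' Shred planted genomes into a depth-annotated contig graph
#'
#' Each genome is cut at random breakpoints (exponential spacing around
#' `mean_contig_len`) with forced breakpoints at every repeat boundary.
#' Identical repeat copies collapse into shared contigs whose depth is
#' `copies x copy_depth`; single-contig dispersed repeats record the planted
#' flank pairing per copy for the mate-pair experiments, while the cp
#' inverted repeat may shred into a multi-contig run (its traversal order is
#' forced by the quadripartite structure, not by mate pairs).  Per-contig
#' depth gets Gaussian noise; adjacent contigs are joined by edges with
#' Poisson spanning-read support around the copy depth; `cross_links`
#' spurious support-1 edges (single chimeric reads) are injected between
#' contigs of different genomes.
#'
#' @param truth A [synthetic_truth()].
#' @param mean_contig_len Mean contig length in bases (>= 200).
#' @param depth_noise_sd Gaussian depth noise sd in fold-coverage.
#' @param cross_links Number of spurious cross-genome edges.
#' @param seed Integer seed.
#' @return List with `graph` (a [contig_graph] with sequences) and `truth`
#'   (augmented with `contigs`, `paths`, `link_truth`).
#' @export
shred_to_graph <- function(truth, mean_contig_len = 1500L, depth_noise_sd = 3,
                           cross_links = 0L, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (mean_contig_len < 200L) stop("mean_contig_len must be >= 200")
  glens <- vapply(truth$genomes, function(g) nchar(g$sequence), numeric(1))
  if (any(mean_contig_len >= glens)) {
    stop("mean_contig_len must be smaller than every genome length")
  }
  with_seed(seed, {
    nodes <- NULL
    edges <- NULL
    contigs <- NULL
    paths <- list()
    link_truth <- NULL

    for (g in truth$genomes) {
      counter <- 0L
      new_id <- function() {
        counter <<- counter + 1L
        sprintf("%s_c%02d", g$name, counter)
      }
      repeat_contigs <- list() # repeat_id -> data.frame(id, len, seq)
      blocks <- g$blocks
      nb <- nrow(blocks)
      path <- NULL
      local_nodes <- list()
      rep_runs <- NULL # repeat occurrences: block row, path positions

      for (bi in seq_len(nb)) {
        b <- blocks[bi, ]
        blen <- b$end - b$start
        bseq <- substr(g$sequence, b$start + 1L, b$end)
        if (b$type == "unique") {
          cuts <- sample_cuts(blen, mean_contig_len)
          # a block sandwiched between two repeat blocks must not collapse
          # into a single contig, so each repeat copy keeps distinct flanks
          prev_rep <- blocks$type[if (bi == 1L) nb else bi - 1L] == "repeat"
          next_rep <- blocks$type[if (bi == nb) 1L else bi + 1L] == "repeat"
          if (!length(cuts) && prev_rep && next_rep && g$circular &&
              blen >= 400L) {
            cuts <- as.integer(blen %/% 2L)
          }
          bounds <- c(0L, cuts, blen)
          for (ci in seq_len(length(bounds) - 1L)) {
            id <- new_id()
            s <- substr(bseq, bounds[ci] + 1L, bounds[ci + 1L])
            local_nodes[[id]] <- list(len = nchar(s), seq = s)
            path <- rbind(path, data.frame(contig_id = id, orient = FORWARD,
                                           stringsAsFactors = FALSE))
          }
        } else {
          rid <- b$repeat_id
          if (is.null(repeat_contigs[[rid]])) {
            # define the repeat's contigs once, from its forward sequence
            fseq <- if (isTRUE(b$inverted)) revcomp(bseq) else bseq
            cuts <- if (isTRUE(b$cut_internal)) {
              sample_cuts(blen, mean_contig_len)
            } else integer(0)
            bounds <- c(0L, cuts, blen)
            ids <- character(length(bounds) - 1L)
            for (ci in seq_len(length(bounds) - 1L)) {
              id <- new_id()
              s <- substr(fseq, bounds[ci] + 1L, bounds[ci + 1L])
              local_nodes[[id]] <- list(len = nchar(s), seq = s)
              ids[ci] <- id
            }
            repeat_contigs[[rid]] <- ids
          }
          ids <- repeat_contigs[[rid]]
          pos0 <- if (is.null(path)) 0L else nrow(path)
          if (isTRUE(b$inverted)) {
            path <- rbind(path, data.frame(contig_id = rev(ids),
                                           orient = REVERSE,
                                           stringsAsFactors = FALSE))
          } else {
            path <- rbind(path, data.frame(contig_id = ids, orient = FORWARD,
                                           stringsAsFactors = FALSE))
          }
          rep_runs <- rbind(rep_runs, data.frame(
            repeat_id = rid, copy = b$copy, from = pos0 + 1L,
            to = nrow(path), single = length(ids) == 1L,
            stringsAsFactors = FALSE))
        }
      }

      np <- nrow(path)
      mult <- table(path$contig_id)
      for (id in names(local_nodes)) {
        m <- as.integer(mult[[id]])
        depth <- max(1, m * g$copy_depth + stats::rnorm(1L, 0, depth_noise_sd))
        nodes <- rbind(nodes, data.frame(
          contig_id = id, length = local_nodes[[id]]$len, depth = depth,
          sequence = local_nodes[[id]]$seq, stringsAsFactors = FALSE))
        contigs <- rbind(contigs, data.frame(
          contig_id = id, genome = g$name, kind = g$kind,
          length = local_nodes[[id]]$len, multiplicity = m, depth = depth,
          stringsAsFactors = FALSE))
      }
      n_adj <- if (g$circular) np else np - 1L
      for (i in seq_len(max(0L, n_adj))) {
        j <- (i %% np) + 1L
        edges <- rbind(edges, data.frame(
          a_id = path$contig_id[i], a_end = exit_end(path$orient[i]),
          b_id = path$contig_id[j], b_end = entry_end(path$orient[j]),
          support = max(1L, stats::rpois(1L, g$copy_depth)),
          stringsAsFactors = FALSE))
      }
      # planted flank pairing per single-contig repeat copy
      if (!is.null(rep_runs)) {
        for (k in seq_len(nrow(rep_runs))) {
          rr <- rep_runs[k, ]
          if (!rr$single || !g$circular) next
          prev <- if (rr$from == 1L) np else rr$from - 1L
          nxt <- (rr$to %% np) + 1L
          link_truth <- rbind(link_truth, data.frame(
            repeat_id = path$contig_id[rr$from], copy = rr$copy,
            five_prime_contig = path$contig_id[prev],
            three_prime_contig = path$contig_id[nxt],
            stringsAsFactors = FALSE))
        }
      }
      paths[[g$name]] <- path
    }

    # spurious cross-genome links: single chimeric reads (support 1)
    if (cross_links > 0L) {
      genome_of <- stats::setNames(contigs$genome, contigs$contig_id)
      placed <- 0L
      guard <- 0L
      while (placed < cross_links && guard < 1000L) {
        guard <- guard + 1L
        pick <- sample(contigs$contig_id, 2L)
        if (genome_of[[pick[1L]]] == genome_of[[pick[2L]]]) next
        edges <- rbind(edges, data.frame(
          a_id = pick[1L], a_end = sample(c(END5, END3), 1L),
          b_id = pick[2L], b_end = sample(c(END5, END3), 1L),
          support = 1L, stringsAsFactors = FALSE))
        placed <- placed + 1L
      }
    }

    graph <- contig_graph(nodes, edges)
    truth$contigs <- contigs
    truth$paths <- paths
    truth$link_truth <- link_truth
    list(graph = graph, truth = truth)
  })
}

#' Simulate a mate-pair candidate-link table
#'
#' For each planted flank pairing of a single-contig dispersed repeat the
#' table gets a row with `link_count ~ Poisson(n_pairs_per_true_link)`; the
#' cross-copy flank combinations (5' flank of one copy with 3' flank of
#' another) get `link_count ~ Poisson(noise_pairs)`, mirroring the
#' 4-rows-per-2-copy-repeat shape of real mate-pair link tables.
#'
#' @param truth A shredded [synthetic_truth()] (must contain dispersed
#'   repeats).
#' @param n_pairs_per_true_link Poisson mean for true pairings (default 50).
#' @param noise_pairs Poisson mean for spurious pairings (default 5; must be
#'   smaller than `n_pairs_per_true_link`).
#' @param seed Integer seed.
#' @return A `link_table` whose `repeat_id` is the repeat contig id.
#' @export
simulate_link_table <- function(truth, n_pairs_per_true_link = 50,
                                noise_pairs = 5, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (is.null(truth$link_truth) || !nrow(truth$link_truth)) {
    stop("simulate_link_table: truth contains no dispersed repeats (shred first)")
  }
  if (noise_pairs >= n_pairs_per_true_link) {
    stop("noise_pairs must be < n_pairs_per_true_link for selection to be meaningful")
  }
  with_seed(seed, {
    rows <- NULL
    for (rid in unique(truth$link_truth$repeat_id)) {
      lt <- truth$link_truth[truth$link_truth$repeat_id == rid, , drop = FALSE]
      m <- nrow(lt)
      for (i in seq_len(m)) {
        rows <- rbind(rows, data.frame(
          repeat_id = rid,
          link_count = stats::rpois(1L, n_pairs_per_true_link),
          five_prime_contig = lt$five_prime_contig[i],
          three_prime_contig = lt$three_prime_contig[i],
          stringsAsFactors = FALSE))
      }
      for (i in seq_len(m)) {
        for (j in seq_len(m)) {
          if (i == j) next
          rows <- rbind(rows, data.frame(
            repeat_id = rid,
            link_count = stats::rpois(1L, noise_pairs),
            five_prime_contig = lt$five_prime_contig[i],
            three_prime_contig = lt$three_prime_contig[j],
            stringsAsFactors = FALSE))
        }
      }
    }
    link_table(rows)
  })
}

#' Subsampling coverage experiment
#'
#' Emulates the minimal-sequencing-data analysis: reads of length
#' `read_len` are drawn from the genome mixture with per-genome probability
#' proportional to `copy_depth x genome length` (the fraction of total DNA
#' mass each genome contributes), and for each sampled data amount the
#' fraction of organellar genome positions hit by at least `min_cov` reads
#' is reported.  Samples are nested (each data point extends the previous
#' one), so coverage is non-decreasing in sampled mass by construction.
#'
#' @param truth A [synthetic_truth()].
#' @param read_len Read length in bases (default 340, a typical
#'   pyrosequencing mean).
#' @param data_points Sorted ascending vector of sampled megabases.
#' @param min_cov Minimum reads per position to call it covered (default 1).
#' @param seed Integer seed.
#' @return A `subsample_table` data frame: `sample_mbp`, `genome`, `kind`,
#'   `covered_pct` (2 decimals).
#' @export
subsample_experiment <- function(truth, read_len = 340L, data_points,
                                 min_cov = 1L, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!length(data_points)) stop("subsample_experiment: empty data_points")
  if (is.unsorted(data_points)) {
    stop("subsample_experiment: data_points must be sorted ascending")
  }
  genomes <- truth$genomes
  lens <- vapply(genomes, function(g) nchar(g$sequence), numeric(1))
  mass <- vapply(genomes, function(g) g$copy_depth * nchar(g$sequence),
                 numeric(1))
  organellar <- names(genomes)[vapply(genomes, function(g) {
    g$kind %in% c(CLASS_CP, CLASS_MT)
  }, logical(1))]

  with_seed(seed, {
    n_reads <- as.integer(round(data_points * 1e6 / read_len))
    n_max <- max(n_reads)
    assign_g <- if (n_max > 0L) {
      sample(names(genomes), n_max, replace = TRUE, prob = mass / sum(mass))
    } else character(0)
    starts <- integer(n_max)
    for (nm in names(genomes)) {
      hit <- which(assign_g == nm)
      if (length(hit)) starts[hit] <- sample.int(lens[[nm]], length(hit),
                                                 replace = TRUE)
    }
    cov <- lapply(organellar, function(nm) integer(lens[[nm]]))
    names(cov) <- organellar

    out <- NULL
    done <- 0L
    for (p in seq_along(data_points)) {
      batch <- if (n_reads[p] > done) (done + 1L):n_reads[p] else integer(0)
      done <- max(done, n_reads[p])
      for (nm in organellar) {
        idx <- batch[assign_g[batch] == nm]
        if (length(idx)) {
          L <- lens[[nm]]
          circ <- genomes[[nm]]$circular
          s <- starts[idx]
          e <- s + read_len - 1L
          d <- numeric(L + 1L)
          if (circ) {
            wrap <- e > L
            d <- d + tabulate(s, nbins = L + 1L)
            d <- d - tabulate(pmin(e, L) + 1L, nbins = L + 1L)
            if (any(wrap)) {
              d[1L] <- d[1L] + sum(wrap)
              d <- d - tabulate(e[wrap] - L + 1L, nbins = L + 1L)
            }
          } else {
            e <- pmin(e, L)
            d <- d + tabulate(s, nbins = L + 1L)
            d <- d - tabulate(e + 1L, nbins = L + 1L)
          }
          cov[[nm]] <- cov[[nm]] + cumsum(d)[seq_len(L)]
        }
        pct <- 100 * mean(cov[[nm]] >= min_cov)
        out <- rbind(out, data.frame(
          sample_mbp = data_points[p], genome = nm,
          kind = genomes[[nm]]$kind,
          covered_pct = round(pct, 2L), stringsAsFactors = FALSE))
      }
    }
    class(out) <- c("subsample_table", "data.frame")
    out
  })
}

#' One-call simulation of a whole shotgun assembly scenario
#'
#' Plants the default cp-like, mt-like and nuclear genomes (overridable),
#' shreds them into one mixed contig graph, and simulates the mate-pair
#' candidate-link table for the mt dispersed repeats.
#'
#' @param seed Integer master seed; sub-seeds for each generator are derived
#'   from it.
#' @param cp,mt,nuclear Genome specs (see [genome_specs]); `NULL` omits the
#'   genome.
#' @param mean_contig_len,depth_noise_sd,cross_links Passed to
#'   [shred_to_graph()].
#' @param n_pairs_per_true_link,noise_pairs Passed to
#'   [simulate_link_table()].
#' @return List with `graph`, `truth`, `links`.
#' @export
simulate_assembly <- function(seed = 1L,
                              cp = cp_genome_spec(),
                              mt = mt_genome_spec(),
                              nuclear = nuclear_genome_spec(),
                              mean_contig_len = 1500L,
                              depth_noise_sd = 3,
                              cross_links = 5L,
                              n_pairs_per_true_link = 50,
                              noise_pairs = 5) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, 5L))
  genomes <- list()
  if (!is.null(cp)) genomes$cp <- make_cp_genome(cp, seeds[1L])
  if (!is.null(mt)) genomes$mt <- make_mt_genome(mt, seeds[2L])
  if (!is.null(nuclear)) {
    genomes$nuc <- make_nuclear_background(nuclear, seeds[3L])
  }
  truth <- synthetic_truth(genomes)
  sh <- shred_to_graph(truth, mean_contig_len = mean_contig_len,
                       depth_noise_sd = depth_noise_sd,
                       cross_links = cross_links, seed = seeds[4L])
  links <- if (!is.null(sh$truth$link_truth) && nrow(sh$truth$link_truth)) {
    simulate_link_table(sh$truth, n_pairs_per_true_link, noise_pairs,
                        seed = seeds[5L])
  } else NULL
  list(graph = sh$graph, truth = sh$truth, links = links)
}
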