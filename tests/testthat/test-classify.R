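# Depth-based classification, seeding, repeat flagging, component extraction.

test_that("depth histogram bins the three-genome depth regime", {
  g <- contig_graph(data.frame(contig_id = c("n", "m", "c"),
                               length = c(500L, 800L, 1200L),
                               depth = c(9, 43, 87)))
  h <- depth_histogram(g, bin_width = 10)
  expect_equal(h$bin_start, c(0, 40, 80))
  expect_equal(h$n_contigs, c(1L, 1L, 1L))
  expect_equal(h$total_bp, c(500, 800, 1200))

  h1 <- depth_histogram(contig_graph(
    data.frame(contig_id = "x", length = 10L, depth = 55)), bin_width = 7)
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$n_contigs, 1L)
  expect_error(depth_histogram(contig_graph(), 10), "empty")
})

test_that("histogram counts always total the number of contigs", {
  set.seed(11)
  for (i in 1:300) {
    n <- sample(1:60, 1L)
    g <- contig_graph(data.frame(
      contig_id = sprintf("c%02d", 1:n),
      length = sample.int(2000, n, TRUE),
      depth = runif(n, 0.5, 200)))
    h <- depth_histogram(g, bin_width = sample(c(1, 5, 10, 25), 1L))
    expect_equal(sum(h$n_contigs), n)
    expect_equal(sum(h$total_bp), sum(g$nodes$length))
  }
})

test_that("depth thresholds separate the three classes with strict MT interval", {
  g <- contig_graph(data.frame(
    contig_id = c("cp1", "mt1", "nuc1", "hi", "lo"),
    length = 1000L,
    depth = c(87, 43, 9, 60, 20)))
  p <- classify_by_depth(g)
  expect_equal(unname(p$labels[c("cp1", "mt1", "nuc1")]),
               c("CP", "MT", "NUCLEAR"))
  expect_equal(unname(p$labels[["hi"]]), "CP")      # boundary: 60 is CP
  expect_equal(unname(p$labels[["lo"]]), "NUCLEAR") # boundary: 20 is NUCLEAR

  same <- contig_graph(data.frame(contig_id = letters[1:4], length = 100L,
                                  depth = 43))
  expect_true(all(classify_by_depth(same)$labels == "MT"))
  expect_error(classify_by_depth(g, t_low = 60, t_high = 20), "t_low")
})

test_that("classification is total and repeat flags override thresholds", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(3:40, 1L)
    g <- contig_graph(data.frame(contig_id = sprintf("c%02d", 1:n),
                                 length = 500L, depth = runif(n, 1, 150)))
    flags <- sample(g$nodes$contig_id, min(n, 2L))
    p <- classify_by_depth(g, repeat_flags = flags)
    expect_length(p$labels, n)
    expect_true(all(p$labels[flags] == "REPEAT"))
  }
})

test_that("seed contigs are found by exact reference containment", {
  set.seed(21)
  gene <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  carrier <- paste0(pad(200), gene, pad(150))
  other <- pad(600)
  g <- contig_graph(data.frame(
    contig_id = c("hit", "miss"),
    length = c(nchar(carrier), nchar(other)),
    depth = 43, sequence = c(carrier, other)))
  ref <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">gene1", gene), ref)
  expect_equal(find_seed_contigs(g, ref, k = 31, min_hits = 10), "hit")

  # reverse-complemented carrier still matches via canonical k-mers
  g2 <- contig_graph(data.frame(
    contig_id = "rc_hit", length = nchar(carrier), depth = 43,
    sequence = revcomp(carrier)))
  expect_equal(find_seed_contigs(g2, ref, k = 31, min_hits = 10), "rc_hit")

  expect_error(find_seed_contigs(g, ref, k = 7), "k must be")
  g_noseq <- contig_graph(data.frame(contig_id = "x", length = 5L, depth = 1))
  expect_error(find_seed_contigs(g_noseq, ref), "no contig carries")
})

test_that("seed finding agrees with brute-force k-mer set intersection", {
  set.seed(31)
  k <- 13L
  for (i in 1:100) {
    ref_seq <- paste(sample(c("A", "C", "G", "T"), sample(60:200, 1), TRUE),
                     collapse = "")
    ctg_seq <- if (runif(1) < 0.5) {
      # embed a fragment of the reference
      n <- nchar(ref_seq)
      a <- sample.int(n - 30L, 1L)
      paste0(paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = ""),
             substr(ref_seq, a, min(n, a + sample(20:120, 1L))))
    } else {
      paste(sample(c("A", "C", "G", "T"), sample(60:200, 1), TRUE), collapse = "")
    }
    min_hits <- sample(1:10, 1L)
    g <- contig_graph(data.frame(contig_id = "c", length = nchar(ctg_seq),
                                 depth = 10, sequence = ctg_seq))
    ref <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">r", ref_seq), ref)
    got <- length(find_seed_contigs(g, ref, k = k, min_hits = min_hits)) == 1L

    # oracle: canonical k-mer sets by direct substring enumeration
    kmers <- function(s) {
      n <- nchar(s)
      if (n < k) return(character(0))
      v <- substring(s, 1:(n - k + 1L), k:n)
      rc <- vapply(v, revcomp, character(1))
      unique(pmin(v, rc))
    }
    want <- length(intersect(kmers(ctg_seq), kmers(ref_seq))) >= min_hits
    expect_identical(got, want)
  }
})

test_that("raising min_hits never adds seeds", {
  set.seed(41)
  gene <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  seqs <- vapply(1:6, function(i) {
    paste0(substr(gene, 1, sample(40:200, 1L)),
           paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = ""))
  }, character(1))
  g <- contig_graph(data.frame(contig_id = sprintf("c%d", 1:6),
                               length = nchar(seqs), depth = 10,
                               sequence = seqs))
  ref <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g", gene), ref)
  prev <- NULL
  for (mh in c(1, 5, 20, 50, 100)) {
    cur <- find_seed_contigs(g, ref, k = 13, min_hits = mh)
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("repeat flagging matches exhaustive multiple search", {
  g <- contig_graph(data.frame(contig_id = c("a", "b", "c", "r"),
                               length = 1000L,
                               depth = c(43, 44, 42, 88)))
  # the 88x contig thresholds into CP territory; the repeat flag keeps it
  # with its class for multiplicity estimation
  p <- classify_by_depth(g, repeat_flags = "r")
  flags <- flag_repeats(g, p, "MT")
  expect_equal(unname(flags[["r"]]), 2L)
  expect_length(flags, 1L)

  # oracle: exhaustive m search minimising relative deviation from base
  base <- attr(flags, "base_depth")
  devs <- vapply(1:6, function(m) abs(88 - m * base) / base, numeric(1))
  expect_equal(which.min(devs), 2L)

  uni <- contig_graph(data.frame(contig_id = letters[1:5], length = 500L,
                                 depth = 43))
  expect_length(flag_repeats(uni, classify_by_depth(uni), "MT"), 0L)

  dbl <- contig_graph(data.frame(contig_id = c("a", "b", "c", "r"),
                                 length = 500L, depth = c(40, 40, 40, 80)))
  p_dbl <- classify_by_depth(dbl, repeat_flags = "r")
  expect_equal(unname(flag_repeats(dbl, p_dbl, "MT")[["r"]]), 2L)

  few <- contig_graph(data.frame(contig_id = c("a", "b"), length = 500L,
                                 depth = 43))
  expect_error(flag_repeats(few, classify_by_depth(few), "MT"), "fewer than 3")
})

test_that("component extraction respects class boundaries", {
  chain <- function(ids, depths) {
    n <- length(ids)
    contig_graph(
      data.frame(contig_id = ids, length = 500L, depth = depths),
      data.frame(a_id = ids[-n], a_end = "3", b_id = ids[-1L], b_end = "5",
                 support = 10L))
  }
  g <- chain(c("m1", "m2", "m3", "m4", "m5"), rep(43, 5))
  p <- classify_by_depth(g)
  ex <- extract_component(g, "m3", p, "MT")
  expect_setequal(ex$nodes$contig_id, g$nodes$contig_id)

  g2 <- chain(c("m1", "m2", "n1", "m3"), c(43, 43, 9, 43))
  p2 <- classify_by_depth(g2)
  ex2 <- extract_component(g2, "m1", p2, "MT")
  expect_setequal(ex2$nodes$contig_id, c("m1", "m2"))

  expect_error(extract_component(g2, "zz", p2, "MT"), "absent")
})

test_that("MT extraction retains cp-like contigs internal to mt paths", {
  # mt cycle with one cp-depth contig spliced inside (organellar transfer),
  # plus a detached cp contig pair that must stay out
  ids <- c("m1", "m2", "x", "m3", "m4")
  n <- length(ids)
  nodes <- data.frame(contig_id = c(ids, "c1", "c2"),
                      length = 500L,
                      depth = c(43, 43, 87, 43, 43, 87, 87))
  edges <- data.frame(
    a_id = c(ids, "c1"), a_end = "3",
    b_id = c(ids[c(2:n, 1L)], "c2"), b_end = "5",
    support = 10L)
  g <- contig_graph(nodes, edges)
  p <- classify_by_depth(g)
  ex <- extract_component(g, "m1", p, "MT")
  expect_setequal(ex$nodes$contig_id, ids)     # x adopted, c1/c2 not
  expect_true("x" %in% attr(ex, "adopted"))
})
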