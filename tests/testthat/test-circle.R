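# Circular walk search, quadripartite annotation, mate-pair link selection.

test_that("a simple cycle yields exactly one 3-step walk", {
  g <- simple_cycle_graph(c("a", "b", "c"))
  walks <- find_circular_path(g)
  expect_length(walks, 1L)
  expect_equal(nrow(walks[[1L]]$steps), 3L)
  expect_true(walks[[1L]]$closed)
})

test_that("the quadripartite toy traverses the IR forward then reverse", {
  g <- cp_toy_graph()
  mult <- infer_multiplicity(g)
  expect_equal(unname(mult[c("L", "I", "S")]), c(1L, 2L, 1L))
  walks <- find_circular_path(g, mult)
  # two walks: the two inversion isomers of the same molecule
  expect_lte(length(walks), 2L)
  keys <- vapply(walks, function(w) oracle_walk_key(w$steps), character(1))
  expect_true(oracle_walk_key(data.frame(
    contig_id = c("L", "I", "S", "I"),
    orient = c("+", "+", "+", "-"))) %in% keys)
})

test_that("a broken cycle is reported with its end-degree violations", {
  g <- simple_cycle_graph(c("a", "b", "c"))
  g2 <- contig_graph(g$nodes, g$edges[-1L, ])
  expect_error(find_circular_path(g2), "end-degree violations")
})

test_that("walk search agrees with exhaustive step-sequence enumeration", {
  set.seed(13)
  for (i in 1:40) {
    # plant a random closed walk over <= 6 contigs, one possibly repeated
    n <- sample(3:5, 1L)
    ids <- letters[1:n]
    steps <- data.frame(contig_id = ids, orient = sample(c("+", "-"), n, TRUE))
    if (n >= 4L && runif(1) < 0.7) {
      dup <- sample(ids, 1L)
      at <- sample(setdiff(seq_len(n), which(steps$contig_id == dup)), 1L)
      steps <- rbind(steps[seq_len(at), ],
                     data.frame(contig_id = dup,
                                orient = sample(c("+", "-"), 1L)),
                     steps[-seq_len(at), ])
    }
    mult <- table(steps$contig_id)
    ns <- nrow(steps)
    exit_of <- function(o) ifelse(o == "+", "3", "5")
    entry_of <- function(o) ifelse(o == "+", "5", "3")
    edges <- data.frame(
      a_id = steps$contig_id, a_end = exit_of(steps$orient),
      b_id = steps$contig_id[c(2:ns, 1L)],
      b_end = entry_of(steps$orient[c(2:ns, 1L)]),
      support = 10L)
    g <- contig_graph(
      data.frame(contig_id = ids, length = 300L,
                 depth = 40 * as.integer(mult[ids])),
      edges)
    m <- setNames(as.integer(mult), names(mult))
    want <- brute_circular_walks(g, m)
    got <- tryCatch(
      sort(vapply(find_circular_path(g, m),
                  function(w) oracle_walk_key(w$steps), character(1)),
           method = "radix"),
      error = function(e) character(0))
    expect_identical(got, want)
    expect_gte(length(want), 1L) # the planted walk itself must be found
  }
})

test_that("walk output is invariant to contig relabelling of the start", {
  g <- simple_cycle_graph(c("k", "b", "z", "m"))
  w1 <- find_circular_path(g)[[1L]]
  relabel <- c(k = "q", b = "b", z = "z", m = "m")
  g2 <- contig_graph(
    transform(g$nodes, contig_id = unname(relabel[contig_id])),
    transform(g$edges, a_id = unname(relabel[a_id]),
              b_id = unname(relabel[b_id])))
  w2 <- find_circular_path(g2)[[1L]]
  back <- setNames(names(relabel), relabel)
  steps_back <- transform(w2$steps, contig_id = unname(back[contig_id]))
  expect_equal(oracle_walk_key(w1$steps), oracle_walk_key(steps_back))
})

test_that("infer_multiplicity recovers planted copy numbers", {
  for (seed in 1:10) {
    sim <- shred_to_graph(
      synthetic_truth(list(make_cp_genome(cp_genome_spec(), seed),
                           make_mt_genome(mt_genome_spec(), seed + 10))),
      seed = seed)
    truth_mult <- setNames(sim$truth$contigs$multiplicity,
                           sim$truth$contigs$contig_id)
    for (gm in c("cp", "mt")) {
      ids <- sim$truth$contigs$contig_id[sim$truth$contigs$genome == gm]
      sub <- orgc:::induced_subgraph_contigs(sim$graph, ids)
      mult <- infer_multiplicity(sub)
      expect_identical(unname(mult[ids]), unname(truth_mult[ids]))
    }
  }
})

test_that("quadripartite annotation recovers the planted region lengths", {
  sim <- shred_to_graph(
    synthetic_truth(list(make_cp_genome(cp_genome_spec(), 3))), seed = 3)
  ids <- sim$truth$contigs$contig_id
  g <- sim$graph
  mult <- infer_multiplicity(g)
  walks <- find_circular_path(g, mult)
  ann <- annotate_quadripartite(walks[[1L]], mult, g)
  expect_equal(ann$lsc_len, 8000)
  expect_equal(ann$ssc_len, 2000)
  expect_equal(ann$ir_len, 3000)
  expect_equal(ann$segments$region, c("LSC", "IRa", "SSC", "IRb"))
  expect_gte(ann$lsc_len, ann$ssc_len)
  # IRa and IRb traverse the same contig set
  s <- walks[[1L]]$steps$contig_id
  expect_setequal(s[ann$steps$IRa], s[ann$steps$IRb])
})

test_that("annotation degenerates gracefully without repeats and ties are logged", {
  g <- simple_cycle_graph(c("a", "b", "c"))
  w <- find_circular_path(g)[[1L]]
  expect_warning(ann <- annotate_quadripartite(w, setNames(rep(1L, 3), letters[1:3]), g),
                 "single LSC")
  expect_equal(ann$segments$region, "LSC")
  expect_equal(ann$lsc_len, 3000)

  # equal arcs: first-traversed arc becomes LSC, with a message
  g2 <- cp_toy_graph()
  nodes <- g2$nodes
  nodes$length[nodes$contig_id == "S"] <- nodes$length[nodes$contig_id == "L"]
  g2 <- contig_graph(nodes, g2$edges)
  mult <- c(L = 1L, I = 2L, S = 1L)
  w2 <- find_circular_path(g2, mult)[[1L]]
  expect_message(ann2 <- annotate_quadripartite(w2, mult, g2), "labelled LSC")
  expect_equal(ann2$lsc_len, ann2$ssc_len)
})

test_that("major-link selection reproduces the published repeat decisions", {
  tab <- read_link_table(system.file("extdata", "boea_mt_repeat_links.tsv",
                                     package = "orgc"))
  sel <- select_major_links(tab)
  pairs <- function(s) {
    sort(paste(s$selected$five_prime_contig, s$selected$three_prime_contig,
               s$selected$link_count))
  }
  expect_equal(pairs(sel[["Repeat 1"]]),
               sort(c("Contig00011 Contig00012 3990",
                      "Contig00059 Contig00050 3226")))
  expect_equal(pairs(sel[["Repeat 2"]]),
               sort(c("Contig00001 Contig00026 810",
                      "Contig00004 Contig00032 615")))
  expect_equal(pairs(sel[["Repeat 3"]]),
               sort(c("Contig00026 Contig00281 53",
                      "Contig00395 Contig200056 51")))
  expect_equal(sel[["Repeat 1"]]$total_support, 7216L)
  # every candidate row lands in selected or rejected
  for (s in sel) {
    expect_equal(nrow(s$selected) + nrow(s$rejected), 4L)
  }
})

test_that("single-candidate repeats and degenerate tables", {
  tab <- link_table(data.frame(repeat_id = "r", link_count = 9L,
                               five_prime_contig = "a",
                               three_prime_contig = "b"))
  sel <- select_major_links(tab)
  expect_equal(nrow(sel[["r"]]$selected), 1L)
  expect_equal(nrow(sel[["r"]]$rejected), 0L)

  tie <- link_table(data.frame(
    repeat_id = "r", link_count = c(5L, 5L, 5L, 5L),
    five_prime_contig = c("a", "c", "a", "c"),
    three_prime_contig = c("b", "d", "d", "b")))
  expect_error(select_major_links(tie), "tied")

  nomatch <- link_table(data.frame(
    repeat_id = "r", link_count = c(5L, 6L),
    five_prime_contig = c("a", "a"),
    three_prime_contig = c("b", "c")))
  expect_error(select_major_links(nomatch), "no perfect")
})

test_that("selection equals brute-force matching on random candidate tables", {
  set.seed(29)
  for (i in 1:200) {
    flanks <- paste0("f", 1:4)
    rows <- data.frame(
      repeat_id = "r",
      link_count = sample.int(500, 4L),
      five_prime_contig = c(flanks[1], flanks[3], flanks[1], flanks[3]),
      three_prime_contig = c(flanks[2], flanks[4], flanks[4], flanks[2]))
    want <- brute_matching(rows)
    got <- tryCatch(select_major_links(link_table(rows)),
                    error = function(e) e)
    if (length(want$sets) > 1L) {
      expect_s3_class(got, "error")
    } else {
      expect_equal(got[["r"]]$total_support, want$weight)
      expect_equal(sort(match(
        paste(got[["r"]]$selected$five_prime_contig,
              got[["r"]]$selected$three_prime_contig),
        paste(rows$five_prime_contig, rows$three_prime_contig))),
        want$sets[[1L]])
    }
  }
})

test_that("applying major links expands a repeat into wired copies", {
  nodes <- data.frame(
    contig_id = c("Contig00011", "Contig00012", "Contig00059", "Contig00050",
                  "Rep1"),
    length = c(4000L, 3000L, 3500L, 2500L, 1000L),
    depth = c(43, 43, 43, 43, 86))
  edges <- data.frame(
    a_id = c("Contig00011", "Rep1", "Contig00059", "Rep1"),
    a_end = c("3", "3", "3", "3"),
    b_id = c("Rep1", "Contig00012", "Rep1", "Contig00050"),
    b_end = c("5", "5", "5", "5"),
    support = 50L)
  g <- contig_graph(nodes, edges)
  tab <- read_link_table(system.file("extdata", "boea_mt_repeat_links.tsv",
                                     package = "orgc"))
  sel <- select_major_links(tab)
  g2 <- apply_major_links(g, c("Repeat 1" = "Rep1"), sel)

  expect_false("Rep1" %in% g2$nodes$contig_id)
  copies <- grep("^Rep1#", g2$nodes$contig_id, value = TRUE)
  expect_length(copies, 2L)
  nb <- function(id) {
    e <- g2$edges
    sort(unique(c(e$b_id[e$a_id == id], e$a_id[e$b_id == id])))
  }
  all_nb <- lapply(copies, nb)
  expect_true(any(vapply(all_nb, identical, logical(1),
                         c("Contig00011", "Contig00012"))))
  expect_true(any(vapply(all_nb, identical, logical(1),
                         c("Contig00050", "Contig00059"))))

  # sequence content conserved: length x multiplicity before == after
  expect_equal(sum(g2$nodes$length),
               sum(nodes$length) + 1000L) # the repeat now counted twice
  expect_error(apply_major_links(g, c("Repeat 2" = "Rep1"), sel),
               "non-neighbour")
})

test_that("after applying planted-link selections the master circle is unique", {
  for (seed in c(4, 9, 12)) {
    sim <- simulate_assembly(seed = seed)
    asm <- suppressWarnings(
      assemble_genome(sim$graph, "MT", link_table = sim$links))
    expect_length(asm$alternates, 0L)
    expect_true(asm$circle$closed)
  }
})
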