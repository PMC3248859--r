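# Synthetic planted genomes, shredding, link simulation, subsampling.

test_that("planted cp genome has the quadripartite layout", {
  spec <- cp_genome_spec()
  g <- make_cp_genome(spec, seed = 1)
  expect_equal(nchar(g$sequence), 16000L)
  ira <- substr(g$sequence, 8001L, 11000L)
  irb <- substr(g$sequence, 13001L, 16000L)
  expect_identical(irb, revcomp(ira))
})

test_that("generators are deterministic under a fixed seed", {
  a <- make_cp_genome(cp_genome_spec(), seed = 5)
  b <- make_cp_genome(cp_genome_spec(), seed = 5)
  c <- make_cp_genome(cp_genome_spec(), seed = 6)
  expect_identical(a$sequence, b$sequence)
  expect_false(identical(a$sequence, c$sequence))

  m1 <- make_mt_genome(mt_genome_spec(), seed = 5)
  m2 <- make_mt_genome(mt_genome_spec(), seed = 5)
  expect_identical(m1$sequence, m2$sequence)
  expect_identical(m1$blocks, m2$blocks)

  s1 <- shred_to_graph(synthetic_truth(list(a)), seed = 9)
  s2 <- shred_to_graph(synthetic_truth(list(b)), seed = 9)
  expect_graph_equal(s1$graph, s2$graph)
})

test_that("mt repeat copies are byte-identical and flank pairings recorded", {
  spec <- mt_genome_spec(total_len = 20000L,
                         repeats = data.frame(repeat_len = 500L,
                                              n_copies = 2L,
                                              inverted = FALSE))
  g <- make_mt_genome(spec, seed = 2)
  reps <- g$blocks[g$blocks$type == "repeat", ]
  expect_equal(nrow(reps), 2L)
  s1 <- substr(g$sequence, reps$start[1L] + 1L, reps$end[1L])
  s2 <- substr(g$sequence, reps$start[2L] + 1L, reps$end[2L])
  expect_identical(s1, s2)

  sh <- shred_to_graph(synthetic_truth(list(g)), seed = 2)
  lt <- sh$truth$link_truth
  expect_equal(nrow(lt), 2L) # one pairing per copy
  expect_equal(length(unique(lt$repeat_id)), 1L)

  # an impossible placement is an overlap error
  tight <- mt_genome_spec(total_len = 6000L,
                          repeats = data.frame(repeat_len = 2000L,
                                               n_copies = 2L,
                                               inverted = FALSE))
  expect_error(make_mt_genome(tight, seed = 1), "overlap")
})

test_that("contigs tile each planted genome exactly", {
  for (seed in 1:10) {
    sim <- shred_to_graph(
      synthetic_truth(list(make_cp_genome(cp_genome_spec(), seed),
                           make_mt_genome(mt_genome_spec(), seed + 20),
                           make_nuclear_background(nuclear_genome_spec(),
                                                   seed + 40))),
      seed = seed)
    truth <- sim$truth
    for (nm in names(truth$genomes)) {
      ctg <- truth$contigs[truth$contigs$genome == nm, ]
      expect_equal(sum(ctg$length * ctg$multiplicity),
                   nchar(truth$genomes[[nm]]$sequence))
    }
    # and the planted path reconstructs every circular genome verbatim
    for (nm in c("cp", "mt")) {
      path <- truth$paths[[nm]]
      seqs <- sim$graph$nodes$sequence[match(path$contig_id,
                                             sim$graph$nodes$contig_id)]
      built <- paste(ifelse(path$orient == "+", seqs,
                            vapply(seqs, revcomp, character(1))),
                     collapse = "")
      expect_identical(built, truth$genomes[[nm]]$sequence)
    }
  }
})

test_that("collapsed repeats sit at an integer multiple of the class depth", {
  sim <- shred_to_graph(
    synthetic_truth(list(make_cp_genome(cp_genome_spec(), 4))),
    depth_noise_sd = 0.5, seed = 4)
  ctg <- sim$truth$contigs
  ir <- ctg[ctg$multiplicity == 2L, ]
  expect_gt(nrow(ir), 0L)
  expect_true(all(abs(ir$depth - 174) < 5))
  expect_true(all(abs(ctg$depth[ctg$multiplicity == 1L] - 87) < 5))
})

test_that("without cross links each circular genome shreds to one cycle", {
  for (seed in 1:5) {
    sim <- shred_to_graph(
      synthetic_truth(list(make_cp_genome(cp_genome_spec(), seed),
                           make_mt_genome(mt_genome_spec(), seed + 30))),
      cross_links = 0L, seed = seed)
    proj <- orgc:::node_projection(sim$graph)
    comp <- igraph::components(proj)
    expect_equal(comp$no, 2L)
    for (nm in c("cp", "mt")) {
      ids <- sim$truth$contigs$contig_id[sim$truth$contigs$genome == nm]
      expect_equal(length(unique(comp$membership[ids])), 1L)
      # a closed walk over the planted multiplicities exists
      sub <- orgc:::induced_subgraph_contigs(sim$graph, ids)
      mult <- setNames(sim$truth$contigs$multiplicity,
                       sim$truth$contigs$contig_id)[ids]
      expect_gte(length(find_circular_path(sub, mult)), 1L)
    }
  }
})

test_that("depth ordering matches the copy-number regime", {
  sim <- shred_to_graph(
    synthetic_truth(list(make_cp_genome(cp_genome_spec(), 11),
                         make_mt_genome(mt_genome_spec(), 12),
                         make_nuclear_background(nuclear_genome_spec(), 13))),
    seed = 11)
  ctg <- sim$truth$contigs[sim$truth$contigs$multiplicity == 1L, ]
  m <- tapply(ctg$depth, ctg$kind, mean)
  expect_gt(m[["CP"]], m[["MT"]])
  expect_gt(m[["MT"]], m[["NUCLEAR"]])
})

test_that("simulated link tables mirror the published table shape", {
  sim <- shred_to_graph(
    synthetic_truth(list(make_mt_genome(mt_genome_spec(), 14))), seed = 14)
  tab <- simulate_link_table(sim$truth, seed = 14)
  # each 2-copy repeat: 2 true + 2 cross-copy noise rows
  expect_true(all(table(tab$repeat_id) == 4L))

  noiseless <- simulate_link_table(sim$truth, n_pairs_per_true_link = 50,
                                   noise_pairs = 0, seed = 14)
  sel <- select_major_links(noiseless)
  lt <- sim$truth$link_truth
  for (rid in unique(lt$repeat_id)) {
    want <- sort(paste(lt$five_prime_contig[lt$repeat_id == rid],
                       lt$three_prime_contig[lt$repeat_id == rid]))
    got <- sort(paste(sel[[rid]]$selected$five_prime_contig,
                      sel[[rid]]$selected$three_prime_contig))
    expect_equal(got, want)
  }

  expect_error(simulate_link_table(sim$truth, 10, 10), "noise_pairs")
  unshred <- synthetic_truth(list(make_cp_genome(cp_genome_spec(), 1)))
  expect_error(simulate_link_table(unshred), "no dispersed repeats")
})

test_that("planted flank pairings are recovered from noisy link counts", {
  sim <- shred_to_graph(
    synthetic_truth(list(make_mt_genome(mt_genome_spec(), 15))), seed = 15)
  lt <- sim$truth$link_truth
  recovered <- 0L
  for (trial in 1:200) {
    tab <- simulate_link_table(sim$truth, n_pairs_per_true_link = 50,
                               noise_pairs = 5, seed = trial)
    ok <- tryCatch({
      sel <- select_major_links(tab)
      all(vapply(unique(lt$repeat_id), function(rid) {
        setequal(paste(sel[[rid]]$selected$five_prime_contig,
                       sel[[rid]]$selected$three_prime_contig),
                 paste(lt$five_prime_contig[lt$repeat_id == rid],
                       lt$three_prime_contig[lt$repeat_id == rid]))
      }, logical(1)))
    }, error = function(e) FALSE)
    recovered <- recovered + ok
  }
  expect_gte(recovered, 198L) # >= 99% of 200 seeded trials
})

test_that("subsampling coverage starts at zero and is monotone", {
  truth <- synthetic_truth(list(
    make_cp_genome(cp_genome_spec(), 16),
    make_mt_genome(mt_genome_spec(), 17),
    make_nuclear_background(nuclear_genome_spec(), 18)))
  tab <- subsample_experiment(truth, data_points = c(0, 0.1, 0.3, 0.8),
                              seed = 19)
  expect_true(all(tab$covered_pct[tab$sample_mbp == 0] == 0))
  for (nm in unique(tab$genome)) {
    v <- tab$covered_pct[tab$genome == nm]
    expect_true(all(diff(v) >= 0))
  }
  expect_error(subsample_experiment(truth, data_points = numeric(0)), "empty")
  expect_error(subsample_experiment(truth, data_points = c(2, 1)), "sorted")
})
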