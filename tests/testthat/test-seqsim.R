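test_that("tree simulation is deterministic, ultrametric and clock-scaled", {
  cfg <- sim_config(seed = 201, n_taxa = 10)
  a <- simulate_trees(cfg)
  b <- simulate_trees(cfg)
  expect_identical(write_newick(a$chronogram), write_newick(b$chronogram))
  expect_identical(write_newick(a$phylogram), write_newick(b$phylogram))
  expect_true(is_chronogram(a$chronogram))
  d <- ape::node.depth.edgelength(a$chronogram)
  expect_equal(max(d), cfg$root_age, tolerance = 1e-9)
  # strict clock: phylogram is an exact scalar multiple of the chronogram
  expect_equal(a$phylogram$edge.length,
               a$chronogram$edge.length * cfg$base_rate, tolerance = 1e-12)
  # lognormal branch noise breaks the strict proportionality
  cfgn <- sim_config(seed = 201, n_taxa = 10, branch_sigma = 0.4)
  n <- simulate_trees(cfgn)
  ratio <- n$phylogram$edge.length / (n$chronogram$edge.length * cfgn$base_rate)
  expect_gt(stats::sd(ratio), 0)
})

test_that("alignment simulation is seed-deterministic and stop-free", {
  cfg <- sim_config(seed = 211, n_taxa = 6)
  tr <- simulate_trees(cfg)
  a <- simulate_codon_alignment(tr$phylogram, 0.2, 2, length_codons = 50,
                                seed = 212)
  b <- simulate_codon_alignment(tr$phylogram, 0.2, 2, length_codons = 50,
                                seed = 212)
  expect_identical(a, b)
  expect_equal(names(a), tr$phylogram$tip.label)
  for (s in a) expect_false(any(split_codons(s) %in% c("TAA", "TAG", "TGA")))
})

test_that("omega = 0 forbids amino-acid change", {
  cfg <- sim_config(seed = 221, n_taxa = 5)
  tr <- simulate_trees(cfg)
  # long branches to accumulate plenty of synonymous change
  tr$phylogram$edge.length <- tr$phylogram$edge.length * 20
  aln <- simulate_codon_alignment(tr$phylogram, omega = 0, kappa = 2,
                                  length_codons = 200, seed = 222)
  # every taxon encodes the identical protein
  prots <- vapply(aln, function(s)
    paste(translate_codons(split_codons(s)), collapse = ""), "")
  expect_length(unique(unname(prots)), 1L)
  # NG86 assigns zero nonsynonymous differences to every single-hit codon
  # (multi-hit codons can pick up fractional Nd through path averaging,
  # which is a property of the counting method, not of the history)
  pairs <- utils::combn(length(aln), 2)
  for (k in seq_len(ncol(pairs))) {
    ca <- split_codons(aln[[pairs[1, k]]])
    cb <- split_codons(aln[[pairs[2, k]]])
    ndiff <- mapply(function(x, y)
      sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]), ca, cb)
    single <- ndiff == 1L
    if (!any(single)) next
    x <- ng86_pair(paste(ca[single], collapse = ""),
                   paste(cb[single], collapse = ""))
    expect_equal(x$Nd, 0)
  }
  expect_gt(ng86_pair(aln[[1]], aln[[2]])$Sd, 0)
})

test_that("rate multiplier zero freezes the root sequence", {
  cfg <- sim_config(seed = 231, n_taxa = 5)
  tr <- simulate_trees(cfg)
  aln <- simulate_codon_alignment(tr$phylogram, 0.2, 2, r = 0,
                                  length_codons = 40, seed = 232)
  expect_length(unique(unname(aln)), 1L)
})

test_that("zero-frequency codons are rejected", {
  cfg <- sim_config(seed = 241, n_taxa = 4)
  tr <- simulate_trees(cfg)
  f <- example_codon_freqs("uniform")
  f[1] <- 0
  expect_error(simulate_codon_alignment(tr$phylogram, 0.2, 2,
                                        codon_freqs = f, length_codons = 10,
                                        seed = 242), "positive")
})

test_that("gene panels carry complete, correct truth", {
  cfg <- sim_config(seed = 251, n_taxa = 8, class_table = data.frame(
    class_label = c("canonical", "mobile"), n_genes = c(3, 2),
    rate_multiplier = c(1, 12.5), length_codons = 60))
  sim <- simulate_gene_set(cfg)
  expect_equal(nrow(sim$truth), 5L)
  expect_false(anyDuplicated(sim$truth$gene_id) > 0)
  expect_setequal(names(sim$gene_trees), sim$truth$gene_id)
  expect_setequal(names(sim$alignments), sim$truth$gene_id)
  # branch-length-true gene trees: chronogram x base_rate x multiplier
  for (i in seq_len(nrow(sim$truth))) {
    g <- sim$truth$gene_id[i]
    expect_equal(sim$gene_trees[[g]]$edge.length,
                 sim$chronogram$edge.length * cfg$base_rate *
                   sim$truth$rate_multiplier[i], tolerance = 1e-12)
  }
  # single class: all relative rates around 1
  cfg1 <- sim_config(seed = 252, n_taxa = 8, class_table = data.frame(
    class_label = "canonical", n_genes = 2, rate_multiplier = 1,
    length_codons = 30))
  sim1 <- simulate_gene_set(cfg1)
  e <- gene_rates(sim1$gene_trees[[1]], sim1$phylogram, sim1$chronogram)
  expect_equal(e$rel_rate[e$included], rep(1, sum(e$included)),
               tolerance = 1e-9)
})

test_that("pileups without error or edits are pure reference", {
  cds <- random_codons(100)
  p <- simulate_pileup(cds, NULL, coverage_mean = 30, error_rate = 0,
                       seed = 261)
  nonref <- mapply(function(i, ref) {
    row <- p[i, c("count_A", "count_C", "count_G", "count_T")]
    sum(row) - row[[paste0("count_", ref)]]
  }, seq_len(nrow(p)), p$ref_base)
  expect_true(all(nonref == 0))
  expect_true(all(p$count_A + p$count_C + p$count_G + p$count_T == p$total))
})

test_that("planted edits at high efficiency are always called", {
  cds <- random_codons(100)
  pos <- which(strsplit(cds, "")[[1]] %in% c("C", "T"))[1:10]
  p <- simulate_pileup(cds, data.frame(pos = pos, efficiency = 1),
                       coverage_mean = 60, error_rate = 0, seed = 271)
  called <- classify_sites(p)
  expect_setequal(called$pos[called$passed], pos)
})

test_that("recall stays high at moderate efficiency and deep coverage", {
  set.seed(281)
  cds <- random_codons(400)
  pos <- which(strsplit(cds, "")[[1]] %in% c("C", "T"))[1:50]
  p <- simulate_pileup(cds, data.frame(pos = pos, efficiency = 0.3),
                       coverage_mean = 100, error_rate = 0, seed = 282)
  called <- classify_sites(p)
  recall <- mean(pos %in% called$pos[called$passed])
  expect_gte(recall, 0.98)
})

test_that("edits planted on non-C/T references are rejected", {
  cds <- "GGGGGG"
  expect_error(simulate_pileup(cds, data.frame(pos = 2, efficiency = 0.5),
                               seed = 291), "not C or T")
})

test_that("codon-usage class generation is deterministic and length-true", {
  ct <- data.frame(class_label = c("a", "b"), n_genes = 3,
                   length_codons = 167)
  ct$codon_freqs <- list(example_codon_freqs("at3"),
                         example_codon_freqs("gc3"))
  s1 <- simulate_codon_usage_classes(ct, seed = 301)
  s2 <- simulate_codon_usage_classes(ct, seed = 301)
  expect_identical(s1, s2)
  expect_true(all(nchar(s1$genes) == 501))
  expect_length(suppressMessages(filter_genes(s1$genes)), 6L)
})
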