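test_that("pruning preserves the path-length matrix among survivors", {
  cfg <- sim_config(seed = 101, n_taxa = 8)
  tr <- simulate_trees(cfg)$phylogram
  pruned <- prune_taxa(tr, c("t01", "t05"))
  keep <- pruned$tip.label
  expect_equal(ape::cophenetic.phylo(pruned)[keep, keep],
               ape::cophenetic.phylo(tr)[keep, keep], tolerance = 1e-9)
  expect_identical(prune_taxa(tr, character(0)), tr)
  expect_error(prune_taxa(tr, "nope"), "not in tree")
  expect_error(prune_taxa(tr, paste0("t0", 1:7)), "fewer than 2")
})

test_that("internode enumeration lists every clade of size >= 2", {
  bal <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  sets <- enumerate_internodes(bal)
  expect_setequal(names(sets), c("A|B", "C|D", "A|B|C|D"))
  cat1 <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,D:1);")
  expect_setequal(names(enumerate_internodes(cat1)),
                  c("A|B", "A|B|C", "A|B|C|D"))
  two <- ape::read.tree(text = "(A:1,B:2);")
  expect_equal(names(enumerate_internodes(two)), "A|B")
})

test_that("tip-to-root sums follow the stated conventions", {
  bal <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(tip_to_root_sum(bal, c("A", "B")), 2)   # stem excluded
  expect_equal(tip_to_root_sum(bal, c("A", "B", "C", "D")), 8)
  chrono <- balanced_chronogram()
  expect_equal(tip_to_root_sum(chrono, c("A", "B", "C", "D")), 4 * 15)
  expect_error(tip_to_root_sum(bal, c("A", "C")), "not a clade")
})

test_that("monophyly check matches the reference topology", {
  ref <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(monophyly_consistent(c("A", "B"), ref))
  expect_false(monophyly_consistent(c("A", "C"), ref))
  expect_true(monophyly_consistent(c("A", "B", "C", "D"), ref))
  expect_error(monophyly_consistent(c("A", "Z"), ref), "Z")
})

test_that("self-normalisation returns relative rate 1 everywhere", {
  cfg <- sim_config(seed = 111, n_taxa = 10)
  sim <- simulate_trees(cfg)
  est <- gene_rates(sim$phylogram, sim$phylogram, sim$chronogram)
  expect_true(all(est$included))
  expect_equal(est$rel_rate, rep(1, nrow(est)), tolerance = 1e-9)
})

test_that("scaling gene branches scales every estimate linearly", {
  cfg <- sim_config(seed = 121, n_taxa = 10)
  sim <- simulate_trees(cfg)
  base <- gene_rates(sim$phylogram, sim$phylogram, sim$chronogram)
  for (c_mult in c(0.5, 3)) {
    g <- sim$phylogram
    g$edge.length <- g$edge.length * c_mult
    est <- gene_rates(g, sim$phylogram, sim$chronogram)
    expect_equal(est$rel_rate, base$rel_rate * c_mult, tolerance = 1e-9)
    expect_equal(est$abs_rate, base$abs_rate * c_mult, tolerance = 1e-9)
  }
})

test_that("absolute rate matches the hand-built four-taxon example", {
  # gene subtree summing to 0.6 subs/site over 4 tips; chronogram tips
  # 15 Myr from the root (sum 60) -> 0.01 subs/site/Myr
  gene <- ape::read.tree(text = "((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05);")
  chrono <- balanced_chronogram()
  phylo <- chrono
  phylo$edge.length <- chrono$edge.length * 1e-3
  est <- gene_rates(gene, phylo, chrono)
  root_row <- est[est$internode_id == "A|B|C|D", ]
  expect_equal(tip_to_root_sum(gene, c("A", "B", "C", "D")), 0.6)
  expect_equal(root_row$abs_rate, 0.01, tolerance = 1e-12)
  expect_equal(root_row$rel_rate, 0.6 / 0.06, tolerance = 1e-12)
})

test_that("non-monophyletic internodes are excluded with a reason", {
  gene <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  chrono <- balanced_chronogram()
  phylo <- chrono; phylo$edge.length <- chrono$edge.length * 1e-3
  est <- gene_rates(gene, phylo, chrono)
  ac <- est[est$internode_id == "A|C", ]
  expect_false(ac$included)
  expect_equal(ac$reason, "not_monophyletic_in_reference")
  expect_true(est$included[est$internode_id == "A|B|C|D"])
  # excluded rows never reach the summaries
  s <- summarize_rates(est)
  expect_equal(s$n, sum(est$included))
})

test_that("pseudogene-like tips are dropped when excluding frameshifts", {
  cfg <- sim_config(seed = 131, n_taxa = 8)
  sim <- simulate_trees(cfg)
  flags <- stats::setNames(c(2L, 0L, 1L), c("t01", "t02", "t03"))
  est <- gene_rates(sim$phylogram, sim$phylogram, sim$chronogram,
                    flags = flags, exclude_pseudogenes = TRUE)
  tips <- unique(unlist(strsplit(est$internode_id, "|", fixed = TRUE)))
  expect_false(any(c("t01", "t03") %in% tips))
  expect_true("t02" %in% tips)
  # flags naming unknown taxa are a hard error
  expect_error(gene_rates(sim$phylogram, sim$phylogram, sim$chronogram,
                          flags = c(zz = 1L), exclude_pseudogenes = TRUE),
               "zz")
})

test_that("dropping a taxon outside an internode leaves its rates unchanged", {
  cfg <- sim_config(seed = 141, n_taxa = 8)
  sim <- simulate_trees(cfg)
  g <- sim$phylogram
  g$edge.length <- g$edge.length * 2
  full <- gene_rates(g, sim$phylogram, sim$chronogram)
  # drop one tip; internodes not containing it keep identical rates
  dropped <- gene_rates(g, sim$phylogram, sim$chronogram, drop = "t08")
  shared <- intersect(full$internode_id[!grepl("t08", full$internode_id)],
                      dropped$internode_id)
  expect_gt(length(shared), 0)
  for (id in shared) {
    expect_equal(dropped$rel_rate[dropped$internode_id == id],
                 full$rel_rate[full$internode_id == id], tolerance = 1e-9)
  }
})

test_that("label harmonisation maps spaces to underscores, errors otherwise", {
  gene <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  gene$tip.label <- c("A sp", "B", "C", "D")
  chrono <- balanced_chronogram()
  chrono$tip.label <- c("A_sp", "B", "C", "D")
  phylo <- chrono; phylo$edge.length <- chrono$edge.length * 1e-3
  est <- gene_rates(gene, phylo, chrono)
  expect_true(all(est$included))
  gene2 <- gene; gene2$tip.label[1] <- "Elsewhere"
  expect_error(gene_rates(gene2, phylo, chrono), "Elsewhere")
})

test_that("rate summaries follow the type-7 quartile / 1.5 IQR convention", {
  est <- data.frame(gene_id = "g", internode_id = letters[1:5],
                    n_tips = 2L, rel_rate = c(1, 2, 3, 4, 100),
                    abs_rate = 1, included = TRUE, reason = "")
  s <- summarize_rates(est)
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(s$whisker_high, 4)
  expect_equal(s$outliers, "100")
  # all-equal estimates: degenerate box, no outliers
  est$rel_rate <- rep(2, 5)
  s2 <- summarize_rates(est)
  expect_equal(s2$outliers, "")
  expect_equal(s2$median, 2)
  # single estimate
  s3 <- summarize_rates(est[1, ])
  expect_equal(s3$median, 2)
  expect_equal(s3$q3 - s3$q1, 0)
  # zero included estimates: flagged empty
  est$included <- FALSE
  s4 <- summarize_rates(est)
  expect_true(s4$empty)
})

test_that("mobile-class rate multiplier is recovered from the gene panel", {
  cfg <- sim_config(seed = 151, n_taxa = 12, class_table = data.frame(
    class_label = c("canonical", "mobile"), n_genes = c(4, 2),
    rate_multiplier = c(1, 12.5), length_codons = 100))
  sim <- simulate_gene_set(cfg)
  med <- function(class) {
    ids <- sim$truth$gene_id[sim$truth$class_label == class]
    rates <- unlist(lapply(ids, function(g) {
      e <- gene_rates(sim$gene_trees[[g]], sim$phylogram, sim$chronogram,
                      gene_id = g)
      e$rel_rate[e$included]
    }))
    stats::median(rates)
  }
  ratio <- med("mobile") / med("canonical")
  expect_lt(abs(ratio - 12.5) / 12.5, 0.2)
})
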