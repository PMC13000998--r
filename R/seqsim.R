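# Seeded synthetic-data generators: clock-like chronogram + rate-scaled
# phylogram, codon alignments evolved under an MG94-flavoured model with
# per-class rate multipliers, pileups with planted editing sites, and
# codon-usage classes with distinct frequency vectors. Every generator
# emits ground truth so downstream recovery is scored exactly.

#' Simulation configuration
#'
#' Defaults describe a fern-plastome-like study system: a 136-Myr crown
#' age (the younger of the two fossil calibrations, kept with the 231.11
#' Myr maximum as metadata), a plastome-order base rate of 2.5e-4
#' substitutions/site/Myr, purifying selection (omega = 0.2), and a
#' transition/transversion ratio of 2.
#'
#' @param seed integer master seed; all derived seeds stay below 2^31.
#' @param n_taxa number of tips (>= 4).
#' @param root_age crown age of the chronogram, Myr.
#' @param base_rate substitutions/site/Myr converting time to expected
#'   substitutions.
#' @param omega target dN/dS of the codon model (< 1 = purifying).
#' @param kappa transition/transversion rate ratio.
#' @param branch_sigma sd of optional lognormal per-branch rate noise on
#'   the phylogram (0 = strict clock).
#' @param class_table data.frame with columns `class_label`, `n_genes`,
#'   `rate_multiplier`, `length_codons` (and optionally a list column
#'   `codon_freqs`).
#' @param coverage_mean mean mapped-read coverage for simulated pileups.
#' @param error_rate per-base sequencing error rate for pileups.
#' @param calibration_max,calibration_min fossil calibration metadata, Myr.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_taxa = 10L, root_age = 136,
                       base_rate = 2.5e-4, omega = 0.2, kappa = 2,
                       branch_sigma = 0, class_table = NULL,
                       coverage_mean = 100, error_rate = 0.01,
                       calibration_max = 231.11, calibration_min = 136) {
  stopifnot(n_taxa >= 4L, root_age > 0, base_rate > 0, omega >= 0,
            kappa > 0, branch_sigma >= 0, coverage_mean > 0,
            error_rate >= 0, error_rate < 1)
  structure(list(seed = as.integer(seed), n_taxa = as.integer(n_taxa),
                 root_age = root_age, base_rate = base_rate, omega = omega,
                 kappa = kappa, branch_sigma = branch_sigma,
                 class_table = class_table, coverage_mean = coverage_mean,
                 error_rate = error_rate, calibration_max = calibration_max,
                 calibration_min = calibration_min),
            class = "sim_config")
}

# small deterministic sub-seed, kept below 2^31
.subseed <- function(seed, k) (as.integer(seed) %% 1000000L) * 1000L + k %% 1000L

#' Simulate a chronogram and matching phylogram
#'
#' A pure-birth tree is drawn and rescaled so every tip-to-root path
#' equals `root_age` (ultrametric); the phylogram multiplies each branch
#' by `base_rate`, with optional lognormal per-branch rate noise
#' (`branch_sigma`; mean rate preserved). With `branch_sigma = 0` the
#' phylogram is an exact scalar multiple of the chronogram.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `chronogram` and `phylogram` ([ape::phylo]).
#' @export
simulate_trees <- function(cfg) {
  set.seed(cfg$seed)
  tr <- ape::rphylo(cfg$n_taxa, birth = 0.1, death = 0)
  tr$tip.label <- sprintf("t%02d", seq_len(cfg$n_taxa))
  d <- ape::node.depth.edgelength(tr)
  tr$edge.length <- tr$edge.length * cfg$root_age / max(d)
  phy <- tr
  mult <- rep(1, nrow(tr$edge))
  if (cfg$branch_sigma > 0)
    mult <- stats::rlnorm(nrow(tr$edge), -cfg$branch_sigma^2 / 2,
                          cfg$branch_sigma)
  phy$edge.length <- tr$edge.length * cfg$base_rate * mult
  list(chronogram = tr, phylogram = phy)
}

# Build the MG94-flavoured rate matrix over the 61 sense codons:
# q_ij proportional to pi_j * kappa^[transition] * omega^[nonsynonymous]
# for single-nucleotide changes (zero to stops and multi-hit), scaled so
# the equilibrium expected rate is 1 substitution/site of branch length.
.codon_q <- function(omega, kappa, freqs) {
  cods <- sense_codons()
  n <- length(cods)
  code <- .code()
  chars <- do.call(rbind, strsplit(cods, ""))
  Q <- matrix(0, n, n, dimnames = list(cods, cods))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dif <- which(chars[i, ] != chars[j, ])
    if (length(dif) != 1L) next
    rate <- freqs[j]
    if (.is_transition(chars[i, dif], chars[j, dif])) rate <- rate * kappa
    if (code[[cods[i]]] != code[[cods[j]]]) rate <- rate * omega
    Q[i, j] <- rate
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  if (mu <= 0) stop("degenerate codon model: zero total rate")
  Q / mu
}

# eigendecomposition of the reversible Q for fast P(t)
.codon_eigen <- function(Q, freqs) {
  sp <- sqrt(freqs)
  Sm <- diag(sp) %*% Q %*% diag(1 / sp)
  e <- eigen((Sm + t(Sm)) / 2, symmetric = TRUE)
  list(U = diag(1 / sp) %*% e$vectors, Ui = t(e$vectors) %*% diag(sp),
       values = e$values)
}

.codon_pmat <- function(eg, t) {
  P <- eg$U %*% (exp(eg$values * t) * eg$Ui)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Evolve a codon alignment along a tree
#'
#' Simulates codon states down a rooted tree under a Markov codon model
#' whose instantaneous rates are proportional to the target codon
#' frequency times kappa for transitions and omega for nonsynonymous
#' changes; multi-nucleotide changes and changes to stop codons have rate
#' zero. Branch lengths are in expected substitutions/site and are
#' multiplied by `r` before simulation; the root sequence is drawn from
#' `codon_freqs`.
#'
#' @param tree rooted [ape::phylo] with branch lengths in subs/site.
#' @param omega,kappa codon-model parameters.
#' @param codon_freqs named frequencies over the 61 sense codons (default
#'   uniform); all must be > 0.
#' @param r rate multiplier applied to every branch.
#' @param length_codons alignment length in codons.
#' @param seed integer seed.
#' @return named character vector of tip sequences (a stop-free codon
#'   alignment).
#' @export
simulate_codon_alignment <- function(tree, omega, kappa, codon_freqs = NULL,
                                     r = 1, length_codons = 300L, seed = 1L) {
  cods <- sense_codons()
  if (is.null(codon_freqs))
    codon_freqs <- stats::setNames(rep(1 / 61, 61), cods)
  codon_freqs <- codon_freqs[cods]
  if (anyNA(codon_freqs) || any(codon_freqs <= 0))
    stop("codon_freqs must be positive over all 61 sense codons")
  codon_freqs <- codon_freqs / sum(codon_freqs)
  Q <- .codon_q(omega, kappa, codon_freqs)
  eg <- .codon_eigen(Q, codon_freqs)
  set.seed(as.integer(seed))
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  states <- matrix(NA_integer_, ntip + nnode, length_codons)
  root <- ntip + 1L
  states[root, ] <- sample.int(61L, length_codons, replace = TRUE,
                               prob = codon_freqs)
  # preorder edge traversal
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1L]; chd <- ord$edge[k, 2L]
    t_len <- ord$edge.length[k] * r
    if (t_len <= 0) { states[chd, ] <- states[par, ]; next }
    P <- .codon_pmat(eg, t_len)
    ps <- states[par, ]
    out <- integer(length_codons)
    for (s in unique(ps)) {
      sel <- which(ps == s)
      out[sel] <- sample.int(61L, length(sel), replace = TRUE, prob = P[s, ])
    }
    states[chd, ] <- out
  }
  seqs <- vapply(seq_len(ntip),
                 function(i) paste(cods[states[i, ]], collapse = ""), "")
  stats::setNames(seqs, tree$tip.label)
}

#' Simulate a multi-class gene panel with branch-length-true gene trees
#'
#' Generates a chronogram/phylogram pair, then for every gene of every
#' class emits (a) a branch-length-true gene phylogram equal to the
#' chronogram scaled by `base_rate` times the class rate multiplier, and
#' (b) a codon alignment evolved on that tree. Canonical-like classes use
#' multiplier 1; a "mobile" class uses an elevated multiplier (e.g. 12.5).
#'
#' @param cfg a [sim_config()] whose `class_table` is non-empty.
#' @return list: `chronogram`, `phylogram`, `gene_trees` (named list),
#'   `alignments` (named list), `truth` (data.frame gene_id, class_label,
#'   rate_multiplier, length_codons).
#' @export
simulate_gene_set <- function(cfg) {
  ct <- cfg$class_table
  if (is.null(ct) || !nrow(ct)) stop("class_table must be non-empty")
  trees <- simulate_trees(cfg)
  gene_trees <- list(); alns <- list(); rows <- list()
  g <- 0L
  for (i in seq_len(nrow(ct))) {
    freqs <- if (!is.null(ct$codon_freqs)) ct$codon_freqs[[i]] else NULL
    for (j in seq_len(ct$n_genes[i])) {
      g <- g + 1L
      gid <- sprintf("%s_g%02d", ct$class_label[i], j)
      gt <- trees$chronogram
      gt$edge.length <- gt$edge.length * cfg$base_rate * ct$rate_multiplier[i]
      gene_trees[[gid]] <- gt
      alns[[gid]] <- simulate_codon_alignment(
        trees$phylogram, cfg$omega, cfg$kappa, codon_freqs = freqs,
        r = ct$rate_multiplier[i], length_codons = ct$length_codons[i],
        seed = .subseed(cfg$seed, g))
      rows[[g]] <- data.frame(gene_id = gid, class_label = ct$class_label[i],
                              rate_multiplier = ct$rate_multiplier[i],
                              length_codons = ct$length_codons[i],
                              stringsAsFactors = FALSE)
    }
  }
  list(chronogram = trees$chronogram, phylogram = trees$phylogram,
       gene_trees = gene_trees, alignments = alns,
       truth = do.call(rbind, rows))
}

#' Simulate a base-count pileup with planted editing sites
#'
#' Coverage is Poisson(`coverage_mean`) per site; at planted sites the
#' edited-read count is Binomial(coverage, efficiency) toward the edited
#' base (C->T or T->C); background errors are Binomial(remaining reads,
#' `error_rate`) spread uniformly over the three non-reference bases.
#'
#' @param cds reference nucleotide string (the DNA sequence reads map to).
#' @param edits data.frame with columns `pos` (1-based) and `efficiency`;
#'   the reference base at each position must be C or T.
#' @param coverage_mean,error_rate see [sim_config()].
#' @param seed integer seed.
#' @param gene_id label for the `gene_id` column.
#' @return validated pileup data.frame (see [read_pileup()]).
#' @export
simulate_pileup <- function(cds, edits = NULL, coverage_mean = 100,
                            error_rate = 0.01, seed = 1L, gene_id = "gene") {
  cds <- toupper(cds)
  L <- nchar(cds)
  ref <- strsplit(cds, "")[[1]]
  if (any(!ref %in% c("A", "C", "G", "T")))
    stop("reference sequence must be over A/C/G/T")
  eff <- rep(0, L)
  if (!is.null(edits) && nrow(edits)) {
    stopifnot(all(edits$pos >= 1L), all(edits$pos <= L))
    bad <- which(!ref[edits$pos] %in% c("C", "T"))
    if (length(bad))
      stop("planted edit at position ", edits$pos[bad[1L]],
           ": reference base ", ref[edits$pos[bad[1L]]], " is not C or T")
    eff[edits$pos] <- edits$efficiency
  }
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  cov <- stats::rpois(L, coverage_mean)
  n_edit <- stats::rbinom(L, cov, eff)
  n_err <- stats::rbinom(L, cov - n_edit, error_rate)
  cnt <- matrix(0L, L, 4L, dimnames = list(NULL, bases))
  edited_base <- ifelse(ref == "C", "T", "C")
  for (i in seq_len(L)) {
    row <- stats::setNames(integer(4L), bases)
    row[edited_base[i]] <- row[edited_base[i]] + n_edit[i]
    if (n_err[i] > 0) {
      alts <- setdiff(bases, ref[i])
      err <- stats::rmultinom(1L, n_err[i], rep(1 / 3, 3L))[, 1L]
      row[alts] <- row[alts] + err
    }
    row[ref[i]] <- row[ref[i]] + cov[i] - n_edit[i] - n_err[i]
    cnt[i, ] <- row
  }
  validate_pileup(data.frame(
    gene_id = gene_id, pos = seq_len(L), ref_base = ref, total = cov,
    count_A = cnt[, "A"], count_C = cnt[, "C"], count_G = cnt[, "G"],
    count_T = cnt[, "T"], stringsAsFactors = FALSE))
}

#' Example codon frequency vectors for codon-usage classes
#'
#' Deterministic biased vectors over the 61 sense codons: `"at3"` weights
#' codons ending in A/T threefold (plastid-like AT bias at third
#' positions), `"gc3"` weights G/C-ending codons threefold (nuclear-like),
#' `"uniform"` is flat. Used to give simulated gene classes distinct,
#' recoverable codon-usage signatures.
#'
#' @param kind one of `"at3"`, `"gc3"`, `"uniform"`.
#' @return named frequency vector summing to 1.
#' @export
example_codon_freqs <- function(kind = c("at3", "gc3", "uniform")) {
  kind <- match.arg(kind)
  cods <- sense_codons()
  third <- substr(cods, 3L, 3L)
  w <- switch(kind,
              at3 = ifelse(third %in% c("A", "T"), 3, 1),
              gc3 = ifelse(third %in% c("G", "C"), 3, 1),
              uniform = rep(1, length(cods)))
  stats::setNames(w / sum(w), cods)
}

#' Simulate gene classes with distinct codon usage
#'
#' Genes are i.i.d. codon draws from their class frequency vector, so
#' between-class RSCU differences are governed entirely by the vectors.
#'
#' @param class_table data.frame with columns `class_label`, `n_genes`,
#'   `length_codons`, and list column `codon_freqs` (named vectors over
#'   the sense codons).
#' @param seed integer seed.
#' @return list: `genes` (named character vector of CDSs), `classes`
#'   (named character vector gene_id -> class_label).
#' @export
simulate_codon_usage_classes <- function(class_table, seed = 1L) {
  stopifnot(nrow(class_table) >= 1L)
  set.seed(as.integer(seed))
  cods <- sense_codons()
  genes <- character(0); classes <- character(0)
  for (i in seq_len(nrow(class_table))) {
    f <- class_table$codon_freqs[[i]][cods]
    if (anyNA(f)) stop("codon_freqs must cover all sense codons")
    f <- f / sum(f)
    for (j in seq_len(class_table$n_genes[i])) {
      gid <- sprintf("%s_g%02d", class_table$class_label[i], j)
      draw <- sample(cods, class_table$length_codons[i], replace = TRUE,
                     prob = f)
      genes[gid] <- paste(draw, collapse = "")
      classes[gid] <- class_table$class_label[i]
    }
  }
  list(genes = genes, classes = classes)
}
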