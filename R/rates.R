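# Relative and absolute substitution rates by internode tip-to-root
# normalisation against a reference phylogram (relative, dimensionless)
# and chronogram (absolute, substitutions/site/Myr).

# exact-match label harmonisation: trim whitespace, spaces -> underscores
.norm_labels <- function(x) gsub("[[:space:]]+", "_", trimws(x))

#' Check that a tree is ultrametric (a chronogram)
#'
#' @param tree an [ape::phylo] object.
#' @param tol relative tolerance on tip-to-root path lengths.
#' @return logical.
#' @export
is_chronogram <- function(tree, tol = 1e-6) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  diff(range(d)) <= tol * max(d)
}

#' Prune taxa from a rooted tree
#'
#' Drops the given leaves; unbranched internal nodes are suppressed with
#' their incident branch lengths summed, so the path-length matrix among
#' survivors is unchanged.
#'
#' @param tree an [ape::phylo] object.
#' @param drop character vector of leaf labels to remove.
#' @return the pruned tree.
#' @export
prune_taxa <- function(tree, drop) {
  drop <- unique(drop)
  if (!length(drop)) return(tree)
  bad <- setdiff(drop, tree$tip.label)
  if (length(bad)) stop("taxa not in tree: ", paste(bad, collapse = ", "))
  if (length(tree$tip.label) - length(drop) < 2L)
    stop("fewer than 2 leaves would remain after pruning")
  ape::drop.tip(tree, drop)
}

#' Enumerate internodes of a rooted tree
#'
#' One entry per internal node (root included) with at least two
#' descendant leaves; the internode id is the sorted descendant leaf set
#' joined with `|`.
#'
#' @param tree an [ape::phylo] object.
#' @return list of character vectors of leaf labels, named by internode id.
#' @export
enumerate_internodes <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  sets <- lapply(pp, function(i) sort(labs[i]))
  sets <- Filter(function(s) length(s) >= 2L, sets)
  names(sets) <- vapply(sets, paste, "", collapse = "|")
  sets
}

# MRCA node of a leaf set; the set is a clade iff the MRCA's descendant
# tips equal it exactly
.clade_node <- function(tree, leafset) {
  idx <- match(leafset, tree$tip.label)
  if (anyNA(idx)) stop("leaves not in tree: ",
                       paste(leafset[is.na(idx)], collapse = ", "))
  if (length(idx) == length(tree$tip.label))
    return(length(tree$tip.label) + 1L)  # root
  m <- ape::getMRCA(tree, idx)
  m
}

.tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  pp <- ape::prop.part(tree)
  sort(attr(pp, "labels")[pp[[node - ntip]]])
}

#' Sum of tip-to-root path lengths within a clade
#'
#' The root of the subphylogram is the clade's most recent common
#' ancestor; its stem branch is not included (paths start at the
#' internode).
#'
#' @param tree an [ape::phylo] object with branch lengths.
#' @param leafset character vector of leaf labels forming a clade of `tree`.
#' @return total path length (same units as the branch lengths).
#' @export
tip_to_root_sum <- function(tree, leafset) {
  leafset <- sort(leafset)
  node <- .clade_node(tree, leafset)
  if (!identical(.tips_under(tree, node), leafset))
    stop("leaf set is not a clade of the tree: ",
         paste(leafset, collapse = ","))
  depth <- ape::node.depth.edgelength(tree)
  tips <- match(leafset, tree$tip.label)
  sum(depth[tips] - depth[node])
}

#' Is a leaf set monophyletic in a reference tree?
#'
#' TRUE iff the set equals the descendant leaf set of some node of the
#' reference (the reference should already be restricted to the relevant
#' taxon set).
#'
#' @param leafset character vector of leaf labels.
#' @param reference an [ape::phylo] object containing all of `leafset`.
#' @return logical.
#' @export
monophyly_consistent <- function(leafset, reference) {
  leafset <- sort(leafset)
  bad <- setdiff(leafset, reference$tip.label)
  if (length(bad)) stop("leaves not in reference: ", paste(bad, collapse = ", "))
  if (length(leafset) == length(reference$tip.label)) return(TRUE)
  if (length(leafset) < 2L) return(TRUE)
  node <- ape::getMRCA(reference, leafset)
  identical(.tips_under(reference, node), leafset)
}

#' Per-internode relative and absolute substitution rates for one gene
#'
#' Implements the internode tip-to-root normalisation: optionally drop
#' pseudogene-like tips (frameshift count > 0) and any further taxa, then
#' enumerate every internode of the gene phylogram; for internodes whose
#' descendant set is monophyletic in both the reference phylogram and
#' chronogram (each restricted to the gene's taxon set), the relative rate
#' is the gene subtree's tip-to-root sum divided by the reference
#' phylogram's, and the absolute rate the same sum divided by the
#' chronogram's (substitutions/site/Myr). Excluded internodes are emitted
#' with a reason, never dropped silently.
#'
#' @param gene_tree gene phylogram ([ape::phylo], substitutions/site).
#' @param ref_phylogram reference plastome phylogram.
#' @param ref_chronogram reference ultrametric chronogram (Myr); must share
#'   the phylogram's topology.
#' @param flags optional named integer vector: taxon -> frameshift count.
#' @param exclude_pseudogenes drop taxa with `flags > 0` before estimating.
#' @param drop further taxa to prune (e.g. outgroups); taxa absent from the
#'   gene tree are ignored.
#' @param gene_id label used in the output.
#' @return data.frame with columns `gene_id`, `internode_id`, `n_tips`,
#'   `rel_rate`, `abs_rate`, `included`, `reason`.
#' @export
gene_rates <- function(gene_tree, ref_phylogram, ref_chronogram,
                       flags = NULL, exclude_pseudogenes = FALSE,
                       drop = character(0), gene_id = "gene") {
  gene_tree$tip.label <- .norm_labels(gene_tree$tip.label)
  ref_phylogram$tip.label <- .norm_labels(ref_phylogram$tip.label)
  ref_chronogram$tip.label <- .norm_labels(ref_chronogram$tip.label)
  drop <- .norm_labels(drop)
  if (!is.null(flags)) names(flags) <- .norm_labels(names(flags))
  if (!is_chronogram(ref_chronogram))
    stop("reference chronogram is not ultrametric")
  to_drop <- intersect(drop, gene_tree$tip.label)
  if (exclude_pseudogenes && !is.null(flags)) {
    bad_flags <- setdiff(names(flags), gene_tree$tip.label)
    if (length(bad_flags))
      stop("frameshift flags name taxa absent from the gene tree: ",
           paste(bad_flags, collapse = ", "))
    pseudo <- names(flags)[flags > 0]
    to_drop <- union(to_drop, pseudo)
  }
  if (length(gene_tree$tip.label) - length(to_drop) < 2L)
    stop("gene tree empty (fewer than 2 taxa) after exclusions")
  if (length(to_drop)) gene_tree <- prune_taxa(gene_tree, to_drop)
  gtips <- gene_tree$tip.label
  unmatched <- setdiff(gtips, ref_phylogram$tip.label)
  if (length(unmatched))
    stop("gene-tree taxa absent from reference: ",
         paste(unmatched, collapse = ", "))
  ref_p <- if (length(gtips) < length(ref_phylogram$tip.label))
    ape::keep.tip(ref_phylogram, gtips) else ref_phylogram
  ref_c <- if (length(gtips) < length(ref_chronogram$tip.label))
    ape::keep.tip(ref_chronogram, gtips) else ref_chronogram
  internodes <- enumerate_internodes(gene_tree)
  n <- length(internodes)
  out <- data.frame(gene_id = rep(gene_id, n),
                    internode_id = names(internodes),
                    n_tips = vapply(internodes, length, 0L),
                    rel_rate = NA_real_, abs_rate = NA_real_,
                    included = FALSE, reason = "",
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  for (i in seq_len(n)) {
    ls <- internodes[[i]]
    if (!monophyly_consistent(ls, ref_p) || !monophyly_consistent(ls, ref_c)) {
      out$reason[i] <- "not_monophyletic_in_reference"
      next
    }
    num <- tip_to_root_sum(gene_tree, ls)
    den_p <- tip_to_root_sum(ref_p, ls)
    den_c <- tip_to_root_sum(ref_c, ls)
    if (den_p <= 0 || den_c <= 0) {
      out$reason[i] <- "zero_reference_sum"
      next
    }
    out$rel_rate[i] <- num / den_p
    out$abs_rate[i] <- num / den_c
    out$included[i] <- TRUE
  }
  out
}

#' Boxplot-style summaries of included internode rates per gene
#'
#' Five-number summary (type-7 quartiles) with Tukey whiskers: whiskers
#' reach the most extreme values within 1.5 x IQR of the box; points
#' beyond are listed as outliers.
#'
#' @param estimates data.frame from [gene_rates()] (rows for several genes
#'   may be concatenated).
#' @param value which rate column to summarise (`"rel_rate"` or
#'   `"abs_rate"`).
#' @return data.frame with one row per gene: `gene_id`, `n`, `median`,
#'   `q1`, `q3`, `whisker_low`, `whisker_high`, `outliers` (comma-joined),
#'   `empty`.
#' @export
summarize_rates <- function(estimates, value = c("rel_rate", "abs_rate")) {
  value <- match.arg(value)
  genes <- unique(estimates$gene_id)
  rows <- lapply(genes, function(g) {
    x <- estimates[[value]][estimates$gene_id == g & estimates$included]
    x <- x[!is.na(x)]
    if (!length(x))
      return(data.frame(gene_id = g, n = 0L, median = NA_real_,
                        q1 = NA_real_, q3 = NA_real_,
                        whisker_low = NA_real_, whisker_high = NA_real_,
                        outliers = "", empty = TRUE,
                        stringsAsFactors = FALSE))
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3L] - q[1L]
    # guard against floating-point jitter classifying ties as outliers
    eps <- 1e-8 * (abs(q[1L]) + abs(q[3L]) + 1)
    lo_fence <- q[1L] - 1.5 * iqr - eps; hi_fence <- q[3L] + 1.5 * iqr + eps
    inside <- x >= lo_fence & x <= hi_fence
    data.frame(gene_id = g, n = length(x), median = q[2L],
               q1 = q[1L], q3 = q[3L],
               whisker_low = min(x[inside]), whisker_high = max(x[inside]),
               outliers = paste(sort(x[!inside]), collapse = ","),
               empty = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
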