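# Relative synonymous codon usage (RSCU) and PCA ordination of RSCU
# profiles across gene classes.

# the 59 codons retained for RSCU: sense codons minus ATG (Met) and TGG
# (Trp), whose amino acids are encoded by a single codon
rscu_codons <- function() {
  setdiff(sense_codons(), c("ATG", "TGG"))
}

# synonymous families over the retained codons: list AA -> codons
.rscu_families <- function() {
  cods <- rscu_codons()
  split(cods, unname(.code()[cods]))
}

#' Count in-frame codons of a CDS
#'
#' Counts codons over the 64-codon table; codons containing N or gaps are
#' skipped, and a terminal stop codon is excluded (internal stops are
#' counted under their codon but never contribute to RSCU families).
#'
#' @param cds nucleotide string, length divisible by 3.
#' @return named integer vector of length 64.
#' @export
count_codons <- function(cds) {
  cods <- split_codons(cds)
  if (length(cods) && cods[length(cods)] %in% .STOPS)
    cods <- cods[-length(cods)]
  cods <- cods[.is_clean_codon(cods) | cods %in% .STOPS]
  cods <- cods[!is.na(.code()[cods])]
  out <- stats::setNames(integer(64L), names(.code()))
  if (!length(cods)) {
    warning("no countable codons in sequence")
    return(out)
  }
  tb <- table(cods)
  out[names(tb)] <- as.integer(tb)
  out
}

#' Relative synonymous codon usage from codon counts
#'
#' For codon j in a synonymous family i of size n_i with family total X_i,
#' RSCU_ij = x_ij / (X_i / n_i), so uniform usage gives 1 everywhere and
#' each observed family's values sum to the family size. Methionine and
#' tryptophan (single-codon families) and stop codons are excluded;
#' families with zero observations yield `NA` values.
#'
#' @param counts named codon count vector (as from [count_codons()]).
#' @return named numeric vector over the 59 retained codons.
#' @export
rscu <- function(counts) {
  fams <- .rscu_families()
  out <- stats::setNames(rep(NA_real_, length(rscu_codons())), rscu_codons())
  for (fam in fams) {
    x <- counts[fam]
    x[is.na(x)] <- 0
    tot <- sum(x)
    if (tot > 0) out[fam] <- x / (tot / length(fam))
  }
  out
}

#' Filter CDSs by minimum length
#'
#' Retains genes longer than `min_len` nucleotides (strictly, matching the
#' "longer than 500 bp" convention that guards RSCU against short-gene
#' stochasticity); set `strict_gt = FALSE` for an inclusive boundary.
#'
#' @param genes named character vector of CDS sequences.
#' @param min_len length threshold in nt.
#' @param strict_gt keep length > min_len (TRUE) or >= min_len (FALSE).
#' @return the retained subset (number removed reported via message).
#' @export
filter_genes <- function(genes, min_len = 500L, strict_gt = TRUE) {
  len <- nchar(genes)
  keep <- if (strict_gt) len > min_len else len >= min_len
  removed <- sum(!keep)
  if (removed) message(removed, " gene(s) below length threshold removed")
  if (!any(keep)) warning("no genes pass the length filter")
  genes[keep]
}

#' RSCU profiles for a set of CDSs
#'
#' @param genes named character vector of CDS sequences (already
#'   length-filtered as desired).
#' @return matrix genes x 59 retained codons of RSCU values (NA for
#'   unobserved families).
#' @export
rscu_profiles <- function(genes) {
  m <- t(vapply(genes, function(g) rscu(count_codons(g)),
                numeric(length(rscu_codons()))))
  rownames(m) <- names(genes)
  m
}

#' PCA ordination of RSCU profiles
#'
#' Centered (unscaled) principal component analysis of the gene x codon
#' RSCU matrix via singular-value decomposition. Undefined RSCU entries
#' (unobserved families) are imputed as 1, the no-information expectation,
#' before the fit; imputed genes are flagged. A deterministic sign
#' convention is applied: within each component the loading of largest
#' magnitude is positive.
#'
#' @param profiles matrix genes x codons (as from [rscu_profiles()]).
#' @param n_components number of components to return.
#' @param scale. standardise columns to unit variance before the fit
#'   (default FALSE: RSCU is already dimensionless and family-normalised).
#' @return list of class `rscu_pca`: `scores` (genes x components),
#'   `loadings` (codons x components), `explained` (variance fractions),
#'   `imputed` (logical per gene).
#' @export
pca_rscu <- function(profiles, n_components = 2L, scale. = FALSE) {
  if (nrow(profiles) < 3L) stop("need at least 3 profiles")
  if (n_components > nrow(profiles))
    stop("fewer profiles than requested components")
  imputed <- apply(profiles, 1L, anyNA)
  profiles[is.na(profiles)] <- 1
  keep_col <- !scale. | apply(profiles, 2L, stats::sd) > 0
  p <- stats::prcomp(profiles[, keep_col, drop = FALSE],
                     center = TRUE, scale. = scale.)
  k <- min(n_components, ncol(p$rotation))
  scores <- p$x[, seq_len(k), drop = FALSE]
  loadings <- p$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    jm <- which.max(abs(loadings[, j]))
    if (loadings[jm, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  tot <- sum(p$sdev^2)
  expl <- if (tot > 0) p$sdev[seq_len(k)]^2 / tot else rep(0, k)
  structure(list(scores = scores, loadings = loadings,
                 explained = expl, imputed = imputed),
            class = "rscu_pca")
}

#' @export
print.rscu_pca <- function(x, ...) {
  cat("RSCU PCA:", nrow(x$scores), "genes,", ncol(x$scores), "components\n")
  cat("explained variance fractions:",
      paste(sprintf("%.3f", x$explained), collapse = ", "), "\n")
  invisible(x)
}
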