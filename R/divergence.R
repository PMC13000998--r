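# Sliding-window divergence over codon-aware alignments: pairwise
# nucleotide diversity (pi) by codon position, and windowed NG86 dN/dS
# with a codon-column bootstrap.

# validate a named character vector as a codon alignment
check_alignment <- function(aln, require_codon = TRUE) {
  if (is.null(names(aln)) || any(!nzchar(names(aln))))
    stop("alignment sequences must be named by taxon")
  if (anyDuplicated(names(aln))) stop("duplicate taxon names in alignment")
  L <- unique(nchar(aln))
  if (length(L) != 1L) stop("alignment rows differ in length")
  if (require_codon && L %% 3L != 0L)
    stop("alignment length ", L, " not divisible by 3")
  if (any(grepl("[^ACGTN-]", aln)))
    stop("alignment alphabet must be A/C/G/T/N/-")
  invisible(L)
}

# alignment -> character matrix (taxa x columns)
.aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln), ""))
  rownames(m) <- names(aln)
  m
}

#' Remove codon columns containing stop codons from an alignment
#'
#' Deletes every in-frame codon triplet in which any taxon carries a stop
#' codon (TAA/TAG/TGA over plain A/C/G/T), keeping the matrix rectangular
#' and in frame. The removed codon indices are attached as attribute
#' `removed_codons` (1-based codon numbers in the input frame).
#'
#' @param aln named character vector of aligned sequences (length divisible
#'   by 3, frame anchored at the first column).
#' @return the filtered alignment, with attribute `removed_codons`.
#' @export
remove_stop_codons <- function(aln) {
  L <- check_alignment(aln)
  n_cod <- L %/% 3L
  has_stop <- rep(FALSE, n_cod)
  for (s in aln) {
    cods <- split_codons(s)
    has_stop <- has_stop | (cods %in% .STOPS)
  }
  if (!any(has_stop)) {
    attr(aln, "removed_codons") <- integer(0)
    return(aln)
  }
  keep_cols <- rep(!has_stop, each = 3L)
  if (!any(keep_cols)) warning("all codons removed: every codon has a stop")
  m <- .aln_matrix(aln)[, keep_cols, drop = FALSE]
  out <- apply(m, 1L, paste, collapse = "")
  if (ncol(m) == 0L) out <- stats::setNames(rep("", length(aln)), names(aln))
  names(out) <- names(aln)
  attr(out, "removed_codons") <- which(has_stop)
  out
}

# window start columns (0-based) for length L
.window_starts <- function(L, window, step) {
  if (window > L) stop("window (", window, ") exceeds alignment length ", L)
  if (window %% 3L != 0L) stop("window must be divisible by 3")
  if (step %% 3L != 0L) stop("step must be divisible by 3")
  seq(0L, L - window, by = step)
}

#' Sliding-window nucleotide diversity by codon position
#'
#' For each window, the mean over all unordered taxon pairs of the
#' proportion of differing sites among pair-sites where both bases are
#' plain nucleotides, computed separately for codon positions 1, 2, 3
#' (frame anchored at alignment column 1). Pair-sites with a gap or N are
#' excluded from numerator and denominator; pairs with zero comparable
#' sites in a window are excluded from the mean and flagged.
#'
#' @param aln named character vector of aligned sequences.
#' @param window window width in nucleotides (multiple of 3).
#' @param step step in nucleotides (multiple of 3, keeps codon framing).
#' @return data.frame with one row per window: `start_1based`, `end_1based`,
#'   `pi1`, `pi2`, `pi3`, `flags`.
#' @export
window_pi <- function(aln, window = 90L, step = 3L) {
  L <- check_alignment(aln)
  starts <- .window_starts(L, window, step)
  m <- .aln_matrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 taxa")
  pairs <- utils::combn(n, 2L)
  np <- ncol(pairs)
  clean <- m %in% c("A", "C", "G", "T")
  dim(clean) <- dim(m)
  # per pair x column: comparable site, differing site
  comp <- clean[pairs[1L, ], , drop = FALSE] & clean[pairs[2L, ], , drop = FALSE]
  diffm <- (m[pairs[1L, ], , drop = FALSE] != m[pairs[2L, ], , drop = FALSE]) & comp
  # cumulative sums per codon-position class, prepended with 0
  cum <- function(x) cbind(0, t(apply(x, 1L, cumsum)))
  res <- matrix(NA_real_, length(starts), 3L)
  flags <- rep("ok", length(starts))
  ccomp <- cum(comp); cdiff <- cum(diffm)
  pos_class <- ((seq_len(L) - 1L) %% 3L) + 1L
  for (k in 1:3) {
    cols_k <- which(pos_class == k)
    comp_k <- comp[, cols_k, drop = FALSE]
    diff_k <- diffm[, cols_k, drop = FALSE]
    ck <- cum(comp_k); dk <- cum(diff_k)
    # map window [s, s+window) to indices within cols_k (cols_k is the
    # arithmetic sequence k, k+3, ...)
    for (w in seq_along(starts)) {
      s <- starts[w]
      i0 <- s %/% 3L            # first codon in window (0-based)
      nw <- window %/% 3L       # codons per window
      csum <- ck[, i0 + nw + 1L] - ck[, i0 + 1L]
      dsum <- dk[, i0 + nw + 1L] - dk[, i0 + 1L]
      ok <- csum > 0
      if (!all(ok)) flags[w] <- "pair_no_sites"
      res[w, k] <- if (any(ok)) mean(dsum[ok] / csum[ok]) else NA_real_
    }
  }
  data.frame(start_1based = starts + 1L, end_1based = starts + window,
             pi1 = res[, 1L], pi2 = res[, 2L], pi3 = res[, 3L],
             flags = flags, stringsAsFactors = FALSE)
}

# Precompute per-pair, per-codon-column NG86 quantities for an alignment.
# Returns list of npair x ncodon matrices S, N, Sd, Nd and logical comp.
.ng86_column_arrays <- function(aln) {
  L <- check_alignment(aln)
  tab <- ng86_tables()
  n <- length(aln)
  if (n < 2L) stop("need at least 2 taxa")
  n_cod <- L %/% 3L
  idx <- matrix(NA_integer_, n, n_cod)
  for (i in seq_len(n)) idx[i, ] <- .codon_index(split_codons(aln[[i]]), tab)
  pairs <- utils::combn(n, 2L)
  np <- ncol(pairs)
  ia <- idx[pairs[1L, ], , drop = FALSE]
  ib <- idx[pairs[2L, ], , drop = FALSE]
  comp <- !is.na(ia) & !is.na(ib)
  Sm <- matrix(0, np, n_cod); Nm <- matrix(0, np, n_cod)
  Sm[comp] <- (tab$S[ia[comp]] + tab$S[ib[comp]]) / 2
  Nm[comp] <- (tab$N[ia[comp]] + tab$N[ib[comp]]) / 2
  Sdm <- matrix(0, np, n_cod); Ndm <- matrix(0, np, n_cod)
  lin <- cbind(ia[comp], ib[comp])
  Sdm[comp] <- tab$Sd[lin]; Ndm[comp] <- tab$Nd[lin]
  list(S = Sm, N = Nm, Sd = Sdm, Nd = Ndm, comp = comp,
       n_pairs = np, n_codons = n_cod)
}

# window means from per-pair sums, excluding degenerate pairs
.dnds_from_sums <- function(S, N, Sd, Nd, ncomp) {
  ok <- ncomp > 0 & S > 0 & N > 0
  pS <- Sd / S; pN <- Nd / N
  dom <- ok & pS < 0.75 & pN < 0.75
  dS <- mean(jc_correct(pS[dom]))
  dN <- mean(jc_correct(pN[dom]))
  n_deg <- sum(!dom)
  list(dN = if (any(dom)) dN else NA_real_,
       dS = if (any(dom)) dS else NA_real_,
       dnds = if (any(dom) && !is.na(dS) && dS > 0) dN / dS else NA_real_,
       n_deg = n_deg, n_ok = sum(dom))
}

#' Sliding-window dN/dS with bootstrap confidence intervals
#'
#' Per window, dN and dS are the means over all taxon pairs of the
#' JC-corrected NG86 nonsynonymous and synonymous divergences restricted to
#' the window's codons; `dnds_mean = mean(dN) / mean(dS)`. Pairs that are
#' degenerate in a window (no comparable codons, zero synonymous or
#' nonsynonymous sites, or a raw proportion >= 0.75) are excluded and the
#' window flagged. The 95% CI is a seeded nonparametric bootstrap over the
#' window's codon columns (percentile method); `n_boot = 0` disables it.
#'
#' @inheritParams window_pi
#' @param n_boot bootstrap replicates (codon columns resampled).
#' @param seed integer seed for the bootstrap.
#' @return data.frame with one row per window: `start_1based`,
#'   `end_1based`, `dN`, `dS`, `dnds_mean`, `ci_low`, `ci_high`, `flags`.
#' @export
window_dnds <- function(aln, window = 90L, step = 3L, n_boot = 1000L,
                        seed = 1L) {
  L <- check_alignment(aln)
  starts <- .window_starts(L, window, step)
  arr <- .ng86_column_arrays(aln)
  w_cod <- window %/% 3L
  cum <- function(x) cbind(0, t(apply(x, 1L, cumsum)))
  cS <- cum(arr$S); cN <- cum(arr$N); cSd <- cum(arr$Sd); cNd <- cum(arr$Nd)
  cC <- cum(arr$comp)
  nw <- length(starts)
  out <- data.frame(start_1based = starts + 1L, end_1based = starts + window,
                    dN = NA_real_, dS = NA_real_, dnds_mean = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_, flags = "ok",
                    stringsAsFactors = FALSE)
  if (n_boot > 0) set.seed(as.integer(seed))
  for (w in seq_len(nw)) {
    i0 <- starts[w] %/% 3L
    hi <- i0 + w_cod + 1L; lo <- i0 + 1L
    S <- cS[, hi] - cS[, lo]; N <- cN[, hi] - cN[, lo]
    Sd <- cSd[, hi] - cSd[, lo]; Nd <- cNd[, hi] - cNd[, lo]
    ncomp <- cC[, hi] - cC[, lo]
    st <- .dnds_from_sums(S, N, Sd, Nd, ncomp)
    out$dN[w] <- st$dN; out$dS[w] <- st$dS; out$dnds_mean[w] <- st$dnds
    fl <- character(0)
    if (st$n_ok == 0L) fl <- c(fl, "no_pairs")
    else if (st$n_deg > 0L) fl <- c(fl, "degenerate_pairs")
    if (!is.na(st$dS) && st$dS == 0) fl <- c(fl, "ds_zero")
    if (length(fl)) out$flags[w] <- paste(fl, collapse = ",")
    if (n_boot > 0 && st$n_ok > 0L) {
      cols <- (i0 + 1L):(i0 + w_cod)
      Ssl <- arr$S[, cols, drop = FALSE]; Nsl <- arr$N[, cols, drop = FALSE]
      Sdsl <- arr$Sd[, cols, drop = FALSE]; Ndsl <- arr$Nd[, cols, drop = FALSE]
      Csl <- arr$comp[, cols, drop = FALSE] + 0
      B <- matrix(0L, w_cod, n_boot)
      draws <- sample.int(w_cod, w_cod * n_boot, replace = TRUE)
      for (b in seq_len(n_boot))
        B[, b] <- tabulate(draws[((b - 1L) * w_cod + 1L):(b * w_cod)], w_cod)
      Sb <- Ssl %*% B; Nb <- Nsl %*% B
      Sdb <- Sdsl %*% B; Ndb <- Ndsl %*% B
      Cb <- Csl %*% B
      pSb <- Sdb / Sb; pNb <- Ndb / Nb
      dom <- Cb > 0 & Sb > 0 & Nb > 0 & pSb < 0.75 & pNb < 0.75
      dSb <- -0.75 * log(pmax(1 - 4 * pSb / 3, .Machine$double.eps))
      dNb <- -0.75 * log(pmax(1 - 4 * pNb / 3, .Machine$double.eps))
      dSb[!dom] <- NA; dNb[!dom] <- NA
      dS_b <- colMeans(dSb, na.rm = TRUE); dN_b <- colMeans(dNb, na.rm = TRUE)
      ratio <- ifelse(is.finite(dS_b) & dS_b > 0 & is.finite(dN_b),
                      dN_b / dS_b, NA_real_)
      if (any(!is.na(ratio))) {
        q <- stats::quantile(ratio, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
        out$ci_low[w] <- q[1L]; out$ci_high[w] <- q[2L]
      }
    }
  }
  out
}

#' Combined sliding-window scan (pi by codon position and dN/dS)
#'
#' Convenience wrapper merging [window_pi()] and [window_dnds()] on the
#' same window grid, as plotted for mobile-ORF alignments.
#'
#' @inheritParams window_dnds
#' @return merged data.frame of both window tables.
#' @export
sliding_window <- function(aln, window = 90L, step = 3L, n_boot = 1000L,
                           seed = 1L) {
  p <- window_pi(aln, window, step)
  d <- window_dnds(aln, window, step, n_boot, seed)
  cbind(p[, c("start_1based", "end_1based", "pi1", "pi2", "pi3")],
        d[, c("dN", "dS", "dnds_mean", "ci_low", "ci_high", "flags")])
}
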