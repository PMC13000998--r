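# Nei-Gojobori (1986) counting machinery.
#
# Site and difference counts are precomputed once per session as lookup
# tables over the 61 sense codons, which makes the sliding-window and
# bootstrap layers pure table arithmetic.

.ng86_env <- new.env(parent = emptyenv())

# Per-codon synonymous / nonsynonymous site fractions. Each of the 9
# single-nucleotide neighbours is synonymous, nonsynonymous, or a stop;
# stop-creating changes are excluded from both site counts, so
# S + N = 3 - (#stop neighbours)/3 for each codon.
.build_site_counts <- function() {
  cods <- sense_codons()
  code <- .code()
  S <- N <- numeric(length(cods))
  bases <- c("A", "C", "G", "T")
  for (k in seq_along(cods)) {
    cod <- cods[k]
    aa <- code[[cod]]
    ch <- strsplit(cod, "")[[1]]
    for (pos in 1:3) for (b in bases) {
      if (b == ch[pos]) next
      alt <- ch; alt[pos] <- b
      alt <- paste(alt, collapse = "")
      aa2 <- code[[alt]]
      if (aa2 == "*") next
      if (aa2 == aa) S[k] <- S[k] + 1 / 3 else N[k] <- N[k] + 1 / 3
    }
  }
  list(codons = cods, S = S, N = N)
}

# Sd/Nd for one ordered codon pair: average over all orderings of the
# minimal mutation paths, excluding paths through stop codons. If every
# path crosses a stop, fall back to all paths (flagged via attr).
.pair_path_counts <- function(c1, c2) {
  code <- .code()
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  diff_pos <- which(a != b)
  nd <- length(diff_pos)
  if (nd == 0L) return(c(0, 0, 0))
  perms <- if (nd == 1L) list(diff_pos) else
    if (nd == 2L) list(diff_pos, rev(diff_pos)) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
             function(o) diff_pos[o])
  walk <- function(order, exclude_stops) {
    cur <- a; sd <- 0; nd_ <- 0
    for (pos in order) {
      nxt <- cur; nxt[pos] <- b[pos]
      cc <- paste(cur, collapse = ""); cn <- paste(nxt, collapse = "")
      if (exclude_stops && code[[cn]] == "*" && cn != c2) return(NULL)
      if (code[[cc]] == "*" || code[[cn]] == "*") {
        # step touching a stop endpoint contributes to neither count
      } else if (code[[cc]] == code[[cn]]) sd <- sd + 1 else nd_ <- nd_ + 1
      cur <- nxt
    }
    c(sd, nd_)
  }
  ok <- Filter(Negate(is.null), lapply(perms, walk, exclude_stops = TRUE))
  blocked <- length(ok) == 0L
  if (blocked) ok <- lapply(perms, walk, exclude_stops = FALSE)
  m <- do.call(rbind, ok)
  c(mean(m[, 1L]), mean(m[, 2L]), as.numeric(blocked))
}

# Lazily build and cache all lookup tables.
ng86_tables <- function() {
  if (!is.null(.ng86_env$tab)) return(.ng86_env$tab)
  sc <- .build_site_counts()
  n <- length(sc$codons)
  Sd <- Nd <- matrix(0, n, n, dimnames = list(sc$codons, sc$codons))
  blocked <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    v <- .pair_path_counts(sc$codons[i], sc$codons[j])
    Sd[i, j] <- v[1L]; Nd[i, j] <- v[2L]; blocked[i, j] <- v[3L] > 0
  }
  .ng86_env$tab <- list(codons = sc$codons, S = sc$S, N = sc$N,
                        Sd = Sd, Nd = Nd, blocked = blocked)
  .ng86_env$tab
}

# Jukes-Cantor multiple-hit correction; NA outside its domain.
jc_correct <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  out
}

# Map codon strings to indices into the sense-codon table (NA for codons
# containing gaps/N); in-frame stops are an error.
.codon_index <- function(codons, tab) {
  idx <- match(codons, tab$codons)
  stop_hit <- codons %in% .STOPS
  if (any(stop_hit))
    stop("in-frame stop codon at codon ", which(stop_hit)[1L],
         "; run remove_stop_codons() first")
  idx
}

#' Pairwise Nei-Gojobori synonymous/nonsynonymous counts
#'
#' Counts synonymous and nonsynonymous sites and differences between two
#' aligned coding sequences using the NG86 counting method: per-codon site
#' fractions (changes to stop codons excluded from both counts), multi-hit
#' codons averaged over minimal mutation paths excluding stop intermediates,
#' and Jukes-Cantor correction of the raw proportions. Codons containing
#' gaps or N in either sequence are excluded pairwise.
#'
#' @param a,b nucleotide strings of equal length divisible by 3, stop-free.
#' @return an object of class `ng86`: list with `S`, `N` (fractional site
#'   counts), `Sd`, `Nd` (differences), `pS`, `pN`, `dS`, `dN` (JC-corrected;
#'   raw proportion reported when p >= 0.75), `dnds`, `n_codons` (compared),
#'   and `flag` (`"ok"`, `"no_synonymous_sites"`, `"out_of_domain"`,
#'   `"no_sites"`, `"stop_path"`; comma-joined when several apply).
#' @export
ng86_pair <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("ng86_pair: sequences differ in length")
  tab <- ng86_tables()
  ca <- split_codons(a); cb <- split_codons(b)
  ia <- .codon_index(ca, tab); ib <- .codon_index(cb, tab)
  keep <- !is.na(ia) & !is.na(ib)
  ia <- ia[keep]; ib <- ib[keep]
  flags <- character(0)
  if (!length(ia)) {
    res <- list(S = 0, N = 0, Sd = 0, Nd = 0, pS = NA_real_, pN = NA_real_,
                dS = NA_real_, dN = NA_real_, dnds = NA_real_,
                n_codons = 0L, flag = "no_sites")
    class(res) <- "ng86"
    return(res)
  }
  S <- sum((tab$S[ia] + tab$S[ib]) / 2)
  N <- sum((tab$N[ia] + tab$N[ib]) / 2)
  Sd <- sum(tab$Sd[cbind(ia, ib)])
  Nd <- sum(tab$Nd[cbind(ia, ib)])
  if (any(tab$blocked[cbind(ia, ib)])) flags <- c(flags, "stop_path")
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  if (S <= 0) flags <- c(flags, "no_synonymous_sites")
  dS <- jc_correct(pS); dN <- jc_correct(pN)
  if ((!is.na(pS) && pS >= 0.75) || (!is.na(pN) && pN >= 0.75)) {
    flags <- c(flags, "out_of_domain")
    if (!is.na(pS) && pS >= 0.75) dS <- pS
    if (!is.na(pN) && pN >= 0.75) dN <- pN
  }
  dnds <- if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_
  res <- list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
              dS = dS, dN = dN, dnds = dnds, n_codons = length(ia),
              flag = if (length(flags)) paste(flags, collapse = ",") else "ok")
  class(res) <- "ng86"
  res
}

#' @export
print.ng86 <- function(x, ...) {
  cat("NG86 pairwise counts (", x$n_codons, " codons)\n", sep = "")
  cat(sprintf("  S = %.4f  N = %.4f  Sd = %.4f  Nd = %.4f\n",
              x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  dS = %s  dN = %s  dN/dS = %s  [%s]\n",
              format(x$dS), format(x$dN), format(x$dnds), x$flag))
  invisible(x)
}
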