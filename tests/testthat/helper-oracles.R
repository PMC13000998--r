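# Independent oracles and small fixture builders used across test files.

# translation oracle independent of the package's lookup path
oracle_translate <- function(codon) {
  as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                     no.init.codon = TRUE))
}

# Brute-force NG86 site counts for one codon: enumerate all 9 single-base
# neighbours, classify against the standard code, exclude stop-creating
# changes from both counts.
oracle_site_counts <- function(codon) {
  aa <- oracle_translate(codon)
  ch <- strsplit(codon, "")[[1]]
  S <- N <- 0
  for (pos in 1:3) for (b in c("A", "C", "G", "T")) {
    if (b == ch[pos]) next
    alt <- ch; alt[pos] <- b
    aa2 <- oracle_translate(paste(alt, collapse = ""))
    if (aa2 == "*") next
    if (aa2 == aa) S <- S + 1 / 3 else N <- N + 1 / 3
  }
  c(S = S, N = N)
}

# Recursive path-enumeration oracle for Sd/Nd between two codons:
# depth-first over which differing position to change next, dropping
# branches that pass through a stop codon; average over surviving paths.
oracle_pair_diffs <- function(c1, c2) {
  paths <- list()
  recurse <- function(cur, sd, nd) {
    dif <- which(strsplit(cur, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(dif)) {
      paths[[length(paths) + 1L]] <<- c(sd, nd)
      return(invisible())
    }
    for (pos in dif) {
      nxt <- strsplit(cur, "")[[1]]
      nxt[pos] <- strsplit(c2, "")[[1]][pos]
      nxt <- paste(nxt, collapse = "")
      if (oracle_translate(nxt) == "*" && nxt != c2) next
      syn <- oracle_translate(cur) == oracle_translate(nxt)
      recurse(nxt, sd + as.integer(syn), nd + as.integer(!syn))
    }
  }
  recurse(c1, 0L, 0L)
  if (!length(paths)) return(NULL)  # all paths blocked by stops
  m <- do.call(rbind, paths)
  c(Sd = mean(m[, 1L]), Nd = mean(m[, 2L]))
}

# random stop-free codon string of n codons
random_codons <- function(n) {
  cods <- setdiff(names(Biostrings::GENETIC_CODE),
                  c("TAA", "TAG", "TGA"))
  paste(sample(cods, n, replace = TRUE), collapse = "")
}

# balanced 4-taxon trees used by the rates tests
balanced_chronogram <- function() {
  ape::read.tree(text = "((A:10,B:10):5,(C:10,D:10):5);")
}
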