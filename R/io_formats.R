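#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are upper-cased and U (RNA) is transliterated to T. Record
#' order is preserved. Duplicate ids are an error.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (names = record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: ", dup[1L])
  seqs <- chartr("u", "T", chartr("U", "T", toupper(as.character(set))))
  if (any(nchar(seqs) == 0L)) stop("empty sequence in FASTA: ",
                                   ids[which(nchar(seqs) == 0L)[1L]])
  names(seqs) <- ids
  seqs
}

#' Write named sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(unname(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a rooted Newick tree with branch lengths
#'
#' All non-root edges must carry branch lengths; a missing length is an
#' error naming a tip below the offending edge.
#'
#' @param path path to a Newick file (single tree).
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in ", path,
                                          ": ", conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree in ", path)
    tr <- tr[[1L]]
  }
  if (is.null(tr$edge.length) || anyNA(tr$edge.length) ||
      length(tr$edge.length) != nrow(tr$edge)) {
    bad <- if (is.null(tr$edge.length)) seq_len(nrow(tr$edge)) else
      which(is.na(tr$edge.length))
    lab <- .edge_label(tr, bad[1L])
    stop("missing branch length on edge above ", lab)
  }
  tr
}

# human-readable label for an edge: a descendant tip of its child node
.edge_label <- function(tr, edge_idx) {
  child <- tr$edge[edge_idx, 2L]
  if (child <= length(tr$tip.label)) return(tr$tip.label[child])
  tips <- ape::extract.clade(tr, child)$tip.label
  paste0("clade(", paste(tips, collapse = ","), ")")
}

#' Write a tree to Newick text
#'
#' Round-trips through [read_newick()] preserve topology and branch
#' lengths to 1e-9.
#'
#' @param tree an [ape::phylo] object.
#' @param path optional output path; if `NULL` the Newick string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read a per-site base-count pileup table
#'
#' Expects a TSV with header columns `gene_id`, `pos`, `ref_base`, `total`,
#' `count_A`, `count_C`, `count_G`, `count_T` (the shape emitted by
#' read-count utilities run on CDS-mapped RNA reads).
#'
#' @param path path to the TSV file.
#' @return a `data.frame` with the typed, validated columns.
#' @export
read_pileup <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_pileup(df)
}

#' Validate a pileup data frame
#'
#' @param df data frame with pileup columns (see [read_pileup()]).
#' @return the validated data frame (invariant checks applied).
#' @export
validate_pileup <- function(df) {
  need <- c("gene_id", "pos", "ref_base", "total",
            "count_A", "count_C", "count_G", "count_T")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pileup missing columns: ", paste(miss, collapse = ", "))
  df$ref_base <- toupper(df$ref_base)
  if (!all(df$ref_base %in% c("A", "C", "G", "T")))
    stop("pileup row ", which(!df$ref_base %in% c("A", "C", "G", "T"))[1L],
         ": ref_base must be one of A/C/G/T")
  num <- c("pos", "total", "count_A", "count_C", "count_G", "count_T")
  for (cl in num) df[[cl]] <- as.integer(df[[cl]])
  neg <- which(df$total < 0L | df$count_A < 0L | df$count_C < 0L |
                 df$count_G < 0L | df$count_T < 0L)
  if (length(neg)) stop("pileup row ", neg[1L], ": negative count")
  s <- df$count_A + df$count_C + df$count_G + df$count_T
  bad <- which(s > df$total)
  if (length(bad)) stop("pileup row ", bad[1L], ": base counts (", s[bad[1L]],
                        ") exceed total (", df$total[bad[1L]], ")")
  key <- paste(df$gene_id, df$pos)
  if (anyDuplicated(key)) stop("duplicate (gene_id, pos) in pileup: ",
                               key[which(duplicated(key))[1L]])
  df
}

#' Write a pileup table to TSV
#' @param df pileup data frame.
#' @param path output path.
#' @export
write_pileup <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Scan a sequence for open reading frames on both strands
#'
#' Scans the three forward frames and the three frames of the reverse
#' complement for ATG...stop ORFs (standard code stops TAA/TAG/TGA) with no
#' internal stop. Only the longest ORF per stop per frame is reported (the
#' first in-frame ATG after the previous stop). A codon containing N neither
#' starts nor terminates an ORF, but ORFs may span it. Lengths count
#' nucleotides including the stop codon; the 500 bp default matches common
#' ORF-finder usage for nominating mobile-ORF candidates.
#'
#' @param seq nucleotide string over A/C/G/T/N.
#' @param min_len minimum ORF length in nucleotides, stop codon included.
#' @param contig_id label used in the output.
#' @return data.frame with columns `contig_id`, `start` (0-based inclusive),
#'   `end` (0-based exclusive, forward coordinates), `strand`, `length_nt`,
#'   `frame`; sorted by (start, strand).
#' @export
find_orfs <- function(seq, min_len = 500L, contig_id = "seq") {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("find_orfs: sequence must be over A/C/G/T/N")
  L <- nchar(seq)
  fwd <- .scan_orfs_one_strand(seq, min_len)
  rev <- .scan_orfs_one_strand(reverse_complement(seq), min_len)
  if (nrow(rev)) {
    # map [s, e) on the reverse complement to forward coordinates
    s <- L - rev$end
    rev$end <- L - rev$start
    rev$start <- s
    rev$strand <- "-"
  }
  out <- rbind(fwd, rev)
  if (nrow(out)) {
    out$contig_id <- contig_id
    out <- out[order(out$start, out$strand), , drop = FALSE]
    rownames(out) <- NULL
  }
  out[, c("contig_id", "start", "end", "strand", "length_nt", "frame")]
}

# scan the 3 frames of one strand; coordinates 0-based half-open on that strand
.scan_orfs_one_strand <- function(seq, min_len) {
  L <- nchar(seq)
  res <- list()
  for (frame in 0:2) {
    n_cod <- (L - frame) %/% 3L
    if (n_cod < 2L) next
    cods <- substring(seq, frame + seq(1L, by = 3L, length.out = n_cod),
                      frame + seq(3L, by = 3L, length.out = n_cod))
    has_n <- grepl("N", cods, fixed = TRUE)
    is_start <- cods == "ATG" & !has_n
    is_stop <- cods %in% .STOPS & !has_n
    open_at <- NA_integer_  # codon index of first ATG since last stop
    for (i in seq_len(n_cod)) {
      if (is_stop[i]) {
        if (!is.na(open_at)) {
          len <- (i - open_at + 1L) * 3L
          if (len >= min_len) {
            res[[length(res) + 1L]] <- data.frame(
              contig_id = "", start = frame + (open_at - 1L) * 3L,
              end = frame + i * 3L, strand = "+", length_nt = len,
              frame = frame, stringsAsFactors = FALSE)
          }
        }
        open_at <- NA_integer_
      } else if (is.na(open_at) && is_start[i]) {
        open_at <- i
      }
    }
  }
  if (!length(res))
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      length_nt = integer(0), frame = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, res)
}
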