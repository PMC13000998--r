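# RNA-editing site classification from base-count pileups.
#
# A site passes when >= min_coverage RNA reads map to it and the candidate
# edited base is supported by >= min_edit_reads reads making up >=
# min_edit_fraction of the mapped reads (all thresholds inclusive).

#' Editing-caller thresholds
#'
#' Defaults follow the standard plastid editing-detection rule: at least
#' 10 mapped reads, and at least 3 reads and 10% of them showing the
#' edited base.
#'
#' @param min_coverage minimum mapped reads at the site.
#' @param min_edit_reads minimum reads showing the edited base.
#' @param min_edit_fraction minimum fraction of mapped reads edited.
#' @return list of class `editing_config`.
#' @export
editing_config <- function(min_coverage = 10L, min_edit_reads = 3L,
                           min_edit_fraction = 0.10) {
  stopifnot(min_coverage >= 0, min_edit_reads >= 0,
            min_edit_fraction >= 0, min_edit_fraction <= 1)
  structure(list(min_coverage = as.integer(min_coverage),
                 min_edit_reads = as.integer(min_edit_reads),
                 min_edit_fraction = min_edit_fraction),
            class = "editing_config")
}

#' Classify candidate RNA-editing sites in a pileup
#'
#' For each site the candidate edit base is the non-reference base with
#' the highest read count; when two or more non-reference bases tie for
#' the maximum, each is emitted as a separate candidate row (none is
#' auto-passed). Editing efficiency (`edit_reads / coverage`) is reported
#' for every candidate, passed or not. `edit_type` is `C-to-U` for a C
#' reference read as T, `U-to-C` for a T reference read as C, otherwise
#' `other` (reported but normally excluded from summaries).
#'
#' @param pileup validated pileup data frame (see [read_pileup()]).
#' @param cfg thresholds from [editing_config()].
#' @return data.frame with one row per candidate: `gene_id`, `pos`,
#'   `ref_base`, `edit_base`, `edit_type`, `coverage`, `edit_reads`,
#'   `efficiency`, `passed`.
#' @export
classify_sites <- function(pileup, cfg = editing_config()) {
  pileup <- validate_pileup(pileup)
  bases <- c("A", "C", "G", "T")
  cnt <- as.matrix(pileup[, paste0("count_", bases)])
  colnames(cnt) <- bases
  rows <- list()
  for (i in seq_len(nrow(pileup))) {
    ref <- pileup$ref_base[i]
    alt <- cnt[i, setdiff(bases, ref)]
    mx <- max(alt)
    if (mx == 0L) next
    for (b in names(alt)[alt == mx]) {
      cov <- pileup$total[i]
      er <- unname(alt[b])
      type <- if (ref == "C" && b == "T") "C-to-U"
      else if (ref == "T" && b == "C") "U-to-C" else "other"
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = pileup$gene_id[i], pos = pileup$pos[i], ref_base = ref,
        edit_base = b, edit_type = type, coverage = cov, edit_reads = er,
        efficiency = er / cov,
        passed = cov >= cfg$min_coverage && er >= cfg$min_edit_reads &&
          er / cov >= cfg$min_edit_fraction,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(0), pos = integer(0),
                      ref_base = character(0), edit_base = character(0),
                      edit_type = character(0), coverage = integer(0),
                      edit_reads = integer(0), efficiency = numeric(0),
                      passed = logical(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$pos, out$edit_base), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate the coding effect of an editing site
#'
#' Given the CDS the site falls in and its 1-based offset within the CDS,
#' fills in the codon position and the induced amino-acid change under the
#' standard code. Offsets outside [1, nchar(cds)] (the +/-100 nt flanks)
#' are annotated `noncoding`.
#'
#' @param site one row from [classify_sites()] (data.frame or list).
#' @param cds CDS nucleotide string, length divisible by 3.
#' @param cds_offset 1-based position of the site within the CDS
#'   (non-positive or past the end = flanking/noncoding).
#' @return the site row with `codon_pos`, `ref_aa`, `edit_aa`, `silent`
#'   added.
#' @export
annotate_effect <- function(site, cds, cds_offset) {
  cds <- toupper(cds)
  L <- nchar(cds)
  if (L %% 3L != 0L) stop("CDS length not divisible by 3")
  site <- as.data.frame(site, stringsAsFactors = FALSE)
  if (cds_offset < 1L || cds_offset > L) {
    if (cds_offset < -100L - 3L || cds_offset > L + 103L)
      stop("cds_offset ", cds_offset, " out of range for CDS of length ", L)
    site$codon_pos <- "noncoding"
    site$ref_aa <- NA_character_; site$edit_aa <- NA_character_
    site$silent <- NA
    return(site)
  }
  if (substr(cds, cds_offset, cds_offset) != site$ref_base)
    stop("CDS base at offset ", cds_offset, " (",
         substr(cds, cds_offset, cds_offset),
         ") does not match site ref_base (", site$ref_base, ")")
  cp <- ((cds_offset - 1L) %% 3L) + 1L
  cod_start <- cds_offset - cp + 1L
  ref_codon <- substr(cds, cod_start, cod_start + 2L)
  edit_codon <- ref_codon
  substr(edit_codon, cp, cp) <- site$edit_base
  site$codon_pos <- as.character(cp)
  site$ref_aa <- unname(translate_codons(ref_codon))
  site$edit_aa <- unname(translate_codons(edit_codon))
  site$silent <- identical(site$ref_aa, site$edit_aa)
  site
}

#' Gene-level and genome-level editing summaries
#'
#' Counts genes with at least one passed canonical (C-to-U / U-to-C) site,
#' the fraction of surveyed genes edited, the number of passed sites, and
#' the overall site frequency (passed sites over total surveyed CDS
#' bases) -- the headline "fraction of genes edited / percent of sites"
#' form.
#'
#' @param sites data.frame from [classify_sites()].
#' @param gene_lengths named numeric vector: gene id -> surveyed CDS length
#'   (nt, > 0).
#' @param canonical_only count only C-to-U / U-to-C sites (default TRUE).
#' @return list with `genes_with_editing`, `n_genes`, `fraction_of_genes`,
#'   `sites_passed`, `total_bases`, `overall_site_frequency`.
#' @export
summarize_editing <- function(sites, gene_lengths, canonical_only = TRUE) {
  stopifnot(all(gene_lengths > 0))
  keep <- sites$passed
  if (canonical_only) keep <- keep & sites$edit_type %in% c("C-to-U", "U-to-C")
  hit <- unique(sites$gene_id[keep])
  n_genes <- length(gene_lengths)
  total <- sum(gene_lengths)
  list(genes_with_editing = length(intersect(hit, names(gene_lengths))),
       n_genes = n_genes,
       fraction_of_genes = if (n_genes) length(intersect(hit, names(gene_lengths))) / n_genes else 0,
       sites_passed = sum(keep),
       total_bases = total,
       overall_site_frequency = if (total > 0) sum(keep) / total else 0)
}
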