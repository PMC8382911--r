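#' Read a protein alignment from FASTA
#'
#' Sequence names are taken up to the first whitespace; the gap character is
#' `-`. Returns the package's working representation of an alignment: an
#' upper-case character matrix with one row per sequence and one column per
#' site, row names holding the (unique) sequence names.
#'
#' @param path FASTA file path.
#' @return Character matrix.
#' @export
read_fasta <- function(path) {
  x <- ape::read.FASTA(path, type = "AA")
  names(x) <- sub("\\s.*$", "", names(x))
  m <- toupper(as.character(as.matrix(x)))
  rownames(m) <- names(x)
  validate_alignment(m)
}

#' Write a character-matrix alignment to FASTA
#'
#' @param aln Character matrix (rows = sequences).
#' @param path Output path.
#' @export
write_fasta <- function(aln, path) {
  lines <- character(2L * nrow(aln))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(aln))
  lines[c(FALSE, TRUE)] <- apply(aln, 1, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a relaxed-PHYLIP alignment
#'
#' One header line (`n_seq n_col`) then `name sequence` records; names are
#' not truncated (relaxed format). Used for concatenated supermatrices.
#'
#' @inheritParams write_fasta
#' @export
write_phylip <- function(aln, path) {
  lines <- c(paste(nrow(aln), ncol(aln)),
             paste(rownames(aln), apply(aln, 1, paste, collapse = "")))
  writeLines(lines, path)
  invisible(path)
}

#' Validate an alignment matrix
#'
#' Checks rectangularity, unique non-empty row names, and membership of all
#' symbols in `alphabet` plus the missing-data symbols (`-`, `X`, `?`, `*`).
#'
#' @param aln Character matrix.
#' @param alphabet Allowed residue states (default the 20 amino acids).
#' @return The validated matrix, invisibly unchanged.
#' @export
validate_alignment <- function(aln, alphabet = AA_STATES) {
  if (!is.matrix(aln) || !is.character(aln))
    stop("alignment must be a character matrix")
  nm <- rownames(aln)
  if (is.null(nm) || any(!nzchar(nm))) stop("alignment rows must be named")
  if (anyDuplicated(nm)) stop("duplicate sequence names in alignment")
  bad <- setdiff(unique(as.vector(aln)), c(alphabet, MISSING_SYMBOLS))
  if (length(bad))
    stop("alignment contains symbols outside the alphabet: ",
         paste(bad, collapse = " "))
  aln
}

#' Drop gappy alignment columns
#'
#' Removes columns whose gap fraction is strictly greater than
#' `max_gap_fraction` (default 0.2, i.e. the ">20% of gaps" rule). Only `-`
#' counts as a gap.
#'
#' @param aln Character matrix alignment.
#' @param max_gap_fraction Threshold in `[0, 1]`.
#' @return The filtered alignment; attribute `kept` holds the surviving
#'   original column indices.
#' @export
filter_gappy_columns <- function(aln, max_gap_fraction = 0.2) {
  validate_alignment(aln)
  if (ncol(aln) == 0) stop("empty alignment")
  if (max_gap_fraction < 0 || max_gap_fraction > 1)
    stop("max_gap_fraction must lie in [0, 1]")
  gap_frac <- colMeans(aln == "-")
  keep <- which(gap_frac <= max_gap_fraction)
  out <- aln[, keep, drop = FALSE]
  attr(out, "kept") <- keep
  out
}

#' Remove the fastest-evolving columns
#'
#' Drops exactly `floor(fraction * L)` columns with the highest posterior
#' mean rate, emulating stepwise fast-site removal by 10% fractions. Ties
#' are broken by removing the lower column index first; surviving columns
#' keep their original order.
#'
#' @param aln Character matrix alignment.
#' @param rates A [site_posterior_rates()] result, or a numeric vector of
#'   per-column rates of length `ncol(aln)`.
#' @param fraction Fraction of columns to remove, in `[0, 1]`.
#' @return Filtered alignment with attributes `kept` and `removed`
#'   (original column indices).
#' @export
remove_fast_sites <- function(aln, rates, fraction) {
  validate_alignment(aln)
  r <- if (inherits(rates, "site_rates")) rates$mean_rate else as.numeric(rates)
  L <- ncol(aln)
  if (length(r) != L) stop("rates length must equal alignment length")
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]")
  k <- floor(fraction * L)
  ord <- order(-r, seq_len(L))          # highest rate first, lower index first on ties
  removed <- sort(ord[seq_len(k)])
  keep <- setdiff(seq_len(L), removed)
  out <- aln[, keep, drop = FALSE]
  attr(out, "kept") <- keep
  attr(out, "removed") <- removed
  out
}

#' Concatenate gene-family alignments into a supermatrix
#'
#' Each taxon's row is the concatenation of its rows across families, in the
#' given family order; a taxon absent from a family is padded with gaps over
#' that family's block.
#'
#' @param families List of character-matrix alignments.
#' @param taxon_set Character vector of taxa defining row order; every
#'   family's taxa must be a subset.
#' @return Concatenated alignment; attribute `blocks` is a data frame with
#'   the start/end column of each family block.
#' @export
concatenate_alignments <- function(families, taxon_set) {
  if (!length(families)) stop("no families to concatenate")
  if (anyDuplicated(taxon_set)) stop("duplicate taxa in taxon_set")
  for (f in families) {
    validate_alignment(f)
    if (anyDuplicated(rownames(f))) stop("duplicate taxon within one family")
    if (!all(rownames(f) %in% taxon_set))
      stop("family contains taxa outside taxon_set: ",
           paste(setdiff(rownames(f), taxon_set), collapse = " "))
  }
  lens <- vapply(families, ncol, integer(1))
  total <- sum(lens)
  out <- matrix("-", length(taxon_set), total,
                dimnames = list(taxon_set, NULL))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  for (i in seq_along(families)) {
    f <- families[[i]]
    out[rownames(f), starts[i]:ends[i]] <- f
  }
  attr(out, "blocks") <- data.frame(
    family = if (is.null(names(families))) seq_along(families) else names(families),
    start = starts, end = ends, length = lens, row.names = NULL)
  out
}

#' Write per-site rates to TSV
#'
#' @param rates A [site_posterior_rates()] result.
#' @param path Output path.
#' @export
write_site_rates <- function(rates, path) {
  stopifnot(inherits(rates, "site_rates"))
  df <- data.frame(column = seq_along(rates$mean_rate),
                   mean_rate = rates$mean_rate,
                   all_gap = rates$all_gap)
  w <- as.data.frame(rates$weights)
  names(w) <- paste0("w", seq_len(ncol(w)))
  utils::write.table(cbind(df, w), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
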