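# Alignment container: a character matrix, rows = sequences (rownames = ids),
# columns = alignment sites, residues uppercase, gaps "-".

GAP_CHARS <- c("-", ".", "?", "X", "*")

#' Coerce sequences to an alignment matrix
#'
#' @param x character matrix, or named character vector of equal-length
#'   sequence strings
#' @return character matrix with rownames
#' @export
as_alignment_matrix <- function(x) {
  if (is.matrix(x)) {
    m <- toupper(x)
  } else if (is.character(x)) {
    if (is.null(names(x))) stop("sequences must be named")
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) stop("sequences have unequal lengths")
    m <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
    rownames(m) <- names(x)
  } else {
    stop("cannot coerce to an alignment matrix")
  }
  if (is.null(rownames(m))) stop("alignment rows must be named")
  m
}

#' Collapse an alignment matrix to named sequence strings
#' @param aln alignment matrix
#' @export
alignment_strings <- function(aln) {
  aln <- as_alignment_matrix(aln)
  setNames(apply(aln, 1L, paste, collapse = ""), rownames(aln))
}

#' Read an amino-acid FASTA file as an alignment matrix
#' @param path FASTA file
#' @export
read_fasta_aln <- function(path) {
  x <- ape::read.FASTA(path, type = "AA")
  seqs <- vapply(as.character(x), function(s) paste(toupper(s), collapse = ""),
                 character(1L))
  as_alignment_matrix(seqs)
}

#' Write an alignment (or named sequences) to FASTA
#' @param aln alignment matrix or named character vector
#' @param path output file
#' @export
write_fasta_aln <- function(aln, path) {
  seqs <- alignment_strings(as_alignment_matrix(aln))
  bin <- ape::as.AAbin(strsplit(seqs, "", fixed = TRUE))
  names(bin) <- names(seqs)
  ape::write.FASTA(bin, path)
  invisible(path)
}
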