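## GeneAlignment container: a plain upper-case character matrix
## (rows = taxa, columns = sites) with a gene name attribute. Kept
## deliberately light so column statistics vectorize naturally; converters
## to ape's DNAbin and phangorn's phyDat are provided for tree inference.

#' Construct a gene alignment
#'
#' @param seqs Named character vector of equal-length sequences (one per
#'   taxon) over `A,C,G,T,N,-`, or a character matrix with one row per taxon
#'   and one column per site.
#' @param gene_name Gene identifier.
#' @return An object of class `gene_alignment`: a character matrix with
#'   attributes `gene_name`.
#' @export
gene_alignment <- function(seqs, gene_name = "gene") {
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
  } else {
    stopifnot(is.character(seqs), !is.null(names(seqs)))
    n <- nchar(seqs)
    if (length(unique(n)) != 1L)
      stop("all sequences must have equal length in an alignment")
    m <- do.call(rbind, lapply(toupper(seqs), str_chars))
    rownames(m) <- names(seqs)
  }
  if (is.null(rownames(m))) stop("alignment rows must be named by taxon")
  if (anyDuplicated(rownames(m))) stop("duplicate taxon names in alignment")
  bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad))
    stop("unsupported alignment characters: ", paste(bad, collapse = ", "))
  structure(m, gene_name = gene_name, class = c("gene_alignment", "matrix", "array"))
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat("<gene_alignment> ", attr(x, "gene_name"), ": ",
      nrow(x), " taxa x ", ncol(x), " sites\n", sep = "")
  invisible(x)
}

#' Taxon ids of an alignment
#' @param aln A `gene_alignment`.
#' @return Character vector of taxon names.
#' @export
aln_taxa <- function(aln) rownames(aln)

aln_length <- function(aln) ncol(aln)

#' Convert an alignment to ape's DNAbin
#' @param aln A `gene_alignment`.
#' @return A `DNAbin` matrix.
#' @export
as_DNAbin <- function(aln) {
  m <- unclass(aln)
  attr(m, "gene_name") <- NULL
  ape::as.DNAbin(tolower(m))
}

#' Row sequences as a named character vector
#' @param aln A `gene_alignment`.
#' @return Named character vector of sequences.
#' @export
aln_sequences <- function(aln) {
  stats::setNames(apply(unclass(aln), 1L, paste, collapse = ""), rownames(aln))
}

#' Read an aligned FASTA file
#' @param path FASTA file path.
#' @param gene_name Gene identifier; defaults to the file base name.
#' @return A `gene_alignment`.
#' @export
read_alignment <- function(path, gene_name = sub("\\.[^.]*$", "", basename(path))) {
  x <- ape::read.FASTA(path)
  m <- toupper(as.character(as.matrix(x)))
  gene_alignment(m, gene_name = gene_name)
}

#' Write an alignment as FASTA
#' @param aln A `gene_alignment`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- aln_sequences(aln)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  invisible(path)
}

#' Concatenate alignments over their common taxa
#'
#' Genes are concatenated in the order given (use a sorted name order for
#' reproducibility); only taxa present in every alignment are kept.
#'
#' @param alns Named list of `gene_alignment`s.
#' @param gene_name Name for the concatenated alignment.
#' @return A `gene_alignment` with a `gene_boundaries` attribute.
#' @export
concatenate_alignments <- function(alns, gene_name = "concat") {
  stopifnot(length(alns) >= 1L)
  taxa <- Reduce(intersect, lapply(alns, aln_taxa))
  if (length(taxa) < 2L) stop("fewer than 2 taxa shared by all alignments")
  mats <- lapply(alns, function(a) unclass(a)[taxa, , drop = FALSE])
  m <- do.call(cbind, mats)
  rownames(m) <- taxa
  out <- gene_alignment(m, gene_name = gene_name)
  attr(out, "gene_boundaries") <- cumsum(vapply(alns, ncol, 0L))
  out
}
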