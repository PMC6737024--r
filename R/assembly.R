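#' Create an assembly set
#'
#' A minimal container for one genome: a name and a set of named chromosome
#' sequences. All coordinates used against an assembly are 0-based half-open.
#'
#' @param name single string naming the genome (e.g. a cultivar).
#' @param seqs named character vector of chromosome sequences (A/C/G/T/N).
#' @return an object of class `assembly_set`.
#' @export
assembly_set <- function(name, seqs) {
  stopifnot(is.character(name), length(name) == 1L, is.character(seqs))
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("chromosome sequences must be named")
  if (any(nchar(seqs) == 0L))
    stop("zero-length chromosome in assembly '", name, "'")
  structure(list(name = name, seqs = toupper(seqs)), class = "assembly_set")
}

#' @export
print.assembly_set <- function(x, ...) {
  cat("<assembly_set> ", x$name, ": ", length(x$seqs), " chromosomes, ",
      format(sum(nchar(x$seqs)), big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' Chromosome lengths of an assembly or genotype matrix
#'
#' @param x an `assembly_set` or `genotype_matrix`.
#' @return named integer vector of chromosome lengths in bp.
#' @export
chromosome_lengths <- function(x) {
  if (inherits(x, "assembly_set")) return(setNames(nchar(x$seqs), names(x$seqs)))
  if (inherits(x, "genotype_matrix")) return(x$chrom_lengths)
  stop("no chromosome lengths for object of class ", class(x)[1])
}

#' Read a FASTA file into an assembly set
#'
#' @param path FASTA file (optionally gzipped).
#' @param name genome name; defaults to the file name without extension.
#' @return an `assembly_set`.
#' @export
read_assembly <- function(path, name = NULL) {
  if (is.null(name))
    name <- sub("\\.(fa|fasta)(\\.gz)?$", "", basename(path))
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  assembly_set(name, seqs)
}

#' Write an assembly set to FASTA
#'
#' @param x an `assembly_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_assembly <- function(x, path) {
  stopifnot(inherits(x, "assembly_set"))
  ss <- Biostrings::DNAStringSet(x$seqs)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}
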