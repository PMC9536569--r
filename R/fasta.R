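#' Genome sequences with soft-masking preserved
#'
#' A genome is a named character vector of nucleotide sequences over
#' `A,C,G,T,N`. Case is significant and preserved end-to-end: lowercase
#' letters mark soft-masked (repeat / low-complexity) regions, as in the
#' `dna_sm` genome builds distributed by Ensembl.
#'
#' @param sequences Named character vector of sequences.
#' @return The validated vector with class `genome`.
#' @export
genome <- function(sequences) {
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    stop("all sequences must be named")
  if (anyDuplicated(names(sequences))) stop("duplicated sequence names")
  if (any(nchar(sequences) < 1L)) stop("zero-length sequence")
  if (any(!grepl("^[ACGTNacgtn]*$", sequences)))
    stop("sequences may contain only A,C,G,T,N (either case)")
  structure(sequences, class = "genome")
}

#' @exportS3Method base::as.character
as.character.genome <- function(x, ...) {
  # keep sequence names, as XStringSet coercion does
  out <- unclass(x)
  attributes(out) <- list(names = names(x))
  out
}

#' @exportS3Method base::print
print.genome <- function(x, ...) {
  cat("genome:", length(x), "sequence(s),", sum(nchar(x)), "bp total\n")
  for (nm in utils::head(names(x), 10L))
    cat(" ", nm, nchar(x[[nm]]), "bp\n")
  invisible(x)
}

#' Read / write FASTA
#'
#' Lossless FASTA round-trip with case (soft-masking) preserved, backed by
#' Biostrings.
#'
#' @param path File path.
#' @return `read_fasta` returns a [genome()]; `write_fasta` invisibly
#'   returns `path`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  # FASTA headers may carry descriptions after the first token
  names(seqs) <- sub("\\s.*$", "", names(ss))
  genome(seqs)
}

#' @param x A [genome()] (or named character vector of sequences).
#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  if (!inherits(x, "genome")) x <- genome(x)
  ss <- Biostrings::BStringSet(unclass(x))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
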