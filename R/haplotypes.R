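#' Parental haplotype of an amplicon
#'
#' A haplotype is one parent's allele of the pollen-typing amplicon: a plain
#' DNA string over \code{A,C,G,T} plus an accession label (e.g. \code{"Col"},
#' \code{"Ler"}). Ambiguity codes are rejected at load because downstream
#' exact-match read classification is undefined for them.
#'
#' @param accession_id Accession label, e.g. \code{"Col"}.
#' @param sequence DNA string; upper- or lower-case, no ambiguity codes.
#' @param role Either \code{"parentA"} or \code{"parentB"}.
#' @return An object of class \code{haplotype}.
#' @export
haplotype <- function(accession_id, sequence, role = c("parentA", "parentB")) {
  role <- match.arg(role)
  stopifnot(is.character(accession_id), length(accession_id) == 1L,
            nzchar(accession_id))
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || !nzchar(sequence))
    stop("haplotype sequence must be a single non-empty string", call. = FALSE)
  if (grepl("[^ACGT]", sequence))
    stop("haplotype '", accession_id,
         "' contains bases outside {A,C,G,T}; ambiguity codes are not allowed",
         call. = FALSE)
  structure(list(accession_id = accession_id, sequence = sequence, role = role),
            class = "haplotype")
}

#' Read one haplotype from a FASTA file
#'
#' Reads the first record of a FASTA file as a parental haplotype.
#'
#' @param path Path to a FASTA file.
#' @param accession_id Optional accession label; defaults to the FASTA header.
#' @inheritParams haplotype
#' @return A \code{haplotype}.
#' @export
read_haplotype_fasta <- function(path, accession_id = NULL,
                                 role = c("parentA", "parentB")) {
  role <- match.arg(role)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  if (is.null(accession_id)) accession_id <- names(set)[1L]
  haplotype(accession_id, as.character(set[[1L]]), role)
}

#' @export
print.haplotype <- function(x, ...) {
  cat("haplotype", x$accession_id, sprintf("(%s), %d bp\n",
      x$role, nchar(x$sequence)))
  invisible(x)
}

nchar_hap <- function(h) nchar(h$sequence)

#' Reverse complement of a DNA string
#' @param x A character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
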