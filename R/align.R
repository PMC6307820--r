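#' Globally align two parental haplotypes
#'
#' Needleman-Wunsch/Gotoh global alignment with affine gap penalties, used to
#' build the panmolecule union coordinate system. A gap of length L costs
#' \code{gap_open + L * gap_extend}. Tie-breaking is deterministic: among
#' equally optimal alignments, gaps in parent A are placed as far right as
#' possible, so repeated runs always yield the same coordinate system.
#'
#' @param hap_a,hap_b \code{haplotype} objects (parent A and parent B).
#' @param match Match score (default +1).
#' @param mismatch Mismatch score (default -2).
#' @param gap_open Gap opening penalty (default -6, charged once per gap).
#' @param gap_extend Gap extension penalty (default -1 per gapped base).
#' @return An object of class \code{aligned_pair} with elements
#'   \code{haplotype_a}, \code{haplotype_b}, \code{states} (0 = both present,
#'   1 = B-only base, 2 = A-only base, one per alignment column), gapped
#'   sequences \code{a_gapped}/\code{b_gapped} and the alignment \code{score}.
#' @export
align_haplotypes <- function(hap_a, hap_b, match = 1, mismatch = -2,
                             gap_open = -6, gap_extend = -1) {
  stopifnot(inherits(hap_a, "haplotype"), inherits(hap_b, "haplotype"))
  res <- gotoh_align_cpp(hap_a$sequence, hap_b$sequence,
                         match, mismatch, gap_open, gap_extend)
  states <- res$states
  a_chars <- strsplit(hap_a$sequence, "")[[1]]
  b_chars <- strsplit(hap_b$sequence, "")[[1]]
  a_col <- rep("-", length(states))
  b_col <- rep("-", length(states))
  a_col[states != 1L] <- a_chars
  b_col[states != 2L] <- b_chars
  out <- structure(list(haplotype_a = hap_a,
                        haplotype_b = hap_b,
                        states = states,
                        a_gapped = paste(a_col, collapse = ""),
                        b_gapped = paste(b_col, collapse = ""),
                        score = res$score),
                   class = "aligned_pair")
  validate_aligned_pair(out)
  out
}

validate_aligned_pair <- function(ap) {
  states <- ap$states
  if (sum(states != 1L) != nchar(ap$haplotype_a$sequence) ||
      sum(states != 2L) != nchar(ap$haplotype_b$sequence))
    stop("internal error: alignment does not conserve sequence lengths",
         call. = FALSE)
  invisible(ap)
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf("aligned_pair %s/%s: %d columns, score %g, %d A-only, %d B-only\n",
              x$haplotype_a$accession_id, x$haplotype_b$accession_id,
              length(x$states), x$score,
              sum(x$states == 2L), sum(x$states == 1L)))
  invisible(x)
}
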