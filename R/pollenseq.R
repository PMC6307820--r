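#' Exact-match alignment of one read against both parental templates
#'
#' Finds every zero-mismatch occurrence of the read, on both strands, in both
#' parental template sequences. A minus-strand hit means the reverse
#' complement of the read matches the template at the reported coordinates.
#' Reads containing ambiguous bases have no defined exact match and return an
#' empty hit list.
#'
#' @param read DNA string.
#' @param pm A \code{panmolecule} carrying the two template sequences.
#' @return A data.frame of hits: \code{template} (\code{"A"}/\code{"B"}),
#'   \code{strand} (\code{"+"}/\code{"-"}), \code{start} (1-based template
#'   coordinate), \code{length}.
#' @export
align_exact <- function(read, pm) {
  stopifnot(inherits(pm, "panmolecule"))
  read <- toupper(read)
  empty <- data.frame(template = character(), strand = character(),
                      start = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  if (grepl("[^ACGT]", read)) return(empty)
  out <- list()
  pat_f <- Biostrings::DNAString(read)
  pat_r <- Biostrings::reverseComplement(pat_f)
  for (tpl in c("A", "B")) {
    subj <- Biostrings::DNAString(if (tpl == "A") pm$seq_a else pm$seq_b)
    if (length(pat_f) > length(subj)) next
    for (str in c("+", "-")) {
      pat <- if (str == "+") pat_f else pat_r
      hits <- Biostrings::matchPattern(pat, subj)
      if (length(hits))
        out[[length(out) + 1L]] <-
          data.frame(template = tpl, strand = str,
                     start = IRanges::start(hits),
                     length = nchar(read), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Vectorized exact matching of many equal-length reads against both templates
# and strands (PDict index). Returns per read: total hit count and, when the
# read has exactly one hit overall, its template / strand / start.
exact_hits_unique <- function(reads, pm) {
  n <- length(reads)
  res <- data.frame(n_hits = integer(n), template = NA_character_,
                    strand = NA_character_, start = NA_integer_,
                    stringsAsFactors = FALSE)
  clean <- !grepl("[^ACGT]", reads)
  widths <- nchar(reads)
  subjects <- list(A = Biostrings::DNAString(pm$seq_a),
                   B = Biostrings::DNAString(pm$seq_b))
  for (w in unique(widths[clean])) {
    idx <- which(clean & widths == w)
    fwd <- Biostrings::DNAStringSet(reads[idx])
    rev <- Biostrings::reverseComplement(fwd)
    for (str in c("+", "-")) {
      pd <- Biostrings::PDict(if (str == "+") fwd else rev)
      for (tpl in c("A", "B")) {
        mi <- Biostrings::matchPDict(pd, subjects[[tpl]])
        si <- Biostrings::startIndex(mi)      # plain list of start vectors
        counts <- lengths(si)
        hit1 <- which(counts > 0L)
        res$n_hits[idx] <- res$n_hits[idx] + counts
        if (length(hit1)) {
          starts <- vapply(hit1, function(k) si[[k]][1L], integer(1))
          first <- is.na(res$template[idx[hit1]])
          res$template[idx[hit1][first]] <- tpl
          res$strand[idx[hit1][first]] <- str
          res$start[idx[hit1][first]] <- starts[first]
        }
      }
    }
  }
  # location fields are only meaningful for uniquely matching reads
  multi <- res$n_hits != 1L
  res$template[multi] <- NA_character_
  res$strand[multi] <- NA_character_
  res$start[multi] <- NA_integer_
  res
}

#' Classify crossover read pairs by the exact-match filter cascade
#'
#' Applies the sequential filters used to identify crossover read pairs from
#' pooled crossover-molecule sequencing, recording a per-stage ledger:
#' \describe{
#'   \item{Total}{all input read pairs;}
#'   \item{Mapped}{both ends have at least one exact (zero-mismatch) hit on
#'     either strand of either template (reads with ambiguous bases fail);}
#'   \item{Unique}{both ends match one template only, at exactly one
#'     location;}
#'   \item{Matched}{one end matches parent A, the other parent B;}
#'   \item{Orientate}{the end matching \code{lower_parent} lies at a lower
#'     pan coordinate than its mate (the published coordinate rule has the
#'     Ler-matching read lower, i.e. \code{lower_parent = "B"});}
#'   \item{Strand}{the two ends lie on opposite strands.}
#' }
#' Survivors are crossover read pairs; the breakpoint span is the open pan
#' interval between the inner ends of the two reads, where the crossover
#' breakpoint must lie.
#'
#' @param pairs Data frame with columns \code{pair_id}, \code{seq1},
#'   \code{seq2}.
#' @param pm A \code{panmolecule}.
#' @param lower_parent Which parent the lower-coordinate end must match;
#'   default \code{"B"} (published orientation). Use \code{"A"} for data
#'   amplified in the reciprocal orientation.
#' @param span \code{"inner"} (default) scores the open interval between the
#'   inner read ends; \code{"fragment"} scores the full outer footprint.
#' @return A list with \code{pairs} (data.frame of accepted crossover read
#'   pairs: \code{pair_id}, \code{span_start}, \code{span_end},
#'   \code{frag_start}, \code{frag_end}, per-end template/strand/pan fields)
#'   and \code{ledger} (class \code{filter_ledger}).
#' @export
classify_pairs <- function(pairs, pm, lower_parent = c("B", "A"),
                           span = c("inner", "fragment")) {
  lower_parent <- match.arg(lower_parent)
  span <- match.arg(span)
  stopifnot(all(c("pair_id", "seq1", "seq2") %in% names(pairs)),
            inherits(pm, "panmolecule"))
  n <- nrow(pairs)
  h1 <- exact_hits_unique(toupper(pairs$seq1), pm)
  h2 <- exact_hits_unique(toupper(pairs$seq2), pm)

  mapped <- h1$n_hits >= 1L & h2$n_hits >= 1L
  unique_ <- mapped & h1$n_hits == 1L & h2$n_hits == 1L
  matched <- unique_ & !is.na(h1$template) & !is.na(h2$template) &
    h1$template != h2$template

  # pan coordinates of each end (defined where matched)
  idx <- which(matched)
  ps1 <- pe1 <- ps2 <- pe2 <- rep(NA_integer_, n)
  if (length(idx)) {
    for (parent in c("A", "B")) {
      j <- idx[h1$template[idx] == parent]
      if (length(j)) {
        ps1[j] <- lift_to_pan(pm, h1$start[j], parent)
        pe1[j] <- lift_to_pan(pm, h1$start[j] + nchar(pairs$seq1[j]) - 1L, parent)
      }
      j <- idx[h2$template[idx] == parent]
      if (length(j)) {
        ps2[j] <- lift_to_pan(pm, h2$start[j], parent)
        pe2[j] <- lift_to_pan(pm, h2$start[j] + nchar(pairs$seq2[j]) - 1L, parent)
      }
    }
  }
  # identify low (lower_parent) and high end per pair
  low_is_1 <- h1$template == lower_parent
  low_ps <- ifelse(low_is_1, ps1, ps2); low_pe <- ifelse(low_is_1, pe1, pe2)
  hi_ps <- ifelse(low_is_1, ps2, ps1); hi_pe <- ifelse(low_is_1, pe2, pe1)
  orientate <- matched & !is.na(low_pe) & !is.na(hi_ps) & low_pe < hi_ps
  strand_ok <- orientate & h1$strand != h2$strand

  ledger <- structure(c(Total = n, Mapped = sum(mapped),
                        Unique = sum(unique_), Matched = sum(matched),
                        Orientate = sum(orientate), Strand = sum(strand_ok)),
                      class = "filter_ledger")
  acc <- which(strand_ok)
  out <- data.frame(pair_id = pairs$pair_id[acc],
                    span_start = if (span == "inner") low_pe[acc] + 1L else low_ps[acc],
                    span_end = if (span == "inner") hi_ps[acc] - 1L else hi_pe[acc],
                    frag_start = low_ps[acc], frag_end = hi_pe[acc],
                    low_template = rep(lower_parent, length(acc)),
                    low_strand = ifelse(low_is_1[acc], h1$strand[acc], h2$strand[acc]),
                    high_strand = ifelse(low_is_1[acc], h2$strand[acc], h1$strand[acc]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  list(pairs = out, ledger = ledger)
}

#' @export
print.filter_ledger <- function(x, ...) {
  cat("read-pair filter ledger:\n")
  print(unclass(x))
  invisible(x)
}

#' Accumulate per-position crossover coverage
#'
#' Adds 1 to every pan position inside each accepted pair's breakpoint span;
#' positions outside all spans stay 0.
#'
#' @param xos Accepted pairs data.frame from [classify_pairs()].
#' @param pm A \code{panmolecule}.
#' @return Integer vector of raw counts, one per pan position.
#' @export
accumulate_coverage <- function(xos, pm) {
  raw <- integer(pm$length_bp)
  if (nrow(xos) == 0L) return(raw)
  for (i in seq_len(nrow(xos))) {
    s <- xos$span_start[i]; e <- xos$span_end[i]
    if (!is.na(s) && !is.na(e) && s <= e) raw[s:e] <- raw[s:e] + 1L
  }
  raw
}

#' Normalize and cM-weight a coverage profile
#'
#' Divides raw per-position counts by the total number of crossover read
#' pairs, then weights by the amplicon genetic distance so profiles from
#' different genotypes and library sizes are comparable.
#'
#' @param raw Integer vector from [accumulate_coverage()].
#' @param n_crossover_pairs Total accepted crossover read pairs (>= 1).
#' @param cm Amplicon genetic distance: \code{genetic_distance} or cM value.
#' @return An object of class \code{coverage_profile}: data.frame with
#'   \code{pan}, \code{raw}, \code{normalized}, \code{weighted}; the cM used
#'   is carried in the \code{"cM"} attribute.
#' @export
normalize_profile <- function(raw, n_crossover_pairs, cm) {
  if (n_crossover_pairs < 1L)
    stop("need at least one crossover read pair to normalize", call. = FALSE)
  cmv <- if (inherits(cm, "genetic_distance")) cm$cM else as.numeric(cm)
  prof <- data.frame(pan = seq_along(raw), raw = raw,
                     normalized = raw / n_crossover_pairs,
                     weighted = raw / n_crossover_pairs * cmv)
  structure(prof, class = c("coverage_profile", "data.frame"),
            cM = cmv, n_pairs = n_crossover_pairs)
}

#' Fragment length distribution of accepted crossover pairs
#'
#' Summarizes the outer-end to outer-end span lengths (the sonication
#' fragment sizes as seen on the panmolecule).
#'
#' @param xos Accepted pairs data.frame from [classify_pairs()].
#' @param binwidth Histogram bin width in bp (default 10).
#' @return A list with \code{lengths}, \code{mean}, \code{sd}, \code{n} and a
#'   \code{histogram} data.frame (\code{bin_start}, \code{bin_end},
#'   \code{count}).
#' @export
fragment_length_histogram <- function(xos, binwidth = 10) {
  if (nrow(xos) == 0L) stop("no accepted pairs", call. = FALSE)
  len <- xos$frag_end - xos$frag_start + 1L
  breaks <- seq(floor(min(len) / binwidth) * binwidth,
                ceiling(max(len) / binwidth) * binwidth + binwidth, binwidth)
  h <- hist(len, breaks = breaks, plot = FALSE, right = FALSE)
  list(lengths = len, mean = mean(len), sd = sd(len), n = length(len),
       histogram = data.frame(bin_start = h$breaks[-length(h$breaks)],
                              bin_end = h$breaks[-1L], count = h$counts))
}

#' Read paired FASTQ files into a read-pair table
#'
#' Minimal paired FASTQ ingestion for the classifier: two files with records
#' in the same order.
#'
#' @param fastq1,fastq2 Paths to the two mate files.
#' @return Data frame with \code{pair_id}, \code{seq1}, \code{seq2}.
#' @export
read_fastq_pairs <- function(fastq1, fastq2) {
  r1 <- Biostrings::readDNAStringSet(fastq1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(fastq2, format = "fastq")
  if (length(r1) != length(r2))
    stop("mate files differ in record count", call. = FALSE)
  ids <- sub("[/ ].*$", "", names(r1))
  data.frame(pair_id = ids, seq1 = as.character(r1), seq2 = as.character(r2),
             stringsAsFactors = FALSE)
}
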