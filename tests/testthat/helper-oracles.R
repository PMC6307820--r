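# Independent oracles used across the suite. These deliberately use naive
# algorithms (exhaustive enumeration, substring scans) so they share no code
# with the implementation they check.

# Brute-force optimal global alignment score with affine gaps: enumerates
# every alignment (every monotone move path) and scores it by a direct
# column walk. Exponential -- tiny sequences only.
brute_force_align_score <- function(a, b, match = 1, mismatch = -2,
                                    gap_open = -6, gap_extend = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  score_moves <- function(moves) {
    i <- 0L; j <- 0L; prev <- ""
    sc <- 0
    for (mv in moves) {
      if (mv == "M") {
        i <- i + 1L; j <- j + 1L
        sc <- sc + if (av[i] == bv[j]) match else mismatch
      } else {
        if (mv != prev) sc <- sc + gap_open
        sc <- sc + gap_extend
        if (mv == "X") i <- i + 1L else j <- j + 1L
      }
      prev <- mv
    }
    sc
  }
  best <- -Inf
  rec <- function(i, j, moves) {
    if (i == la && j == lb) {
      best <<- max(best, score_moves(moves))
      return(invisible())
    }
    if (i < la && j < lb) rec(i + 1L, j + 1L, c(moves, "M"))
    if (j < lb) rec(i, j + 1L, c(moves, "Y"))
    if (i < la) rec(i + 1L, j, c(moves, "X"))
  }
  rec(0L, 0L, character(0))
  best
}

# Naive exact substring scan: all start positions of `read` (or its reverse
# complement) in both templates, via precomputed k-mer tables.
naive_exact_hits <- function(read, pm) {
  scan <- function(tpl_seq, pat) {
    w <- nchar(pat)
    L <- nchar(tpl_seq)
    if (w > L) return(integer(0))
    kmers <- substring(tpl_seq, 1:(L - w + 1), w:L)
    which(kmers == pat)
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  out <- list()
  for (tpl in c("A", "B")) {
    sq <- if (tpl == "A") pm$seq_a else pm$seq_b
    for (str in c("+", "-")) {
      pat <- if (str == "+") read else rc
      st <- scan(sq, pat)
      if (length(st))
        out[[length(out) + 1L]] <- data.frame(template = tpl, strand = str,
                                              start = st,
                                              length = nchar(read),
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(template = character(), strand = character(),
                      start = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# The toy panmolecule from the 8 bp / 9 bp haplotype pair (one B insertion).
toy_panmolecule <- function() {
  build_panmolecule(align_haplotypes(
    haplotype("Col", "ACGTACGT", "parentA"),
    haplotype("Ler", "ACGTTACGT", "parentB")))
}

# Small divergent locus with known truth, shared by several test files.
small_locus <- function(seed = 101, length_bp = 3000) {
  make_haplotypes(sim_config(seed = seed, length_bp = length_bp))
}
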