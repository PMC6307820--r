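#' Simulation configuration for the synthetic pollen-typing experiment
#'
#' Bundles the parameters of the synthetic-data generator. Defaults emulate
#' the measured experiment: a ~9.5 kb amplicon with 27.4 SNPs/kb interhomolog
#' divergence, indels amounting to a few percent of the sequence, sonication
#' fragments of 300-400 bp sequenced as 2x75 bp read pairs, and titration
#' series of allele-specific PCR reactions with Poisson-sampled outcomes.
#'
#' @param seed RNG seed applied by the generator entry points.
#' @param length_bp Parent-A amplicon length (default 9,482 bp).
#' @param snp_rate SNPs per bp between the parents (default 0.0274).
#' @param indel_rate Indel events per bp (default 0.004, half insertions in
#'   each parent).
#' @param indel_mean_len Mean indel length, geometric model (default 8 bp).
#' @param min_spacing Minimum bp between polymorphism events (default 10).
#' @param landscape Breakpoint intensity over inter-polymorphism intervals:
#'   \code{list(kind = "uniform")}, \code{list(kind = "table", weights = w)}
#'   (one weight per interval), or
#'   \code{list(kind = "inverse_divergence", a=, b=, c=, window_bp = 500)}.
#' @param n_molecules Number of recombinant molecules to sample.
#' @param fragment_min,fragment_max Sonication fragment bounds (300, 400 bp).
#' @param read_len Read length (75 bp).
#' @param error_rate Per-base sequencing error rate (default 0: exact-match
#'   classification is lossless).
#' @param titration Named list of true stock concentrations (molecules per
#'   unit volume) per class and the level design, e.g.
#'   \code{list(lambda = c(crossover = 0.15, parental = 200),
#'   dilution_factor = c(1, 2, 4), n_reactions = 24)}.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, length_bp = 9482L, snp_rate = 0.0274,
                       indel_rate = 0.004, indel_mean_len = 8,
                       min_spacing = 10L,
                       landscape = list(kind = "uniform"),
                       n_molecules = 1000L,
                       fragment_min = 300L, fragment_max = 400L,
                       read_len = 75L, error_rate = 0,
                       titration = list(lambda = c(crossover = 0.15,
                                                   parental = 200),
                                        dilution_factor = c(1, 2, 4),
                                        n_reactions = 24L)) {
  stopifnot(snp_rate >= 0, snp_rate < 1, indel_rate >= 0, indel_rate < 1,
            length_bp > 0, fragment_min <= fragment_max,
            read_len <= fragment_min, error_rate >= 0, error_rate < 1)
  structure(list(seed = as.integer(seed), length_bp = as.integer(length_bp),
                 snp_rate = snp_rate, indel_rate = indel_rate,
                 indel_mean_len = indel_mean_len,
                 min_spacing = as.integer(min_spacing),
                 landscape = landscape, n_molecules = as.integer(n_molecules),
                 fragment_min = as.integer(fragment_min),
                 fragment_max = as.integer(fragment_max),
                 read_len = as.integer(read_len), error_rate = error_rate,
                 titration = titration),
            class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

other_base <- function(b) {
  vapply(b, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1L),
         character(1), USE.NAMES = FALSE)
}

# Assemble a truth panmolecule (and both haplotypes) from an explicit edit
# list on parent A: SNP positions, deletion spans (A-only) and insertions
# (B-only, anchored after an A position). This is the generator's ground
# truth; it does not go through the aligner.
build_truth_pan <- function(a_chars, snp_pos, del_events, ins_events,
                            accession_a = "ColSim", accession_b = "LerSim") {
  lenA <- length(a_chars)
  del_mask <- rep(FALSE, lenA)
  for (k in seq_len(nrow(del_events))) {
    s <- del_events$start[k]; e <- s + del_events$len[k] - 1L
    del_mask[s:e] <- TRUE
    # keep the deleted run in canonical (rightmost-gap) form: if its first
    # base equals the base following the run the gap could slide right, so
    # the realized alignment would differ from the recorded truth
    if (e + 1L <= lenA && a_chars[s] == a_chars[e + 1L])
      a_chars[s] <- other_base(a_chars[e + 1L])
  }
  ins_after <- split(ins_events$len, ins_events$after)

  is_snp <- rep(FALSE, lenA); is_snp[snp_pos] <- TRUE
  # build per-A-position records, inserting B-only runs after their anchors
  recs_a <- character(lenA); recs_b <- character(lenA)
  codes <- integer(lenA); snps <- logical(lenA)
  for (i in seq_len(lenA)) {
    if (del_mask[i]) {
      recs_a[i] <- a_chars[i]; recs_b[i] <- NA_character_
      codes[i] <- 2L; snps[i] <- FALSE
    } else if (is_snp[i]) {
      recs_a[i] <- a_chars[i]; recs_b[i] <- other_base(a_chars[i])
      codes[i] <- 0L; snps[i] <- TRUE
    } else {
      recs_a[i] <- a_chars[i]; recs_b[i] <- a_chars[i]
      codes[i] <- 0L; snps[i] <- FALSE
    }
  }
  # expand with insertions
  anchors <- sort(unique(ins_events$after))
  pieces_a <- list(); pieces_b <- list(); pieces_c <- list(); pieces_s <- list()
  prev <- 0L
  push <- function(va, vb, vc, vs) {
    pieces_a[[length(pieces_a) + 1L]] <<- va
    pieces_b[[length(pieces_b) + 1L]] <<- vb
    pieces_c[[length(pieces_c) + 1L]] <<- vc
    pieces_s[[length(pieces_s) + 1L]] <<- vs
  }
  for (anchor in anchors) {
    if (anchor >= prev + 1L && anchor >= 1L)
      push(recs_a[(prev + 1L):anchor], recs_b[(prev + 1L):anchor],
           codes[(prev + 1L):anchor], snps[(prev + 1L):anchor])
    for (len in ins_after[[as.character(anchor)]]) {
      ins_b <- strsplit(random_dna(len), "")[[1]]
      # canonical rightmost form: the first inserted base must differ from
      # the next shared base or the insertion run could slide right
      if (anchor + 1L <= lenA && ins_b[1L] == a_chars[anchor + 1L])
        ins_b[1L] <- other_base(a_chars[anchor + 1L])
      push(rep(NA_character_, len), ins_b, rep(1L, len), rep(FALSE, len))
    }
    prev <- anchor
  }
  if (prev < lenA)
    push(recs_a[(prev + 1L):lenA], recs_b[(prev + 1L):lenA],
         codes[(prev + 1L):lenA], snps[(prev + 1L):lenA])
  base_a <- unlist(pieces_a); base_b <- unlist(pieces_b)
  code <- unlist(pieces_c); snp_flag <- unlist(pieces_s)

  n <- length(code)
  coord_a <- ifelse(code != 1L, cumsum(code != 1L), NA_integer_)
  coord_b <- ifelse(code != 2L, cumsum(code != 2L), NA_integer_)
  positions <- data.frame(pan = seq_len(n),
                          coord_a = as.integer(coord_a),
                          coord_b = as.integer(coord_b),
                          base_a = base_a, base_b = base_b,
                          snp = snp_flag, ins_code = code,
                          stringsAsFactors = FALSE)
  new_panmolecule(positions, accession_a = accession_a,
                  accession_b = accession_b)
}

#' Generate a divergent haplotype pair with known ground truth
#'
#' Draws a random ancestral sequence for parent A and derives parent B by
#' Bernoulli SNP substitutions and geometric-length insertion/deletion
#' events (minimum spacing enforced so every event is unambiguous). The
#' truth set includes the exact panmolecule implied by the edits, built
#' without alignment, so aligner output can be scored against it.
#'
#' @param cfg A [sim_config()].
#' @return A list with \code{hap_a}, \code{hap_b} (class \code{haplotype})
#'   and \code{truth}: \code{pan} (the true \code{panmolecule}),
#'   \code{snp_pan} (pan positions of SNPs), \code{n_ins_a},
#'   \code{n_ins_b} (A-only / B-only base totals).
#' @export
make_haplotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$length_bp
  a_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

  cand_indel <- which(runif(L) < cfg$indel_rate)
  lens <- rgeom(length(cand_indel), 1 / cfg$indel_mean_len) + 1L
  kind <- sample(c("del", "ins"), length(cand_indel), replace = TRUE)
  # enforce spacing and keep events inside the sequence
  keep <- logical(length(cand_indel))
  last_end <- -Inf
  for (k in seq_along(cand_indel)) {
    s <- cand_indel[k]
    e <- if (kind[k] == "del") s + lens[k] - 1L else s
    if (s > last_end + cfg$min_spacing && e <= L - cfg$min_spacing && s > cfg$min_spacing) {
      keep[k] <- TRUE
      last_end <- e
    }
  }
  cand_indel <- cand_indel[keep]; lens <- lens[keep]; kind <- kind[keep]
  del_events <- data.frame(start = cand_indel[kind == "del"],
                           len = lens[kind == "del"])
  ins_events <- data.frame(after = cand_indel[kind == "ins"],
                           len = lens[kind == "ins"])

  blocked <- rep(FALSE, L)
  for (k in seq_len(nrow(del_events)))
    blocked[max(1L, del_events$start[k] - 1L):
            min(L, del_events$start[k] + del_events$len[k])] <- TRUE
  blocked[ins_events$after] <- TRUE
  snp_pos <- which(runif(L) < cfg$snp_rate & !blocked)

  finish_haplotype_pair(a_chars, snp_pos, del_events, ins_events)
}

#' Generate a haplotype pair with exact polymorphism totals
#'
#' Deterministic construction used for worked examples: parent A of a given
#' length, a requested total of B-only inserted bases, A-only bases and SNP
#' count, distributed over evenly spaced events.
#'
#' @param length_a Parent-A length in bp.
#' @param ins_b_total Total B-only (parent-B inserted) bases.
#' @param ins_a_total Total A-only bases.
#' @param n_snp Number of SNPs.
#' @param n_events_b,n_events_a Number of insertion events the totals are
#'   split over.
#' @param seed RNG seed.
#' @return Same structure as [make_haplotypes()].
#' @export
make_divergent_pair <- function(length_a, ins_b_total, ins_a_total, n_snp,
                                n_events_b = 5L, n_events_a = 4L, seed = 1L) {
  set.seed(seed)
  a_chars <- sample(c("A", "C", "G", "T"), length_a, replace = TRUE)
  split_total <- function(total, k) {
    if (total == 0L) return(integer(0))
    k <- min(k, total)
    base <- total %/% k
    out <- rep(base, k)
    out[seq_len(total - base * k)] <- out[seq_len(total - base * k)] + 1L
    out
  }
  lens_b <- split_total(ins_b_total, n_events_b)
  lens_a <- split_total(ins_a_total, n_events_a)
  n_ev <- length(lens_b) + length(lens_a) + n_snp
  slots <- round(seq(100L, length_a - 100L, length.out = max(n_ev, 2L)))
  slots <- slots[seq_len(n_ev)]
  slots <- slots[sample.int(n_ev)]    # interleave event kinds along the locus
  take <- function(k) {
    got <- slots[seq_len(k)]
    slots <<- slots[-seq_len(k)]
    got
  }
  ins_after <- take(length(lens_b))
  del_start <- take(length(lens_a))
  snp_pos <- sort(take(n_snp))
  del_events <- data.frame(start = del_start, len = lens_a)
  ins_events <- data.frame(after = ins_after, len = lens_b)
  finish_haplotype_pair(a_chars, snp_pos, del_events, ins_events)
}

finish_haplotype_pair <- function(a_chars, snp_pos, del_events, ins_events) {
  pan <- build_truth_pan(a_chars, snp_pos, del_events, ins_events)
  hap_a <- haplotype(pan$accession_a, pan$seq_a, "parentA")
  hap_b <- haplotype(pan$accession_b, pan$seq_b, "parentB")
  list(hap_a = hap_a, hap_b = hap_b,
       truth = list(pan = pan,
                    snp_pan = pan$positions$pan[pan$positions$snp],
                    n_ins_a = sum(pan$positions$ins_code == 2L),
                    n_ins_b = sum(pan$positions$ins_code == 1L)))
}

# Inter-polymorphism gaps of a panmolecule: pan spans strictly between
# consecutive polymorphism records (candidate breakpoint sites). Gaps are
# restricted to the region bracketed by SNPs, mirroring the allele-specific
# amplification that selects crossovers occurring between genotypable sites.
marker_gaps <- function(pm) {
  track <- polymorphism_track(pm)
  if (nrow(track) < 2L)
    stop("need >= 2 polymorphism records to place breakpoints", call. = FALSE)
  gs <- track$pan_end[-nrow(track)] + 1L
  ge <- track$pan_start[-1L] - 1L
  snp_pan <- track$pan_start[track$kind == "snp"]
  if (length(snp_pan) < 2L)
    stop("need >= 2 SNPs to delimit the assayable region", call. = FALSE)
  ok <- gs <= ge & gs > min(snp_pan) & ge < max(snp_pan)
  data.frame(gap_start = gs[ok], gap_end = ge[ok],
             left_marker = track$pan_end[-nrow(track)][ok],
             right_marker = track$pan_start[-1L][ok])
}

gap_intensity <- function(pm, gaps, landscape) {
  len <- gaps$gap_end - gaps$gap_start + 1
  kind <- landscape$kind %||% "uniform"
  if (kind == "uniform") return(len)
  if (kind == "table") {
    w <- landscape$weights
    if (length(w) != nrow(gaps))
      stop("landscape table needs one weight per inter-polymorphism gap (",
           nrow(gaps), ")", call. = FALSE)
    return(w * len)
  }
  if (kind == "inverse_divergence") {
    wbp <- landscape$window_bp %||% 500L
    track <- polymorphism_track(pm)
    mid <- (gaps$gap_start + gaps$gap_end) / 2
    x <- vapply(mid, function(m) {
      lo <- m - wbp / 2; hi <- m + wbp / 2
      ov <- pmax(0, pmin(track$pan_end, hi) - pmax(track$pan_start, lo) + 1)
      snp <- track$kind == "snp"
      sum(ov[snp] > 0) + sum(ov[!snp])
    }, numeric(1))
    x <- pmax(x, 1)
    intensity <- pmax(log(landscape$a) + landscape$b * x^(-landscape$c), 0)
    return(intensity * len)
  }
  stop("unknown landscape kind: ", kind, call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample recombinant crossover molecules
#'
#' Draws breakpoints from the configured landscape over inter-polymorphism
#' intervals (breakpoints never fall inside an indel: they are placed between
#' polymorphisms, the resolution at which they are observable). Each molecule
#' is parent-A sequence left of its breakpoint joined to parent-B sequence
#' right of it in pan space, giving exactly one genotype transition.
#'
#' @param pm A \code{panmolecule}.
#' @param n Number of molecules.
#' @param landscape Landscape spec, see [sim_config()].
#' @param seed Optional seed.
#' @param with_sequences,with_genotypes Skip building molecule sequences or
#'   per-SNP genotype tables (cheap breakpoint-only sampling for large
#'   simulations).
#' @return A list with \code{molecules} (data.frame: \code{molecule_id},
#'   \code{breakpoint} = last A-side pan position, \code{left_marker},
#'   \code{right_marker}, \code{n_left} = molecule length of the A-side
#'   prefix, \code{length}, \code{seq}) and \code{genotypes} (data.frame:
#'   \code{molecule_id}, \code{pan_position}, \code{allele} at every SNP).
#' @export
sample_crossover_molecules <- function(pm, n, landscape = list(kind = "uniform"),
                                       seed = NULL, with_sequences = TRUE,
                                       with_genotypes = TRUE) {
  stopifnot(inherits(pm, "panmolecule"))
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L)
    return(list(molecules = data.frame(), genotypes = data.frame()))
  gaps <- marker_gaps(pm)
  inten <- gap_intensity(pm, gaps, landscape)
  if (sum(inten) <= 0) stop("landscape not normalizable", call. = FALSE)
  gi <- sample.int(nrow(gaps), n, replace = TRUE, prob = inten)
  b <- gaps$gap_start[gi] +
    floor(runif(n) * (gaps$gap_end[gi] - gaps$gap_start[gi] + 1L))
  b <- as.integer(b)

  p <- pm$positions
  a_present <- !is.na(p$coord_a)
  b_present <- !is.na(p$coord_b)
  chars_a <- p$base_a
  chars_b <- p$base_b
  snp_pan <- p$pan[p$snp]

  n_left <- vapply(b, function(bp) sum(a_present & p$pan <= bp), integer(1))
  n_right <- vapply(b, function(bp) sum(b_present & p$pan > bp), integer(1))
  if (with_sequences) {
    seqs <- vapply(b, function(bp) {
      paste(c(chars_a[a_present & p$pan <= bp],
              chars_b[b_present & p$pan > bp]), collapse = "")
    }, character(1))
  } else {
    seqs <- NA_character_
  }
  mols <- data.frame(molecule_id = sprintf("xo%05d", seq_len(n)),
                     breakpoint = b,
                     left_marker = gaps$left_marker[gi],
                     right_marker = gaps$right_marker[gi],
                     n_left = n_left,
                     length = n_left + n_right,
                     seq = seqs, stringsAsFactors = FALSE)
  gt <- NULL
  if (with_genotypes)
    gt <- data.frame(molecule_id = rep(mols$molecule_id, each = length(snp_pan)),
                     pan_position = rep(snp_pan, n),
                     allele = ifelse(rep(snp_pan, n) <= rep(b, each = length(snp_pan)),
                                     "A", "B"),
                     stringsAsFactors = FALSE)
  list(molecules = mols, genotypes = gt)
}

#' Non-recombinant (parental) molecules
#'
#' @param pm A \code{panmolecule}.
#' @param n Number of molecules.
#' @param parent \code{"A"} or \code{"B"}.
#' @return Data frame in the same layout as the recombinant molecule table
#'   (breakpoint fields NA).
#' @export
make_parental_molecules <- function(pm, n, parent = c("A", "B")) {
  parent <- match.arg(parent)
  sq <- if (parent == "A") pm$seq_a else pm$seq_b
  data.frame(molecule_id = sprintf("par%s%05d", parent, seq_len(n)),
             breakpoint = NA_integer_, left_marker = NA_integer_,
             right_marker = NA_integer_,
             n_left = if (parent == "A") nchar(sq) else 0L,
             length = nchar(sq), seq = sq, stringsAsFactors = FALSE)
}

#' Simulate sonicated paired-end reads from molecules
#'
#' Per pair: a source molecule is drawn uniformly, a fragment length uniform
#' on \code{[fragment_min, fragment_max]} and a fragment start uniform on the
#' molecule; read 1 is the first \code{read_len} bases of the fragment and
#' read 2 the reverse complement of its last \code{read_len} bases (the ends
#' are emitted in random order, as in a real library). Fragments longer than
#' the molecule are resampled against the molecule length. With the default
#' zero error rate every read is an exact substring (or reverse complement)
#' of its source molecule; a positive \code{error_rate} substitutes bases
#' uniformly.
#'
#' @param molecules Molecule data.frame (recombinant or parental).
#' @param n_pairs Number of read pairs.
#' @param cfg A [sim_config()] supplying fragment/read geometry.
#' @param seed Optional seed.
#' @return Data frame: \code{pair_id}, \code{molecule_id}, \code{seq1},
#'   \code{seq2}, \code{frag_start}, \code{frag_end} (molecule coordinates),
#'   \code{swapped} (whether read1 is the right-hand end).
#' @export
make_read_pairs <- function(molecules, n_pairs, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nrow(molecules) >= 1L)
  mi <- sample.int(nrow(molecules), n_pairs, replace = TRUE)
  mlen <- molecules$length[mi]
  flen <- cfg$fragment_min +
    floor(runif(n_pairs) * (cfg$fragment_max - cfg$fragment_min + 1L))
  short <- flen > mlen
  if (any(short)) {
    message(sum(short), " fragments longer than their molecule; clamped")
    flen[short] <- mlen[short]
  }
  fstart <- 1L + floor(runif(n_pairs) * (mlen - flen + 1L))
  fend <- fstart + flen - 1L
  seqs <- molecules$seq[mi]
  left <- substr(seqs, fstart, fstart + cfg$read_len - 1L)
  right <- revcomp(substr(seqs, fend - cfg$read_len + 1L, fend))
  if (cfg$error_rate > 0) {
    left <- add_seq_errors(left, cfg$error_rate)
    right <- add_seq_errors(right, cfg$error_rate)
  }
  swapped <- runif(n_pairs) < 0.5
  data.frame(pair_id = sprintf("pair%06d", seq_len(n_pairs)),
             molecule_id = molecules$molecule_id[mi],
             seq1 = ifelse(swapped, right, left),
             seq2 = ifelse(swapped, left, right),
             frag_start = as.integer(fstart), frag_end = as.integer(fend),
             swapped = swapped, stringsAsFactors = FALSE)
}

add_seq_errors <- function(reads, rate) {
  vapply(reads, function(r) {
    ch <- strsplit(r, "")[[1]]
    hit <- which(runif(length(ch)) < rate)
    if (length(hit)) ch[hit] <- other_base(ch[hit])
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Map a molecule coordinate to the panmolecule
#'
#' For a recombinant molecule (A prefix then B suffix) with a known
#' breakpoint, converts molecule positions to pan coordinates.
#'
#' @param pm A \code{panmolecule}.
#' @param molecule One row of the molecule table (needs \code{breakpoint},
#'   \code{n_left}).
#' @param pos Integer vector of 1-based molecule coordinates.
#' @return Integer vector of pan coordinates.
#' @export
molecule_pos_to_pan <- function(pm, molecule, pos) {
  p <- pm$positions
  a_pan <- p$pan[!is.na(p$coord_a) & p$pan <= molecule$breakpoint]
  b_pan <- p$pan[!is.na(p$coord_b) & p$pan > molecule$breakpoint]
  all_pan <- c(a_pan, b_pan)
  all_pan[pos]
}

#' Simulate a titration series with known truth
#'
#' At dilution d of a stock with true concentration lambda, each reaction is
#' positive iff it received at least one molecule:
#' \code{n_positive ~ Binomial(n_reactions, 1 - exp(-lambda / d))}.
#'
#' @param lambda True stock concentration (molecules per unit volume).
#' @param dilution_factor Vector of fold-dilutions.
#' @param n_reactions Reactions per level (scalar or vector).
#' @param molecule_class Class label for the series.
#' @param seed Optional seed.
#' @return A \code{titration_series}.
#' @export
simulate_titration <- function(lambda, dilution_factor, n_reactions,
                               molecule_class = "crossover", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(lambda >= 0)
  n_reactions <- rep_len(as.integer(n_reactions), length(dilution_factor))
  p <- 1 - exp(-lambda / dilution_factor)
  pos <- rbinom(length(dilution_factor), n_reactions, p)
  titration_series(dilution_factor, n_reactions, pos,
                   molecule_class = molecule_class)
}

#' Write haplotypes to FASTA
#' @param haps List of \code{haplotype}s.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_haplotype_fasta <- function(haps, path) {
  set <- Biostrings::DNAStringSet(vapply(haps, function(h) h$sequence,
                                         character(1)))
  names(set) <- vapply(haps, function(h) h$accession_id, character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write read pairs to a pair of FASTQ files
#' @param pairs Read-pair data.frame from [make_read_pairs()].
#' @param prefix Output prefix; writes \code{<prefix>_1.fastq} and
#'   \code{<prefix>_2.fastq}.
#' @return Character vector of the two paths, invisibly.
#' @export
write_fastq_pairs <- function(pairs, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (k in 1:2) {
    sq <- pairs[[paste0("seq", k)]]
    con <- file(paths[k], "w")
    writeLines(paste0("@", pairs$pair_id, "/", k, "\n", sq, "\n+\n",
                      strrep("I", nchar(sq))), con)
    close(con)
  }
  invisible(paths)
}
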