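#' Build the panmolecule union coordinate system
#'
#' The panmolecule contains every base present in either parental haplotype:
#' one position per alignment column, so indels from both sides occupy
#' coordinates. Each position records the parental coordinates (where the
#' parent has a base), the parental bases, whether it is a SNP, and an
#' insertion code (0 = shared, 1 = B-only base, 2 = A-only base) following the
#' published key-table dialect.
#'
#' @param ap An \code{aligned_pair} from [align_haplotypes()].
#' @return An object of class \code{panmolecule}: a list with
#'   \code{positions} (data.frame: \code{pan}, \code{coord_a}, \code{coord_b},
#'   \code{base_a}, \code{base_b}, \code{snp}, \code{ins_code}),
#'   \code{length_bp}, accession labels and the parental sequences.
#' @export
build_panmolecule <- function(ap) {
  stopifnot(inherits(ap, "aligned_pair"))
  states <- ap$states
  n <- length(states)
  base_a <- base_b <- rep(NA_character_, n)
  base_a[states != 1L] <- strsplit(ap$haplotype_a$sequence, "")[[1]]
  base_b[states != 2L] <- strsplit(ap$haplotype_b$sequence, "")[[1]]
  coord_a <- ifelse(states != 1L, cumsum(states != 1L), NA_integer_)
  coord_b <- ifelse(states != 2L, cumsum(states != 2L), NA_integer_)
  snp <- states == 0L & base_a != base_b
  snp[is.na(snp)] <- FALSE
  positions <- data.frame(pan = seq_len(n),
                          coord_a = as.integer(coord_a),
                          coord_b = as.integer(coord_b),
                          base_a = base_a, base_b = base_b,
                          snp = snp, ins_code = as.integer(states),
                          stringsAsFactors = FALSE)
  new_panmolecule(positions,
                  accession_a = ap$haplotype_a$accession_id,
                  accession_b = ap$haplotype_b$accession_id,
                  seq_a = ap$haplotype_a$sequence,
                  seq_b = ap$haplotype_b$sequence)
}

new_panmolecule <- function(positions, accession_a, accession_b,
                            seq_a = NULL, seq_b = NULL) {
  if (is.null(seq_a) && !all(is.na(positions$base_a)))
    seq_a <- paste(positions$base_a[!is.na(positions$base_a)], collapse = "")
  if (is.null(seq_b) && !all(is.na(positions$base_b)))
    seq_b <- paste(positions$base_b[!is.na(positions$base_b)], collapse = "")
  pm <- structure(list(positions = positions,
                       length_bp = nrow(positions),
                       accession_a = accession_a,
                       accession_b = accession_b,
                       seq_a = seq_a, seq_b = seq_b),
                  class = "panmolecule")
  validate_panmolecule(pm)
  pm
}

validate_panmolecule <- function(pm) {
  p <- pm$positions
  if (!identical(p$pan, seq_len(nrow(p))))
    stop("pan coordinates must run 1..length_bp without gaps", call. = FALSE)
  ca <- p$coord_a[!is.na(p$coord_a)]
  cb <- p$coord_b[!is.na(p$coord_b)]
  if (is.unsorted(ca, strictly = TRUE) || is.unsorted(cb, strictly = TRUE))
    stop("parental coordinates must be strictly increasing", call. = FALSE)
  n_ins_b <- sum(p$ins_code == 1L)
  n_ins_a <- sum(p$ins_code == 2L)
  if (nrow(p) - n_ins_b != length(ca) || nrow(p) - n_ins_a != length(cb))
    stop("length conservation violated: length_bp - insertions != parent length",
         call. = FALSE)
  bad_snp <- p$snp & (is.na(p$coord_a) | is.na(p$coord_b))
  if (any(bad_snp))
    stop("SNP positions must carry both parental coordinates", call. = FALSE)
  invisible(pm)
}

#' @export
print.panmolecule <- function(x, ...) {
  p <- x$positions
  cat(sprintf("panmolecule %s/%s: %d bp (%d from %s, %d from %s)\n",
              x$accession_a, x$accession_b, x$length_bp,
              sum(!is.na(p$coord_a)), x$accession_a,
              sum(!is.na(p$coord_b)), x$accession_b))
  cat(sprintf("  %d SNPs, %d %s-only bases, %d %s-only bases\n",
              sum(p$snp), sum(p$ins_code == 1L), x$accession_b,
              sum(p$ins_code == 2L), x$accession_a))
  invisible(x)
}

parent_length <- function(pm, parent = c("A", "B")) {
  parent <- match.arg(parent)
  col <- if (parent == "A") "coord_a" else "coord_b"
  sum(!is.na(pm$positions[[col]]))
}

#' Lift a parental coordinate to the panmolecule
#'
#' @param pm A \code{panmolecule}.
#' @param coord Integer vector of 1-based parental coordinates.
#' @param parent \code{"A"} or \code{"B"}.
#' @return Integer vector of pan coordinates.
#' @export
lift_to_pan <- function(pm, coord, parent = c("A", "B")) {
  parent <- match.arg(parent)
  col <- if (parent == "A") "coord_a" else "coord_b"
  len <- parent_length(pm, parent)
  coord <- as.integer(coord)
  if (any(is.na(coord)) || any(coord < 1L) || any(coord > len))
    stop("parental coordinate out of range 1..", len, call. = FALSE)
  match(coord, pm$positions[[col]])
}

#' Lift a pan coordinate back to a parent
#'
#' Returns \code{NA} where the pan position is an insertion of the other
#' parent (the queried parent has no base there).
#'
#' @inheritParams lift_to_pan
#' @param pan_coord Integer vector of 1-based pan coordinates.
#' @return Integer vector of parental coordinates, \code{NA} where absent.
#' @export
lift_from_pan <- function(pm, pan_coord, parent = c("A", "B")) {
  parent <- match.arg(parent)
  col <- if (parent == "A") "coord_a" else "coord_b"
  pan_coord <- as.integer(pan_coord)
  if (any(is.na(pan_coord)) || any(pan_coord < 1L) ||
      any(pan_coord > pm$length_bp))
    stop("pan coordinate out of range 1..", pm$length_bp, call. = FALSE)
  pm$positions[[col]][pan_coord]
}

#' Polymorphism annotation track
#'
#' Collapses the panmolecule's per-position annotations into a record track:
#' each SNP contributes one record of weight 1, and each maximal run of
#' insertion positions collapses to a single record whose weight is its length
#' in base pairs (the counting rule used throughout the windowed analyses:
#' SNPs count 1, indels their length).
#'
#' @param pm A \code{panmolecule}.
#' @return A data.frame with columns \code{pan_start}, \code{pan_end},
#'   \code{kind} (\code{"snp"}, \code{"insertion_a"}, \code{"insertion_b"})
#'   and \code{weight_bp}, sorted and non-overlapping.
#' @export
polymorphism_track <- function(pm) {
  p <- pm$positions
  recs <- list()
  if (any(p$snp)) {
    s <- p$pan[p$snp]
    recs[[1L]] <- data.frame(pan_start = s, pan_end = s, kind = "snp",
                             weight_bp = 1L, stringsAsFactors = FALSE)
  }
  r <- rle(p$ins_code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  if (any(keep)) {
    recs[[length(recs) + 1L]] <-
      data.frame(pan_start = starts[keep], pan_end = ends[keep],
                 kind = ifelse(r$values[keep] == 1L, "insertion_b",
                               "insertion_a"),
                 weight_bp = r$lengths[keep], stringsAsFactors = FALSE)
  }
  if (length(recs) == 0L)
    return(data.frame(pan_start = integer(), pan_end = integer(),
                      kind = character(), weight_bp = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, recs)
  out <- out[order(out$pan_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a panmolecule key table (CSV)
#'
#' Writes the published key-table dialect: pan coordinate, the two parental
#' coordinates, a SNP column flagged with 1, a parent-B insertion column
#' flagged with 1 and a parent-A insertion column flagged with 2 (blank
#' elsewhere). With \code{bases = TRUE} (default) two extra columns carry the
#' parental bases so that writing then reading reproduces the panmolecule
#' exactly.
#'
#' @param pm A \code{panmolecule}.
#' @param path Output CSV path.
#' @param bases Append \code{base_<A>} / \code{base_<B>} columns?
#' @return \code{path}, invisibly.
#' @export
write_key_table <- function(pm, path, bases = TRUE) {
  p <- pm$positions
  blank <- function(x) ifelse(is.na(x), "", as.character(x))
  df <- data.frame(pan = p$pan,
                   a = blank(p$coord_a),
                   b = blank(p$coord_b),
                   SNP = ifelse(p$snp, "1", ""),
                   ins_b = ifelse(p$ins_code == 1L, "1", ""),
                   ins_a = ifelse(p$ins_code == 2L, "2", ""),
                   stringsAsFactors = FALSE)
  names(df) <- c("pan_coordinate", pm$accession_a, pm$accession_b, "SNP",
                 paste0(pm$accession_b, "_insertion"),
                 paste0(pm$accession_a, "_insertion"))
  if (bases) {
    df[[paste0("base_", pm$accession_a)]] <- blank(p$base_a)
    df[[paste0("base_", pm$accession_b)]] <- blank(p$base_b)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a panmolecule key table (CSV)
#'
#' Parses the key-table dialect written by [write_key_table()]. Columns are
#' positional: pan coordinate, parent-A coordinate, parent-B coordinate, SNP
#' flag, B-insertion flag (1), A-insertion flag (2), with optional trailing
#' base columns. Accession labels are taken from the header. Malformed rows
#' (non-monotone coordinates, both insertion flags set) raise an error naming
#' the offending row.
#'
#' @param path CSV path.
#' @return A \code{panmolecule}.
#' @export
read_key_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 6L)
    stop("key table must have at least 6 columns", call. = FALSE)
  acc_a <- names(df)[2L]
  acc_b <- names(df)[3L]
  int_or_na <- function(x) suppressWarnings(as.integer(ifelse(x == "", NA, x)))
  pan <- int_or_na(df[[1L]])
  coord_a <- int_or_na(df[[2L]])
  coord_b <- int_or_na(df[[3L]])
  snp <- !is.na(int_or_na(df[[4L]])) & int_or_na(df[[4L]]) == 1L
  ins_b <- !is.na(int_or_na(df[[5L]])) & int_or_na(df[[5L]]) == 1L
  ins_a <- !is.na(int_or_na(df[[6L]])) & int_or_na(df[[6L]]) == 2L
  both <- which(ins_a & ins_b)
  if (length(both))
    stop("key table row ", both[1L] + 1L,
         ": both insertion flags set", call. = FALSE)
  if (!identical(pan, seq_along(pan)))
    stop("key table row ", which(pan != seq_along(pan))[1L] + 1L,
         ": pan coordinates must run 1..n", call. = FALSE)
  for (side in list(list(v = coord_a, nm = acc_a),
                    list(v = coord_b, nm = acc_b))) {
    v <- side$v[!is.na(side$v)]
    if (is.unsorted(v, strictly = TRUE)) {
      bad <- which(diff(v) <= 0)[1L]
      stop("key table: non-monotone ", side$nm, " coordinates near row ",
           which(!is.na(side$v))[bad + 1L] + 1L, call. = FALSE)
    }
  }
  mism <- which((ins_b & !is.na(coord_a)) | (ins_a & !is.na(coord_b)))
  if (length(mism))
    stop("key table row ", mism[1L] + 1L,
         ": insertion flag contradicts parental coordinates", call. = FALSE)
  base_cols <- grep("^base_", names(df))
  base_a <- base_b <- rep(NA_character_, length(pan))
  if (length(base_cols) >= 2L) {
    pick <- function(nm) {
      hit <- which(names(df) == paste0("base_", nm))
      if (length(hit)) df[[hit[1L]]] else NULL
    }
    ba <- pick(acc_a); bb <- pick(acc_b)
    if (!is.null(ba)) base_a <- ifelse(ba == "", NA_character_, ba)
    if (!is.null(bb)) base_b <- ifelse(bb == "", NA_character_, bb)
  }
  ins_code <- ifelse(ins_b, 1L, ifelse(ins_a, 2L, 0L))
  positions <- data.frame(pan = pan, coord_a = coord_a, coord_b = coord_b,
                          base_a = base_a, base_b = base_b,
                          snp = snp, ins_code = ins_code,
                          stringsAsFactors = FALSE)
  new_panmolecule(positions, accession_a = acc_a, accession_b = acc_b)
}
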