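#' Adjacent-window crossover and polymorphism table
#'
#' Cuts the panmolecule into adjacent windows of \code{window_bp} and
#' assigns, per window, a crossover value and a polymorphism weight.
#'
#' Crossover values come in two modes. In Sanger mode (\code{x} is a
#' breakpoint-call table) each simple crossover contributes fractionally to
#' every window its breakpoint interval overlaps, proportional to the
#' overlap: a crossover whose 150 bp interval has 50 bp in one window and
#' 100 bp in the next counts 0.33 and 0.67 there, so window totals conserve
#' the crossover count exactly. In profile mode (\code{x} is a
#' \code{coverage_profile}) the value is the mean cM-weighted coverage in the
#' window (crossover reads per cM).
#'
#' Polymorphism weights sum SNPs as 1 and indels as their length in bp,
#' splitting indel records that straddle a boundary by bp overlap.
#'
#' The final window is flagged excluded when it is shorter than
#' \code{window_bp}; it still receives values (so totals are conserved) but
#' is dropped from correlation and model fits.
#'
#' @param x Either a data.frame of breakpoint calls (needs \code{status},
#'   \code{pan_start}, \code{pan_end}; e.g. from [call_breakpoints()]) or a
#'   \code{coverage_profile} from [normalize_profile()].
#' @param track Polymorphism track from [polymorphism_track()].
#' @param window_bp Window size in bp (500 for Sanger-interval analyses,
#'   250 for sequencing profiles).
#' @param length_bp Panmolecule length; required when \code{x} is a call
#'   table, inferred from the profile otherwise.
#' @return An object of class \code{window_table}: data.frame with
#'   \code{window_index}, \code{pan_start}, \code{pan_end},
#'   \code{crossover_value}, \code{polymorphism_weight}, \code{included}.
#' @export
window_counts <- function(x, track, window_bp, length_bp = NULL) {
  if (window_bp < 1L) stop("window_bp must be >= 1", call. = FALSE)
  if (inherits(x, "coverage_profile")) {
    mode <- "profile"
    length_bp <- nrow(x)
  } else {
    mode <- "sanger"
    if (is.null(length_bp))
      stop("length_bp required for breakpoint-call input", call. = FALSE)
  }
  starts <- seq.int(1L, length_bp, by = window_bp)
  ends <- pmin(starts + window_bp - 1L, length_bp)
  nw <- length(starts)
  if (nw == 1L && ends[1L] - starts[1L] + 1L < window_bp)
    warning("window larger than panmolecule; single partial window excluded",
            call. = FALSE)
  value <- numeric(nw)

  overlap_frac <- function(s, e) {
    # fraction of [s, e] falling in each window; s..e on pan coordinates
    ov <- pmax(0L, pmin(ends, e) - pmax(starts, s) + 1L)
    ov
  }

  if (mode == "sanger") {
    simple <- x[x$status == "simple", , drop = FALSE]
    for (i in seq_len(nrow(simple))) {
      s <- simple$pan_start[i] + 1L      # open span between flanking markers
      e <- simple$pan_end[i] - 1L
      if (s > e) {
        # zero-length interval (adjacent markers): assign at the boundary
        w <- findInterval(simple$pan_start[i], starts)
        value[w] <- value[w] + 1
      } else {
        ov <- overlap_frac(s, e)
        value <- value + ov / (e - s + 1L)
      }
    }
  } else {
    for (w in seq_len(nw))
      value[w] <- mean(x$weighted[starts[w]:ends[w]])
  }

  poly <- numeric(nw)
  for (i in seq_len(nrow(track))) {
    if (track$kind[i] == "snp") {
      w <- findInterval(track$pan_start[i], starts)
      poly[w] <- poly[w] + 1
    } else {
      poly <- poly + overlap_frac(track$pan_start[i], track$pan_end[i])
    }
  }

  included <- rep(TRUE, nw)
  if (ends[nw] - starts[nw] + 1L < window_bp) included[nw] <- FALSE
  out <- data.frame(window_index = seq_len(nw), pan_start = starts,
                    pan_end = ends, crossover_value = value,
                    polymorphism_weight = poly, included = included)
  structure(out, class = c("window_table", "data.frame"), mode = mode,
            window_bp = window_bp)
}

#' Express window crossover values as percentages
#'
#' Divides each included window's crossover value by the total over included
#' windows (x100), so landscapes from hybrids with different total crossover
#' counts can be overlaid.
#'
#' @param wt A \code{window_table}.
#' @return The table with a \code{crossover_percent} column (NA for excluded
#'   windows).
#' @export
percent_normalize <- function(wt) {
  stopifnot(inherits(wt, "window_table"))
  tot <- sum(wt$crossover_value[wt$included])
  if (tot <= 0) stop("all included windows have zero crossovers", call. = FALSE)
  wt$crossover_percent <- ifelse(wt$included,
                                 100 * wt$crossover_value / tot, NA_real_)
  wt
}

#' Spearman correlation between polymorphism and crossover values
#'
#' Rank correlation with mid-ranks for ties and the two-sided asymptotic
#' p-value, as used to test the negative relationship between interhomolog
#' polymorphism and crossover frequency across windows.
#'
#' @param x,y Numeric vectors (e.g. polymorphism weights and crossover
#'   values of included windows), or a single \code{window_table}.
#' @return A list with \code{rho} and \code{p_value}.
#' @export
spearman_windows <- function(x, y = NULL) {
  if (inherits(x, "window_table")) {
    wt <- x[x$included, , drop = FALSE]
    y <- wt$crossover_value
    x <- wt$polymorphism_weight
  }
  if (length(x) != length(y) || length(x) < 3L)
    stop("need >= 3 paired observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant vector; Spearman correlation undefined", call. = FALSE)
  ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p_value = ht$p.value)
}

#' Project a pan interval onto one parent's coordinates
#'
#' Utility for cross-hybrid comparisons performed against one parent's
#' reference sequence: maps a pan interval to the smallest parental interval
#' covering the parent's bases inside it. Returns NA bounds when the parent
#' has no base in the span.
#'
#' @param pm A \code{panmolecule}.
#' @param pan_start,pan_end Pan interval bounds (inclusive).
#' @param parent \code{"A"} or \code{"B"}.
#' @return Integer vector \code{c(start, end)} in parental coordinates.
#' @export
project_interval_to_parent <- function(pm, pan_start, pan_end,
                                       parent = c("A", "B")) {
  parent <- match.arg(parent)
  col <- if (parent == "A") "coord_a" else "coord_b"
  v <- pm$positions[[col]][pan_start:pan_end]
  v <- v[!is.na(v)]
  if (!length(v)) return(c(NA_integer_, NA_integer_))
  c(min(v), max(v))
}
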