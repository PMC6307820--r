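#' Per-molecule allele calls at polymorphic markers
#'
#' The genotype of one Sanger-sequenced single molecule: an ordered list of
#' allele calls (parent A, parent B or unknown) at polymorphism positions on
#' the panmolecule.
#'
#' @param molecule_id Identifier.
#' @param pan_position Integer vector of marker pan coordinates, strictly
#'   increasing.
#' @param allele Character vector over \code{"A"}, \code{"B"}, \code{"unknown"}.
#' @return An object of class \code{molecule_genotype}.
#' @export
molecule_genotype <- function(molecule_id, pan_position, allele) {
  stopifnot(length(pan_position) == length(allele))
  pan_position <- as.integer(pan_position)
  if (is.unsorted(pan_position, strictly = TRUE))
    stop("marker positions must be strictly increasing", call. = FALSE)
  allele <- as.character(allele)
  if (!all(allele %in% c("A", "B", "unknown")))
    stop("alleles must be 'A', 'B' or 'unknown'", call. = FALSE)
  structure(list(molecule_id = molecule_id,
                 calls = data.frame(pan_position = pan_position,
                                    allele = allele,
                                    stringsAsFactors = FALSE)),
            class = "molecule_genotype")
}

#' Call the crossover breakpoint interval of one molecule
#'
#' Transitions are counted over consecutive informative (non-unknown) calls.
#' Exactly one A-to-B transition (reading along the panmolecule, the
#' orientation selected by the allele-specific amplification) gives a simple
#' crossover whose interval is bounded by the flanking markers: the last
#' A-side marker and the first B-side marker. Zero transitions is a parental
#' molecule; more than one is a complex molecule (reported, excluded from
#' rate tables).
#'
#' @param mg A \code{molecule_genotype} with at least two informative calls.
#' @return An object of class \code{crossover_call}: \code{molecule_id},
#'   \code{status} (\code{"simple"}, \code{"parental"}, \code{"complex"}),
#'   \code{n_transitions}, and for simple calls \code{pan_start} /
#'   \code{pan_end} (the flanking marker positions; the breakpoint lies
#'   strictly between them).
#' @export
call_breakpoint <- function(mg) {
  stopifnot(inherits(mg, "molecule_genotype"))
  inf <- mg$calls[mg$calls$allele != "unknown", , drop = FALSE]
  if (nrow(inf) < 2L)
    stop("molecule ", mg$molecule_id,
         ": fewer than 2 informative calls; uninformative molecule",
         call. = FALSE)
  al <- inf$allele
  trans <- which(al[-1L] != al[-length(al)])
  n_tr <- length(trans)
  if (n_tr == 0L) {
    status <- "parental"; ps <- NA_integer_; pe <- NA_integer_
  } else if (n_tr == 1L && al[1L] == "A" && al[length(al)] == "B") {
    status <- "simple"
    ps <- inf$pan_position[trans]
    pe <- inf$pan_position[trans + 1L]
  } else {
    status <- "complex"; ps <- NA_integer_; pe <- NA_integer_
  }
  structure(list(molecule_id = mg$molecule_id, status = status,
                 n_transitions = n_tr,
                 pan_start = ps, pan_end = pe),
            class = "crossover_call")
}

#' Call breakpoints for a table of molecule genotypes
#'
#' @param genotypes Data frame with columns \code{molecule_id},
#'   \code{pan_position}, \code{allele} (the molecule-genotype CSV layout).
#' @return A data.frame with one row per molecule: \code{molecule_id},
#'   \code{status}, \code{n_transitions}, \code{pan_start}, \code{pan_end}.
#' @export
call_breakpoints <- function(genotypes) {
  need <- c("molecule_id", "pan_position", "allele")
  if (!all(need %in% names(genotypes)))
    stop("genotype table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  rows <- lapply(split(genotypes, genotypes$molecule_id), function(d) {
    d <- d[order(d$pan_position), , drop = FALSE]
    cc <- call_breakpoint(molecule_genotype(d$molecule_id[1L],
                                            d$pan_position, d$allele))
    data.frame(molecule_id = cc$molecule_id, status = cc$status,
               n_transitions = cc$n_transitions,
               pan_start = cc$pan_start, pan_end = cc$pan_end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-interval recombination rate table
#'
#' Distributes the total amplicon genetic distance over breakpoint intervals:
#' each simple crossover call is assigned to its flanking-marker interval, and
#' interval cM = (crossovers in interval / total simple calls) x total cM.
#' Interval lengths are panmolecule distances between the flanking markers
#' (bases strictly between them), and rates are cM per megabase of that
#' length. Complex molecules are excluded (their count is carried in the
#' \code{"n_complex"} attribute).
#'
#' @param calls Data frame from [call_breakpoints()] (or a list of
#'   \code{crossover_call}s).
#' @param total_cm Total amplicon genetic distance: a
#'   \code{genetic_distance} or a plain cM value.
#' @param markers Optional integer vector of all marker pan positions; when
#'   given, every consecutive-marker interval appears in the table (zero
#'   crossovers allowed), mirroring the published interval tables.
#' @return A data.frame with columns \code{pan_start}, \code{pan_end},
#'   \code{length_bp}, \code{n_crossovers}, \code{cM}, \code{cM_per_Mb}.
#' @export
interval_rates <- function(calls, total_cm, markers = NULL) {
  if (is.list(calls) && !is.data.frame(calls))
    calls <- do.call(rbind, lapply(calls, function(cc)
      data.frame(molecule_id = cc$molecule_id, status = cc$status,
                 n_transitions = cc$n_transitions,
                 pan_start = cc$pan_start, pan_end = cc$pan_end,
                 stringsAsFactors = FALSE)))
  cm <- if (inherits(total_cm, "genetic_distance")) total_cm$cM
        else as.numeric(total_cm)
  simple <- calls[calls$status == "simple", , drop = FALSE]
  n_complex <- sum(calls$status == "complex")
  if (nrow(simple) == 0L)
    stop("no simple crossover calls; rate table undefined", call. = FALSE)
  if (is.null(markers)) {
    key <- unique(simple[, c("pan_start", "pan_end")])
  } else {
    markers <- sort(unique(as.integer(markers)))
    key <- data.frame(pan_start = markers[-length(markers)],
                      pan_end = markers[-1L])
    missed <- !(simple$pan_start %in% key$pan_start &
                simple$pan_end %in% key$pan_end)
    if (any(missed))
      key <- unique(rbind(key, simple[missed, c("pan_start", "pan_end")]))
  }
  key <- key[order(key$pan_start, key$pan_end), , drop = FALSE]
  n_in <- mapply(function(s, e) sum(simple$pan_start == s & simple$pan_end == e),
                 key$pan_start, key$pan_end)
  total <- nrow(simple)
  len <- key$pan_end - key$pan_start - 1L
  interval_cm <- n_in / total * cm
  out <- data.frame(pan_start = key$pan_start, pan_end = key$pan_end,
                    length_bp = len, n_crossovers = as.integer(n_in),
                    cM = interval_cm,
                    cM_per_Mb = ifelse(len > 0,
                                       round(interval_cm / (len * 1e-6), 2),
                                       NA_real_))
  rownames(out) <- NULL
  attr(out, "n_complex") <- n_complex
  attr(out, "total_cM") <- cm
  out
}
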