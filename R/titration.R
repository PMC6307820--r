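#' Limiting-dilution titration series
#'
#' One titration experiment for one molecule class (crossover or parental):
#' at each dilution level a number of allele-specific PCR reactions is run and
#' the number containing at least one amplifiable molecule is recorded.
#'
#' @param dilution_factor Numeric vector, fold-dilution of each level relative
#'   to the stock (larger = more dilute).
#' @param n_reactions Integer vector, reactions run per level.
#' @param n_positive Integer vector, positive reactions per level.
#' @param molecule_class \code{"crossover"} or \code{"parental"}.
#' @return An object of class \code{titration_series}.
#' @export
titration_series <- function(dilution_factor, n_reactions, n_positive,
                             molecule_class = c("crossover", "parental")) {
  molecule_class <- match.arg(molecule_class)
  stopifnot(length(dilution_factor) == length(n_reactions),
            length(n_reactions) == length(n_positive),
            length(dilution_factor) >= 1L)
  if (any(dilution_factor <= 0)) stop("dilution_factor must be > 0", call. = FALSE)
  if (any(n_positive < 0) || any(n_positive > n_reactions))
    stop("need 0 <= n_positive <= n_reactions at every level", call. = FALSE)
  structure(list(molecule_class = molecule_class,
                 levels = data.frame(dilution_factor = dilution_factor,
                                     n_reactions = as.integer(n_reactions),
                                     n_positive = as.integer(n_positive))),
            class = "titration_series")
}

#' Read titration series from CSV
#'
#' Expects columns \code{class}, \code{dilution_factor}, \code{n_reactions},
#' \code{n_positive}; returns one \code{titration_series} per class.
#'
#' @param path CSV path.
#' @return Named list of \code{titration_series}.
#' @export
read_titration_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("class", "dilution_factor", "n_reactions", "n_positive")
  if (!all(need %in% names(df)))
    stop("titration CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(df, df$class), function(d)
    titration_series(d$dilution_factor, d$n_reactions, d$n_positive,
                     molecule_class = d$class[1L]))
  out
}

#' Estimate molecule concentration from a titration series
#'
#' Single-molecule limiting-dilution estimator: at each informative level
#' (some but not all reactions positive) the Poisson zero-class MLE is
#' \eqn{\hat\lambda = -\log(1 - k/n)} molecules per reaction, rescaled by the
#' level's dilution factor to the stock concentration. Level estimates are
#' combined by inverse-variance weighting (default) or a plain mean, with
#' variances from the delta method applied to the binomial positive fraction.
#'
#' @param ts A \code{titration_series}.
#' @param combine \code{"inverse_variance"} (default) or \code{"mean"}.
#' @return An object of class \code{molecule_estimate}: list with
#'   \code{concentration} (molecules per unit stock volume), \code{variance},
#'   \code{n_levels_used} and \code{molecule_class}.
#' @export
estimate_concentration <- function(ts, combine = c("inverse_variance", "mean")) {
  combine <- match.arg(combine)
  stopifnot(inherits(ts, "titration_series"))
  lv <- ts$levels
  p_hat <- lv$n_positive / lv$n_reactions
  informative <- p_hat > 0 & p_hat < 1
  if (!any(informative)) {
    if (all(p_hat == 1))
      stop("all titration levels saturated (every reaction positive); ",
           "re-dilute the template", call. = FALSE)
    stop("no positive reactions at any level; concentrate the template",
         call. = FALSE)
  }
  p <- p_hat[informative]
  n <- lv$n_reactions[informative]
  d <- lv$dilution_factor[informative]
  lambda <- -log(1 - p) * d                 # per unit stock volume
  # delta method: var(lambda_rxn) = p / (n (1-p)), times d^2
  v <- d^2 * p / (n * (1 - p))
  if (combine == "inverse_variance") {
    w <- 1 / v
    conc <- sum(w * lambda) / sum(w)
    var_c <- 1 / sum(w)
  } else {
    conc <- mean(lambda)
    var_c <- sum(v) / length(v)^2
  }
  structure(list(concentration = conc, variance = var_c,
                 n_levels_used = sum(informative),
                 molecule_class = ts$molecule_class),
            class = "molecule_estimate")
}

#' @export
print.molecule_estimate <- function(x, ...) {
  cat(sprintf("%s molecules: %.4g per unit volume (sd %.3g, %d levels)\n",
              x$molecule_class, x$concentration, sqrt(x$variance),
              x$n_levels_used))
  invisible(x)
}

#' Genetic distance from molecule concentrations
#'
#' Computes \code{cM = crossovers / (crossovers + parentals) * 100} from the
#' estimated concentrations of crossover and parental amplifiable molecules,
#' with a delta-method standard deviation propagated from both estimator
#' variances.
#'
#' @param xo \code{molecule_estimate} for crossover molecules.
#' @param par \code{molecule_estimate} for parental molecules.
#' @return An object of class \code{genetic_distance}: \code{cM}, \code{sd},
#'   and the two concentrations \code{crossover_conc}, \code{parental_conc}.
#' @export
genetic_distance <- function(xo, par) {
  stopifnot(inherits(xo, "molecule_estimate"), inherits(par, "molecule_estimate"))
  x <- xo$concentration; p <- par$concentration
  tot <- x + p
  if (tot <= 0)
    stop("both concentrations are zero; genetic distance undefined",
         call. = FALSE)
  cm <- 100 * x / tot
  # gradient of 100 x/(x+p): (100 p, -100 x) / (x+p)^2
  var_cm <- (100 / tot^2)^2 * (p^2 * xo$variance + x^2 * par$variance)
  structure(list(cM = cm, sd = sqrt(var_cm),
                 crossover_conc = x, parental_conc = p),
            class = "genetic_distance")
}

#' @export
print.genetic_distance <- function(x, ...) {
  cat(sprintf("genetic distance: %.4g cM (sd %.3g)\n", x$cM, x$sd))
  invisible(x)
}

#' Recombination rate in cM/Mb
#'
#' Divides the genetic distance by the physical span (panmolecule length) in
#' megabases; reported to two decimals, the precision used throughout the
#' interval and amplicon rate tables.
#'
#' @param gd A \code{genetic_distance}, or a plain cM value.
#' @param length_bp Physical span in bp (panmolecule distance).
#' @return cM/Mb, rounded to 2 decimals.
#' @export
cm_per_mb <- function(gd, length_bp) {
  cm <- if (inherits(gd, "genetic_distance")) gd$cM else as.numeric(gd)
  if (length_bp <= 0) stop("length_bp must be positive", call. = FALSE)
  round(cm / (length_bp * 1e-6), 2)
}

#' Compare two genotypes' genetic distances by a 2x2 chi-square test
#'
#' Builds a 2x2 contingency table of the per-unit-volume mean crossover and
#' parental molecule counts (rounded to the nearest integer) for two
#' genotypes and performs a Pearson chi-square test (df = 1, no continuity
#' correction).
#'
#' @param a,b \code{genetic_distance} objects carrying the underlying
#'   concentrations.
#' @param digits Rounding applied to the per-unit means before testing
#'   (default 0, i.e. nearest integer).
#' @return An object of class \code{contingency_result}: \code{chi2},
#'   \code{df}, \code{p_value} and the \code{table} used.
#' @export
compare_genetic_distance <- function(a, b, digits = 0) {
  stopifnot(inherits(a, "genetic_distance"), inherits(b, "genetic_distance"))
  tab <- round(matrix(c(a$crossover_conc, a$parental_conc,
                        b$crossover_conc, b$parental_conc),
                      nrow = 2, byrow = TRUE,
                      dimnames = list(c("a", "b"),
                                      c("crossover", "parental"))), digits)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in the 2x2 table; chi-square test undefined",
         call. = FALSE)
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  structure(list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, table = tab),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("chi-square = %.4g, df = %d, p = %.3g\n",
              x$chi2, x$df, x$p_value))
  invisible(x)
}
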