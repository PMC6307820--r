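empty_track <- function() {
  data.frame(pan_start = integer(), pan_end = integer(), kind = character(),
             weight_bp = integer(), stringsAsFactors = FALSE)
}

simple_calls <- function(starts, ends) {
  data.frame(molecule_id = sprintf("m%d", seq_along(starts)),
             status = "simple", n_transitions = 1L,
             pan_start = as.integer(starts), pan_end = as.integer(ends))
}

test_that("boundary-straddling intervals are split proportionally", {
  # two crossovers in a 150 bp interval: 50 bp in window 1, 100 bp in window 2
  wt <- window_counts(simple_calls(c(450, 450), c(601, 601)), empty_track(),
                      500, length_bp = 1000)
  expect_equal(round(wt$crossover_value, 2), c(0.67, 1.33))
  expect_equal(sum(wt$crossover_value), 2)

  # an interval entirely inside one window contributes exactly 1 there
  wt1 <- window_counts(simple_calls(100, 201), empty_track(), 500,
                       length_bp = 1000)
  expect_equal(wt1$crossover_value, c(1, 0))
})

test_that("fractional assignment conserves totals for random call sets", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 40
    s <- sample(1:4400, n)
    e <- s + sample(2:300, n, replace = TRUE)
    wt <- window_counts(simple_calls(s, pmin(e, 4499)), empty_track(), 500,
                        length_bp = 4567)
    expect_equal(sum(wt$crossover_value), n, tolerance = 1e-9)
  }
})

test_that("polymorphism weights count SNPs as one and indels by length", {
  track <- data.frame(
    pan_start = c(10L, 50L, 90L, 120L, 495L),
    pan_end = c(10L, 50L, 90L, 129L, 504L),
    kind = c("snp", "snp", "snp", "insertion_b", "insertion_a"),
    weight_bp = c(1L, 1L, 1L, 10L, 10L), stringsAsFactors = FALSE)
  wt <- window_counts(simple_calls(200, 260), track, 500, length_bp = 1000)
  # window 1: 3 SNPs + 10 bp indel + 6 bp of the straddling indel
  expect_equal(wt$polymorphism_weight, c(13 + 6, 4))
})

test_that("the final partial window is flagged and excluded", {
  wt <- window_counts(simple_calls(100, 151), empty_track(), 500,
                      length_bp = 1250)
  expect_equal(nrow(wt), 3L)
  expect_equal(wt$included, c(TRUE, TRUE, FALSE))
  expect_equal(wt$pan_end[3], 1250L)
  # an exact multiple leaves every window included
  wt2 <- window_counts(simple_calls(100, 151), empty_track(), 500,
                       length_bp = 1500)
  expect_true(all(wt2$included))
})

test_that("windowing at w then merging pairs equals windowing at 2w", {
  hp <- small_locus(seed = 83)
  pm <- hp$truth$pan
  L <- (pm$length_bp %/% 500L) * 500L   # trim to a multiple of both sizes
  sim <- sample_crossover_molecules(pm, 150, seed = 84, with_sequences = FALSE)
  calls <- call_breakpoints(sim$genotypes)
  calls <- calls[calls$pan_end - 1L <= L, , drop = FALSE]
  track <- polymorphism_track(pm)
  track <- track[track$pan_end <= L, , drop = FALSE]
  w1 <- window_counts(calls, track, 250, length_bp = L)
  w2 <- window_counts(calls, track, 500, length_bp = L)
  merged <- tapply(w1$crossover_value, (w1$window_index + 1L) %/% 2L, sum)
  expect_equal(as.numeric(merged), w2$crossover_value, tolerance = 1e-9)
  merged_p <- tapply(w1$polymorphism_weight, (w1$window_index + 1L) %/% 2L, sum)
  expect_equal(as.numeric(merged_p), w2$polymorphism_weight)
})

test_that("profile-mode windows average the weighted coverage", {
  raw <- rep(c(0L, 10L), each = 250)
  prof <- normalize_profile(raw, 5, 0.1)
  wt <- window_counts(prof, empty_track(), 250)
  expect_equal(wt$crossover_value, c(0, 10 / 5 * 0.1))
  expect_equal(attr(wt, "mode"), "profile")
})

test_that("percent normalization conserves 100% and ignores excluded windows", {
  wt <- window_counts(simple_calls(c(100, 600, 1100), c(151, 651, 1151)),
                      empty_track(), 500, length_bp = 1700)
  pn <- percent_normalize(wt)
  expect_equal(sum(pn$crossover_percent[pn$included]), 100)
  expect_true(is.na(pn$crossover_percent[!pn$included]))
  # equal values give 100/n each
  eq <- window_counts(simple_calls(c(100, 600), c(151, 651)), empty_track(),
                      500, length_bp = 1000)
  expect_equal(percent_normalize(eq)$crossover_percent, c(50, 50))
  # proportional landscapes give identical percent columns
  dbl <- eq
  dbl$crossover_value <- eq$crossover_value * 7
  expect_equal(percent_normalize(dbl)$crossover_percent,
               percent_normalize(eq)$crossover_percent)
})

test_that("Spearman correlation matches hand-ranked values", {
  expect_equal(spearman_windows(1:10, 10:1)$rho, -1)
  expect_equal(spearman_windows(1:10, (1:10)^3)$rho, 1)
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  y <- c(2, 7, 1, 8.2, 0.3, 6)
  d <- rank(x) - rank(y)
  expect_equal(spearman_windows(x, y)$rho,
               1 - 6 * sum(d^2) / (6 * (36 - 1)), tolerance = 1e-12)
  expect_error(spearman_windows(rep(1, 5), 1:5), "constant")
  expect_error(spearman_windows(1:2, 2:1), "3 paired")
})
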