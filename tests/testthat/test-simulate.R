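test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 123, length_bp = 1500)
  h1 <- make_haplotypes(cfg)
  h2 <- make_haplotypes(cfg)
  expect_identical(h1$hap_a$sequence, h2$hap_a$sequence)
  expect_identical(h1$hap_b$sequence, h2$hap_b$sequence)
  expect_identical(h1$truth$pan$positions, h2$truth$pan$positions)
  m1 <- sample_crossover_molecules(h1$truth$pan, 20, seed = 9)
  m2 <- sample_crossover_molecules(h1$truth$pan, 20, seed = 9)
  expect_identical(m1$molecules, m2$molecules)
  r1 <- make_read_pairs(m1$molecules, 50, cfg, seed = 10)
  r2 <- make_read_pairs(m1$molecules, 50, cfg, seed = 10)
  expect_identical(r1, r2)
})

test_that("zero rates give identical haplotypes", {
  cfg <- sim_config(seed = 5, length_bp = 500, snp_rate = 0, indel_rate = 0)
  hp <- make_haplotypes(cfg)
  expect_identical(hp$hap_a$sequence, hp$hap_b$sequence)
  expect_equal(hp$truth$pan$length_bp, 500L)
  expect_equal(length(hp$truth$snp_pan), 0L)
})

test_that("SNP counts concentrate around the configured rate", {
  cfg <- sim_config(seed = 6, length_bp = 100000L, snp_rate = 0.027,
                    indel_rate = 0)
  hp <- make_haplotypes(cfg)
  n_snp <- length(hp$truth$snp_pan)
  expect_lt(abs(n_snp - 2700), 3 * sqrt(100000 * 0.027 * 0.973))
})

test_that("truth panmolecule matches the aligner on well-separated events", {
  hp <- make_divergent_pair(2500, 60, 40, 50, seed = 17)
  expect_equal(nchar(hp$hap_a$sequence), 2500L)
  expect_equal(nchar(hp$hap_b$sequence), 2500L + 60L - 40L)
  expect_equal(hp$truth$n_ins_b, 60L)
  expect_equal(hp$truth$n_ins_a, 40L)
  pm <- build_panmolecule(align_haplotypes(hp$hap_a, hp$hap_b))
  cols <- c("coord_a", "coord_b", "snp", "ins_code")
  expect_identical(pm$positions[cols], hp$truth$pan$positions[cols])
})

test_that("breakpoints follow the requested landscape", {
  hp <- small_locus(seed = 41)
  pm <- hp$truth$pan
  gaps <- panxo:::marker_gaps(pm)
  # concentrated intensity: all breakpoints in the chosen interval
  w <- rep(0, nrow(gaps)); w[7] <- 1
  conc <- sample_crossover_molecules(pm, 50, landscape = list(kind = "table",
                                                              weights = w),
                                     seed = 42, with_sequences = FALSE,
                                     with_genotypes = FALSE)
  expect_true(all(conc$molecules$breakpoint >= gaps$gap_start[7] &
                    conc$molecules$breakpoint <= gaps$gap_end[7]))

  # uniform intensity: empirical CDF over eligible positions is uniform
  unif <- sample_crossover_molecules(pm, 10000, seed = 43,
                                     with_sequences = FALSE,
                                     with_genotypes = FALSE)
  eligible <- sort(unlist(mapply(seq.int, gaps$gap_start, gaps$gap_end,
                                 SIMPLIFY = FALSE)))
  ranks <- findInterval(unif$molecules$breakpoint, eligible)
  set.seed(44)
  u <- (ranks - runif(length(ranks))) / length(eligible)  # de-discretized
  ks <- suppressWarnings(ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("titration simulation matches the Poisson zero-class law", {
  ts0 <- simulate_titration(0, c(1, 2), 50, seed = 3)
  expect_true(all(ts0$levels$n_positive == 0L))
  set.seed(4)
  lam <- 2; d <- 4; n <- 40000
  ts <- simulate_titration(lam, d, n)
  p_hat <- ts$levels$n_positive / n
  p_true <- 1 - exp(-lam / d)
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
})

test_that("simulated reads are exact substrings of their source molecules", {
  hp <- small_locus(seed = 45)
  cfg <- sim_config(seed = 45, length_bp = 3000)
  sim <- sample_crossover_molecules(hp$truth$pan, 10, seed = 46)
  rp <- make_read_pairs(sim$molecules, 300, cfg, seed = 47)
  flen <- rp$frag_end - rp$frag_start + 1L
  expect_true(all(flen >= 300 & flen <= 400))
  seqs <- sim$molecules$seq[match(rp$molecule_id, sim$molecules$molecule_id)]
  left <- substr(seqs, rp$frag_start, rp$frag_start + 74L)
  right <- revcomp(substr(seqs, rp$frag_end - 74L, rp$frag_end))
  expect_identical(ifelse(rp$swapped, right, left), rp$seq1)
  expect_identical(ifelse(rp$swapped, left, right), rp$seq2)
})

test_that("sequencing errors break exact matching but not the negative control", {
  hp <- small_locus(seed = 48)
  cfg <- sim_config(seed = 48, length_bp = 3000, error_rate = 0.01)
  par <- make_parental_molecules(hp$truth$pan, 2, "A")
  rp <- make_read_pairs(par, 400, cfg, seed = 49)
  res <- classify_pairs(rp, hp$truth$pan, lower_parent = "A")
  expect_equal(nrow(res$pairs), 0L)         # errors cannot create crossovers
  expect_lt(unname(res$ledger["Mapped"]), 400L)  # but they do cost mappability
})

test_that("windows from inverse-divergence molecules show the generating relationship", {
  hp <- small_locus(seed = 95, length_bp = 6000)
  pm <- hp$truth$pan
  landscape <- list(kind = "inverse_divergence", a = 1, b = 30, c = 1,
                    window_bp = 500)
  sim <- sample_crossover_molecules(pm, 800, landscape, seed = 96,
                                    with_sequences = FALSE)
  calls <- call_breakpoints(sim$genotypes)
  track <- polymorphism_track(pm)
  wt <- window_counts(calls, track, 500, length_bp = pm$length_bp)
  # strong negative crossover-polymorphism relationship, as generated
  expect_lt(spearman_windows(wt)$rho, -0.5)
  # the fitted curve is a decreasing power law of the generating shape:
  # positive b and an exponent of the right order (window aggregation
  # attenuates c relative to the generating value)
  fit <- fit_divergence_model(wt)
  expect_gt(fit$b, 0)
  expect_gt(fit$c, 0.3)
  expect_lt(fit$c, 3)
})

test_that("the reconstructed profile tracks the true landscape", {
  hp <- small_locus(seed = 91, length_bp = 4000)
  pm <- hp$truth$pan
  cfg <- sim_config(seed = 91, length_bp = 4000)
  gaps <- panxo:::marker_gaps(pm)
  # smooth two-peak landscape (hotspot-like variation at window scale)
  mid <- (gaps$gap_start + gaps$gap_end) / 2
  w <- exp(2 * sin(2 * pi * mid / pm$length_bp)) +
    3 * exp(-((mid - 3000) / 300)^2)
  sim <- sample_crossover_molecules(pm, 1000,
                                    landscape = list(kind = "table", weights = w),
                                    seed = 93, with_genotypes = FALSE)
  rp <- make_read_pairs(sim$molecules, 12000, cfg, seed = 94)
  res <- classify_pairs(rp, pm, lower_parent = "A")
  expect_gt(nrow(res$pairs), 300)
  raw <- accumulate_coverage(res$pairs, pm)
  prof <- normalize_profile(raw, nrow(res$pairs), 0.1)
  # true per-position breakpoint intensity, window-averaged
  intensity <- numeric(pm$length_bp)
  glen <- gaps$gap_end - gaps$gap_start + 1L
  for (i in seq_len(nrow(gaps)))
    intensity[gaps$gap_start[i]:gaps$gap_end[i]] <- w[i] / glen[i]
  win <- 250L
  starts <- seq(1L, pm$length_bp - win + 1L, by = win)
  true_w <- vapply(starts, function(s) sum(intensity[s:(s + win - 1L)]),
                   numeric(1))
  rec_w <- vapply(starts, function(s) mean(prof$weighted[s:(s + win - 1L)]),
                  numeric(1))
  rho <- suppressWarnings(cor.test(true_w, rec_w, method = "spearman",
                                   exact = FALSE))$estimate
  expect_gt(unname(rho), 0.8)
})
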