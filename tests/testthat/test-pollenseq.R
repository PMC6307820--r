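make_pollenseq_fixture <- function(seed = 51) {
  hp <- small_locus(seed = seed)
  pm <- hp$truth$pan
  cfg <- sim_config(seed = seed, length_bp = 3000)
  list(hp = hp, pm = pm, cfg = cfg)
}

test_that("exact alignment finds unique, allele-specific and shared hits", {
  fx <- make_pollenseq_fixture()
  pm <- fx$pm
  # a read copied from template A at a polymorphic region: unique (A, +)
  snp_a <- pm$positions$coord_a[pm$positions$snp][10]
  read_a <- substr(pm$seq_a, snp_a - 30, snp_a + 30)
  hits <- align_exact(read_a, pm)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$template, "A")
  expect_equal(hits$strand, "+")
  expect_equal(hits$start, snp_a - 30)

  # the same window taken from B (carrying the B allele) hits B only
  snp_b <- pm$positions$coord_b[pm$positions$snp][10]
  read_b <- substr(pm$seq_b, snp_b - 30, snp_b + 30)
  hits_b <- align_exact(read_b, pm)
  expect_true(all(hits_b$template == "B"))

  # reverse-complemented reads map on the minus strand at the same start
  hits_rc <- align_exact(revcomp(read_a), pm)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$start, snp_a - 30)

  # a window between polymorphisms is present in both templates
  gaps <- panxo:::marker_gaps(pm)
  big <- gaps[which(gaps$gap_end - gaps$gap_start >= 25)[1], ]
  shared <- substr(pm$seq_a, pm$positions$coord_a[big$gap_start],
                   pm$positions$coord_a[big$gap_start] + 20)
  hits_sh <- align_exact(shared, pm)
  expect_true(all(c("A", "B") %in% hits_sh$template))

  # ambiguous bases never match
  expect_equal(nrow(align_exact("ACGTNACGT", pm)), 0L)
})

test_that("exact alignment agrees with a naive substring-scan oracle", {
  fx <- make_pollenseq_fixture(seed = 57)
  pm <- fx$pm
  set.seed(58)
  for (k in 1:60) {
    kind <- sample(c("subA", "subB", "rc", "random"), 1)
    read <- switch(kind,
      subA = { s <- sample(nchar(pm$seq_a) - 30, 1); substr(pm$seq_a, s, s + 29) },
      subB = { s <- sample(nchar(pm$seq_b) - 30, 1); substr(pm$seq_b, s, s + 29) },
      rc   = { s <- sample(nchar(pm$seq_a) - 30, 1);
               revcomp(substr(pm$seq_a, s, s + 29)) },
      random = random_seq(30))
    got <- align_exact(read, pm)
    ref <- naive_exact_hits(read, pm)
    ord <- function(d) d[order(d$template, d$strand, d$start), , drop = FALSE]
    expect_equal(unname(as.matrix(ord(got))), unname(as.matrix(ord(ref))),
                 info = paste(kind, read))
  }
})

test_that("classification accepts a constructed crossover pair with the hand-lifted span", {
  fx <- make_pollenseq_fixture(seed = 61)
  pm <- fx$pm
  sim <- sample_crossover_molecules(pm, 1, seed = 62)
  mol <- sim$molecules
  # left read: from the A-side prefix over an A-specific SNP; right read from
  # the B-side suffix; coordinates chosen from the known breakpoint
  snps <- pm$positions[pm$positions$snp, ]
  left_snp <- max(snps$pan[snps$pan <= mol$breakpoint])
  right_snp <- min(snps$pan[snps$pan > mol$breakpoint])
  a_end <- pm$positions$coord_a[left_snp] + 5L
  b_start <- pm$positions$coord_b[right_snp] - 5L
  read1 <- substr(pm$seq_a, a_end - 74L, a_end)
  read2 <- revcomp(substr(pm$seq_b, b_start, b_start + 74L))
  pair <- data.frame(pair_id = "p1", seq1 = read1, seq2 = read2)
  res <- classify_pairs(pair, pm, lower_parent = "A")
  expect_equal(nrow(res$pairs), 1L)
  # hand liftover of the inner ends
  inner_low <- lift_to_pan(pm, a_end, "A")
  inner_high <- lift_to_pan(pm, b_start, "B")
  expect_equal(res$pairs$span_start, inner_low + 1L)
  expect_equal(res$pairs$span_end, inner_high - 1L)
  expect_true(res$pairs$span_start <= mol$breakpoint + 1L)
  expect_true(res$pairs$span_end >= mol$breakpoint)
  expect_equal(unname(res$ledger["Strand"]), 1L)
})

test_that("rejections are attributed to the right cascade stage", {
  fx <- make_pollenseq_fixture(seed = 63)
  pm <- fx$pm
  snps <- pm$positions[pm$positions$snp, ]
  a_pos <- pm$positions$coord_a[snps$pan[5]]
  a_pos2 <- pm$positions$coord_a[snps$pan[40]]
  b_pos <- pm$positions$coord_b[snps$pan[40]]
  readA1 <- substr(pm$seq_a, a_pos - 37, a_pos + 37)
  readA2 <- substr(pm$seq_a, a_pos2 - 37, a_pos2 + 37)
  readB2 <- substr(pm$seq_b, b_pos - 37, b_pos + 37)
  shared0 <- pm$positions$pan[pm$positions$ins_code == 0L & !pm$positions$snp]
  # both ends on template A -> fails Matched
  both_a <- data.frame(pair_id = "pA", seq1 = readA1, seq2 = revcomp(readA2))
  res <- classify_pairs(both_a, pm, lower_parent = "A")
  expect_equal(unname(res$ledger),
               c(1L, 1L, 1L, 0L, 0L, 0L))
  # A/B pair in correct orientation but on the same strand -> fails at Strand
  same_strand <- data.frame(pair_id = "pS", seq1 = readA1, seq2 = readB2)
  res2 <- classify_pairs(same_strand, pm, lower_parent = "A")
  expect_equal(unname(res2$ledger["Orientate"]), 1L)
  expect_equal(unname(res2$ledger["Strand"]), 0L)
  # B end lower than A end required: reversed orientation dies at Orientate
  rev_or <- data.frame(pair_id = "pO", seq1 = readB2, seq2 = revcomp(readA1))
  res3 <- classify_pairs(rev_or, pm, lower_parent = "B")
  expect_equal(unname(res3$ledger["Matched"]), 1L)
  expect_equal(unname(res3$ledger["Orientate"]), 0L)
  # unmappable read (ambiguous base) dies at Mapped
  bad <- data.frame(pair_id = "pN", seq1 = "ACGTN", seq2 = readB2)
  res4 <- classify_pairs(bad, pm, lower_parent = "A")
  expect_equal(unname(res4$ledger["Mapped"]), 0L)
  # ledger is non-increasing left to right in all cases
  for (r in list(res, res2, res3, res4))
    expect_true(all(diff(unname(r$ledger)) <= 0))
})

test_that("coverage accumulation is additive over breakpoint spans", {
  fx <- make_pollenseq_fixture(seed = 65)
  pm <- fx$pm
  one <- data.frame(pair_id = "p", span_start = 1001L, span_end = 1200L,
                    frag_start = 900L, frag_end = 1300L)
  raw <- accumulate_coverage(one, pm)
  expect_equal(sum(raw), 200L)
  expect_true(all(raw[1001:1200] == 1L))
  expect_true(all(raw[-(1001:1200)] == 0L))
  expect_equal(accumulate_coverage(one[0, ], pm), integer(pm$length_bp))
  twice <- accumulate_coverage(rbind(one, one), pm)
  expect_equal(twice, 2L * raw)
})

test_that("profile normalization divides by pairs and weights by cM", {
  raw <- c(0L, 2L, 4L, 0L)
  prof <- normalize_profile(raw, 4, 0.08)
  expect_equal(prof$weighted[2], 0.04)
  expect_equal(prof$normalized, raw / 4)
  expect_true(all(prof$weighted <= 0.08 + 1e-15))
  # scaling counts and pair total together leaves the profile unchanged
  prof3 <- normalize_profile(raw * 3L, 12, 0.08)
  expect_equal(prof3$normalized, prof$normalized)
  expect_equal(prof3$weighted, prof$weighted)
  expect_error(normalize_profile(raw, 0, 0.08), "at least one")
})

test_that("fragment lengths of accepted pairs match the simulated geometry", {
  fx <- make_pollenseq_fixture(seed = 67)
  pm <- fx$pm
  sim <- sample_crossover_molecules(pm, 100, seed = 68)
  rp <- make_read_pairs(sim$molecules, 3000, fx$cfg, seed = 69)
  res <- classify_pairs(rp, pm, lower_parent = "A")
  fl <- fragment_length_histogram(res$pairs)
  expect_gt(fl$n, 50)
  # spans are never shorter than two read lengths
  expect_true(all(fl$lengths >= 2 * fx$cfg$read_len))
  # fragments are uniform on [300, 400] in molecule coordinates; on the
  # panmolecule a span can only stretch by the other parent's inserted bases
  n_ins <- sum(pm$positions$ins_code != 0L)
  expect_true(all(fl$lengths >= 300))
  expect_true(all(fl$lengths <= 400 + n_ins))
  expect_gt(fl$mean, 300)
  expect_lt(fl$mean, 420)
  one <- fragment_length_histogram(res$pairs[1, , drop = FALSE])
  expect_equal(one$n, 1L)
  expect_equal(sum(one$histogram$count), 1L)
})

test_that("reads from non-recombinant molecules are never called crossovers", {
  fx <- make_pollenseq_fixture(seed = 71)
  pm <- fx$pm
  parA <- make_parental_molecules(pm, 5, "A")
  parB <- make_parental_molecules(pm, 5, "B")
  rp <- make_read_pairs(rbind(parA, parB), 2000, fx$cfg, seed = 72)
  res <- classify_pairs(rp, pm, lower_parent = "A")
  expect_equal(nrow(res$pairs), 0L)
  expect_equal(unname(res$ledger["Matched"]), 0L)
  res_b <- classify_pairs(rp, pm, lower_parent = "B")
  expect_equal(nrow(res_b$pairs), 0L)
})

test_that("paired FASTQ round trip preserves ids and sequences", {
  fx <- make_pollenseq_fixture(seed = 73)
  sim <- sample_crossover_molecules(fx$pm, 5, seed = 74)
  rp <- make_read_pairs(sim$molecules, 20, fx$cfg, seed = 75)
  prefix <- tempfile()
  write_fastq_pairs(rp, prefix)
  back <- read_fastq_pairs(paste0(prefix, "_1.fastq"), paste0(prefix, "_2.fastq"))
  expect_equal(back$pair_id, rp$pair_id)
  expect_equal(back$seq1, rp$seq1)
  expect_equal(back$seq2, rp$seq2)
})
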