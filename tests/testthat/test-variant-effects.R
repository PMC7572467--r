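test_that("the window set overlapping a variant has 4n-2 candidates", {
  lom <- random_lom(8, 2, seed = 51)
  ctx <- substr(strrep("ACGTA", 4), 1, 15)  # width 2n-1
  cand <- oracle_candidate_scores(ctx, lom)
  expect_equal(attr(cand, "n_candidates"), 30L)  # 4n - 2 for n = 8
  expect_equal(best_window_score(ctx, lom), max(cand))
})

test_that("any context scores 0 under a flat matrix and length is checked", {
  flat <- to_log_odds(new_pwm(matrix(0.25, 4, 4), "flat"))
  expect_equal(best_window_score("ACGTACG", flat), 0)
  expect_error(best_window_score("ACGT", flat), "context length")
  # all windows N -> unscorable
  expect_true(is.na(best_window_score(strrep("N", 7), flat)))
  # a single N only removes the windows containing it
  sharp <- random_lom(4, 3, seed = 52)
  ctx <- "ACGNACG"
  expect_equal(best_window_score(ctx, sharp), oracle_best_window_score(ctx, sharp))
})

test_that("best window scores are bitwise identical to naive enumeration", {
  set.seed(61)
  for (k in 1:40) {
    n <- sample(3:6, 1)
    lom <- random_lom(n, runif(1, 0.5, 3), seed = 600 + k)
    ctx <- paste(sample(c("A", "C", "G", "T", "N"), 2 * n - 1, replace = TRUE,
                        prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    got <- best_window_score(ctx, lom)
    want <- oracle_best_window_score(ctx, lom)
    expect_identical(got, want)
  }
})

test_that("allele scoring matches the naive oracle on a toy genome", {
  g <- genome_from_seqs(c(toy = "ACGTACGT"))
  cgt <- to_log_odds(new_pwm(diag(4)[, c(2, 3, 4)], "cgt"), pseudocount = 1e-4)
  res <- score_snv(g, list(chrom = "toy", pos = 5, ref = "A", alt = "C"), cgt)
  ctx <- oracle_context("ACGTACGT", 5, 3)
  expect_identical(res$wt_score, oracle_best_window_score(ctx, cgt))
  actx <- ctx
  substr(actx, 3, 3) <- "C"
  expect_identical(res$alt_score, oracle_best_window_score(actx, cgt))
  expect_equal(res$delta, res$alt_score - res$wt_score)
  expect_error(score_snv(g, list(chrom = "toy", pos = 5, ref = "G", alt = "C"), cgt),
               "mismatch")
  expect_error(score_snv(g, list(chrom = "toy", pos = 5, ref = "A", alt = "A"), cgt),
               "ref == alt")
})

test_that("scores are invariant under reverse-complementing the genome", {
  g <- generate_genome(400, 0.45, seed = 71, chrom = "c")
  lom <- random_lom(7, 2, seed = 72)
  set.seed(73)
  pos <- sample(20:380, 30)
  ref <- substring(g$seqs[["c"]], pos, pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  fwd <- score_snvs(g, snv_df("c", pos, ref, alt), lom)
  L <- g$lengths[["c"]]
  grc <- genome_from_seqs(c(c = oracle_revcomp(g$seqs[["c"]])))
  comp <- function(b) chartr("ACGT", "TGCA", b)
  rev <- score_snvs(grc, snv_df("c", L + 1L - pos, comp(ref), comp(alt)), lom)
  expect_equal(rev$wt_score, fwd$wt_score)
  expect_equal(rev$alt_score, fwd$alt_score)
})

test_that("classification follows the threshold-crossing definitions", {
  thr <- structure(list(pwm_id = "P", alpha = 1e-4, granularity = 1e-3,
                        threshold = 3, attained_pvalue = 5e-5),
                   class = "tfbs_threshold")
  sc <- function(wt, alt) list(pwm_id = "P", wt_score = wt, alt_score = alt)
  expect_equal(classify(sc(5, 1), thr), "DISRUPTION")
  expect_equal(classify(sc(1, 5), thr), "GAIN")
  expect_equal(classify(sc(5, 4), thr), "SITE_RETAINED")
  expect_equal(classify(sc(1, 2), thr), "NO_SITE")
  # boundary: significant means >= threshold
  expect_equal(classify(sc(3, 2.999), thr), "DISRUPTION")
  expect_true(is.na(classify(sc(NA, 5), thr)))
  expect_error(classify(list(pwm_id = "Q", wt_score = 5, alt_score = 1), thr),
               "different PWMs")
})

test_that("gain and disruption are mirror images under allele swap", {
  g <- generate_genome(3000, 0.5, seed = 81, chrom = "c")
  pwm <- generate_pwm(8, 2.5, seed = 82, pwm_id = "P")
  lom <- to_log_odds(pwm)
  thr <- score_threshold(lom)
  pl <- plant_sites(g, pwm, 12, seed = 83)
  g <- pl$genome
  set.seed(84)
  pos <- seq(20L, 2980L, by = 16L)
  ref <- substring(g$seqs[["c"]], pos, pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  fwd <- score_snvs(g, snv_df("c", pos, ref, alt), lom)
  calls_fwd <- classify(fwd, thr)
  swapped <- genome_from_seqs(c(c = g$seqs[["c"]]))
  swapped <- tfbsnv:::genome_substitute(swapped, "c", pos, alt)
  bwd <- score_snvs(swapped, snv_df("c", pos, alt, ref), lom)
  calls_bwd <- classify(bwd, thr)
  expect_identical(calls_fwd == "GAIN", calls_bwd == "DISRUPTION")
  expect_identical(calls_fwd == "DISRUPTION", calls_bwd == "GAIN")
  expect_identical(calls_fwd == "SITE_RETAINED", calls_bwd == "SITE_RETAINED")
})

test_that("exhaustive scans agree with position-by-position enumeration", {
  g <- generate_genome(60, 0.5, seed = 91, chrom = "c")
  pwm <- generate_pwm(4, 4, seed = 92, pwm_id = "P")
  lom <- to_log_odds(pwm)
  thr <- structure(list(pwm_id = "P", alpha = 0.01, granularity = 1e-3,
                        threshold = score_threshold(lom, alpha = 0.02)$threshold,
                        attained_pvalue = NA), class = "tfbs_threshold")
  res <- scan_all_possible(g, NULL, lom, thr, emit_records = TRUE)
  want <- oracle_scan_counts(g$seqs[["c"]], 1:60, lom, thr$threshold)
  expect_equal(res$counts$n_total, want$n_total)
  expect_equal(res$counts$n_in_site, want$n_in_site)
  expect_equal(res$counts$n_retained, want$n_retained)
  expect_equal(res$counts$n_disrupt, want$n_disrupt)
  expect_equal(res$counts$n_gain, want$n_gain)
  expect_equal(res$counts$n_total, 3L * 60L)
  # emitted database rows all have at least one significant allele
  expect_true(all(pmax(res$records$wt_score, res$records$alt_score) >=
                    thr$threshold))
})

test_that("N-only genomes and empty regions give zero tallies", {
  gN <- genome_from_seqs(c(c = strrep("N", 50)))
  lom <- random_lom(4, 2, seed = 95)
  thr <- structure(list(pwm_id = "P", threshold = 1, alpha = 0.01,
                        granularity = 1e-3, attained_pvalue = NA),
                   class = "tfbs_threshold")
  thr$pwm_id <- lom$pwm_id
  res <- scan_all_possible(gN, NULL, lom, thr)
  expect_equal(res$n_total, 0)
  empty <- GenomicRanges::GRanges()
  g <- generate_genome(50, 0.5, seed = 96)
  res2 <- scan_all_possible(g, empty, lom, thr)
  expect_equal(res2$n_total, 0)
})
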