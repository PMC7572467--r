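test_that("mutation spectra are empirical frequencies over 12 types", {
  one <- estimate_spectrum(snv_df("c", 1:3, "A", "G"))
  expect_equal(unname(one[["A>G"]]), 1)
  expect_equal(sum(one), 1)

  all12 <- do.call(rbind, lapply(c("A", "C", "G", "T"), function(r) {
    snv_df("c", 1:3, r, setdiff(c("A", "C", "G", "T"), r))
  }))
  expect_equal(unname(unclass(estimate_spectrum(all12))), rep(1 / 12, 12))
  expect_error(estimate_spectrum(data.frame(ref = character(0),
                                            alt = character(0))), "empty")
  expect_error(mutation_spectrum(rep(1, 5)), "12 entries")
})

test_that("spectrum-matched sampling is deterministic and respects the spectrum", {
  g <- generate_genome(4000, 0.5, seed = 200)
  sp <- mutation_spectrum(c(0, 1, rep(0, 10)))  # all mass on A>G
  s1 <- sample_snvs(g, NULL, sp, 500, seed = 201)
  expect_true(all(s1$ref == "A" & s1$alt == "G"))
  s2 <- sample_snvs(g, NULL, sp, 500, seed = 201)
  expect_identical(s1, s2)
  s3 <- sample_snvs(g, NULL, sp, 500, seed = 202)
  expect_false(identical(s1, s3))
  # sampled positions really carry the reference base
  expect_true(all(substring(g$seqs[[1]], s1$pos, s1$pos) == "A"))

  gA <- genome_from_seqs(c(c = strrep("A", 100)))
  expect_error(sample_snvs(gA, NULL, mutation_spectrum(c(rep(0, 5), 1, rep(0, 6))),
                           10, seed = 1), "no 'C' bases")
})

test_that("sampled type frequencies converge to the spectrum", {
  g <- generate_genome(20000, 0.45, seed = 210)
  m <- 1e5
  s <- sample_snvs(g, NULL, uniform_spectrum(), m, seed = 211)
  freq <- unclass(estimate_spectrum(s))
  se <- sqrt((1 / 12) * (11 / 12) / m)
  expect_true(all(abs(freq - 1 / 12) <= 4 * se))
})

test_that("enumerated references equal the exhaustive scan", {
  g <- generate_genome(1200, 0.5, seed = 220)
  bank <- make_random_bank(2, lengths = 8, sharpness = 2.5, seed = 221)
  ref <- build_reference(g, NULL, bank, mode = "enumerated")
  for (id in names(bank$loms)) {
    ps <- compute_parameters(scan_all_possible(g, NULL, bank$loms[[id]],
                                               bank$thresholds[[id]]))
    expect_equal(unname(ref$means[id, ]),
                 c(ps$gainability, ps$disruptability, ps$hitability, ps$robustness))
  }
  # an enumerated reference has no null distribution to test against
  expect_null(ref$samples)
  expect_error(empirical_significance(0.1, numeric(0)), "at least 19")
})

test_that("sampled references converge to enumerated values", {
  g <- generate_genome(8000, 0.45, seed = 230)
  bank <- make_random_bank(2, lengths = 8, sharpness = 2.5, seed = 231)
  # plant sites for both PWMs so every parameter (incl. robustness) is defined
  for (k in seq_along(bank$pwms)) {
    g <- plant_sites(g, bank$pwms[[k]], 12, seed = 233 + k)$genome
  }
  enum <- build_reference(g, NULL, bank, mode = "enumerated")
  sp <- composition_spectrum(g, NULL)
  m <- 20000
  ns <- 5L
  sam <- build_reference(g, NULL, bank, mode = "sampled", spectrum = sp,
                         n_samples = ns, sample_size = m, seed = 232)
  expect_equal(dim(sam$samples), c(ns, 2L, 4L))
  total <- ns * m
  # a 3-SE band on every cell has a ~5% chance of one false alarm across
  # 8 cells, so require near-complete coverage with a 4-SE hard cap
  zs <- c()
  for (id in bank$meta$pwm_id) {
    H <- enum$means[id, "hitability"]
    checks <- c(
      hitability = sqrt(H * (1 - H) / total),
      disruptability = sqrt(enum$means[id, "disruptability"] *
                              (1 - enum$means[id, "disruptability"]) / total),
      gainability = sqrt(enum$means[id, "gainability"] *
                           (1 - enum$means[id, "gainability"]) / (total * (1 - H))),
      robustness = sqrt(enum$means[id, "robustness"] *
                          (1 - enum$means[id, "robustness"]) / (total * H))
    )
    for (p in names(checks)) {
      zs <- c(zs, abs(sam$means[id, p] - enum$means[id, p]) /
                (checks[[p]] + 1e-15))
    }
  }
  expect_gte(mean(zs <= 3), 7 / 8)
  expect_true(all(zs <= 4))
})

test_that("single-sample references degenerate gracefully", {
  g <- generate_genome(3000, 0.5, seed = 240)
  bank <- make_random_bank(1, lengths = 8, sharpness = 2.5, seed = 241)
  one <- build_reference(g, NULL, bank, mode = "sampled",
                         spectrum = uniform_spectrum(), n_samples = 1L,
                         sample_size = 2000, seed = 242)
  expect_equal(dim(one$samples)[1], 1L)
  expect_equal(unname(one$means[1, "hitability"]),
               unname(one$samples[1, 1, "hitability"]))
})

test_that("delta scores transform, cancel, and negate as expected", {
  ids <- c("P1", "P2")
  means <- matrix(c(1e-4, 2e-4, 1e-3, 5e-4, 0.01, 0.02, 0.5, 0.6),
                  nrow = 2, dimnames = list(ids, c("gainability", "disruptability",
                                                  "hitability", "robustness")))
  ref <- structure(list(mode = "enumerated", pwm_ids = ids, means = means,
                        samples = NULL, n_samples = 0L, sample_size = NA,
                        seed = 1L, spectrum = NULL), class = "baseline_ref")
  obs <- data.frame(pwm_id = ids, tf_id = c("T1", "T2"),
                    gainability = c(1e-3, 2e-4), disruptability = c(1e-3, 5e-4),
                    hitability = c(0.01, 0.02), robustness = c(0.7, 0.6),
                    stringsAsFactors = FALSE)
  dd <- delta_scores(obs, ref)
  expect_equal(dd$delta[dd$id == "P1" & dd$parameter == "gainability"], 1)
  expect_equal(dd$delta[dd$id == "P1" & dd$parameter == "robustness"],
               0.7 - 0.5)  # identity transform for robustness
  expect_equal(dd$delta[dd$id == "P2"], rep(0, 4))

  # antisymmetry: swapping observed and reference negates every delta
  ref2 <- ref
  ref2$means <- as.matrix(obs[, colnames(means)])
  rownames(ref2$means) <- ids
  obs2 <- cbind(data.frame(pwm_id = ids, tf_id = c("T1", "T2")),
                as.data.frame(means))
  dd2 <- delta_scores(obs2, ref2)
  expect_equal(dd2$delta, -dd$delta)

  # zero observed values under log10 are omitted with a message
  obs3 <- obs
  obs3$gainability[1] <- 0
  expect_message(dd3 <- delta_scores(obs3, ref), "omitted 1")
  expect_false(any(dd3$id == "P1" & dd3$parameter == "gainability"))
})

test_that("empirical significance follows the add-one rank rule", {
  samples <- as.numeric(1:100)
  top <- empirical_significance(1000, samples)
  expect_equal(top$p, 2 / 101)
  expect_equal(top$direction, "enriched")
  mid <- empirical_significance(50.5, samples)
  expect_equal(mid$p, 1)
  low <- empirical_significance(-5, samples)
  expect_equal(low$p, 2 / 101)
  expect_equal(low$direction, "depleted")

  # calibration: a draw from the null has approximately uniform p
  set.seed(250)
  ps <- replicate(400, {
    null <- rnorm(39)
    empirical_significance(rnorm(1), null)$p
  })
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
  expect_lt(mean(ps <= 0.05), 0.10)
})

test_that("reference bundles round-trip through the TSV serialization", {
  g <- generate_genome(2500, 0.5, seed = 260)
  bank <- make_random_bank(2, lengths = 8, sharpness = 2.5, seed = 261)
  ref <- build_reference(g, NULL, bank, mode = "sampled",
                         spectrum = composition_spectrum(g, NULL),
                         n_samples = 20L, sample_size = 1500, seed = 262)
  dir <- withr::local_tempdir()
  write_reference(ref, dir)
  back <- read_reference(dir)
  expect_equal(back$mode, "sampled")
  expect_equal(back$means, ref$means)
  expect_equal(back$samples, ref$samples)
  expect_equal(back$n_samples, ref$n_samples)
  expect_equal(unclass(back$spectrum), unclass(ref$spectrum))
})
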