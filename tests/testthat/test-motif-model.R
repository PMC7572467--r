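test_that("PWM files parse, normalize, and keep file order", {
  dir <- withr::local_tempdir()
  writeLines(c("Pos\tA\tC\tG\tT", "1\t1\t0\t0\t0", "2\t0\t1\t0\t0",
               "3\t0\t0\t1\t0"), file.path(dir, "onehot.txt"))
  writeLines(c("Pos\tA\tC\tG\tT", "1\t2\t2\t2\t2"), file.path(dir, "flat.txt"))
  pwms <- parse_pwm_collection(dir)
  expect_length(pwms, 2L)
  # sorted file order: flat before onehot
  expect_equal(vapply(pwms, `[[`, character(1), "pwm_id"), c("flat", "onehot"))
  expect_equal(unname(pwms[[1L]]$matrix[, 1L]), rep(0.25, 4))
  oh <- pwms[[2L]]
  expect_equal(oh$n, 3L)
  expect_equal(unname(oh$matrix), diag(4)[, 1:3])
  expect_false(oh$has_metadata)
  expect_equal(oh$family, "unknown")

  meta <- data.frame(pwm_id = "onehot", tf_id = "TF1", tf_name = "TF1",
                     family = "bHLH", stringsAsFactors = FALSE)
  pwms2 <- parse_pwm_collection(dir, metadata = meta)
  expect_true(pwms2[[2L]]$has_metadata)
  expect_equal(pwms2[[2L]]$family, "bHLH")
  expect_false(pwms2[[1L]]$has_metadata)
})

test_that("malformed PWM files are rejected with file and line", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Pos\tA\tC\tG\tT", "1\t0.2\t0.3\tx\t0.1"), f)
  expect_error(parse_pwm_collection(f), "non-numeric.*line 2")
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Pos\tA\tC\tG\tT", "1\t0.2\t0.3"), f2)
  expect_error(parse_pwm_collection(f2), "malformed.*line 2")
  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines("Pos\tA\tC\tG\tT", f3)
  expect_error(parse_pwm_collection(f3), "empty")
})

test_that("log-odds conversion follows the pseudocount formula", {
  flat <- new_pwm(matrix(0.25, 4, 3), "flat")
  lom <- to_log_odds(flat, pseudocount = 0.3)
  expect_equal(unname(lom$entries), matrix(0, 4, 3))

  onehot <- new_pwm(matrix(c(1, 0, 0, 0), 4, 1), "oh")
  lom2 <- to_log_odds(onehot, pseudocount = 1e-4)
  # hand evaluation of the formula for the matched base
  expect_equal(unname(lom2$entries["A", 1L]),
               log((1 + 0.25e-4) / (0.25 * (1 + 1e-4))))
  expect_equal(unname(lom2$entries["C", 1L]),
               log((0.25e-4) / (0.25 * (1 + 1e-4))))
  expect_error(to_log_odds(onehot, pseudocount = 0), "zero frequency")

  pos <- new_pwm(matrix(c(0.4, 0.3, 0.2, 0.1), 4, 1), "pos")
  lom3 <- to_log_odds(pos, pseudocount = 0)
  expect_equal(unname(lom3$entries[, 1L]), log(c(0.4, 0.3, 0.2, 0.1) / 0.25))
})

test_that("information content spans [0, 2n] and is symmetric", {
  flat <- new_pwm(matrix(0.25, 4, 5), "flat")
  expect_equal(information_content(flat)$total_bits, 0)
  oh1 <- new_pwm(matrix(c(1, 0, 0, 0), 4, 1), "oh1")
  expect_equal(information_content(oh1)$total_bits, 2)
  oh <- new_pwm(diag(4)[, c(1, 2, 3, 4, 1, 2)], "oh")
  ic <- information_content(oh)
  expect_equal(ic$total_bits, 12)
  expect_equal(ic$per_base_bits, 2)

  pwm <- generate_pwm(7, 1.5, seed = 11, pwm_id = "r")
  ic0 <- information_content(pwm)$total_bits
  perm <- new_pwm(pwm$matrix[, sample(7)], "perm")
  expect_equal(information_content(perm)$total_bits, ic0)
  rc <- new_pwm(pwm$matrix[4:1, 7:1], "rc")
  expect_equal(information_content(rc)$total_bits, ic0)
})

test_that("score thresholds match exhaustive enumeration", {
  for (seed in 1:12) {
    n <- 7L + (seed %% 2L)
    lom <- random_lom(n, sharpness = 1.5 + (seed %% 3) * 0.7, seed = 400 + seed)
    oracle <- oracle_threshold(lom, alpha = 1e-4, granularity = 1e-3)
    got <- tryCatch(score_threshold(lom, alpha = 1e-4, granularity = 1e-3),
                    error = function(e) NULL)
    if (is.null(oracle)) {
      expect_null(got)
    } else {
      expect_equal(got$threshold, oracle$threshold)
      expect_equal(got$attained_pvalue, oracle$attained)
    }
  }
})

test_that("threshold handles degenerate and boundary alphas", {
  lom <- random_lom(6, 2, seed = 7)
  thr1 <- score_threshold(lom, alpha = 1)
  # at alpha = 1 the minimum achievable score qualifies with p = 1
  expect_equal(thr1$attained_pvalue, 1)
  enum <- tfbsnv:::enumerate_score_distribution(lom, granularity = 1e-3)
  expect_equal(thr1$threshold, min(enum$units) * 1e-3)

  flat <- to_log_odds(new_pwm(matrix(0.25, 4, 6), "flat"))
  expect_error(score_threshold(flat, alpha = 1e-4), "no threshold attainable")
})

test_that("decreasing alpha never decreases the threshold", {
  lom <- random_lom(8, 2, seed = 21)
  alphas <- c(0.5, 0.1, 0.01, 1e-3, 1e-4)
  thrs <- vapply(alphas, function(a) score_threshold(lom, alpha = a)$threshold,
                 numeric(1))
  expect_true(all(diff(thrs) >= 0))
  for (i in seq_along(alphas)) {
    expect_lte(score_threshold(lom, alpha = alphas[[i]])$attained_pvalue,
               alphas[[i]])
  }
})

test_that("exact p-value enumeration behaves at the extremes", {
  lom <- random_lom(5, 2, seed = 31)
  enum <- tfbsnv:::enumerate_score_distribution(lom)
  expect_equal(exact_score_pvalue(lom, min(enum$score) - 1), 1)
  expect_equal(exact_score_pvalue(lom, max(enum$score) + 1e-9), 0)

  oh2 <- to_log_odds(new_pwm(diag(4)[, 1:2], "oh2"), pseudocount = 1e-4)
  maxsc <- 2 * log((1 + 0.25e-4) / (0.25 * (1 + 1e-4)))
  expect_equal(exact_score_pvalue(oh2, maxsc), 1 / 16)
  big <- random_lom(11, 2, seed = 32)
  expect_error(exact_score_pvalue(big, 0), "refused")
})

test_that("thresholds round-trip through the TSV export", {
  bank <- make_random_bank(3, lengths = 8, sharpness = 2, seed = 900)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_thresholds(bank$thresholds, path)
  back <- read_thresholds(path)
  expect_equal(names(back), names(bank$thresholds))
  for (id in names(back)) {
    expect_equal(back[[id]]$threshold, bank$thresholds[[id]]$threshold)
    expect_equal(back[[id]]$attained_pvalue,
                 bank$thresholds[[id]]$attained_pvalue)
  }
})
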