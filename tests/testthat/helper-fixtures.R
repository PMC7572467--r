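# Shared fixture builders. Banks are built from generated PWMs; seeds are
# advanced deterministically until every matrix admits a threshold at the
# requested alpha (weak short matrices cannot reach small p-values).

make_random_bank <- function(n_pwms, lengths, sharpness, seed,
                             alpha = 1e-4, granularity = 1e-3,
                             family = NULL) {
  lengths <- rep_len(lengths, n_pwms)
  sharpness <- rep_len(sharpness, n_pwms)
  pwms <- vector("list", n_pwms)
  attempt <- 0L
  for (k in seq_len(n_pwms)) {
    repeat {
      attempt <- attempt + 1L
      pwm <- generate_pwm(lengths[[k]], sharpness[[k]], seed = seed + attempt,
                          pwm_id = sprintf("PWM%03d", k),
                          tf_id = sprintf("TF%03d", k),
                          tf_name = sprintf("TF%03d", k),
                          family = if (is.null(family)) sprintf("fam%d", (k %% 4) + 1L) else family)
      ok <- tryCatch({
        score_threshold(to_log_odds(pwm), alpha = alpha, granularity = granularity)
        TRUE
      }, error = function(e) FALSE)
      if (ok) break
      if (attempt > 200L * n_pwms) stop("could not build bank")
    }
    pwms[[k]] <- pwm
  }
  motif_bank(pwms, alpha = alpha, granularity = granularity)
}

random_lom <- function(n, sharpness, seed, pwm_id = "P") {
  to_log_odds(generate_pwm(n, sharpness, seed = seed, pwm_id = pwm_id))
}

# small deterministic SNV data frame constructor
snv_df <- function(chrom, pos, ref, alt) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}
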