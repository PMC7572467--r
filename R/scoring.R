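#' Best window score of a variant context
#'
#' Considers one candidate window per start offset of the `2n - 1` bp
#' context on each strand (`4n - 2` candidates in all) and returns the
#' maximum log-odds score. Candidates truncated by the context boundary and
#' windows containing `N` (including chromosome-end positions, which are
#' N-padded) are skipped, so the windows actually scored are the ones fully
#' overlapping the central base; if every window is skipped the variant is
#' unscorable and `NA` is returned.
#'
#' @param context DNA string of length `2n - 1` centered on the variant base.
#' @param lom a `tfbs_lom`.
#' @return Maximum window score, or `NA_real_` if unscorable.
#' @export
best_window_score <- function(context, lom) {
  stopifnot(inherits(lom, "tfbs_lom"))
  w <- 2L * lom$n - 1L
  if (nchar(context) != w) {
    stop("context length ", nchar(context), " != 2n-1 = ", w)
  }
  ctx <- matrix(str_to_codes(toupper(context)), nrow = 1L)
  score_context_codes(ctx, lom)
}

# forward-strand best over the n windows of an m x (2n-1) code matrix.
# N (code 5) rows of the padded matrix carry -Inf so any window containing N
# scores -Inf and is effectively skipped.
fwd_best_scores <- function(ctx, lom) {
  n <- lom$n
  E <- rbind(lom$entries, rep(-Inf, n))
  m <- nrow(ctx)
  best <- rep(-Inf, m)
  for (j in seq_len(n)) {
    s <- numeric(m)
    for (i in seq_len(n)) {
      s <- s + E[ctx[, j + i - 1L] + (i - 1L) * 5L]
    }
    best <- pmax(best, s)
  }
  best
}

# best over both strands; reverse strand is scored by reverse-complementing
# the whole context and scanning forward, which reproduces window-by-window
# summation order of scoring each reverse-complemented window directly.
score_context_codes <- function(ctx, lom) {
  w <- 2L * lom$n - 1L
  stopifnot(ncol(ctx) == w)
  if (nrow(ctx) == 0L) return(numeric(0))
  rc <- matrix(.COMPLEMENT_CODE[ctx[, w:1L, drop = FALSE]], nrow = nrow(ctx))
  best <- pmax(fwd_best_scores(ctx, lom), fwd_best_scores(rc, lom))
  best[!is.finite(best)] <- NA_real_
  best
}

#' Score the reference and alternate alleles of SNVs against one PWM
#'
#' For each SNV the `2n - 1` bp context around the variant base is extracted
#' from the genome, the best overlapping-window score is computed for the
#' reference context and for the context with the central base substituted by
#' the alternate allele, and the difference (delta = alt - wt) is reported.
#' The same window set is used for both alleles so the delta reflects only
#' the substituted base.
#'
#' @param genome a `tfbs_genome`.
#' @param snvs data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (single upper-case bases, `ref != alt`).
#' @param lom a `tfbs_lom`.
#' @param check_ref verify that `ref` matches the genome base (default TRUE).
#' @return The input data frame with columns `pwm_id`, `wt_score`,
#'   `alt_score`, `delta` appended; unscorable alleles are `NA`.
#' @export
score_snvs <- function(genome, snvs, lom, check_ref = TRUE) {
  stopifnot(inherits(genome, "tfbs_genome"), inherits(lom, "tfbs_lom"))
  snvs <- validate_snvs(snvs)
  m <- nrow(snvs)
  wt <- alt <- rep(NA_real_, m)
  flank <- lom$n - 1L
  w <- 2L * lom$n - 1L
  for (chrom in unique(snvs$chrom)) {
    sel <- which(snvs$chrom == chrom)
    ctx_str <- extract_contexts(genome, chrom, snvs$pos[sel], flank)
    ctx <- strings_to_code_matrix(ctx_str, w)
    refcode <- .CODE_TABLE[utf8ToInt(paste(snvs$ref[sel], collapse = ""))]
    if (check_ref) {
      bad <- which(ctx[, lom$n] != refcode)
      if (length(bad)) {
        b <- sel[bad[[1L]]]
        stop("reference allele mismatch at ", snvs$chrom[b], ":", snvs$pos[b],
             " (expected ", snvs$ref[b], ")")
      }
    }
    wt[sel] <- score_context_codes(ctx, lom)
    ctx[, lom$n] <- .CODE_TABLE[utf8ToInt(paste(snvs$alt[sel], collapse = ""))]
    alt[sel] <- score_context_codes(ctx, lom)
  }
  snvs$pwm_id <- lom$pwm_id
  snvs$wt_score <- wt
  snvs$alt_score <- alt
  snvs$delta <- alt - wt
  snvs
}

#' Score a single SNV
#'
#' @inheritParams score_snvs
#' @param snv a one-row SNV data frame or a list with `chrom`, `pos`, `ref`,
#'   `alt`.
#' @return A one-row data frame as from [score_snvs()].
#' @export
score_snv <- function(genome, snv, lom, check_ref = TRUE) {
  df <- as.data.frame(snv[c("chrom", "pos", "ref", "alt")], stringsAsFactors = FALSE)
  score_snvs(genome, df, lom, check_ref = check_ref)
}

validate_snvs <- function(snvs) {
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(snvs))) {
    stop("SNV table needs columns: ", paste(need, collapse = ", "))
  }
  snvs <- as.data.frame(snvs, stringsAsFactors = FALSE)
  snvs$ref <- toupper(snvs$ref)
  snvs$alt <- toupper(snvs$alt)
  if (!all(snvs$ref %in% .BASES) || !all(snvs$alt %in% .BASES)) {
    stop("SNV alleles must be single bases in A/C/G/T")
  }
  if (any(snvs$ref == snvs$alt)) stop("SNV with ref == alt")
  snvs$pos <- as.integer(snvs$pos)
  snvs
}

#' Classify the effect of an SNV on a binding site
#'
#' Applies the threshold-crossing rule: an SNV whose wild-type score reaches
#' the threshold but whose alternate score does not is a `DISRUPTION`; the
#' opposite crossing is a `GAIN`; both above is `SITE_RETAINED`, both below
#' `NO_SITE`. "Significant" means score >= threshold, applied uniformly.
#'
#' @param scores one-row data frame (or list) with `wt_score`, `alt_score`
#'   and `pwm_id`, as produced by [score_snvs()].
#' @param thr a `tfbs_threshold` for the same PWM.
#' @return One of `"GAIN"`, `"DISRUPTION"`, `"SITE_RETAINED"`, `"NO_SITE"`,
#'   or `NA` if either allele is unscorable.
#' @export
classify <- function(scores, thr) {
  stopifnot(inherits(thr, "tfbs_threshold"))
  if (!is.null(scores$pwm_id) && !is.na(scores$pwm_id[[1L]]) &&
      scores$pwm_id[[1L]] != thr$pwm_id) {
    stop("scores (", scores$pwm_id[[1L]], ") and threshold (", thr$pwm_id,
         ") refer to different PWMs")
  }
  classify_calls(scores$wt_score, scores$alt_score, thr$threshold)
}

classify_calls <- function(wt, alt, t) {
  out <- rep(NA_character_, length(wt))
  ok <- !is.na(wt) & !is.na(alt)
  out[ok & wt >= t & alt < t] <- "DISRUPTION"
  out[ok & wt < t & alt >= t] <- "GAIN"
  out[ok & wt >= t & alt >= t] <- "SITE_RETAINED"
  out[ok & wt < t & alt < t] <- "NO_SITE"
  out
}

#' Enumerate and classify every possible SNV in a region set
#'
#' Visits every reference position inside `regions` and each of its three
#' alternate alleles, scores both alleles against the PWM and tallies the
#' effect calls. Positions whose reference base is `N`, and variants for
#' which every overlapping window is skipped, are unscorable and excluded
#' from all tallies. Contexts are drawn from the genome even where they
#' extend beyond the query regions: regions select positions, not sequence.
#'
#' @param genome a `tfbs_genome`.
#' @param regions a [GenomicRanges::GRanges] of query regions (or NULL for
#'   the whole genome).
#' @param lom a `tfbs_lom`.
#' @param thr matching `tfbs_threshold`.
#' @param emit_records also return the per-SNV rows for which at least one
#'   allele has a significant score (the altered-site database rows).
#' @return An [effect_counts()] object; with `emit_records = TRUE`, a list
#'   with elements `counts` and `records`.
#' @export
scan_all_possible <- function(genome, regions, lom, thr, emit_records = FALSE) {
  stopifnot(inherits(lom, "tfbs_lom"), inherits(thr, "tfbs_threshold"))
  if (lom$pwm_id != thr$pwm_id) stop("lom and threshold refer to different PWMs")
  pos_df <- region_positions(genome, regions)
  tallies <- c(n_total = 0, n_in_site = 0, n_retained = 0, n_disrupt = 0, n_gain = 0)
  records <- if (emit_records) list() else NULL
  t <- thr$threshold
  flank <- lom$n - 1L
  w <- 2L * lom$n - 1L
  for (chrom in unique(pos_df$chrom)) {
    pos <- pos_df$pos[pos_df$chrom == chrom]
    if (length(pos) == 0L) next
    ctx0 <- strings_to_code_matrix(extract_contexts(genome, chrom, pos, flank), w)
    refcode <- ctx0[, lom$n]
    scorable_ref <- refcode != 5L
    wt <- rep(NA_real_, length(pos))
    wt[scorable_ref] <- score_context_codes(ctx0[scorable_ref, , drop = FALSE], lom)
    for (slot in 1:3) {
      # slot-th alternate base for each reference base, in alphabetical order
      altcode <- alt_code_slot(refcode, slot)
      keep <- scorable_ref & !is.na(wt)
      if (!any(keep)) next
      ctx <- ctx0[keep, , drop = FALSE]
      ctx[, lom$n] <- altcode[keep]
      alt_sc <- score_context_codes(ctx, lom)
      ok <- !is.na(alt_sc)
      wtk <- wt[keep][ok]
      altk <- alt_sc[ok]
      in_site <- wtk >= t
      tallies["n_total"] <- tallies["n_total"] + length(wtk)
      tallies["n_in_site"] <- tallies["n_in_site"] + sum(in_site)
      tallies["n_retained"] <- tallies["n_retained"] + sum(in_site & altk >= t)
      tallies["n_disrupt"] <- tallies["n_disrupt"] + sum(in_site & altk < t)
      tallies["n_gain"] <- tallies["n_gain"] + sum(!in_site & altk >= t)
      if (emit_records) {
        sig <- pmax(wtk, altk) >= t
        if (any(sig)) {
          posk <- pos[keep][ok][sig]
          refk <- c("A", "C", "G", "T")[refcode[keep][ok][sig]]
          altb <- c("A", "C", "G", "T")[altcode[keep][ok][sig]]
          records[[length(records) + 1L]] <- data.frame(
            chrom = chrom, pos = posk, ref = refk, alt = altb,
            pwm_id = lom$pwm_id, wt_score = wtk[sig], alt_score = altk[sig],
            delta = altk[sig] - wtk[sig],
            call = classify_calls(wtk[sig], altk[sig], t),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  counts <- effect_counts(
    pwm_id = lom$pwm_id,
    n_total = as.integer(tallies[["n_total"]]),
    n_in_site = as.integer(tallies[["n_in_site"]]),
    n_retained = as.integer(tallies[["n_retained"]]),
    n_disrupt = as.integer(tallies[["n_disrupt"]]),
    n_gain = as.integer(tallies[["n_gain"]])
  )
  if (emit_records) {
    recs <- if (length(records)) do.call(rbind, records) else data.frame(
      chrom = character(0), pos = integer(0), ref = character(0),
      alt = character(0), pwm_id = character(0), wt_score = numeric(0),
      alt_score = numeric(0), delta = numeric(0), call = character(0),
      stringsAsFactors = FALSE)
    list(counts = counts, records = recs)
  } else {
    counts
  }
}

# the `slot`-th (1..3) alternate base code for each reference code, listing
# non-reference bases in alphabetical order; N refs get an arbitrary code
# (they are filtered before use)
alt_code_slot <- function(refcode, slot) {
  tab <- rbind(c(2L, 3L, 4L),   # ref A -> C G T
               c(1L, 3L, 4L),   # ref C -> A G T
               c(1L, 2L, 4L),   # ref G -> A C T
               c(1L, 2L, 3L),   # ref T -> A C G
               c(1L, 2L, 3L))   # ref N (unused)
  tab[cbind(refcode, rep(slot, length(refcode)))]
}

# tally calls from already-scored SNVs (used by sampled baselines/cohorts)
count_effects <- function(wt, alt, t, pwm_id) {
  ok <- !is.na(wt) & !is.na(alt)
  wt <- wt[ok]; alt <- alt[ok]
  in_site <- wt >= t
  effect_counts(
    pwm_id = pwm_id,
    n_total = length(wt),
    n_in_site = sum(in_site),
    n_retained = sum(in_site & alt >= t),
    n_disrupt = sum(in_site & alt < t),
    n_gain = sum(!in_site & alt >= t)
  )
}
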