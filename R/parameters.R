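#' Effect-count tallies for one PWM
#'
#' Counts of the four outcomes over a set of scored SNVs: `n_in_site` is the
#' number with a significant wild-type score, split into `n_retained` and
#' `n_disrupt` by the alternate allele; `n_gain` counts significant alternate
#' scores arising outside existing sites.
#'
#' @param pwm_id matrix identifier.
#' @param n_total scored SNVs (both alleles scorable).
#' @param n_in_site SNVs with `wt_score >= threshold`.
#' @param n_retained in-site SNVs with `alt_score >= threshold`.
#' @param n_disrupt in-site SNVs with `alt_score < threshold`.
#' @param n_gain outside-site SNVs with `alt_score >= threshold`.
#' @return An object of class `effect_counts` (also reports
#'   `n_outside = n_total - n_in_site`).
#' @export
effect_counts <- function(pwm_id, n_total, n_in_site, n_retained, n_disrupt, n_gain) {
  x <- structure(
    list(pwm_id = as.character(pwm_id), n_total = n_total, n_in_site = n_in_site,
         n_retained = n_retained, n_disrupt = n_disrupt, n_gain = n_gain,
         n_outside = n_total - n_in_site),
    class = "effect_counts"
  )
  validate_effect_counts(x)
  x
}

validate_effect_counts <- function(x) {
  vals <- unlist(x[c("n_total", "n_in_site", "n_retained", "n_disrupt",
                     "n_gain", "n_outside")])
  if (any(vals < 0)) stop("negative effect count")
  if (x$n_in_site != x$n_retained + x$n_disrupt) {
    stop("effect counts violate n_in_site = n_retained + n_disrupt")
  }
  if (x$n_gain > x$n_outside) stop("n_gain exceeds n_outside")
  invisible(x)
}

#' @exportS3Method base::print
print.effect_counts <- function(x, ...) {
  cat("effect_counts", x$pwm_id, ": total", x$n_total, "in-site", x$n_in_site,
      "( retained", x$n_retained, "/ disrupt", x$n_disrupt, ") gain",
      x$n_gain, "\n")
  invisible(x)
}

#' Compute the four binding-site parameters from effect counts
#'
#' Gainability `G = n_gain / n_outside` (probability that an SNV outside
#' existing sites creates one), disruptability `D = n_disrupt / n_total`,
#' hitability `H = n_in_site / n_total` and robustness
#' `R = n_retained / n_in_site`. The identity `D = H * (1 - R)` holds exactly
#' whenever all three are defined. `0/0` cases are returned as `NA` with the
#' corresponding `defined` flag set to `FALSE`.
#'
#' @param counts an [effect_counts()] object (or the `counts` element of a
#'   [scan_all_possible()] result).
#' @return An object of class `param_set`: list with `id`, the four
#'   parameters, and a logical `defined` vector.
#' @export
compute_parameters <- function(counts) {
  if (is.list(counts) && !inherits(counts, "effect_counts") &&
      inherits(counts$counts, "effect_counts")) {
    counts <- counts$counts
  }
  stopifnot(inherits(counts, "effect_counts"))
  validate_effect_counts(counts)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  G <- ratio(counts$n_gain, counts$n_outside)
  D <- ratio(counts$n_disrupt, counts$n_total)
  H <- ratio(counts$n_in_site, counts$n_total)
  R <- ratio(counts$n_retained, counts$n_in_site)
  vals <- c(gainability = G, disruptability = D, hitability = H, robustness = R)
  structure(
    list(id = counts$pwm_id, gainability = G, disruptability = D,
         hitability = H, robustness = R, defined = !is.na(vals)),
    class = "param_set"
  )
}

#' @exportS3Method base::print
print.param_set <- function(x, ...) {
  cat("param_set", x$id, ": G =", signif(x$gainability, 4),
      "D =", signif(x$disruptability, 4), "H =", signif(x$hitability, 4),
      "R =", signif(x$robustness, 4), "\n")
  invisible(x)
}

.PARAM_NAMES <- c("gainability", "disruptability", "hitability", "robustness")

param_set_to_row <- function(ps) {
  data.frame(id = ps$id, gainability = ps$gainability,
             disruptability = ps$disruptability, hitability = ps$hitability,
             robustness = ps$robustness, stringsAsFactors = FALSE)
}

#' Aggregate PWM-level parameters to one TF
#'
#' A TF with several PWMs is represented by the per-parameter median across
#' its matrices; undefined (0/0) values are excluded from each median rather
#' than imputed. Note the identity `D = H * (1 - R)` is not guaranteed after
#' this aggregation; it holds only at the PWM level.
#'
#' @param per_pwm list of `param_set` for PWMs of one TF.
#' @param tf_id identifier for the aggregated set (default: id of the first
#'   element).
#' @return A `param_set` at TF level.
#' @export
aggregate_tf <- function(per_pwm, tf_id = NULL) {
  if (length(per_pwm) == 0L) stop("aggregate_tf: empty input")
  vals <- vapply(.PARAM_NAMES, function(p) {
    v <- vapply(per_pwm, `[[`, numeric(1), p)
    v <- v[!is.na(v)]
    if (length(v)) median(v) else NA_real_
  }, numeric(1))
  structure(
    list(id = tf_id %||% per_pwm[[1L]]$id, gainability = vals[["gainability"]],
         disruptability = vals[["disruptability"]],
         hitability = vals[["hitability"]], robustness = vals[["robustness"]],
         defined = !is.na(vals)),
    class = "param_set"
  )
}

#' Per-PWM parameter table for a motif bank
#'
#' Runs [scan_all_possible()] (or tallies pre-scored SNVs) for every PWM in a
#' bank and returns one row per PWM with counts and parameters.
#'
#' @param genome a `tfbs_genome`.
#' @param regions a `GRanges` or NULL for whole genome.
#' @param bank a [motif_bank()].
#' @param snvs optional SNV data frame; when supplied, parameters are
#'   computed from this SNV set instead of the full enumeration.
#' @return Data frame with columns `pwm_id`, `tf_id`, `family`, counts, and
#'   the four parameters.
#' @export
pwm_parameter_table <- function(genome, regions, bank, snvs = NULL) {
  stopifnot(inherits(bank, "motif_bank"))
  rows <- lapply(names(bank$loms), function(id) {
    lom <- bank$loms[[id]]
    thr <- bank$thresholds[[id]]
    counts <- if (is.null(snvs)) {
      scan_all_possible(genome, regions, lom, thr)
    } else {
      sc <- score_snvs(genome, snvs, lom)
      count_effects(sc$wt_score, sc$alt_score, thr$threshold, id)
    }
    ps <- compute_parameters(counts)
    cbind(
      data.frame(pwm_id = id,
                 tf_id = bank$meta$tf_id[match(id, bank$meta$pwm_id)],
                 family = bank$meta$family[match(id, bank$meta$pwm_id)],
                 n_total = counts$n_total, n_in_site = counts$n_in_site,
                 n_retained = counts$n_retained, n_disrupt = counts$n_disrupt,
                 n_gain = counts$n_gain, n_outside = counts$n_outside,
                 stringsAsFactors = FALSE),
      param_set_to_row(ps)[, .PARAM_NAMES]
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate a per-PWM parameter table to TF level
#'
#' @param pwm_table data frame from [pwm_parameter_table()] (needs `tf_id`,
#'   `family` and the four parameter columns). PWMs without TF metadata
#'   (`tf_id` NA) are dropped.
#' @return Data frame with one row per TF: `tf_id`, `family`, `n_pwms`, and
#'   the per-parameter medians.
#' @export
tf_parameter_table <- function(pwm_table) {
  tab <- pwm_table[!is.na(pwm_table$tf_id), , drop = FALSE]
  if (nrow(tab) == 0L) stop("no PWMs with TF metadata")
  split_rows <- split(seq_len(nrow(tab)), tab$tf_id)
  rows <- lapply(names(split_rows), function(tf) {
    idx <- split_rows[[tf]]
    med <- vapply(.PARAM_NAMES, function(p) {
      v <- tab[[p]][idx]
      v <- v[!is.na(v)]
      if (length(v)) median(v) else NA_real_
    }, numeric(1))
    data.frame(tf_id = tf, family = tab$family[idx[[1L]]],
               n_pwms = length(idx), gainability = med[["gainability"]],
               disruptability = med[["disruptability"]],
               hitability = med[["hitability"]],
               robustness = med[["robustness"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare each TF family against all TFs
#'
#' For every family with at least `min_members` TFs and every parameter, a
#' two-sided Mann-Whitney U test of the family's values against the values
#' of all TFs (family included in the comparator, matching the
#' family-versus-all-TFs design). Families labelled `"unknown"` are excluded
#' from the family side. Undefined values are dropped, not imputed.
#'
#' @param tf_table data frame from [tf_parameter_table()].
#' @param min_members family-size floor (default 10).
#' @param test `"wilcox"` (Mann-Whitney, default) or `"kruskal"` for a
#'   single across-family Kruskal-Wallis test per parameter.
#' @return For `"wilcox"`: data frame `family`, `parameter`, `n_family`,
#'   `median_family`, `median_all`, `p_value`. For `"kruskal"`: data frame
#'   `parameter`, `p_value`, `n_families`.
#' @export
aggregate_family <- function(tf_table, min_members = 10L,
                             test = c("wilcox", "kruskal")) {
  test <- match.arg(test)
  tab <- tf_table[!is.na(tf_table$family) & tf_table$family != "unknown", ,
                  drop = FALSE]
  fam_sizes <- table(tab$family)
  keep_fams <- names(fam_sizes)[fam_sizes >= min_members]
  if (length(keep_fams) == 0L) {
    warning("no family meets the ", min_members, "-member floor")
    return(data.frame())
  }
  if (test == "kruskal") {
    sub <- tab[tab$family %in% keep_fams, , drop = FALSE]
    rows <- lapply(.PARAM_NAMES, function(p) {
      ok <- !is.na(sub[[p]])
      kt <- kruskal.test(sub[[p]][ok], factor(sub$family[ok]))
      data.frame(parameter = p, p_value = kt$p.value,
                 n_families = length(keep_fams), stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  rows <- list()
  for (fam in keep_fams) {
    for (p in .PARAM_NAMES) {
      fam_vals <- tab[[p]][tab$family == fam]
      all_vals <- tf_table[[p]]
      fam_vals <- fam_vals[!is.na(fam_vals)]
      all_vals <- all_vals[!is.na(all_vals)]
      if (length(fam_vals) == 0L || length(all_vals) == 0L) next
      wt <- suppressWarnings(wilcox.test(fam_vals, all_vals))
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, parameter = p, n_family = length(fam_vals),
        median_family = median(fam_vals), median_all = median(all_vals),
        p_value = wt$p.value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation between two per-TF parameter vectors
#'
#' @param x,y paired numeric vectors (e.g. two parameters across TFs).
#'   Undefined pairs are dropped pairwise; non-positive values are dropped
#'   when `log_transform = TRUE`.
#' @param log_transform correlate `log10` values (the convention for
#'   gainability/disruptability/hitability; robustness is used untransformed).
#' @return List with `r`, `p_value`, `n`; `r` is `NA` (with a warning) when
#'   either vector has zero variance or fewer than 3 pairs remain.
#' @export
correlate_parameters <- function(x, y, log_transform = FALSE) {
  ok <- !is.na(x) & !is.na(y)
  if (log_transform) ok <- ok & x > 0 & y > 0
  x <- x[ok]; y <- y[ok]
  if (log_transform) { x <- log10(x); y <- log10(y) }
  if (length(x) < 3L) {
    warning("fewer than 3 defined pairs; correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_, n = length(x)))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
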