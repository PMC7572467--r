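#' Mutation spectrum of an SNV set
#'
#' Empirical frequencies of the 12 ordered single-nucleotide substitution
#' types (A>C, A>G, A>T, C>A, ..., T>G), used to match random baselines to an
#' observed SNV set.
#'
#' @param snvs non-empty SNV data frame (`ref`, `alt`).
#' @return An object of class `mutation_spectrum`: named numeric vector of
#'   length 12 summing to 1.
#' @export
estimate_spectrum <- function(snvs) {
  if (is.null(snvs) || nrow(snvs) == 0L) stop("empty SNV set: spectrum undefined")
  types <- paste0(toupper(snvs$ref), ">", toupper(snvs$alt))
  if (!all(types %in% .SUB_TYPES)) stop("invalid substitution type in SNV set")
  counts <- table(factor(types, levels = .SUB_TYPES))
  mutation_spectrum(as.numeric(counts) / sum(counts))
}

#' Construct a mutation spectrum
#'
#' @param freqs 12 non-negative frequencies in the fixed substitution order
#'   (A>C, A>G, A>T, C>A, C>G, C>T, G>A, G>C, G>T, T>A, T>C, T>G); normalized
#'   to sum to 1.
#' @return A named `mutation_spectrum` vector.
#' @export
mutation_spectrum <- function(freqs) {
  if (length(freqs) != 12L) stop("a mutation spectrum has 12 entries")
  freqs <- as.numeric(freqs)
  if (any(freqs < 0) || sum(freqs) <= 0) stop("spectrum frequencies must be non-negative with positive sum")
  freqs <- freqs / sum(freqs)
  names(freqs) <- .SUB_TYPES
  structure(freqs, class = "mutation_spectrum")
}

#' Uniform mutation spectrum
#'
#' All 12 substitution types equally likely (the all-possible-SNV reference
#' frequency when the positional universe is base-composition balanced).
#'
#' @return A `mutation_spectrum`.
#' @export
uniform_spectrum <- function() mutation_spectrum(rep(1 / 12, 12L))

#' Mutation spectrum of the all-possible-SNV set of a region
#'
#' The spectrum of the full enumeration of a positional universe: each
#' reference base contributes mass proportional to its abundance in the
#' regions, split evenly over its three alternates. Sampling with this
#' spectrum converges to the enumerated (uniform all-possible-SNV) reference.
#'
#' @param genome a `tfbs_genome`.
#' @param regions a `GRanges` (or NULL for the whole genome).
#' @return A [mutation_spectrum()].
#' @export
composition_spectrum <- function(genome, regions = NULL) {
  pools <- ref_base_pools(genome, regions)
  counts <- vapply(pools, nrow, integer(1))
  if (sum(counts) == 0L) stop("regions contain no A/C/G/T bases")
  mutation_spectrum(rep(counts / sum(counts) / 3, each = 3L))
}

#' Draw random SNVs matching a mutation spectrum
#'
#' Samples `m` SNVs with replacement from the bases of `regions`: each draw
#' first picks a substitution type from the spectrum, then a position
#' uniformly among region bases whose reference nucleotide matches the
#' type's reference base. Deterministic given `seed`.
#'
#' @param genome a `tfbs_genome`.
#' @param regions a `GRanges` (or NULL for the whole genome).
#' @param spectrum a [mutation_spectrum()].
#' @param m number of SNVs to draw.
#' @param seed integer seed.
#' @return SNV data frame (`chrom`, `pos`, `ref`, `alt`), in draw order, not
#'   de-duplicated.
#' @export
sample_snvs <- function(genome, regions, spectrum, m, seed) {
  stopifnot(inherits(spectrum, "mutation_spectrum"), m >= 1)
  pools <- ref_base_pools(genome, regions)
  needed <- .BASES[vapply(.BASES, function(b) {
    any(spectrum[startsWith(.SUB_TYPES, b)] > 0)
  }, logical(1))]
  absent <- needed[vapply(needed, function(b) nrow(pools[[b]]) == 0L, logical(1))]
  if (length(absent)) {
    stop("regions contain no '", absent[[1L]],
         "' bases but the spectrum needs substitutions from it")
  }
  with_seed(seed, {
    type_idx <- sample.int(12L, m, replace = TRUE, prob = as.numeric(spectrum))
    ref <- substr(.SUB_TYPES[type_idx], 1L, 1L)
    alt <- substr(.SUB_TYPES[type_idx], 3L, 3L)
    chrom <- character(m)
    pos <- integer(m)
    for (b in .BASES) {
      sel <- which(ref == b)
      if (!length(sel)) next
      pool <- pools[[b]]
      pick <- sample.int(nrow(pool), length(sel), replace = TRUE)
      chrom[sel] <- pool$chrom[pick]
      pos[sel] <- pool$pos[pick]
    }
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  })
}

# positions of each reference base within the regions
ref_base_pools <- function(genome, regions) {
  pos_df <- region_positions(genome, regions)
  code <- integer(nrow(pos_df))
  for (ch in unique(pos_df$chrom)) {
    sel <- pos_df$chrom == ch
    code[sel] <- genome_base_codes(genome, ch, pos_df$pos[sel])
  }
  out <- lapply(1:4, function(b) pos_df[code == b, , drop = FALSE])
  names(out) <- .BASES
  out
}

#' Build a reference (baseline) parameter set
#'
#' Either enumerates all possible SNVs in the regions (`mode = "enumerated"`,
#' the uniform all-possible-SNV reference with zero sampling variance) or
#' draws `n_samples` spectrum-matched random SNV samples of `sample_size`
#' each and computes the four parameters per PWM for every sample
#' (`mode = "sampled"`); the per-PWM means across samples are the reference
#' values and the per-sample values are retained for empirical significance.
#'
#' @param genome a `tfbs_genome`.
#' @param regions a `GRanges` (or NULL).
#' @param bank a [motif_bank()].
#' @param mode `"sampled"` or `"enumerated"`.
#' @param spectrum a [mutation_spectrum()]; required for sampled mode.
#' @param n_samples number of random samples (default 100).
#' @param sample_size SNVs per sample (default 1e6).
#' @param seed master seed; child seeds are derived deterministically so any
#'   single sample can be regenerated in isolation.
#' @return An object of class `baseline_ref`: list with `mode`, `pwm_ids`,
#'   `means` (PWM x parameter matrix), `samples` (n_samples x PWM x
#'   parameter array, sampled mode only), `n_samples`, `sample_size`,
#'   `seed`, `spectrum`.
#' @export
build_reference <- function(genome, regions, bank, mode = c("sampled", "enumerated"),
                            spectrum = NULL, n_samples = 100L,
                            sample_size = 1e6, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(bank, "motif_bank"))
  ids <- names(bank$loms)
  if (mode == "enumerated") {
    means <- t(vapply(ids, function(id) {
      ps <- compute_parameters(scan_all_possible(genome, regions,
                                                 bank$loms[[id]],
                                                 bank$thresholds[[id]]))
      c(ps$gainability, ps$disruptability, ps$hitability, ps$robustness)
    }, numeric(4)))
    colnames(means) <- .PARAM_NAMES
    return(structure(list(mode = "enumerated", pwm_ids = ids, means = means,
                          samples = NULL, n_samples = 0L, sample_size = NA,
                          seed = seed, spectrum = NULL),
                     class = "baseline_ref"))
  }
  if (is.null(spectrum)) stop("sampled mode requires a mutation spectrum")
  seeds <- derive_seeds(seed, n_samples)
  samples <- array(NA_real_, dim = c(n_samples, length(ids), 4L),
                   dimnames = list(NULL, ids, .PARAM_NAMES))
  for (s in seq_len(n_samples)) {
    snvs <- sample_snvs(genome, regions, spectrum, sample_size, seeds[[s]])
    for (id in ids) {
      sc <- score_snvs(genome, snvs, bank$loms[[id]], check_ref = FALSE)
      cnt <- count_effects(sc$wt_score, sc$alt_score,
                           bank$thresholds[[id]]$threshold, id)
      ps <- compute_parameters(cnt)
      samples[s, id, ] <- c(ps$gainability, ps$disruptability,
                            ps$hitability, ps$robustness)
    }
  }
  means <- apply(samples, c(2L, 3L), function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  })
  structure(list(mode = "sampled", pwm_ids = ids, means = means,
                 samples = samples, n_samples = n_samples,
                 sample_size = sample_size, seed = seed, spectrum = spectrum),
            class = "baseline_ref")
}

#' @exportS3Method base::print
print.baseline_ref <- function(x, ...) {
  cat("baseline_ref (", x$mode, "):", length(x$pwm_ids), "PWM(s)")
  if (x$mode == "sampled") {
    cat(",", x$n_samples, "samples x", format(x$sample_size, big.mark = ","), "SNVs")
  }
  cat("\n")
  invisible(x)
}

.DEFAULT_TRANSFORMS <- c(gainability = "log10", disruptability = "log10",
                         hitability = "log10", robustness = "identity")

apply_transform <- function(x, transform) {
  if (transform == "log10") {
    out <- rep(NA_real_, length(x))
    ok <- !is.na(x) & x > 0
    out[ok] <- log10(x[ok])
    out
  } else {
    x
  }
}

#' Delta scores of observed parameters against a reference
#'
#' For each PWM (or TF) and parameter, the transformed observed value minus
#' the transformed reference value: by default `log10` for gainability,
#' disruptability and hitability and the identity for robustness. Entries
#' undefined on either side (including zero values under `log10`) are
#' omitted with a message. For a sampled reference an empirical two-sided
#' p-value per entry is included (see [empirical_significance()]).
#'
#' @param observed per-PWM parameter table ([pwm_parameter_table()] output)
#'   or a matrix/data frame with a `pwm_id` column and parameter columns.
#' @param reference a [build_reference()] result over the same PWM universe.
#' @param transforms named character vector over the four parameters with
#'   values `"log10"` or `"identity"`.
#' @param level `"pwm"` (default) or `"tf"`: with `"tf"`, per-PWM deltas are
#'   aggregated to TF medians using the `tf_id` column of `observed`.
#' @return Data frame with `id`, `parameter`, `observed`, `reference`,
#'   `delta`, and (sampled references, pwm level) `empirical_p`,
#'   `direction`.
#' @export
delta_scores <- function(observed, reference,
                         transforms = .DEFAULT_TRANSFORMS, level = c("pwm", "tf")) {
  level <- match.arg(level)
  stopifnot(inherits(reference, "baseline_ref"))
  transforms <- transforms[.PARAM_NAMES]
  if (anyNA(transforms)) stop("transforms must cover all four parameters")
  common <- intersect(observed$pwm_id, reference$pwm_ids)
  if (length(common) == 0L) stop("no PWMs shared between observed and reference")
  dropped <- 0L
  rows <- list()
  for (id in common) {
    orow <- observed[match(id, observed$pwm_id), ]
    for (p in .PARAM_NAMES) {
      obs <- apply_transform(orow[[p]], transforms[[p]])
      ref <- apply_transform(reference$means[id, p], transforms[[p]])
      if (is.na(obs) || is.na(ref)) {
        dropped <- dropped + 1L
        next
      }
      row <- data.frame(id = id, tf_id = if ("tf_id" %in% names(orow)) orow$tf_id else NA_character_,
                        parameter = p, observed = obs, reference = ref,
                        delta = obs - ref, stringsAsFactors = FALSE)
      if (reference$mode == "sampled") {
        es <- empirical_significance(orow[[p]], reference$samples[, id, p])
        row$empirical_p <- es$p
        row$direction <- es$direction
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (dropped > 0L) {
    message("delta_scores: omitted ", dropped,
            " undefined observed/reference entries")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (level == "tf") {
    if (!"tf_id" %in% names(observed)) stop("tf-level deltas need a tf_id column")
    out <- out[!is.na(out$tf_id), , drop = FALSE]
    agg <- stats::aggregate(delta ~ tf_id + parameter, data = out, FUN = median)
    names(agg)[names(agg) == "tf_id"] <- "id"
    out <- agg[order(agg$id, agg$parameter), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Empirical significance of an observed value against null samples
#'
#' Distribution-free two-sided p-value with add-one correction:
#' `p = 2 * min(r_hi, r_lo) / (n + 1)` capped at 1, where
#' `r_hi = 1 + #(samples >= observed)` and `r_lo = 1 + #(samples <= observed)`.
#' Exact under exchangeability of the observed value with the null samples.
#'
#' @param observed observed (untransformed) parameter value.
#' @param samples per-sample null values from a sampled [build_reference()].
#' @return List with `p` and `direction` (`"enriched"` when the observed
#'   value exceeds the null mean, else `"depleted"`).
#' @export
empirical_significance <- function(observed, samples) {
  samples <- samples[!is.na(samples)]
  n <- length(samples)
  if (n < 19L) stop("empirical significance needs at least 19 null samples")
  if (is.na(observed)) return(list(p = NA_real_, direction = NA_character_))
  r_hi <- 1L + sum(samples >= observed)
  r_lo <- 1L + sum(samples <= observed)
  p <- min(1, 2 * min(r_hi, r_lo) / (n + 1L))
  list(p = p, direction = if (observed >= mean(samples)) "enriched" else "depleted")
}

#' Serialize a baseline reference as a TSV bundle
#'
#' Writes `manifest.json` (mode, sizes, seed, spectrum), `means.tsv` and, for
#' sampled references, `samples.tsv` (long format), so references are
#' shareable and bit-reproducible.
#'
#' @param reference a `baseline_ref`.
#' @param dir output directory (created if needed).
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(mode = reference$mode, n_samples = reference$n_samples,
                   sample_size = reference$sample_size, seed = reference$seed,
                   pwm_ids = reference$pwm_ids,
                   spectrum = if (is.null(reference$spectrum)) NULL else as.list(unclass(reference$spectrum)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  means <- data.frame(pwm_id = rownames(reference$means), reference$means,
                      stringsAsFactors = FALSE, check.names = FALSE)
  write.table(means, file.path(dir, "means.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(reference$samples)) {
    long <- expand.grid(sample = seq_len(dim(reference$samples)[1L]),
                        pwm_id = reference$pwm_ids, parameter = .PARAM_NAMES,
                        stringsAsFactors = FALSE)
    long$value <- mapply(function(s, id, p) reference$samples[s, id, p],
                         long$sample, long$pwm_id, long$parameter)
    write.table(long, file.path(dir, "samples.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(dir)
}

#' Read a baseline reference bundle written by [write_reference()]
#'
#' @param dir bundle directory.
#' @return A `baseline_ref`.
#' @export
read_reference <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  means_df <- read.delim(file.path(dir, "means.tsv"), stringsAsFactors = FALSE)
  means <- as.matrix(means_df[, .PARAM_NAMES])
  rownames(means) <- means_df$pwm_id
  samples <- NULL
  sp <- file.path(dir, "samples.tsv")
  if (file.exists(sp)) {
    long <- read.delim(sp, stringsAsFactors = FALSE)
    ns <- max(long$sample)
    samples <- array(NA_real_, dim = c(ns, nrow(means), 4L),
                     dimnames = list(NULL, rownames(means), .PARAM_NAMES))
    samples[cbind(long$sample, match(long$pwm_id, rownames(means)),
                  match(long$parameter, .PARAM_NAMES))] <- long$value
  }
  spectrum <- if (!is.null(manifest$spectrum)) {
    mutation_spectrum(unlist(manifest$spectrum[.SUB_TYPES]))
  } else NULL
  structure(list(mode = manifest$mode, pwm_ids = rownames(means),
                 means = means, samples = samples,
                 n_samples = manifest$n_samples %||% 0L,
                 sample_size = manifest$sample_size %||% NA,
                 seed = manifest$seed, spectrum = spectrum),
            class = "baseline_ref")
}
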