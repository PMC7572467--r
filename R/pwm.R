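#' Construct a position weight matrix object
#'
#' A PWM stores per-position nucleotide frequencies (columns sum to 1) plus
#' the identity of the transcription factor it models. Columns are positions,
#' rows are A, C, G, T.
#'
#' @param mat numeric matrix, 4 rows (A, C, G, T) by n positions, or an n x 4
#'   matrix which is transposed. Columns are re-normalized to sum to 1.
#' @param pwm_id identifier of the matrix.
#' @param tf_id,tf_name,family optional TF metadata; missing family defaults
#'   to `"unknown"` and the object is flagged `has_metadata = FALSE`.
#' @return An object of class `tfbs_pwm` with fields `pwm_id`, `tf_id`,
#'   `tf_name`, `family`, `matrix` (4 x n), `n`, `has_metadata`.
#' @export
new_pwm <- function(mat, pwm_id, tf_id = NA_character_, tf_name = NA_character_,
                    family = "unknown") {
  mat <- as.matrix(mat)
  if (ncol(mat) == 4L && nrow(mat) != 4L) mat <- t(mat)
  if (nrow(mat) != 4L) stop("PWM matrix must have 4 nucleotide rows")
  if (ncol(mat) < 1L) stop("PWM must have at least one position")
  storage.mode(mat) <- "double"
  if (anyNA(mat) || any(mat < 0)) stop("PWM frequencies must be non-negative numbers")
  cs <- colSums(mat)
  if (any(cs <= 0)) stop("PWM column with zero total frequency")
  mat <- sweep(mat, 2L, cs, "/")
  dimnames(mat) <- list(.BASES, NULL)
  has_meta <- !is.na(tf_id)
  structure(
    list(pwm_id = as.character(pwm_id), tf_id = as.character(tf_id),
         tf_name = as.character(tf_name),
         family = if (is.na(family) || family == "") "unknown" else as.character(family),
         matrix = mat, n = ncol(mat), has_metadata = has_meta),
    class = "tfbs_pwm"
  )
}

#' @exportS3Method base::print
print.tfbs_pwm <- function(x, ...) {
  cat("tfbs_pwm", x$pwm_id, "(", x$n, "positions ) TF:",
      ifelse(is.na(x$tf_id), "<no metadata>", x$tf_id),
      "family:", x$family, "\n")
  invisible(x)
}

#' Parse a collection of PWM text files
#'
#' Reads one or many matrices in the tab-delimited motif-database layout
#' (header `Pos A C G T`, one row per motif position) and attaches TF
#' metadata. Rows are re-normalized to sum to 1. Matrices without a metadata
#' entry are returned flagged (`has_metadata = FALSE`, family `"unknown"`),
#' not dropped.
#'
#' @param path a single matrix file or a directory of `*.txt` files; a
#'   directory is read in sorted file order.
#' @param metadata optional metadata: a data frame or TSV path with columns
#'   `pwm_id`, `tf_id`, `tf_name`, `family`. The `pwm_id` is the file name
#'   without extension.
#' @return A list of [new_pwm()] objects.
#' @export
parse_pwm_collection <- function(path, metadata = NULL) {
  if (length(path) == 1L && dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(txt|tsv|pwm)$", full.names = TRUE)
  } else {
    files <- path
  }
  if (length(files) == 0L) stop("no PWM files found under ", path)
  meta <- NULL
  if (!is.null(metadata)) {
    meta <- if (is.character(metadata)) read.delim(metadata, stringsAsFactors = FALSE) else metadata
    need <- c("pwm_id", "tf_id", "tf_name", "family")
    missing_cols <- setdiff(need, names(meta))
    if (length(missing_cols)) stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  lapply(files, function(f) {
    pwm_id <- sub("\\.[^.]*$", "", basename(f))
    mat <- parse_pwm_file(f)
    if (!is.null(meta) && pwm_id %in% meta$pwm_id) {
      row <- meta[match(pwm_id, meta$pwm_id), ]
      new_pwm(mat, pwm_id, tf_id = row$tf_id, tf_name = row$tf_name, family = row$family)
    } else {
      new_pwm(mat, pwm_id)
    }
  })
}

# one file -> 4 x n frequency matrix (un-normalized); errors name file & line
parse_pwm_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("empty PWM matrix in ", path)
  header <- toupper(strsplit(trimws(lines[[1L]]), "[\t ]+")[[1L]])
  cols <- match(.BASES, header)
  if (anyNA(cols)) stop("PWM header must name columns A C G T in ", path)
  body <- lines[-1L]
  mat <- matrix(NA_real_, nrow = 4L, ncol = length(body))
  for (k in seq_along(body)) {
    fields <- strsplit(trimws(body[[k]]), "[\t ]+")[[1L]]
    if (length(fields) < max(cols)) {
      stop("malformed PWM row (", length(fields), " fields) in ", path, " line ", k + 1L)
    }
    vals <- suppressWarnings(as.numeric(fields[cols]))
    if (anyNA(vals)) stop("non-numeric PWM cell in ", path, " line ", k + 1L)
    mat[, k] <- vals
  }
  mat
}

#' Write a PWM in the tab-delimited motif text format
#'
#' @param pwm a `tfbs_pwm`.
#' @param path output path (conventionally `<pwm_id>.txt`).
#' @export
write_pwm <- function(pwm, path) {
  df <- data.frame(Pos = seq_len(pwm$n), t(pwm$matrix), check.names = FALSE)
  names(df) <- c("Pos", .BASES)
  write.table(format(df, digits = 10, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a PWM to a log-odds scoring matrix
#'
#' Entries are `log((f + p * b) / ((1 + p) * b))` for frequency `f`,
#' background `b` and pseudocount `p` (natural log). With the default uniform
#' background a uniform column scores 0 for every base.
#'
#' @param pwm a `tfbs_pwm`.
#' @param background nucleotide background probabilities (A, C, G, T), summing
#'   to 1; default uniform.
#' @param pseudocount non-negative additive pseudocount, applied in proportion
#'   to the background; must be positive if any frequency is 0.
#' @return An object of class `tfbs_lom` with fields `pwm_id`, `entries`
#'   (4 x n log-ratio matrix), `background`, `pseudocount`, `n`.
#' @export
to_log_odds <- function(pwm, background = rep(0.25, 4), pseudocount = 1e-4) {
  stopifnot(inherits(pwm, "tfbs_pwm"))
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6) {
    stop("background must be 4 positive probabilities summing to 1")
  }
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  if (pseudocount == 0 && any(pwm$matrix == 0)) {
    stop("zero frequency with zero pseudocount would give -Inf log-odds; ",
         "use a positive pseudocount")
  }
  E <- log((pwm$matrix + pseudocount * background) /
             ((1 + pseudocount) * background))
  dimnames(E) <- list(.BASES, NULL)
  structure(
    list(pwm_id = pwm$pwm_id, entries = E, background = as.numeric(background),
         pseudocount = pseudocount, n = pwm$n),
    class = "tfbs_lom"
  )
}

#' @exportS3Method base::print
print.tfbs_lom <- function(x, ...) {
  cat("tfbs_lom", x$pwm_id, "(", x$n, "positions ), pseudocount",
      x$pseudocount, "\n")
  invisible(x)
}

#' Information content of a PWM
#'
#' Total information content in bits, `sum_i (2 + sum_x f log2 f)` with the
#' convention `0 log 0 = 0`, and the per-position average.
#'
#' @param pwm a `tfbs_pwm`.
#' @return A list with `pwm_id`, `total_bits` and `per_base_bits`.
#' @export
information_content <- function(pwm) {
  stopifnot(inherits(pwm, "tfbs_pwm"))
  f <- pwm$matrix
  term <- ifelse(f > 0, f * log2(f), 0)
  total <- sum(2 + colSums(term))
  list(pwm_id = pwm$pwm_id, total_bits = total, per_base_bits = total / pwm$n)
}

#' Bundle PWMs with their scoring matrices and thresholds
#'
#' Convenience constructor used by the pipeline functions: converts each PWM
#' to log-odds form and calibrates its score threshold once, so downstream
#' steps (scans, baselines, cohorts) can share the result.
#'
#' @param pwms list of `tfbs_pwm`.
#' @inheritParams to_log_odds
#' @inheritParams score_threshold
#' @return An object of class `motif_bank`: list with `pwms`, `loms`,
#'   `thresholds` (all named by pwm_id) and a `meta` data frame
#'   (`pwm_id`, `tf_id`, `tf_name`, `family`, `n`, `total_bits`).
#' @export
motif_bank <- function(pwms, background = rep(0.25, 4), pseudocount = 1e-4,
                       alpha = 1e-4, granularity = 1e-3) {
  stopifnot(length(pwms) > 0L)
  ids <- vapply(pwms, `[[`, character(1), "pwm_id")
  if (anyDuplicated(ids)) stop("duplicate pwm_id in PWM collection")
  names(pwms) <- ids
  loms <- lapply(pwms, to_log_odds, background = background, pseudocount = pseudocount)
  thresholds <- lapply(loms, score_threshold, alpha = alpha, granularity = granularity)
  meta <- data.frame(
    pwm_id = ids,
    tf_id = vapply(pwms, `[[`, character(1), "tf_id"),
    tf_name = vapply(pwms, `[[`, character(1), "tf_name"),
    family = vapply(pwms, `[[`, character(1), "family"),
    n = vapply(pwms, `[[`, integer(1), "n"),
    total_bits = vapply(pwms, function(p) information_content(p)$total_bits, numeric(1)),
    stringsAsFactors = FALSE
  )
  structure(list(pwms = pwms, loms = loms, thresholds = thresholds, meta = meta),
            class = "motif_bank")
}

#' @exportS3Method base::print
print.motif_bank <- function(x, ...) {
  cat("motif_bank:", length(x$pwms), "PWM(s),",
      length(unique(stats::na.omit(x$meta$tf_id))), "TF(s)\n")
  invisible(x)
}
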