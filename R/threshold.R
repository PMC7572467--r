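#' Calibrate a PWM score threshold at a target p-value
#'
#' Computes the exact distribution of the log-odds score of a random
#' background sequence by column-wise convolution over scores discretized to
#' multiples of `granularity` (round-down, so the reported threshold is
#' conservative), and returns the smallest achievable discretized score `t`
#' with `P(score >= t) <= alpha`.
#'
#' @param lom a `tfbs_lom` scoring matrix.
#' @param alpha target p-value in (0, 1]; default `1e-4`.
#' @param granularity score-discretization step (> 0) for the dynamic
#'   program; default `1e-3` score units.
#' @return An object of class `tfbs_threshold`: list with `pwm_id`, `alpha`,
#'   `granularity`, `threshold` and `attained_pvalue`.
#' @details For a zero-information matrix every sequence attains the maximum
#'   score with probability 1, so no threshold with `alpha < 1` exists and an
#'   error `"no threshold attainable"` is raised.
#' @export
score_threshold <- function(lom, alpha = 1e-4, granularity = 1e-3) {
  stopifnot(inherits(lom, "tfbs_lom"))
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  if (!(granularity > 0)) stop("granularity must be positive")
  d <- floor(lom$entries / granularity)   # integer score units, round-down
  bg <- lom$background
  p <- 1
  base <- 0
  for (i in seq_len(lom$n)) {
    di <- d[, i]
    dmin <- min(di)
    newp <- numeric(length(p) + (max(di) - dmin))
    for (x in 1:4) {
      sh <- di[[x]] - dmin
      idx <- seq_along(p) + sh
      newp[idx] <- newp[idx] + p * bg[[x]]
    }
    p <- newp
    base <- base + dmin
  }
  tail_p <- rev(cumsum(rev(p)))           # P(score >= base + k - 1)
  supp <- which(p > 0)
  ok <- supp[tail_p[supp] <= alpha]
  if (length(ok) == 0L) {
    stop("no threshold attainable for ", lom$pwm_id, " at alpha = ", alpha)
  }
  k <- min(ok)
  structure(
    list(pwm_id = lom$pwm_id, alpha = alpha, granularity = granularity,
         threshold = (base + k - 1) * granularity,
         attained_pvalue = tail_p[[k]]),
    class = "tfbs_threshold"
  )
}

#' @exportS3Method base::print
print.tfbs_threshold <- function(x, ...) {
  cat("tfbs_threshold", x$pwm_id, ": t =", signif(x$threshold, 6),
      "( P >= t ) =", signif(x$attained_pvalue, 4), "at alpha", x$alpha, "\n")
  invisible(x)
}

#' Exact score p-value by full enumeration
#'
#' Enumerates all `4^n` sequences and their background probabilities and
#' returns `P(F(S) >= t)`. Intended as an independent check of
#' [score_threshold()] for short motifs; refuses `n > 10`.
#'
#' @param lom a `tfbs_lom`.
#' @param t score threshold.
#' @param granularity optional discretization step; when positive, column
#'   scores are rounded down to multiples of `granularity` exactly as the
#'   threshold dynamic program does, so the two operate on the same score
#'   space. Default 0 (continuous scores).
#' @return `P(F >= t)` as a scalar.
#' @export
exact_score_pvalue <- function(lom, t, granularity = 0) {
  stopifnot(inherits(lom, "tfbs_lom"))
  if (lom$n > 10L) stop("exact enumeration refused for n > 10")
  enum <- enumerate_score_distribution(lom, granularity)
  if (granularity > 0) {
    ti <- ceiling(t / granularity - 1e-9)
    sum(enum$prob[enum$units >= ti])
  } else {
    sum(enum$prob[enum$score >= t])
  }
}

# all 4^n sequence scores + probabilities; `units` are integer granules when
# granularity > 0
enumerate_score_distribution <- function(lom, granularity = 0) {
  E <- lom$entries
  if (granularity > 0) D <- floor(E / granularity)
  bg <- lom$background
  sc <- 0
  pr <- 1
  for (i in seq_len(lom$n)) {
    col <- if (granularity > 0) D[, i] else E[, i]
    sc <- as.vector(outer(sc, col, "+"))
    pr <- as.vector(outer(pr, bg, "*"))
  }
  if (granularity > 0) list(units = sc, prob = pr, score = sc * granularity)
  else list(score = sc, prob = pr)
}

#' Export calibrated thresholds as a TSV table
#'
#' @param thresholds list of `tfbs_threshold`.
#' @param path output TSV path.
#' @export
write_thresholds <- function(thresholds, path) {
  df <- do.call(rbind, lapply(thresholds, function(t) {
    data.frame(pwm_id = t$pwm_id, alpha = t$alpha, granularity = t$granularity,
               threshold = t$threshold, attained_pvalue = t$attained_pvalue,
               stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a threshold table written by [write_thresholds()]
#'
#' @param path TSV path.
#' @return Named list of `tfbs_threshold`.
#' @export
read_thresholds <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    structure(as.list(df[i, , drop = FALSE]), class = "tfbs_threshold")
  })
  names(out) <- df$pwm_id
  out
}
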