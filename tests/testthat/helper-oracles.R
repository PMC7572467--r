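# Independent reference implementations used only as test oracles.
# These deliberately avoid the package's internal code paths: windows and
# strands are enumerated one string at a time and scored by direct summation.

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
}

# score one n-length string by direct left-to-right summation of log-odds
oracle_window_score <- function(s, lom) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  sc <- 0
  for (i in seq_len(lom$n)) sc <- sc + lom$entries[ch[[i]], i]
  sc
}

# enumerate the candidate windows of a 2n-1 context: one start per context
# offset on each strand (4n-2 candidates); candidates truncated by the
# context boundary or containing N are skipped. Returns the scored values
# with the candidate count as an attribute.
oracle_candidate_scores <- function(context, lom) {
  n <- lom$n
  stopifnot(nchar(context) == 2L * n - 1L)
  out <- numeric(0)
  n_candidates <- 0L
  for (j in seq_len(2L * n - 1L)) {
    w <- substr(context, j, j + n - 1L)
    for (s in c(w, oracle_revcomp(w))) {
      n_candidates <- n_candidates + 1L
      if (nchar(s) < n || grepl("N", s, fixed = TRUE)) next
      out <- c(out, oracle_window_score(s, lom))
    }
  }
  attr(out, "n_candidates") <- n_candidates
  out
}

oracle_best_window_score <- function(context, lom) {
  sc <- oracle_candidate_scores(context, lom)
  if (length(sc) == 0L) NA_real_ else max(sc)
}

# scoring one window string at a time keeps the oracle independent of the
# package's matrix-sweep implementation


# N-padded 2n-1 context around pos, built independently of the package
oracle_context <- function(seqstr, pos, n) {
  L <- nchar(seqstr)
  idx <- (pos - n + 1L):(pos + n - 1L)
  ch <- ifelse(idx >= 1L & idx <= L,
               substring(seqstr, pmax(idx, 1L), pmax(idx, 1L)), "N")
  paste(ch, collapse = "")
}

oracle_classify <- function(wt, alt, t) {
  if (is.na(wt) || is.na(alt)) return(NA_character_)
  if (wt >= t && alt < t) "DISRUPTION"
  else if (wt < t && alt >= t) "GAIN"
  else if (wt >= t && alt >= t) "SITE_RETAINED"
  else "NO_SITE"
}

# position-by-position, allele-by-allele enumeration over a sequence interval
oracle_scan_counts <- function(seqstr, positions, lom, t) {
  n_total <- n_in_site <- n_retained <- n_disrupt <- n_gain <- 0L
  for (pos in positions) {
    ref <- substr(seqstr, pos, pos)
    if (!ref %in% c("A", "C", "G", "T")) next
    ctx <- oracle_context(seqstr, pos, lom$n)
    wt <- oracle_best_window_score(ctx, lom)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      actx <- ctx
      substr(actx, lom$n, lom$n) <- alt
      av <- oracle_best_window_score(actx, lom)
      if (is.na(wt) || is.na(av)) next
      n_total <- n_total + 1L
      if (wt >= t) {
        n_in_site <- n_in_site + 1L
        if (av >= t) n_retained <- n_retained + 1L else n_disrupt <- n_disrupt + 1L
      } else if (av >= t) {
        n_gain <- n_gain + 1L
      }
    }
  }
  list(n_total = n_total, n_in_site = n_in_site, n_retained = n_retained,
       n_disrupt = n_disrupt, n_gain = n_gain)
}

# exhaustive-enumeration threshold: smallest achievable discretized score
# whose tail probability is <= alpha
oracle_threshold <- function(lom, alpha, granularity) {
  grid <- as.matrix(expand.grid(rep(list(1:4), lom$n)))
  D <- floor(lom$entries / granularity)
  units <- rowSums(matrix(D[cbind(as.vector(grid),
                                  rep(seq_len(lom$n), each = nrow(grid)))],
                          nrow = nrow(grid)))
  prob <- apply(matrix(lom$background[grid], nrow = nrow(grid)), 1L, prod)
  agg <- rowsum(prob, units)
  u <- as.numeric(rownames(agg))
  o <- order(u)
  u <- u[o]
  tail_p <- rev(cumsum(rev(agg[o])))
  ok <- which(tail_p <= alpha)
  if (length(ok) == 0L) return(NULL)
  list(threshold = u[[min(ok)]] * granularity,
       attained = tail_p[[min(ok)]],
       next_lower = if (min(ok) > 1L) u[[min(ok) - 1L]] * granularity else NULL)
}

# O(k^3) complete-linkage agglomeration over the rows of X; returns the
# sequence of merge heights
oracle_complete_linkage_heights <- function(X) {
  euc <- function(a, b) sqrt(sum((a - b)^2))
  clusters <- lapply(seq_len(nrow(X)), identity)
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf
    bi <- bj <- NA_integer_
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        h <- -Inf
        for (a in clusters[[i]]) for (b in clusters[[j]]) {
          h <- max(h, euc(X[a, ], X[b, ]))
        }
        if (h < best) {
          best <- h
          bi <- i
          bj <- j
        }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}
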