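#' Per-group delta profiles across TFs
#'
#' For each group (cancer type, carcinogen, or individual sample) the SNV set
#' is de-duplicated, intersected with the regions, scored against every PWM
#' in the bank, converted to the four parameters, and subtracted from the
#' reference at the PWM level on the configured scale; per-TF medians over
#' defined PWM deltas form the profile columns.
#'
#' @param snv_sets named list of SNV data frames, one per group.
#' @param genome a `tfbs_genome`.
#' @param regions a `GRanges` (or NULL).
#' @param bank a [motif_bank()].
#' @param reference a [build_reference()] result.
#' @param parameter which parameter to profile (default `"gainability"`).
#' @param transforms per-parameter transform, as in [delta_scores()].
#' @return An object of class `cohort_profile`: list with `delta` (TF x
#'   group matrix), `parameter`, `transform`, `snv_counts` (per group, after
#'   dedup/intersection), `families` (per-TF family lookup).
#' @export
per_group_profiles <- function(snv_sets, genome, regions, bank, reference,
                               parameter = "gainability",
                               transforms = .DEFAULT_TRANSFORMS) {
  stopifnot(inherits(bank, "motif_bank"), inherits(reference, "baseline_ref"))
  parameter <- match.arg(parameter, .PARAM_NAMES)
  if (is.null(names(snv_sets)) || any(names(snv_sets) == "")) {
    stop("snv_sets must be a named list")
  }
  cols <- list()
  counts <- integer(0)
  for (grp in names(snv_sets)) {
    snvs <- dedupe_snvs(snv_sets[[grp]])
    if (!is.null(regions)) snvs <- snvs_in_regions(snvs, regions)
    counts[[grp]] <- nrow(snvs)
    if (nrow(snvs) == 0L) {
      warning("group ", grp, " is empty after region intersection; dropped")
      next
    }
    obs <- pwm_parameter_table(genome, regions, bank, snvs = snvs)
    dd <- delta_scores(obs, reference, transforms = transforms, level = "tf")
    dd <- dd[dd$parameter == parameter, , drop = FALSE]
    cols[[grp]] <- stats::setNames(dd$delta, dd$id)
  }
  if (length(cols) == 0L) stop("no non-empty groups")
  tf_ids <- sort(unique(unlist(lapply(cols, names))))
  mat <- vapply(cols, function(v) unname(v[tf_ids]), numeric(length(tf_ids)))
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = length(cols))
  dimnames(mat) <- list(tf_ids, names(cols))
  families <- stats::setNames(bank$meta$family, bank$meta$tf_id)
  families <- families[!is.na(names(families)) & !duplicated(names(families))]
  structure(list(delta = mat, parameter = parameter,
                 transform = transforms[[parameter]], snv_counts = counts,
                 families = families),
            class = "cohort_profile")
}

#' @exportS3Method base::print
print.cohort_profile <- function(x, ...) {
  cat("cohort_profile:", nrow(x$delta), "TF(s) x", ncol(x$delta),
      "group(s) of delta", x$parameter,
      if (x$transform == "log10") "(log10 scale)" else "", "\n")
  invisible(x)
}

#' Retain high-mutation-burden samples
#'
#' Keeps samples with strictly more than `min_snvs` unique SNVs after region
#' intersection (a sample with exactly `min_snvs` is excluded).
#'
#' @param snv_sets named list of per-sample SNV data frames.
#' @param regions optional `GRanges`; counts are computed after intersection
#'   and de-duplication.
#' @param min_snvs burden threshold (default 5000); `0` retains all samples.
#' @return List with `retained` (names) and `counts` (all samples).
#' @export
filter_high_burden <- function(snv_sets, regions = NULL, min_snvs = 5000L) {
  counts <- vapply(snv_sets, function(s) {
    s <- dedupe_snvs(s)
    if (!is.null(regions)) s <- snvs_in_regions(s, regions)
    nrow(s)
  }, integer(1))
  list(retained = names(counts)[counts > min_snvs], counts = counts)
}

#' Cluster group profiles
#'
#' Complete-linkage agglomerative clustering of the group columns of a delta
#' profile under Euclidean distance over the TF dimensions. Missing delta
#' entries are imputed as 0 for the distance computation only; all-missing
#' columns are dropped with a warning. Rows (TFs) are ordered by family
#' blocks, not clustered.
#'
#' @param profile a `cohort_profile` or a TF x group numeric matrix.
#' @return List with `hclust` (an [stats::hclust] tree over groups),
#'   `order` (group labels in dendrogram order), `newick` (the dendrogram as
#'   a Newick string), and `row_order` (TF ids grouped by family when family
#'   information is available).
#' @export
cluster_profiles <- function(profile) {
  mat <- if (inherits(profile, "cohort_profile")) profile$delta else as.matrix(profile)
  if (ncol(mat) < 2L) stop("clustering needs at least two groups")
  all_missing <- colSums(!is.na(mat)) == 0L
  if (any(all_missing)) {
    warning("dropping all-missing column(s): ",
            paste(colnames(mat)[all_missing], collapse = ", "))
    mat <- mat[, !all_missing, drop = FALSE]
  }
  mat[is.na(mat)] <- 0
  hc <- hclust(dist(t(mat), method = "euclidean"), method = "complete")
  row_order <- rownames(mat)
  if (inherits(profile, "cohort_profile") && !is.null(profile$families)) {
    fam <- profile$families[rownames(mat)]
    fam[is.na(fam)] <- "unknown"
    row_order <- rownames(mat)[order(fam, rownames(mat))]
  }
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, order = hc$labels[hc$order], newick = newick,
       row_order = row_order)
}

#' Pearson correlation between two delta signatures
#'
#' Correlates two per-TF delta vectors (e.g. a cancer-type profile against a
#' carcinogen-derived profile) over the TFs defined in both, with pairwise
#' deletion of undefined entries.
#'
#' @param profile_a,profile_b named numeric vectors of per-TF deltas.
#' @return List with `r`, `p_value`, `n`; `r = NA` if fewer than 3 shared
#'   defined TFs.
#' @export
correlate_signatures <- function(profile_a, profile_b) {
  common <- intersect(names(profile_a), names(profile_b))
  x <- profile_a[common]
  y <- profile_b[common]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) {
    warning("fewer than 3 shared defined TFs; correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_, n = sum(ok)))
  }
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Median delta per TF family and group
#'
#' @param profile a `cohort_profile`.
#' @param families optional named vector (TF id -> family); defaults to the
#'   profile's own family lookup.
#' @param min_members family-size floor over TFs present in the profile
#'   (default 10); smaller families and `"unknown"` are excluded.
#' @return Family x group matrix of median deltas (defined TF values only).
#' @export
family_medians <- function(profile, families = NULL, min_members = 10L) {
  stopifnot(inherits(profile, "cohort_profile"))
  families <- families %||% profile$families
  fam <- families[rownames(profile$delta)]
  fam[is.na(fam)] <- "unknown"
  sizes <- table(fam[fam != "unknown"])
  keep <- names(sizes)[sizes >= min_members]
  if (length(keep) == 0L) {
    warning("no family meets the ", min_members, "-member floor")
    return(matrix(numeric(0), nrow = 0L, ncol = ncol(profile$delta),
                  dimnames = list(NULL, colnames(profile$delta))))
  }
  out <- t(vapply(keep, function(f) {
    apply(profile$delta[fam == f, , drop = FALSE], 2L, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) median(v) else NA_real_
    })
  }, numeric(ncol(profile$delta))))
  dimnames(out) <- list(keep, colnames(profile$delta))
  out
}

#' Write a delta profile as TSV
#'
#' @param profile a `cohort_profile`.
#' @param path output TSV path (TF rows, group columns).
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(tf_id = rownames(profile$delta), profile$delta,
                   stringsAsFactors = FALSE, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
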