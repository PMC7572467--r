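#' Generate a random genome sequence
#'
#' Bases are drawn i.i.d. with `P(G) + P(C) = gc_content` split evenly (and
#' likewise for A/T), deterministically for a given seed.
#'
#' @param length sequence length in bp (>= 1).
#' @param gc_content GC fraction in (0, 1); default 0.41, a typical
#'   mammalian value.
#' @param seed integer seed.
#' @param chrom chromosome name (default `"chrSim"`).
#' @return A `tfbs_genome` with one chromosome.
#' @export
generate_genome <- function(length, gc_content = 0.41, seed = 1L,
                            chrom = "chrSim") {
  stopifnot(length >= 1, gc_content > 0, gc_content < 1)
  probs <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
             (1 - gc_content) / 2)
  seq <- with_seed(seed, {
    paste(sample(.BASES, length, replace = TRUE, prob = probs), collapse = "")
  })
  genome_from_seqs(stats::setNames(seq, chrom))
}

#' Generate a random PWM of controlled sharpness
#'
#' Columns are drawn from a symmetric Dirichlet distribution with
#' concentration `1 / sharpness` (near-uniform columns and information
#' content near 0 as sharpness approaches 0; near one-hot columns and
#' information content near `2n` bits for large sharpness). Expected
#' information content increases monotonically with sharpness.
#'
#' @param length motif length in positions.
#' @param sharpness non-negative concentration control; 0 gives a flat,
#'   zero-information matrix.
#' @param seed integer seed.
#' @param pwm_id,tf_id,tf_name,family metadata passed to [new_pwm()].
#' @return A `tfbs_pwm`.
#' @export
generate_pwm <- function(length, sharpness, seed = 1L, pwm_id = "simPWM",
                         tf_id = NA_character_, tf_name = NA_character_,
                         family = "unknown") {
  stopifnot(length >= 1, sharpness >= 0)
  mat <- with_seed(seed, {
    if (sharpness == 0) {
      matrix(0.25, nrow = 4L, ncol = length)
    } else {
      conc <- 1 / sharpness
      g <- matrix(stats::rgamma(4L * length, shape = conc), nrow = 4L)
      # guard against all-zero columns at extreme sharpness
      bad <- colSums(g) == 0
      if (any(bad)) {
        g[cbind(with_seed(seed + 1L, sample.int(4L, sum(bad), replace = TRUE)),
                which(bad))] <- 1
      }
      sweep(g, 2L, colSums(g), "/")
    }
  })
  new_pwm(mat, pwm_id, tf_id = tf_id, tf_name = tf_name, family = family)
}

#' Plant consensus motif instances in a genome
#'
#' Writes the PWM's consensus sequence (per-column argmax) at `count`
#' non-overlapping random positions, each on a random strand, and returns
#' the modified genome together with a registry of the planted sites.
#'
#' @param genome a `tfbs_genome`.
#' @param pwm a `tfbs_pwm`.
#' @param count number of sites to plant; `count * n` must be well below the
#'   genome length.
#' @param seed integer seed.
#' @return List with `genome` (modified) and `sites` (data frame `chrom`,
#'   `start`, `end` 1-based inclusive, `strand`).
#' @export
plant_sites <- function(genome, pwm, count, seed = 1L) {
  stopifnot(inherits(genome, "tfbs_genome"), inherits(pwm, "tfbs_pwm"))
  n <- pwm$n
  chrom <- names(genome$seqs)[[1L]]
  L <- genome$lengths[[chrom]]
  if (count * n * 3L > L) stop("too many sites for the genome length")
  consensus <- codes_to_str(apply(pwm$matrix, 2L, which.max))
  placed <- with_seed(seed, {
    starts <- integer(0)
    tries <- 0L
    while (length(starts) < count && tries < count * 200L) {
      cand <- sample.int(L - n + 1L, 1L)
      if (!any(abs(cand - starts) < n)) starts <- c(starts, cand)
      tries <- tries + 1L
    }
    if (length(starts) < count) stop("could not place non-overlapping sites")
    list(starts = sort(starts),
         strand = sample(c("+", "-"), count, replace = TRUE))
  })
  for (k in seq_len(count)) {
    s <- placed$starts[[k]]
    ins <- if (placed$strand[[k]] == "+") consensus else revcomp_string(consensus)
    genome <- genome_substitute(genome, chrom, s:(s + n - 1L),
                                strsplit(ins, "")[[1L]])
  }
  sites <- data.frame(chrom = chrom, start = placed$starts,
                      end = placed$starts + n - 1L, strand = placed$strand,
                      stringsAsFactors = FALSE)
  list(genome = genome, sites = sites)
}

#' Generate an SNV set with known ground truth
#'
#' Modes: `"neutral"` draws uniform random SNVs; `"disruptive"` emits SNVs
#' inside registered sites whose alternate allele drops the best window
#' score below the threshold (every emitted SNV classifies as DISRUPTION);
#' `"gaining"` emits SNVs at near-miss positions that raise the alternate
#' score above the threshold (every emitted SNV classifies as GAIN);
#' `"spectrum_matched"` delegates to [sample_snvs()]. Disruptive and gaining
#' candidates are found by scoring the three alternates at candidate
#' positions with the real scorer, never by heuristics, so the labels are
#' correct by construction.
#'
#' @param mode one of `"neutral"`, `"disruptive"`, `"gaining"`,
#'   `"spectrum_matched"`.
#' @param genome a `tfbs_genome`.
#' @param n number of SNVs (candidates are recycled if fewer exist for the
#'   disruptive/gaining modes; neutral draws are unique positions).
#' @param seed integer seed.
#' @param sites site registry from [plant_sites()] (disruptive mode).
#' @param lom,thr scoring matrix and threshold (disruptive/gaining modes).
#' @param regions optional `GRanges` restricting neutral/spectrum draws.
#' @param spectrum a [mutation_spectrum()] (spectrum_matched mode).
#' @return SNV data frame (`chrom`, `pos`, `ref`, `alt`).
#' @export
generate_snv_set <- function(mode = c("neutral", "disruptive", "gaining",
                                      "spectrum_matched"),
                             genome, n, seed = 1L, sites = NULL, lom = NULL,
                             thr = NULL, regions = NULL, spectrum = NULL) {
  mode <- match.arg(mode)
  if (mode == "spectrum_matched") {
    if (is.null(spectrum)) stop("spectrum_matched mode needs a spectrum")
    return(sample_snvs(genome, regions, spectrum, n, seed))
  }
  if (mode == "neutral") {
    pos_df <- region_positions(genome, regions)
    return(with_seed(seed, {
      pick <- sample.int(nrow(pos_df), min(n, nrow(pos_df)))
      chrom <- pos_df$chrom[pick]
      pos <- pos_df$pos[pick]
      ref <- character(length(pos))
      for (ch in unique(chrom)) {
        sel <- chrom == ch
        ref[sel] <- c(.BASES, "N")[genome_base_codes(genome, ch, pos[sel])]
      }
      ok <- ref %in% .BASES
      chrom <- chrom[ok]; pos <- pos[ok]; ref <- ref[ok]
      alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1L), character(1))
      dedupe_snvs(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                             stringsAsFactors = FALSE))
    }))
  }
  if (is.null(lom) || is.null(thr)) stop(mode, " mode needs lom and thr")
  candidates <- if (mode == "disruptive") {
    if (is.null(sites) || nrow(sites) == 0L) stop("disruptive mode needs planted sites")
    site_regions <- GenomicRanges::GRanges(
      sites$chrom, IRanges::IRanges(sites$start, sites$end))
    res <- scan_all_possible(genome, site_regions, lom, thr, emit_records = TRUE)
    res$records[res$records$call == "DISRUPTION", , drop = FALSE]
  } else {
    res <- scan_all_possible(genome, regions, lom, thr, emit_records = TRUE)
    res$records[res$records$call == "GAIN", , drop = FALSE]
  }
  if (nrow(candidates) == 0L) stop("no ", mode, " candidates found")
  with_seed(seed, {
    pick <- sample.int(nrow(candidates), n, replace = n > nrow(candidates))
    out <- candidates[pick, c("chrom", "pos", "ref", "alt"), drop = FALSE]
    dedupe_snvs(out)
  })
}

#' Write a complete synthetic fixture to disk
#'
#' Materializes a genome (FASTA), PWMs (motif text format + metadata TSV), a
#' planted-site registry (BED) and an SNV set (VCF) so that every parser in
#' the package can be exercised end to end on files.
#'
#' @param dir output directory.
#' @param genome a `tfbs_genome`.
#' @param pwms list of `tfbs_pwm`.
#' @param sites optional site registry data frame.
#' @param snvs optional SNV data frame.
#' @return Invisibly, the named list of written paths.
#' @export
write_fixture <- function(dir, genome, pwms, sites = NULL, snvs = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(genome = file.path(dir, "genome.fa"))
  write_genome(genome, paths$genome)
  pwm_dir <- file.path(dir, "pwms")
  dir.create(pwm_dir, showWarnings = FALSE)
  for (p in pwms) write_pwm(p, file.path(pwm_dir, paste0(p$pwm_id, ".txt")))
  paths$pwms <- pwm_dir
  meta <- data.frame(pwm_id = vapply(pwms, `[[`, character(1), "pwm_id"),
                     tf_id = vapply(pwms, `[[`, character(1), "tf_id"),
                     tf_name = vapply(pwms, `[[`, character(1), "tf_name"),
                     family = vapply(pwms, `[[`, character(1), "family"),
                     stringsAsFactors = FALSE)
  paths$metadata <- file.path(dir, "metadata.tsv")
  write.table(meta, paths$metadata, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sites)) {
    paths$sites <- file.path(dir, "sites.bed")
    gr <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$start, sites$end))
    write_bed(gr, paths$sites)
  }
  if (!is.null(snvs)) {
    paths$snvs <- file.path(dir, "snvs.vcf")
    write_vcf_snvs(snvs, paths$snvs)
  }
  invisible(paths)
}
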