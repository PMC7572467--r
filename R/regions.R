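#' Read a BED file as a region set
#'
#' BED intervals (0-based, half-open) are converted to the 1-based closed
#' [GenomicRanges::GRanges] convention used throughout the package. Rows with
#' `start >= end` are rejected with their line number.
#'
#' @param path BED path (>= 3 tab-separated columns).
#' @param strip_chr normalize chromosome names by stripping a leading
#'   `"chr"` prefix (default FALSE).
#' @return A `GRanges`.
#' @export
read_bed <- function(path, strip_chr = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 3L)) {
    stop("BED row with fewer than 3 columns at line ", which(nf < 3L)[[1L]])
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(start0) || anyNA(end0)) {
    stop("non-numeric BED coordinate at line ",
         which(is.na(start0) | is.na(end0))[[1L]])
  }
  bad <- which(start0 >= end0)
  if (length(bad)) {
    message("read_bed: rejecting ", length(bad),
            " row(s) with start >= end (first at line ", bad[[1L]], ")")
    chrom <- chrom[-bad]; start0 <- start0[-bad]; end0 <- end0[-bad]
  }
  if (strip_chr) chrom <- sub("^chr", "", chrom)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start0 + 1L, end = end0))
}

#' Write a region set as BED
#'
#' @param regions a `GRanges`.
#' @param path output path (0-based half-open coordinates).
#' @export
write_bed <- function(regions, path) {
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(regions)),
    start = GenomicRanges::start(regions) - 1L,
    end = GenomicRanges::end(regions)
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Union of a region set
#'
#' Sorts, merges overlapping and adjacent intervals, and drops strand, so the
#' result is a minimal disjoint cover (the "union of regions across samples"
#' operation).
#'
#' @param regions a `GRanges`.
#' @return A reduced `GRanges`.
#' @export
region_union <- function(regions) {
  GenomicRanges::reduce(GenomicRanges::granges(regions), ignore.strand = TRUE)
}

#' Derive promoter regions from transcription start sites
#'
#' Promoters span -2000 to +250 bp around each TSS in the direction of
#' transcription: on the plus strand bases `TSS - 2000 .. TSS + 250`
#' (1-based, inclusive; 2251 bp when unclipped), mirrored on the minus
#' strand. Regions are clipped at chromosome ends when a genome is supplied
#' and returned as their union.
#'
#' @param tss data frame with columns `chrom`, `tss_pos` (1-based), `strand`
#'   (`"+"`/`"-"`), and optionally `gene_id`.
#' @param genome optional `tfbs_genome` used to clip at chromosome ends and
#'   to skip rows on unknown chromosomes (with a message).
#' @param upstream,downstream distances in bp; defaults 2000 and 250.
#' @return A reduced, unstranded `GRanges`.
#' @export
promoters_from_tss <- function(tss, genome = NULL, upstream = 2000L,
                               downstream = 250L) {
  need <- c("chrom", "tss_pos", "strand")
  if (!all(need %in% names(tss))) {
    stop("TSS table needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(tss$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!is.null(genome)) {
    known <- tss$chrom %in% names(genome$seqs)
    if (!all(known)) {
      message("promoters_from_tss: skipping ", sum(!known),
              " row(s) on unknown chromosomes")
      tss <- tss[known, , drop = FALSE]
    }
  }
  if (nrow(tss) == 0L) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(
    tss$chrom,
    IRanges::IRanges(start = tss$tss_pos, width = 1L),
    strand = tss$strand
  )
  prom <- GenomicRanges::promoters(gr, upstream = upstream,
                                   downstream = downstream + 1L)
  if (!is.null(genome)) {
    # assigning seqlengths warns about the not-yet-trimmed ranges
    suppressWarnings(GenomeInfoDb::seqlengths(prom) <-
                       genome$lengths[GenomeInfoDb::seqlevels(prom)])
    prom <- GenomicRanges::trim(prom)
  } else {
    # clip at position 1 only
    GenomicRanges::start(prom) <- pmax(GenomicRanges::start(prom), 1L)
  }
  region_union(prom)
}

#' Read biallelic SNVs from a VCF file
#'
#' Multiallelic records are split into one SNV per alternate allele; indels
#' and non-ACGT alleles are skipped (with a message giving the count);
#' duplicate (chrom, pos, ref, alt) records are collapsed to one. When
#' `regions` is supplied only SNVs inside an interval are kept; when a
#' genome is supplied the reference allele is checked against it.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param regions optional `GRanges` filter.
#' @param genome optional `tfbs_genome` for reference-allele checking.
#' @param strip_chr normalize chromosome names by stripping `"chr"`.
#' @return Data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
read_vcf_snvs <- function(path, regions = NULL, genome = NULL, strip_chr = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1L, dimnames = list(NULL, names(fx)))
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0)))
  }
  chrom <- fix$CHROM
  if (strip_chr) chrom <- sub("^chr", "", chrom)
  pos <- as.integer(fix$POS)
  ref <- toupper(fix$REF)
  alt_field <- toupper(fix$ALT)
  alts <- strsplit(ifelse(is.na(alt_field), "", alt_field), ",", fixed = TRUE)
  nalt <- lengths(alts)
  df <- data.frame(
    chrom = rep(chrom, nalt), pos = rep(pos, nalt), ref = rep(ref, nalt),
    alt = unlist(alts, use.names = FALSE), stringsAsFactors = FALSE
  )
  keep <- df$ref %in% .BASES & df$alt %in% .BASES & df$ref != df$alt
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message("read_vcf_snvs: skipped ", n_skipped,
            " non-SNV allele record(s) (indels/multi-base/identity)")
  }
  df <- df[keep, , drop = FALSE]
  df <- dedupe_snvs(df)
  if (!is.null(regions)) df <- snvs_in_regions(df, regions)
  if (!is.null(genome) && nrow(df) > 0L) {
    for (ch in unique(df$chrom)) {
      sel <- df$chrom == ch
      gref <- genome_base_codes(genome, ch, df$pos[sel])
      want <- .CODE_TABLE[utf8ToInt(paste(df$ref[sel], collapse = ""))]
      if (any(gref != want)) {
        i <- which(sel)[which(gref != want)[[1L]]]
        stop("VCF reference mismatch at ", df$chrom[i], ":", df$pos[i])
      }
    }
  }
  df
}

#' Deduplicate an SNV table
#'
#' Collapses identical (chrom, pos, ref, alt) rows, yielding the unique SNV
#' set used for all parameter calculations.
#'
#' @param snvs SNV data frame.
#' @return De-duplicated data frame, ordered by chrom then pos.
#' @export
dedupe_snvs <- function(snvs) {
  key <- paste(snvs$chrom, snvs$pos, snvs$ref, snvs$alt, sep = "\r")
  out <- snvs[!duplicated(key), , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep only SNVs inside a region set
#'
#' @param snvs SNV data frame (`chrom`, `pos` 1-based).
#' @param regions a `GRanges`.
#' @return Filtered data frame.
#' @export
snvs_in_regions <- function(snvs, regions) {
  if (nrow(snvs) == 0L) return(snvs)
  gr <- GenomicRanges::GRanges(snvs$chrom, IRanges::IRanges(snvs$pos, width = 1L))
  hits <- IRanges::overlapsAny(gr, regions, ignore.strand = TRUE)
  out <- snvs[hits, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write SNVs as a minimal VCF
#'
#' @param snvs SNV data frame.
#' @param path output path.
#' @export
write_vcf_snvs <- function(snvs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(snvs) > 0L) {
    writeLines(paste(snvs$chrom, snvs$pos, ".", snvs$ref, snvs$alt, ".", ".",
                     ".", sep = "\t"), con)
  }
  invisible(path)
}

# every 1-based position covered by the (reduced) regions; NULL regions means
# the whole genome
region_positions <- function(genome, regions = NULL) {
  if (is.null(regions)) {
    chroms <- names(genome$seqs)
    return(data.frame(
      chrom = rep(chroms, genome$lengths),
      pos = unlist(lapply(genome$lengths, seq_len), use.names = FALSE),
      stringsAsFactors = FALSE))
  }
  red <- region_union(regions)
  if (length(red) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0)))
  }
  chrom <- as.character(GenomeInfoDb::seqnames(red))
  st <- GenomicRanges::start(red)
  en <- GenomicRanges::end(red)
  if (!is.null(genome)) {
    L <- genome$lengths[chrom]
    if (anyNA(L)) stop("regions on unknown chromosome: ",
                       chrom[which(is.na(L))[[1L]]])
    en <- pmin(en, L)
    keep <- st <= en
    chrom <- chrom[keep]; st <- st[keep]; en <- en[keep]
  }
  data.frame(
    chrom = rep(chrom, en - st + 1L),
    pos = unlist(mapply(seq.int, st, en, SIMPLIFY = FALSE), use.names = FALSE),
    stringsAsFactors = FALSE
  )
}
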