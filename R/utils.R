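#' @keywords internal
"_PACKAGE"

#' @importFrom stats median cor.test wilcox.test kruskal.test hclust dist runif
#' @importFrom utils read.delim write.table read.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.BASES <- c("A", "C", "G", "T")

# nucleotide substitution types in fixed order: for each ref A,C,G,T the three
# alternates in alphabetical order
.SUB_TYPES <- {
  out <- character(0)
  for (r in .BASES) for (a in setdiff(.BASES, r)) out <- c(out, paste0(r, ">", a))
  out
}

# ASCII -> base code lookup: A=1 C=2 G=3 T=4, anything else (incl. N) = 5
.CODE_TABLE <- {
  tab <- rep(5L, 256L)
  tab[utf8ToInt("A")] <- 1L; tab[utf8ToInt("a")] <- 1L
  tab[utf8ToInt("C")] <- 2L; tab[utf8ToInt("c")] <- 2L
  tab[utf8ToInt("G")] <- 3L; tab[utf8ToInt("g")] <- 3L
  tab[utf8ToInt("T")] <- 4L; tab[utf8ToInt("t")] <- 4L
  tab
}

.COMPLEMENT_CODE <- c(4L, 3L, 2L, 1L, 5L)

str_to_codes <- function(s) .CODE_TABLE[utf8ToInt(s)]

codes_to_str <- function(codes) {
  chars <- c("A", "C", "G", "T", "N")[codes]
  paste(chars, collapse = "")
}

# strings of equal width -> m x w integer code matrix
strings_to_code_matrix <- function(x, width) {
  if (length(x) == 0L) return(matrix(integer(0), nrow = 0L, ncol = width))
  codes <- .CODE_TABLE[utf8ToInt(paste(x, collapse = ""))]
  matrix(codes, nrow = length(x), ncol = width, byrow = TRUE)
}

# Evaluate `code` with the RNG seeded to `seed`, restoring RNG state afterwards
# so seeded helpers do not perturb the caller's random stream.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Deterministically spawn k child seeds (< 2^31) from one master seed so any
# individual random sample can be regenerated in isolation.
derive_seeds <- function(master_seed, k) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, k))
}

revcomp_string <- function(s) {
  codes_to_str(rev(.COMPLEMENT_CODE[str_to_codes(s)]))
}
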