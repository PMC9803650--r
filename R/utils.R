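#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif setNames
#' @importFrom utils read.table write.table
NULL

# Run `expr` under a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Stable sub-seed derivation so each pipeline stage has its own stream.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 101 + offset) %% 2147483647L)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Parse diploid GT strings ("0/1", "1|1", "./.", "0/.") into a 2 x n integer
# matrix of allele indices; any half-call or malformed entry becomes NA/NA.
parse_gt <- function(gt) {
  gt <- as.character(gt)
  parts <- strsplit(gt, "[/|]")
  out <- vapply(parts, function(p) {
    if (length(p) != 2L || any(p == ".") || anyNA(suppressWarnings(as.integer(p)))) {
      return(c(NA_integer_, NA_integer_))
    }
    as.integer(p)
  }, integer(2))
  out
}

format_gt <- function(a1, a2) {
  ifelse(is.na(a1) | is.na(a2), "./.",
         paste(pmin(a1, a2), pmax(a1, a2), sep = "/"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
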