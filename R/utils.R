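# Internal helpers shared across modules.

# Run code with a temporary RNG state derived from `seed`, restoring the
# caller's RNG afterwards. All generators funnel randomness through this so
# results are pure functions of (inputs, seed).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a child seed from a parent seed and a stage label; keeps every draw
# traceable to the single configured seed while decorrelating stages.
child_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h %% 100003) %% 2000000011)
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over character DNA sequences.
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Complement without reversal, vectorised over single characters or strings.
complement_chars <- function(x) chartr("ACGTN", "TGCAN", x)

# Phred+33 helpers --------------------------------------------------------

phred_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

int_to_phred <- function(q) {
  vapply(q, function(v) intToUtf8(v + 33L), character(1))
}

# Hamming distance between two equal-length strings (fast raw comparison).
str_mismatches <- function(a, b) {
  if (length(a) == 0) return(integer(0))
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b, USE.NAMES = FALSE)
}

# Assemble per-molecule sequences from a character matrix (rows = molecules).
rows_to_strings <- function(m) {
  if (nrow(m) == 0) return(character(0))
  apply(m, 1, paste0, collapse = "")
}

chrom_lengths_of <- function(ref) {
  vapply(ref, nchar, integer(1))
}

stop_if_not_ref <- function(ref) {
  if (!is.character(ref) || is.null(names(ref)) || any(!nzchar(names(ref)))) {
    stop("reference must be a named character vector of chromosome sequences",
         call. = FALSE)
  }
  invisible(ref)
}
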