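# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# Encode a character vector of equal-length sequences as an L x n integer
# matrix (A=1, C=2, G=3, T=4, anything else NA). Column per record.
encode_seqs <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    stop("sequences differ in aligned length")
  }
  m <- matrix(match(unlist(strsplit(toupper(seqs), "", fixed = TRUE)), BASES),
              nrow = lens[1L])
  m
}

strip_gaps <- function(sequence) gsub("-", "", sequence, fixed = TRUE)

# Trim leading/trailing gap runs; keeps interior gaps.
trim_terminal_gaps <- function(sequence) {
  sub("-+$", "", sub("^-+", "", sequence))
}

# Evaluate expr with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards.
with_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Standard error of the mean; 0 for a single value (degenerate convention).
se_mean <- function(x) {
  n <- length(x)
  if (n <= 1L) return(0)
  stats::sd(x) / sqrt(n)
}
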