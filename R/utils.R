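## Internal helpers shared across modules. Sequences are plain character
## strings over {A,C,G,T}; coordinates are 0-based half-open internally and
## converted to 1-based inclusive only at GFF3 boundaries.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x character scalar over the DNA alphabet.
#' @return character scalar, the reverse complement.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Random DNA of length n with optional per-base probabilities (A,C,G,T).
random_dna <- function(n, probs = rep(0.25, 4)) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = probs), collapse = "")
}

## Substitute exactly `k` positions of `x` (each to a different base).
## Hamming distance to the input is exactly k by construction.
mutate_exact <- function(x, k) {
  if (k == 0L) return(x)
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  if (k > length(ch)) stop("more mutations than positions")
  pos <- sample.int(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
  paste(ch, collapse = "")
}

## Substitute each position independently with probability `rate`.
mutate_iid <- function(x, rate) {
  if (rate <= 0) return(x)
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (p in hit) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
  paste(ch, collapse = "")
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Deterministically derive a stage seed from a base seed and a tag,
## kept below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629)
}

## Overwrite a slice [start, start+len) (0-based) of `seq` with `insert`.
overwrite_at <- function(seq, start, insert) {
  n <- nchar(seq)
  len <- nchar(insert)
  stopifnot(start >= 0, start + len <= n)
  paste0(substr(seq, 1L, start), insert, substr(seq, start + len + 1L, n))
}

## 0-based half-open substring.
slice0 <- function(seq, start, end) substr(seq, start + 1L, end)

## Rejection-sample a free 0-based start for a feature of length `len` in a
## contig of length `n`, avoiding intervals in `occupied` (data.frame with
## start/end, 0-based half-open). Errors after `max_tries` collisions.
sample_free_start <- function(n, len, occupied, max_tries = 100L) {
  if (len > n) stop("feature longer than contig")
  for (i in seq_len(max_tries)) {
    s <- sample.int(n - len + 1L, 1L) - 1L
    e <- s + len
    if (nrow(occupied) == 0L ||
        !any(s < occupied$end & occupied$start < e)) {
      return(s)
    }
  }
  stop("could not place feature after ", max_tries,
       " attempts: contig too crowded")
}

## Hamming distance between equal-length strings.
hamming <- function(a, b) {
  x <- utf8ToInt(a); y <- utf8ToInt(b)
  stopifnot(length(x) == length(y))
  sum(x != y)
}
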