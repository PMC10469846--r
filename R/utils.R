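# Internal helpers shared across modules.

# Run expr under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a deterministic 31-bit sub-seed from a base seed and a stream tag.
sub_seed <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) * 7919 + 104729 * k) %% 2147483629)
}

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Draw one integer uniformly from a closed range (safe for lo == hi).
sample_range <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  as.integer(lo + sample.int(hi - lo + 1L, 1L) - 1L)
}

# Random protein sequences: uniform over the 20 standard residues, which
# puts K and R at 5% each so tryptic peptides always exist.
random_sequences <- function(n, len_range) {
  lens <- if (len_range[1] >= len_range[2]) rep(len_range[1], n)
          else sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  vapply(lens, function(L) {
    paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
  }, character(1))
}

reverse_strings <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

round_mass <- function(x) round(x, 6)

# Format doubles so that fwrite/fread round-trips are bit-exact.
format_full <- function(x) sprintf("%.17g", x)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single number in [0, 1]", name), call. = FALSE)
  invisible(x)
}

assert_range <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2 || any(is.na(x)) || x[1] > x[2] ||
      x[1] < 1)
    stop(sprintf("'%s' must be a nonempty positive integer range c(lo, hi)",
                 name), call. = FALSE)
  invisible(x)
}
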