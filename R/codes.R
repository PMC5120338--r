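# Internal 2-bit integer coding of nucleotide tuples.
#
# A tuple w_1..w_L over {A,C,G,T} is coded as sum_i digit(w_i) * 4^(L-i)
# with A=0, C=1, G=2, T=3, i.e. lexicographic rank (0-based) among all
# 4^L tuples of length L.  Codes are kept as doubles; they are exact for
# L <= 26 and the package caps tuple lengths well below that.

.BASES <- c("A", "C", "G", "T")

# Vectorised string -> code.  All strings must share one length.
.encode_fixed <- function(s, L) {
  if (length(s) == 0L) return(numeric(0))
  ch <- strsplit(s, "", fixed = TRUE)
  m <- matrix(match(unlist(ch), .BASES) - 1L, nrow = L)
  if (anyNA(m)) stop("tuples must contain only A/C/G/T characters")
  as.numeric(colSums(m * 4^((L - 1):0)))
}

# Vectorised string -> code for mixed lengths; returns codes + lengths.
.encode <- function(s) {
  L <- nchar(s)
  code <- numeric(length(s))
  for (l in unique(L)) {
    idx <- which(L == l)
    code[idx] <- .encode_fixed(s[idx], l)
  }
  list(code = code, length = L)
}

# Vectorised code -> string at fixed length.
.decode <- function(code, L) {
  if (length(code) == 0L) return(character(0))
  if (L == 0L) return(rep("", length(code)))
  m <- matrix("", nrow = L, ncol = length(code))
  for (i in seq_len(L)) {
    m[i, ] <- .BASES[floor(code / 4^(L - i)) %% 4 + 1]
  }
  if (L == 1L) return(m[1, ])
  apply(m, 2, paste0, collapse = "")
}

# All tuple strings of length k in lexicographic order (small k only).
.all_tuples <- function(k) .decode(0:(4^k - 1), k)

# Run code with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}
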