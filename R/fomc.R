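#' Fit a fixed-order Markov chain background model
#'
#' Estimates an order-\code{r} Markov chain from a tuple-count table.
#' Each transition probability is the ratio of extension counts,
#' \code{P(x | w) = count(wx) / sum_y count(wy)}; contexts never observed
#' with an extension receive the uniform transition so that tuple
#' probabilities remain defined everywhere.  Tuple probabilities start
#' from the chain rule on increasing-order transitions (order \code{i - 1}
#' at position \code{i} until the full order is reached), which makes the
#' order-r model exactly the depth-r truncation of the variable-length
#' context-tree family.  The empirical r-tuple distribution is also stored
#' (field \code{initial}) and seeds \code{\link{simulate.fomc}}.
#'
#' @param table a \code{tuple_counts} object with \code{max_k >= r + 1}.
#' @param order chain order \code{r >= 0}.
#' @return object of class \code{fomc}: fields \code{order},
#'   \code{initial} (probability vector over \code{4^r} contexts),
#'   \code{trans} (\code{4^r x 4} row-stochastic matrix) and
#'   \code{source_sample}.
#' @examples
#' tc <- count_tuples("AAAA", max_k = 2)
#' m <- fomc(tc, order = 0)
#' tuple_probability(m, "AT")
#' @export
fomc <- function(table, order = 1L) {
  stopifnot(inherits(table, "tuple_counts"))
  if (!is.numeric(order) || length(order) != 1L || order < 0)
    stop("order must be a single integer >= 0")
  r <- as.integer(order)
  if (r + 1L > table$max_k)
    stop("order + 1 exceeds the table's max_k (", table$max_k, ")")
  if (sum(table$counts[[1]]$count) == 0)
    stop("empty count table: no valid tuple windows")
  nctx <- 4^r
  # initial distribution over r-tuples (scalar 1 for r = 0)
  if (r == 0L) {
    initial <- 1
  } else {
    dense <- numeric(nctx)
    sp <- table$counts[[r]]
    dense[sp$code + 1] <- sp$count
    if (sum(dense) == 0) stop("no observed tuples at length ", r)
    initial <- dense / sum(dense)
  }
  # transition counts from (r+1)-tuples: row w, column x at code w*4+x
  ext <- numeric(4^(r + 1))
  sp <- table$counts[[r + 1]]
  ext[sp$code + 1] <- sp$count
  cnt <- matrix(ext, ncol = 4, byrow = TRUE)  # nctx rows, columns A,C,G,T
  tot <- rowSums(cnt)
  trans <- cnt / ifelse(tot > 0, tot, 1)
  trans[tot == 0, ] <- 0.25
  colnames(trans) <- .BASES
  if (r <= 8) rownames(trans) <- .all_tuples(r)
  # chain-start transitions for history lengths 0..r-1
  start_trans <- lapply(seq_len(r) - 1L, function(l) .order_trans(table, l))
  structure(
    list(order = r, initial = initial, trans = trans,
         start_trans = start_trans, source_sample = table$sample_id),
    class = "fomc"
  )
}

# Dense 4^l x 4 transition matrix for histories of length l, estimated
# from (l+1)-tuple counts; zero-count histories get the uniform row.
.order_trans <- function(table, l) {
  ext <- numeric(4^(l + 1))
  sp <- table$counts[[l + 1]]
  ext[sp$code + 1] <- sp$count
  cnt <- matrix(ext, ncol = 4, byrow = TRUE)
  tot <- rowSums(cnt)
  tr <- cnt / ifelse(tot > 0, tot, 1)
  tr[tot == 0, ] <- 0.25
  colnames(tr) <- .BASES
  tr
}

#' Number of independent parameters of a background model
#'
#' For an order-r chain over n = 4 nucleotide states this is
#' \code{4^r x 3} (each of the \code{4^r} contexts carries 3 free
#' transition probabilities); for a VLMC context tree it is 3 per
#' non-root node.
#'
#' @param model a fitted \code{fomc} or \code{vlmc} model.
#' @return integer count of free transition parameters.
#' @export
n_parameters <- function(model) UseMethod("n_parameters")

#' @export
n_parameters.fomc <- function(model) {
  nrow(model$trans) * (ncol(model$trans) - 1L)
}

#' Probability of tuples under a background model
#'
#' Chain-rule probability of each tuple.  For a fixed-order model of order
#' r, \code{P(w) = P(w_1..w_r) * prod P(w_i | w_{i-r}..w_{i-1})}; tuples
#' shorter than r are marginals of the initial distribution.  For a VLMC,
#' each factor conditions on the longest suffix of the preceding bases
#' that is a node of the context tree.
#'
#' @param model a fitted \code{fomc} or \code{vlmc}.
#' @param tuples character vector of tuples over \{A,C,G,T\}.
#' @return numeric vector of probabilities.
#' @export
tuple_probability <- function(model, tuples) UseMethod("tuple_probability")

#' @export
tuple_probability.fomc <- function(model, tuples) {
  if (any(grepl("[^ACGT]", tuples)) || any(nchar(tuples) < 1))
    stop("tuples must be non-empty strings over A/C/G/T")
  enc <- .encode(tuples)
  r <- model$order
  out <- numeric(length(tuples))
  for (L in unique(enc$length)) {
    idx <- which(enc$length == L)
    code <- enc$code[idx]
    p <- rep(1, length(code))
    for (i in seq_len(L)) {
      hl <- min(i - 1L, r)
      prefix <- floor(code / 4^(L - i))
      x <- prefix %% 4
      ctx <- floor(prefix / 4) %% 4^hl
      M <- if (hl < r) model$start_trans[[hl + 1L]] else model$trans
      p <- p * M[cbind(ctx + 1, x + 1)]
    }
    out[idx] <- p
  }
  out
}

#' Dense tuple-probability profile
#'
#' Probabilities of all \code{4^k} tuples of length k in lexicographic
#' order, computed by one level-by-level chain-rule pass.  This is the
#' expected-frequency profile used to center observed counts.
#'
#' @param model a fitted \code{fomc} or \code{vlmc}.
#' @param k tuple length.
#' @return numeric vector of length \code{4^k} summing to 1.
#' @export
probability_profile <- function(model, k) UseMethod("probability_profile")

#' @export
probability_profile.fomc <- function(model, k) {
  stopifnot(k >= 1)
  r <- model$order
  p <- 1
  for (i in 0:(k - 1L)) {
    hl <- min(i, r)
    ctx <- (0:(4^i - 1)) %% 4^hl
    M <- if (hl < r) model$start_trans[[hl + 1L]] else model$trans
    p <- as.vector(t(M[ctx + 1, , drop = FALSE] * p))
  }
  p
}

#' @export
predict.fomc <- function(object, tuples = NULL, k = NULL, ...) {
  if (!is.null(tuples)) return(tuple_probability(object, tuples))
  if (!is.null(k)) return(probability_profile(object, k))
  stop("supply tuples= or k=")
}

#' @export
coef.fomc <- function(object, ...) object$trans

#' @export
print.fomc <- function(x, ...) {
  cat("Fixed-order Markov chain background model\n")
  cat("  order: ", x$order, "  contexts: ", nrow(x$trans),
      "  independent parameters: ", n_parameters(x), "\n", sep = "")
  cat("  fitted from sample: ", x$source_sample, "\n", sep = "")
  invisible(x)
}

#' Simulate reads from a fitted Markov chain
#'
#' Draws \code{nsim} reads of length \code{read_length} from the chain:
#' the first r bases from the initial distribution, the rest from the
#' transition matrix.  Used for parameter-recovery checks and as a null
#' read generator.
#'
#' @param object fitted \code{fomc}.
#' @param nsim number of reads.
#' @param seed RNG seed (restores caller RNG state).
#' @param read_length length of each read.
#' @param ... unused.
#' @return character vector of read sequences.
#' @export
simulate.fomc <- function(object, nsim = 1, seed = NULL,
                          read_length = 100L, ...) {
  r <- object$order
  .with_seed(seed, {
    mat <- matrix(0L, nrow = nsim, ncol = read_length)
    ctx <- if (r == 0L) rep(0, nsim) else {
      start <- sample.int(4^r, nsim, replace = TRUE,
                          prob = object$initial) - 1L
      for (i in seq_len(min(r, read_length)))
        mat[, i] <- floor(start / 4^(r - i)) %% 4
      start
    }
    if (read_length > r) {
      for (i in (r + 1):read_length) {
        u <- runif(nsim)
        P <- object$trans[ctx + 1, , drop = FALSE]
        c1 <- P[, 1]; c2 <- c1 + P[, 2]; c3 <- c2 + P[, 3]
        x <- (u > c1) + (u > c2) + (u > c3)
        mat[, i] <- x
        ctx <- if (r == 0L) ctx else (ctx * 4 + x) %% 4^r
      }
    }
    apply(mat, 1, function(row) paste(.BASES[row + 1], collapse = ""))
  })
}

#' Write / read a fitted fixed-order model as TSV
#'
#' Rows \code{context<TAB>pA<TAB>pC<TAB>pG<TAB>pT}; header lines carry the
#' order, source sample and the initial distribution.
#' @param model a \code{fomc} object.
#' @param path file path.
#' @rdname fomc_io
#' @export
write_fomc <- function(model, path) {
  stopifnot(inherits(model, "fomc"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#order=", model$order),
               paste0("#sample=", model$source_sample),
               paste0("#initial=", paste(format(model$initial, digits = 17),
                                         collapse = ","))), con)
  for (l in seq_along(model$start_trans)) {
    writeLines(paste0("#start", l - 1L, "=",
                      paste(format(as.vector(model$start_trans[[l]]),
                                   digits = 17), collapse = ",")), con)
  }
  ctx <- .all_tuples(model$order)
  if (model$order == 0L) ctx <- "."
  writeLines(paste(ctx,
                   apply(format(model$trans, digits = 17), 1, paste,
                         collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

#' @rdname fomc_io
#' @export
read_fomc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  gv <- function(key) sub(paste0("^#", key, "="), "",
                          hdr[startsWith(hdr, paste0("#", key, "="))])
  r <- as.integer(gv("order"))
  initial <- as.numeric(strsplit(gv("initial"), ",")[[1]])
  parts <- strsplit(body, "\t", fixed = TRUE)
  trans <- t(vapply(parts, function(p) as.numeric(p[2:5]), numeric(4)))
  colnames(trans) <- .BASES
  if (r <= 8) rownames(trans) <- if (r == 0L) "" else .all_tuples(r)
  start_trans <- lapply(seq_len(r) - 1L, function(l) {
    v <- as.numeric(strsplit(gv(paste0("start", l)), ",")[[1]])
    matrix(v, ncol = 4, dimnames = list(NULL, .BASES))
  })
  structure(list(order = r, initial = initial, trans = trans,
                 start_trans = start_trans, source_sample = gv("sample")),
            class = "fomc")
}
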