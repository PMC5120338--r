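# Dissimilarities between samples from k-tuple frequency vectors, with
# (d2S, d2*) and without (d2, L1/L2/Linf) background-model normalisation.

#' Center k-tuple counts under a background model
#'
#' Computes the centered counts \code{C~_i = C_i - N * P_i} where
#' \code{P_i} is the probability of the i-th k-tuple under the sample's
#' fitted background model and \code{N} the total k-tuple count.  These
#' are the building blocks of the d2S and d2* dissimilarities.
#'
#' @param counts a \code{tuple_counts} table or a dense numeric vector of
#'   length \code{4^k}.
#' @param model a fitted \code{fomc} or \code{vlmc} for the same sample
#'   (a mismatching sample label triggers a warning, not an error, so
#'   foreign backgrounds can be explored).
#' @param k tuple length.
#' @return object of class \code{centered_counts} with fields \code{k},
#'   \code{counts}, \code{probs}, \code{N} and \code{centered}.
#' @export
center_counts <- function(counts, model, k) {
  if (inherits(counts, "tuple_counts")) {
    src <- counts$sample_id
    vec <- frequency_vector(counts, k, named = FALSE)
  } else if (is.numeric(counts)) {
    src <- NULL
    vec <- counts
    if (length(vec) != 4^k) stop("counts vector must have length 4^k")
  } else stop("counts must be a tuple_counts table or a numeric vector")
  if (!is.null(src) && !is.null(model$source_sample) &&
      !identical(src, model$source_sample))
    warning("model was fitted from sample '", model$source_sample,
            "' but counts are from '", src, "'")
  probs <- probability_profile(model, k)
  if (length(probs) != length(vec)) stop("dimension mismatch")
  N <- sum(vec)
  structure(list(k = k, counts = vec, probs = probs, N = N,
                 centered = vec - N * probs),
            class = "centered_counts")
}

#' @export
print.centered_counts <- function(x, ...) {
  cat("centered ", x$k, "-tuple counts: N = ", x$N,
      ", sum |centered| = ", format(sum(abs(x$centered)), digits = 6),
      "\n", sep = "")
  invisible(x)
}

.check_same_k <- function(X, Y) {
  if (!inherits(X, "centered_counts") || !inherits(Y, "centered_counts"))
    stop("X and Y must be centered_counts objects")
  if (X$k != Y$k) stop("X and Y use different tuple lengths")
}

#' d2S dissimilarity of two centered count vectors
#'
#' Self-standardised centered correlation mapped to [0, 1]:
#' \code{D2S = sum C~_X C~_Y / sqrt(C~_X^2 + C~_Y^2)} and
#' \code{d2S = (1 - D2S / sqrt(A * B)) / 2} with the matching
#' self-normalisation sums A and B.  Terms where both centered values are
#' zero contribute nothing.
#'
#' @param X,Y \code{centered_counts} at the same k.
#' @return dissimilarity in [0, 1] (0 for identical samples).
#' @export
d2s <- function(X, Y) {
  .check_same_k(X, Y)
  cx <- X$centered; cy <- Y$centered
  den <- sqrt(cx^2 + cy^2)
  nz <- den > 0
  if (!any(nz)) {
    warning("both samples are exactly centered to zero; returning 0")
    return(0)
  }
  D2S <- sum(cx[nz] * cy[nz] / den[nz])
  A <- sum(cx[nz]^2 / den[nz])
  B <- sum(cy[nz]^2 / den[nz])
  0.5 * (1 - D2S / sqrt(A * B))
}

#' d2* dissimilarity of two centered count vectors
#'
#' Expectation-standardised centered correlation mapped to [0, 1]:
#' \code{D2* = sum C~_X C~_Y / sqrt(N_X P_X N_Y P_Y)}, normalised by the
#' Cauchy-Schwarz bound.  Tuples with zero expected count on either side
#' must have zero centered count there (else an error): they are skipped.
#'
#' @inheritParams d2s
#' @return dissimilarity in [0, 1].
#' @export
d2star <- function(X, Y) {
  .check_same_k(X, Y)
  cx <- X$centered; cy <- Y$centered
  ex <- X$N * X$probs; ey <- Y$N * Y$probs
  bad <- (ex == 0 & cx != 0) | (ey == 0 & cy != 0)
  if (any(bad))
    stop("zero expected count with non-zero centered count at tuple index ",
         which(bad)[1])
  nz <- ex > 0 & ey > 0
  den <- sqrt(ex[nz] * ey[nz])
  D2 <- sum(cx[nz] * cy[nz] / den)
  A <- sum(cx[nz]^2 / ex[nz])
  B <- sum(cy[nz]^2 / ey[nz])
  if (A == 0 || B == 0) {
    warning("a sample is exactly centered to zero; returning 0")
    return(0)
  }
  0.5 * (1 - D2 / sqrt(A * B))
}

.as_count_vec <- function(x, k) {
  if (inherits(x, "tuple_counts")) frequency_vector(x, k, named = FALSE)
  else if (inherits(x, "centered_counts")) x$counts
  else if (is.numeric(x)) x
  else stop("expected counts as tuple_counts, centered_counts or numeric")
}

#' d2 dissimilarity (cosine form, no background model)
#'
#' \code{d2 = (1 - cos(C_X, C_Y)) / 2} on the raw k-tuple count vectors.
#'
#' @param X,Y \code{tuple_counts}, \code{centered_counts} or dense numeric
#'   count vectors.
#' @param k tuple length (required for \code{tuple_counts} input).
#' @return dissimilarity in [0, 1].
#' @export
d2 <- function(X, Y, k = NULL) {
  cx <- .as_count_vec(X, k); cy <- .as_count_vec(Y, k)
  if (length(cx) != length(cy)) stop("count vectors differ in length")
  nx <- sqrt(sum(cx^2)); ny <- sqrt(sum(cy^2))
  if (nx == 0 || ny == 0) stop("zero count vector")
  0.5 * (1 - sum(cx * cy) / (nx * ny))
}

#' Lp-norm dissimilarities on k-tuple frequencies
#'
#' Manhattan (\code{"ma"}, L1), Euclidean (\code{"eu"}, L2) or Chebyshev
#' (\code{"ch"}, L-infinity) distance between the frequency-normalised
#' vectors \code{C/N}, so samples of unequal sequencing depth are
#' comparable.
#'
#' @inheritParams d2
#' @param p which norm: \code{"ma"}, \code{"eu"} or \code{"ch"}.
#' @return non-negative dissimilarity.
#' @export
lp_dissimilarity <- function(X, Y, p = c("ma", "eu", "ch"), k = NULL) {
  p <- match.arg(p)
  cx <- .as_count_vec(X, k); cy <- .as_count_vec(Y, k)
  if (length(cx) != length(cy)) stop("count vectors differ in length")
  if (sum(cx) == 0 || sum(cy) == 0) stop("zero total count")
  fx <- cx / sum(cx); fy <- cy / sum(cy)
  switch(p,
         ma = sum(abs(fx - fy)),
         eu = sqrt(sum((fx - fy)^2)),
         ch = max(abs(fx - fy)))
}

#' Pairwise dissimilarity matrix over samples
#'
#' Applies one measure at one tuple length to every sample pair.  For the
#' background-normalised measures (d2S, d2*) each sample is centered under
#' its own fitted model.
#'
#' @param samples named list of \code{tuple_counts} tables (>= 2).
#' @param measure one of \code{"d2s"}, \code{"d2star"}, \code{"d2"},
#'   \code{"ma"}, \code{"eu"}, \code{"ch"}.
#' @param k tuple length.
#' @param models named list of fitted backgrounds (one per sample, same
#'   names), required for \code{"d2s"} and \code{"d2star"}; all must be of
#'   one model class.
#' @return a symmetric \code{diss_matrix} (numeric matrix with
#'   \code{measure}, \code{model} and \code{k} attributes, zero diagonal).
#' @export
dissimilarity_matrix <- function(samples, measure, k, models = NULL) {
  measure <- match.arg(measure, c("d2s", "d2star", "d2", "ma", "eu", "ch"))
  if (length(samples) < 2L) stop("need at least 2 samples")
  labels <- names(samples)
  if (is.null(labels) || anyDuplicated(labels))
    stop("samples must be uniquely named")
  needs_model <- measure %in% c("d2s", "d2star")
  model_tag <- "none"
  if (needs_model) {
    if (is.null(models) || !all(labels %in% names(models)))
      stop("measures d2s/d2star need one fitted model per sample")
    cls <- vapply(models[labels], function(m) class(m)[1], character(1))
    if (length(unique(cls)) != 1L)
      stop("mixed model classes across samples: ",
           paste(unique(cls), collapse = ", "))
    model_tag <- if (cls[1] == "fomc")
      paste0("fomc:", models[[labels[1]]]$order) else "vlmc"
    cen <- lapply(labels, function(s)
      center_counts(samples[[s]], models[[s]], k))
    names(cen) <- labels
  }
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- switch(measure,
      d2s = d2s(cen[[i]], cen[[j]]),
      d2star = d2star(cen[[i]], cen[[j]]),
      d2 = d2(samples[[i]], samples[[j]], k = k),
      lp_dissimilarity(samples[[i]], samples[[j]], p = measure, k = k))
    m[i, j] <- m[j, i] <- v
  }
  structure(m, class = c("diss_matrix", "matrix"),
            measure = measure, model = model_tag, k = k)
}

#' @export
print.diss_matrix <- function(x, ...) {
  cat("pairwise ", attr(x, "measure"), " dissimilarities (k = ",
      attr(x, "k"), ", background: ", attr(x, "model"), ")\n", sep = "")
  print(unclass(x)[, , drop = FALSE], digits = 4)
  invisible(x)
}

#' Write / read a dissimilarity matrix as TSV
#'
#' Square tab-separated matrix with a label header row and column;
#' comment headers carry measure, model and k.
#' @param m a \code{diss_matrix} (or plain labelled matrix).
#' @param path file path.
#' @rdname diss_io
#' @export
write_diss_matrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#measure=", attr(m, "measure") %||% ""),
               paste0("#model=", attr(m, "model") %||% ""),
               paste0("#k=", attr(m, "k") %||% "")), con)
  writeLines(paste(c("sample", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], format(m[i, ], digits = 17)),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname diss_io
#' @export
read_diss_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  gv <- function(key) sub(paste0("^#", key, "="), "",
                          hdr[startsWith(hdr, paste0("#", key, "="))])
  parts <- strsplit(body, "\t", fixed = TRUE)
  labels <- parts[[1]][-1]
  m <- t(vapply(parts[-1], function(p) as.numeric(p[-1]),
                numeric(length(labels))))
  dimnames(m) <- list(vapply(parts[-1], `[`, character(1), 1L), labels)
  structure(m, class = c("diss_matrix", "matrix"),
            measure = gv("measure"), model = gv("model"),
            k = suppressWarnings(as.numeric(gv("k"))))
}

#' Export a dissimilarity matrix in PHYLIP format
#'
#' Lower-precision square PHYLIP distance matrix for interoperability
#' with classical phylogenetics tools.
#' @param m labelled symmetric matrix.
#' @param path file path.
#' @export
write_phylip <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  lab <- sprintf("%-10s", substr(rownames(m), 1, 10))
  for (i in seq_len(nrow(m)))
    writeLines(paste0(lab[i], paste(sprintf("%.6f", m[i, ]),
                                    collapse = " ")), con)
  invisible(path)
}
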