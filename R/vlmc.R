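# Variable-length Markov chain context trees estimated from read sets.
#
# A context tree stores, per depth l, the set of observed contexts
# (integer-coded l-tuples), their occurrence counts C(w), transition
# totals N(w) = sum_y C(wy) and row-stochastic transition vectors
# P(.|w) = C(wx)/N(w).  Children of context w are the one-character-longer
# contexts uw (character prepended), so the parent of a context is its
# one-shorter suffix and the tree is prefix-closed upward.

#' Build the full prefix tree of contexts
#'
#' Creates the unpruned context tree from a tuple-count table: one node
#' per observed tuple of length \code{1..max_depth} (with count at least
#' \code{min_count}) plus the root.  Node transitions are extension-count
#' ratios \code{P(x|w) = count(wx)/sum_y count(wy)}; the root carries the
#' single-nucleotide frequencies.  Contexts observed without any
#' length-(l+1) extension receive the uniform transition.
#'
#' @param table a \code{tuple_counts} with \code{max_k >= max_depth + 1}.
#' @param max_depth deepest context length (default 10).
#' @param min_count minimum tuple count for a node (default 1 = all
#'   observed tuples).
#' @return object of class \code{vlmc} (unpruned: \code{K} is \code{NULL}).
#' @examples
#' tc <- count_tuples("AAAA", max_k = 3)
#' tr <- build_prefix_tree(tc, max_depth = 2)
#' contexts(tr)
#' @export
build_prefix_tree <- function(table, max_depth = 10L, min_count = 1L) {
  stopifnot(inherits(table, "tuple_counts"))
  if (max_depth + 1L > table$max_k)
    stop("max_depth + 1 exceeds the table's max_k (", table$max_k, ")")
  if (min_count < 1) stop("min_count must be >= 1")
  if (length(table$counts[[1]]$code) == 0L)
    stop("empty count table: no valid tuple windows")
  levels <- vector("list", max_depth + 1L)
  # root
  dense1 <- numeric(4)
  dense1[table$counts[[1]]$code + 1] <- table$counts[[1]]$count
  tot1 <- sum(dense1)
  levels[[1]] <- list(code = 0, cnt = tot1, n = tot1,
                      trans = matrix(dense1 / tot1, nrow = 1,
                                     dimnames = list(NULL, .BASES)))
  for (l in seq_len(max_depth)) {
    sp <- table$counts[[l]]
    keep <- sp$count >= min_count
    code <- sp$code[keep]
    cnt <- sp$count[keep]
    # prefix closure upward is automatic: every occurrence of uw contains
    # its suffix w, so count(w) >= count(uw) >= min_count
    ext <- table$counts[[l + 1L]]
    extmat <- matrix(0, nrow = length(code), ncol = 4,
                     dimnames = list(NULL, .BASES))
    for (x in 0:3) {
      m <- match(code * 4 + x, ext$code)
      hit <- !is.na(m)
      extmat[hit, x + 1L] <- ext$count[m[hit]]
    }
    n <- rowSums(extmat)
    trans <- extmat / ifelse(n > 0, n, 1)
    trans[n == 0, ] <- 0.25
    levels[[l + 1L]] <- list(code = code, cnt = cnt, n = n, trans = trans)
  }
  structure(
    list(levels = levels, max_depth = as.integer(max_depth), K = NULL,
         min_count = as.integer(min_count),
         source_sample = table$sample_id),
    class = "vlmc"
  )
}

#' Number of non-root contexts in a tree
#'
#' @param tree a \code{vlmc} object.
#' @return integer node count excluding the root (the quantity the AIC
#'   penalty is proportional to).
#' @export
n_contexts <- function(tree) {
  stopifnot(inherits(tree, "vlmc"))
  sum(vapply(tree$levels[-1], function(lv) length(lv$code), numeric(1)))
}

#' @export
n_parameters.vlmc <- function(model) 3L * n_contexts(model)

#' List the contexts of a tree
#'
#' @param tree a \code{vlmc} object.
#' @return data frame with context string, depth, tuple count, transition
#'   total and the four transition probabilities.
#' @export
contexts <- function(tree) {
  stopifnot(inherits(tree, "vlmc"))
  out <- lapply(seq_along(tree$levels), function(i) {
    lv <- tree$levels[[i]]
    if (length(lv$code) == 0L) return(NULL)
    data.frame(context = .decode(lv$code, i - 1L), depth = i - 1L,
               count = lv$cnt, n = lv$n, lv$trans,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

# Count-weighted KL divergences of every non-root node from its parent:
# delta(uw) = N(uw) * sum_x P(x|uw) log(P(x|uw)/P(x|w)), natural log.
# Returns a per-depth list aligned with tree$levels (NULL at root).
.kl_all <- function(tree) {
  d <- vector("list", length(tree$levels))
  for (l in seq_len(tree$max_depth)) {
    lv <- tree$levels[[l + 1L]]
    if (length(lv$code) == 0L) { d[[l + 1L]] <- numeric(0); next }
    par <- tree$levels[[l]]
    pidx <- match(lv$code %% 4^(l - 1), par$code)
    P <- lv$trans
    Q <- par$trans[pidx, , drop = FALSE]
    term <- P * (log(P) - log(Q))
    term[P == 0] <- 0
    rs <- rowSums(term)
    d[[l + 1L]] <- ifelse(lv$n > 0, lv$n * rs, 0)
  }
  d
}

.delta_of <- function(tree) {
  if (is.null(tree$delta)) .kl_all(tree) else tree$delta
}

#' Kullback-Leibler pruning statistic of contexts
#'
#' For a context uw with parent w (its one-character-shorter suffix) the
#' statistic is \code{N(uw) * sum_x P(x|uw) log(P(x|uw)/P(x|w))} with
#' natural logarithm and \code{0 log 0 = 0}; \code{N(uw)} is the context's
#' transition total.  Nodes whose statistic falls below the pruning
#' threshold K carry (almost) no information beyond their parent.
#'
#' @param tree a \code{vlmc} object.
#' @param context character vector of context strings (must be tree nodes).
#' @return numeric vector of non-negative statistics.
#' @export
kl_statistic <- function(tree, context) {
  stopifnot(inherits(tree, "vlmc"))
  if (any(nchar(context) < 1)) stop("the root has no pruning statistic")
  enc <- .encode(context)
  delta <- .delta_of(tree)
  out <- numeric(length(context))
  for (l in unique(enc$length)) {
    if (l > tree$max_depth)
      stop("context not in tree (deeper than max_depth): depth ", l)
    idx <- which(enc$length == l)
    m <- match(enc$code[idx], tree$levels[[l + 1L]]$code)
    if (anyNA(m))
      stop("context not in tree: ", context[idx][is.na(m)][1])
    out[idx] <- delta[[l + 1L]][m]
  }
  out
}

#' Prune a context tree at threshold K
#'
#' Greedy bottom-up pruning: in each sweep every current terminal node
#' (a node with no children left in the tree) whose KL statistic is below
#' \code{K} is removed; sweeps repeat until a fixed point.  The root is
#' never removed.  Larger \code{K} prunes more aggressively; \code{K = 0}
#' removes nothing and \code{K = Inf} leaves only the root.
#'
#' @param tree a \code{vlmc} object (typically unpruned).
#' @param K non-negative pruning threshold.
#' @param trace record the removed nodes (context, statistic, sweep) in
#'   attribute \code{"prune_trace"}.
#' @return the pruned \code{vlmc} with \code{K} set.
#' @export
prune_tree <- function(tree, K, trace = TRUE) {
  stopifnot(inherits(tree, "vlmc"))
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K < 0)
    stop("K must be a single non-negative number")
  delta <- .delta_of(tree)
  keep <- lapply(tree$levels, function(lv) rep(TRUE, length(lv$code)))
  tr_depth <- tr_code <- tr_delta <- tr_iter <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    removed <- FALSE
    for (l in seq_len(tree$max_depth)) {
      lv <- tree$levels[[l + 1L]]
      kl <- keep[[l + 1L]]
      if (!any(kl)) next
      # terminal = no kept child one level deeper
      if (l < tree$max_depth && any(keep[[l + 2L]])) {
        child_par <- tree$levels[[l + 2L]]$code[keep[[l + 2L]]] %% 4^l
        terminal <- kl & !(lv$code %in% child_par)
      } else {
        terminal <- kl
      }
      prune <- terminal & (delta[[l + 1L]] < K)
      if (any(prune)) {
        removed <- TRUE
        keep[[l + 1L]][prune] <- FALSE
        if (trace) {
          tr_depth[[length(tr_depth) + 1L]] <- rep(l, sum(prune))
          tr_code[[length(tr_code) + 1L]] <- lv$code[prune]
          tr_delta[[length(tr_delta) + 1L]] <- delta[[l + 1L]][prune]
          tr_iter[[length(tr_iter) + 1L]] <- rep(iter, sum(prune))
        }
      }
    }
    if (!removed) break
  }
  out <- tree
  for (i in seq_along(out$levels)) {
    ki <- keep[[i]]
    out$levels[[i]] <- list(code = tree$levels[[i]]$code[ki],
                            cnt = tree$levels[[i]]$cnt[ki],
                            n = tree$levels[[i]]$n[ki],
                            trans = tree$levels[[i]]$trans[ki, ,
                                                           drop = FALSE])
    delta[i] <- if (i == 1L) list(NULL) else list(delta[[i]][ki])
  }
  out$K <- K
  out$delta <- delta
  if (trace) {
    depths <- unlist(tr_depth)
    attr(out, "prune_trace") <- data.frame(
      context = if (length(depths))
        unlist(Map(function(cd, dp) .decode(cd, dp[1]),
                   tr_code, tr_depth)) else character(0),
      depth = depths %||% integer(0),
      delta = unlist(tr_delta) %||% numeric(0),
      iteration = unlist(tr_iter) %||% integer(0),
      stringsAsFactors = FALSE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Longest-suffix context lookup: given history codes and lengths, return
# per element the depth and row index of the deepest tree context equal to
# a suffix of the history.  Prefix closure lets the scan stop at the first
# depth where an element's suffix is absent.
.ctx_lookup <- function(tree, hist_code, hist_len) {
  n <- length(hist_code)
  lev <- integer(n)
  idx <- rep(1L, n)
  active <- seq_len(n)
  maxl <- tree$max_depth
  for (l in seq_len(maxl)) {
    active <- active[hist_len[active] >= l]
    if (length(active) == 0L) break
    suf <- hist_code[active] %% 4^l
    m <- match(suf, tree$levels[[l + 1L]]$code)
    found <- !is.na(m)
    lev[active[found]] <- l
    idx[active[found]] <- m[found]
    active <- active[found]
    if (length(active) == 0L) break
  }
  list(level = lev, idx = idx)
}

# Transition probability of symbol x (0..3) after each history.
.trans_prob <- function(tree, hist_code, hist_len, x) {
  ctx <- .ctx_lookup(tree, hist_code, hist_len)
  p <- numeric(length(x))
  for (l in unique(ctx$level)) {
    sel <- ctx$level == l
    p[sel] <- tree$levels[[l + 1L]]$trans[cbind(ctx$idx[sel], x[sel] + 1L)]
  }
  p
}

#' @export
tuple_probability.vlmc <- function(model, tuples) {
  if (any(grepl("[^ACGT]", tuples)) || any(nchar(tuples) < 1))
    stop("tuples must be non-empty strings over A/C/G/T")
  enc <- .encode(tuples)
  out <- numeric(length(tuples))
  for (L in unique(enc$length)) {
    idx <- which(enc$length == L)
    code <- enc$code[idx]
    p <- rep(1, length(code))
    for (i in seq_len(L)) {
      prefix <- floor(code / 4^(L - i))
      x <- prefix %% 4
      hist <- floor(prefix / 4)
      p <- p * .trans_prob(model, hist, rep(i - 1L, length(code)), x)
    }
    out[idx] <- p
  }
  out
}

#' @export
probability_profile.vlmc <- function(model, k) {
  stopifnot(k >= 1)
  p <- 1
  for (i in 0:(k - 1L)) {
    # context row for every length-i history, via dense per-depth lookup
    N <- 4^i
    hist <- 0:(N - 1)
    lvl <- integer(N)
    row <- rep(1L, N)
    for (l in seq_len(min(i, model$max_depth))) {
      ml <- match(0:(4^l - 1), model$levels[[l + 1L]]$code)
      v <- ml[hist %% 4^l + 1]
      hit <- !is.na(v)
      lvl[hit] <- l
      row[hit] <- v[hit]
    }
    TR <- matrix(0, nrow = N, ncol = 4)
    for (l in unique(lvl)) {
      sel <- lvl == l
      TR[sel, ] <- model$levels[[l + 1L]]$trans[row[sel], , drop = FALSE]
    }
    p <- as.vector(t(TR * p))
  }
  p
}

#' @export
predict.vlmc <- function(object, tuples = NULL, k = NULL, ...) {
  if (!is.null(tuples)) return(tuple_probability(object, tuples))
  if (!is.null(k)) return(probability_profile(object, k))
  stop("supply tuples= or k=")
}

#' Summarise a read set's context transitions
#'
#' Aggregates every (history, next base) transition of a read set into
#' window counts: sliding windows of length \code{depth + 1} plus the
#' shorter read-prefix windows whose history has fewer than \code{depth}
#' bases.  Reads are split at non-ACGT characters; the first base of each
#' fragment contributes no transition.  The summary makes repeated
#' pseudo-likelihood evaluations (e.g. across candidate thresholds) cheap.
#'
#' @param reads files, character vector or XStringSet (as
#'   \code{\link{count_tuples}}).
#' @param depth context depth the summary serves.
#' @return object of class \code{read_summary}.
#' @export
read_transition_summary <- function(reads, depth) {
  seqs <- as.character(.as_reads(reads))
  frags <- unlist(strsplit(seqs, "N+"))
  frags <- frags[nchar(frags) >= 2]
  windows <- vector("list", depth + 1L)
  if (length(frags)) {
    full <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(frags), width = depth + 1L,
      simplify.as = "collapsed")
    nz <- which(full > 0)
    windows[[depth + 1L]] <- list(code = as.numeric(nz - 1L),
                                  count = as.numeric(full[nz]))
    len <- nchar(frags)
    for (m in seq_len(min(depth, max(len)))[-1]) {
      sel <- frags[len >= m]
      if (!length(sel)) break
      code <- .encode_fixed(substr(sel, 1L, m), m)
      agg <- rowsum(rep(1, length(code)), code)
      windows[[m]] <- list(code = as.numeric(rownames(agg)),
                           count = as.numeric(agg))
    }
  }
  structure(list(depth = as.integer(depth), windows = windows),
            class = "read_summary")
}

#' Log pseudo-likelihood of reads under a context tree
#'
#' Sum over reads and positions of \code{log P(next base | longest-suffix
#' context of the preceding bases)}; the first base of each read (or
#' fragment after splitting at ambiguous characters) contributes no term.
#' Natural logarithm; forward strand only.
#'
#' @param tree a \code{vlmc} object.
#' @param reads read input as in \code{\link{count_tuples}}, or a
#'   precomputed \code{\link{read_transition_summary}} of matching depth.
#' @return scalar log pseudo-likelihood (0 for an empty read set).
#' @export
log_pseudo_likelihood <- function(tree, reads) {
  stopifnot(inherits(tree, "vlmc"))
  s <- if (inherits(reads, "read_summary")) reads else
    read_transition_summary(reads, tree$max_depth)
  if (s$depth != tree$max_depth)
    stop("read summary depth (", s$depth,
         ") does not match tree depth (", tree$max_depth, ")")
  ll <- 0
  for (m in seq_along(s$windows)) {
    w <- s$windows[[m]]
    if (is.null(w) || length(w$code) == 0L) next
    hist <- floor(w$code / 4)
    x <- w$code %% 4
    p <- .trans_prob(tree, hist, rep(m - 1L, length(x)), x)
    if (any(p == 0))
      stop("observed transition has probability 0 under this tree; ",
           "the tree was not fitted from these reads - refit it")
    ll <- ll + sum(w$count * log(p))
  }
  ll
}

#' Read-based AIC of a context tree
#'
#' \code{AIC = -2 * log-pseudo-likelihood + 2 * 3 * card(tree)}, where
#' \code{card} counts non-root nodes (3 free transition parameters each).
#'
#' @inheritParams log_pseudo_likelihood
#' @return scalar AIC value.
#' @export
aic_read <- function(tree, reads) {
  -2 * log_pseudo_likelihood(tree, reads) + 6 * n_contexts(tree)
}

#' Select the pruning threshold K by read-based AIC
#'
#' Heuristic local search: the KL statistics of all non-root nodes of the
#' full tree are summarised by a Gaussian kernel density (normal-reference
#' bandwidth); candidate thresholds are placed on small grids around the
#' highest density peak and the two inflexion points to its right, plus
#' \code{K = 0}, and the candidate minimising the read-based AIC wins
#' (ties to the smaller K).  Trees with fewer than 10 non-root nodes fall
#' back to an exhaustive scan over the distinct statistics.
#'
#' @param table a \code{tuple_counts} for the sample.
#' @param reads the same sample's reads (or a
#'   \code{\link{read_transition_summary}} at \code{max_depth}).
#' @param max_depth,min_count full-tree construction parameters.
#' @param grid_points candidate grid size per anchor (default 7).
#' @param grid_span half-width of each grid as a fraction of the anchor
#'   value (default 0.25).
#' @return list with elements \code{K} (selected threshold), \code{tree}
#'   (the pruned tree), \code{diagnostics} (data frame of K, card,
#'   log-likelihood, AIC per candidate), \code{anchors} and
#'   \code{delta_density}.
#' @export
select_threshold <- function(table, reads, max_depth = 10L, min_count = 1L,
                             grid_points = 7L, grid_span = 0.25) {
  full <- build_prefix_tree(table, max_depth, min_count)
  full$delta <- .kl_all(full)
  deltas <- unlist(full$delta[-1])
  summ <- if (inherits(reads, "read_summary")) reads else
    read_transition_summary(reads, max_depth)
  dens <- NULL
  if (length(deltas) < 10L || length(unique(deltas)) < 3L) {
    du <- sort(unique(deltas))
    candidates <- c(0, du, if (length(du)) max(du) * 1.001 + 1e-9)
    anchors <- numeric(0)
  } else {
    dens <- stats::density(deltas, bw = "nrd0")
    peak <- dens$x[which.max(dens$y)]
    d2 <- diff(dens$y, differences = 2)
    xin <- dens$x[seq_along(d2) + 1L]
    sgn <- sign(d2)
    flip <- which(sgn[-length(sgn)] * sgn[-1] < 0)
    infl <- xin[flip]
    infl <- infl[infl > peak]
    anchors <- c(peak, infl[seq_len(min(2L, length(infl)))])
    while (length(anchors) < 3L)
      anchors <- c(anchors, peak * 2^(length(anchors)))
    grids <- lapply(anchors, function(a)
      seq(a * (1 - grid_span), a * (1 + grid_span),
          length.out = grid_points))
    candidates <- sort(unique(pmax(0, c(0, unlist(grids)))))
  }
  diag <- data.frame(K = candidates, card = NA_real_,
                     loglik = NA_real_, aic = NA_real_)
  best <- NULL
  for (i in seq_along(candidates)) {
    tr <- prune_tree(full, candidates[i], trace = FALSE)
    ll <- log_pseudo_likelihood(tr, summ)
    diag$card[i] <- n_contexts(tr)
    diag$loglik[i] <- ll
    diag$aic[i] <- -2 * ll + 6 * diag$card[i]
    if (is.null(best) || diag$aic[i] < best$aic) {
      best <- list(K = candidates[i], tree = tr, aic = diag$aic[i],
                   loglik = ll)
    }
  }
  list(K = best$K, tree = best$tree, loglik = best$loglik,
       diagnostics = diag, anchors = anchors, delta_density = dens)
}

#' Fit a VLMC background model to a read set
#'
#' Front end tying the steps together: count tuples (unless a table is
#' supplied), build the full prefix tree of depth \code{max_depth}, prune
#' it at threshold \code{K} -- either a fixed value or \code{"auto"} for
#' read-based AIC selection (\code{\link{select_threshold}}) -- and return
#' the fitted context tree.
#'
#' @param reads read input as in \code{\link{count_tuples}}.
#' @param max_depth deepest context (default 10; tuples up to
#'   \code{max_depth + 1} are counted).
#' @param K \code{"auto"} or a fixed non-negative threshold.
#' @param strand strand mode for counting (model fitting); the
#'   pseudo-likelihood always uses the forward reads as given.
#' @param counts optional precomputed \code{tuple_counts}.
#' @param min_count minimum tuple count for full-tree nodes.
#' @param sample_id sample label.
#' @return a fitted \code{vlmc} with log pseudo-likelihood and (for
#'   \code{K = "auto"}) selection diagnostics attached.
#' @examples
#' reads <- simulate(fomc(count_tuples("ACGTACGTGGCA"), 0), nsim = 50,
#'                   seed = 1, read_length = 40)
#' fit <- vlmc(reads, max_depth = 4)
#' fit
#' @export
vlmc <- function(reads, max_depth = 10L, K = "auto",
                 strand = c("both", "forward"), counts = NULL,
                 min_count = 1L, sample_id = "sample") {
  strand <- match.arg(strand)
  if (is.null(counts)) {
    counts <- count_tuples(reads, max_k = max_depth + 1L, strand = strand,
                           sample_id = sample_id)
  }
  summ <- read_transition_summary(reads, max_depth)
  if (identical(K, "auto")) {
    sel <- select_threshold(counts, summ, max_depth = max_depth,
                            min_count = min_count)
    tree <- sel$tree
    tree$selection <- sel[c("K", "diagnostics", "anchors", "delta_density")]
    tree$loglik <- sel$loglik
  } else {
    full <- build_prefix_tree(counts, max_depth, min_count)
    full$delta <- .kl_all(full)
    tree <- prune_tree(full, K, trace = FALSE)
    tree$loglik <- log_pseudo_likelihood(tree, summ)
  }
  tree$n_transitions <- sum(vapply(summ$windows, function(w)
    if (is.null(w)) 0 else sum(w$count), numeric(1)))
  tree$source_sample <- sample_id
  tree
}

#' @export
logLik.vlmc <- function(object, ...) {
  if (is.null(object$loglik))
    stop("no stored pseudo-likelihood; fit with vlmc() or use ",
         "log_pseudo_likelihood()")
  structure(object$loglik, df = 3 * n_contexts(object),
            nobs = object$n_transitions, class = "logLik")
}

#' @export
print.vlmc <- function(x, ...) {
  cat("VLMC context-tree background model\n")
  cat("  depth: ", x$max_depth, "  contexts (non-root): ", n_contexts(x),
      "  parameters: ", n_parameters(x), "\n", sep = "")
  if (!is.null(x$K))
    cat("  pruning threshold K: ", format(x$K, digits = 5),
        if (!is.null(x$selection)) "  (AIC-selected)", "\n", sep = "")
  else cat("  unpruned full prefix tree\n")
  if (!is.null(x$loglik))
    cat("  log pseudo-likelihood: ", format(x$loglik, digits = 8),
        "  AIC: ", format(-2 * x$loglik + 6 * n_contexts(x), digits = 8),
        "\n", sep = "")
  cat("  sample: ", x$source_sample %||% "?", "\n", sep = "")
  invisible(x)
}

#' @export
summary.vlmc <- function(object, ...) {
  per_depth <- vapply(object$levels, function(lv) length(lv$code),
                      numeric(1))
  out <- list(depth = object$max_depth, K = object$K,
              card = n_contexts(object),
              nodes_per_depth = stats::setNames(per_depth,
                                                seq_along(per_depth) - 1L),
              loglik = object$loglik,
              selection = object$selection$diagnostics)
  class(out) <- "summary.vlmc"
  out
}

#' @export
print.summary.vlmc <- function(x, ...) {
  cat("VLMC context tree (depth ", x$depth, ", K = ",
      format(x$K %||% NA, digits = 5), ")\n", sep = "")
  cat("  nodes per depth (0 = root):\n")
  print(x$nodes_per_depth)
  if (!is.null(x$loglik))
    cat("  log pseudo-likelihood: ", format(x$loglik, digits = 8), "\n",
        sep = "")
  if (!is.null(x$selection)) {
    cat("  threshold search (candidate K, card, AIC):\n")
    print(x$selection, row.names = FALSE)
  }
  invisible(x)
}

#' Plot the threshold-selection diagnostics of a fitted VLMC
#'
#' Left: kernel density of the per-node KL statistics with the search
#' anchors (peak and right inflexions) and the selected K.  Right: AIC
#' over the candidate thresholds.
#'
#' @param x a \code{vlmc} fitted with \code{K = "auto"}.
#' @param ... passed to \code{plot}.
#' @export
plot.vlmc <- function(x, ...) {
  if (is.null(x$selection))
    stop("no selection diagnostics; fit with K = 'auto'")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  dens <- x$selection$delta_density
  if (!is.null(dens)) {
    plot(dens, main = "KL statistic density", xlab = "delta", ...)
    graphics::abline(v = x$selection$anchors, lty = 3, col = "grey40")
    graphics::abline(v = x$selection$K, col = "red3")
  }
  d <- x$selection$diagnostics
  plot(d$K, d$aic, type = "b", xlab = "candidate K", ylab = "read AIC",
       main = "Threshold search", ...)
  graphics::abline(v = x$selection$K, col = "red3")
  invisible(x)
}

#' Write / read a context tree as TSV
#'
#' Rows \code{context<TAB>count<TAB>pA<TAB>pC<TAB>pG<TAB>pT} (root row has
#' an empty context) with header lines \code{#max_depth}, \code{#K},
#' \code{#card}.  A reloaded tree answers probability queries; pruning
#' statistics are not serialised.
#'
#' @param tree a \code{vlmc} object.
#' @param path file path.
#' @rdname vlmc_io
#' @export
write_vlmc <- function(tree, path) {
  stopifnot(inherits(tree, "vlmc"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#max_depth=", tree$max_depth),
               paste0("#K=", format(tree$K %||% NA, digits = 17)),
               paste0("#card=", n_contexts(tree)),
               paste0("#sample=", tree$source_sample %||% "")), con)
  for (i in seq_along(tree$levels)) {
    lv <- tree$levels[[i]]
    if (length(lv$code) == 0L) next
    writeLines(paste(.decode(lv$code, i - 1L),
                     format(lv$cnt, scientific = FALSE, trim = TRUE),
                     apply(format(lv$trans, digits = 17), 1, paste,
                           collapse = "\t"),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname vlmc_io
#' @export
read_vlmc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  gv <- function(key) sub(paste0("^#", key, "="), "",
                          hdr[startsWith(hdr, paste0("#", key, "="))])
  max_depth <- as.integer(gv("max_depth"))
  K <- suppressWarnings(as.numeric(gv("K")))
  parts <- strsplit(body, "\t", fixed = TRUE)
  ctx <- vapply(parts, `[`, character(1), 1L)
  cnt <- as.numeric(vapply(parts, `[`, character(1), 2L))
  trans <- t(vapply(parts, function(p) as.numeric(p[3:6]), numeric(4)))
  colnames(trans) <- .BASES
  len <- nchar(ctx)
  enc <- .encode(ctx[len > 0])
  levels <- vector("list", max_depth + 1L)
  root <- which(len == 0)
  levels[[1]] <- list(code = 0, cnt = cnt[root], n = NA_real_,
                      trans = trans[root, , drop = FALSE])
  pos <- which(len > 0)
  for (l in seq_len(max_depth)) {
    idx <- pos[len[pos] == l]
    eidx <- which(len[pos] == l)
    o <- order(enc$code[eidx])
    levels[[l + 1L]] <- list(code = enc$code[eidx][o], cnt = cnt[idx][o],
                             n = rep(NA_real_, length(idx)),
                             trans = trans[idx[o], , drop = FALSE])
  }
  structure(list(levels = levels, max_depth = max_depth,
                 K = if (is.na(K)) NULL else K,
                 source_sample = gv("sample")),
            class = "vlmc")
}
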