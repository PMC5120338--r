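# Independent brute-force oracles used across the suite.

# Naive all-windows tuple counter: enumerate every window of every length
# 1..max_k in every read (and its reverse complement under "both"),
# dropping windows with non-ACGT characters.
naive_count <- function(reads, max_k, strand = "both") {
  pool <- reads
  rc_one <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s),
                                           "")[[1]]), collapse = "")
  clean <- gsub("[^ACGT]", "N", chartr("U", "T", toupper(reads)))
  pool <- clean
  if (strand == "both") pool <- c(pool, vapply(gsub("N", "N", clean),
    function(s) paste(rev(strsplit(chartr("ACGTN", "TGCAN", s),
                                   "")[[1]]), collapse = ""), character(1)))
  out <- list()
  for (s in pool) {
    n <- nchar(s)
    for (k in seq_len(max_k)) {
      if (n < k) next
      for (i in seq_len(n - k + 1)) {
        w <- substr(s, i, i + k - 1)
        if (grepl("N", w, fixed = TRUE)) next
        out[[w]] <- (out[[w]] %||% 0) + 1
      }
    }
  }
  unlist(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Naive triplet-topology oracle: prune the tree to each 3-leaf subset and
# read the topology off the pruned tree (cherry pair, or unresolved).
naive_triplet_code <- function(tree, trio) {
  sub <- ape::keep.tip(tree, trio)
  sub$edge.length <- NULL
  if (sub$Nnode == 1L) return("star")
  # binary: find the cherry = two tips sharing the deeper internal node
  ntip <- 3L
  root <- ntip + 1L
  deep <- setdiff(unique(sub$edge[, 1]), root)
  pair <- sort(sub$tip.label[sub$edge[sub$edge[, 1] == deep &
                                        sub$edge[, 2] <= ntip, 2]])
  paste(pair, collapse = "|")
}

naive_triples_distance <- function(t1, t2) {
  labs <- sort(t1$tip.label)
  trios <- utils::combn(labs, 3)
  sum(vapply(seq_len(ncol(trios)), function(i) {
    naive_triplet_code(t1, trios[, i]) != naive_triplet_code(t2, trios[, i])
  }, logical(1)))
}

# Build a tuple_counts table directly from per-length sparse counts
# (tuple string -> count), for hand-constructed fixtures.
manual_table <- function(counts_by_tuple, max_k, sample_id = "manual") {
  counts <- vector("list", max_k)
  tup <- names(counts_by_tuple)
  len <- nchar(tup)
  for (k in seq_len(max_k)) {
    sel <- which(len == k)
    code <- vlmcsig:::.encode_fixed(tup[sel], k)
    o <- order(code)
    counts[[k]] <- list(code = code[o],
                        count = as.numeric(counts_by_tuple[sel][o]))
  }
  structure(list(sample_id = sample_id, max_k = max_k, strand = "forward",
                 n_reads = 1L, counts = counts),
            class = "tuple_counts")
}

# Group labels of the scaled-down community design
group_labels <- function(n_groups, samples_per_group) {
  split(paste0("G", rep(seq_len(n_groups), each = samples_per_group),
               "_s", rep(seq_len(samples_per_group), n_groups)),
        rep(seq_len(n_groups), each = samples_per_group))
}

groups_are_clades <- function(tree, groups) {
  cl <- vlmcsig:::.clade_set(tree)
  all(vapply(groups, function(g)
    paste(sort(g), collapse = "|") %in% cl, logical(1)))
}

# Deterministic random read generator over ACGT
random_reads <- function(n, len, seed, p = rep(0.25, 4)) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
          collapse = ""), character(1))
}
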