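#' Count k-tuples in a read set
#'
#' Slides a window of every length \code{1..max_k} over each read and, with
#' \code{strand = "both"}, over its reverse complement, recording exact
#' occurrence counts.  Windows containing any character outside
#' \{A,C,G,T\} contribute nothing; input is case-insensitive and U is read
#' as T.  The resulting table is the sample's sequence signature from which
#' background models and dissimilarities are computed.
#'
#' @param reads one or more FASTA/FASTQ file paths (plain or gzipped), a
#'   character vector of read sequences, or a \code{Biostrings::XStringSet}.
#' @param max_k largest tuple length counted (>= 1).  The default 11 serves
#'   a context tree of depth 10, whose depth-10 contexts need length-11
#'   extension counts for their transition probabilities.
#' @param strand \code{"both"} (count each read and its reverse complement)
#'   or \code{"forward"}.
#' @param sample_id label stored with the table.
#' @return An object of class \code{tuple_counts} with fields
#'   \code{sample_id}, \code{max_k}, \code{strand}, \code{n_reads} (number
#'   of input records, not doubled by strand) and \code{counts}, a per-length
#'   list of sparse (code, count) pairs over observed tuples.
#' @examples
#' tc <- count_tuples("ACGT", max_k = 2)
#' count_of(tc, c("A", "AC"))
#' @export
count_tuples <- function(reads, max_k = 11L,
                         strand = c("both", "forward"),
                         sample_id = "sample") {
  strand <- match.arg(strand)
  if (!is.numeric(max_k) || length(max_k) != 1L || max_k < 1)
    stop("max_k must be a single integer >= 1")
  max_k <- as.integer(max_k)
  seqs <- .as_reads(reads)
  n_reads <- length(seqs)
  pool <- seqs
  if (strand == "both" && n_reads > 0L) {
    pool <- c(pool, Biostrings::reverseComplement(seqs))
  }
  counts <- vector("list", max_k)
  for (k in seq_len(max_k)) {
    v <- Biostrings::oligonucleotideFrequency(pool, width = k,
                                              simplify.as = "collapsed")
    nz <- which(v > 0)
    counts[[k]] <- list(code = as.numeric(nz - 1L), count = as.numeric(v[nz]))
  }
  structure(
    list(sample_id = sample_id, max_k = max_k, strand = strand,
         n_reads = n_reads, counts = counts),
    class = "tuple_counts"
  )
}

# Normalise read input to a sanitized DNAStringSet: uppercase, U -> T,
# anything outside ACGT -> N (N windows are skipped by the counters).
.as_reads <- function(reads) {
  if (inherits(reads, "XStringSet")) {
    ch <- as.character(reads)
  } else if (is.character(reads) && length(reads) > 0 &&
             all(file.exists(reads))) {
    ch <- unlist(lapply(reads, .read_seq_file))
  } else if (is.character(reads)) {
    looks_path <- grepl("[/\\\\]|\\.(fa|fasta|fq|fastq|gz)$", reads,
                        ignore.case = TRUE)
    if (any(looks_path & !file.exists(reads)))
      stop("cannot read file(s): ",
           paste(reads[looks_path & !file.exists(reads)], collapse = ", "))
    ch <- reads
  } else {
    stop("reads must be file paths, a character vector, or an XStringSet")
  }
  ch <- chartr("U", "T", toupper(ch))
  ch <- gsub("[^ACGT]", "N", ch)
  Biostrings::DNAStringSet(ch)
}

.read_seq_file <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  as.character(Biostrings::readBStringSet(path, format = fmt))
}

#' Reverse complement of nucleotide tuples
#'
#' @param s character vector of tuples over \{A,C,G,T\}.
#' @return character vector of Watson-Crick reverse complements.
#' @examples
#' reverse_complement(c("ACGT", "GCTAC"))
#' @export
reverse_complement <- function(s) {
  if (length(s) == 0L) return(character(0))
  if (!is.character(s) || any(grepl("[^ACGT]", s)))
    stop("tuples must contain only A/C/G/T characters")
  vapply(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

#' Dense k-tuple frequency vector
#'
#' Materialises the table's counts at one tuple length as a dense vector
#' over all \code{4^k} tuples in lexicographic order (A < C < G < T);
#' unobserved tuples are 0.
#'
#' @param table a \code{tuple_counts} object.
#' @param k tuple length, \code{1 <= k <= max_k}.
#' @param named attach tuple-string names (default only for
#'   \code{4^k <= 65536}).
#' @return numeric vector of length \code{4^k}.
#' @export
frequency_vector <- function(table, k, named = 4^k <= 65536) {
  stopifnot(inherits(table, "tuple_counts"))
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > table$max_k)
    stop("k must be in [1, max_k]")
  k <- as.integer(k)
  v <- numeric(4^k)
  sp <- table$counts[[k]]
  v[sp$code + 1] <- sp$count
  if (named) names(v) <- .all_tuples(k)
  v
}

#' Look up counts of specific tuples
#'
#' @param table a \code{tuple_counts} object.
#' @param tuples character vector of tuples (lengths \code{1..max_k}).
#' @return named numeric vector of counts (0 for unobserved tuples).
#' @export
count_of <- function(table, tuples) {
  stopifnot(inherits(table, "tuple_counts"))
  enc <- .encode(tuples)
  if (any(enc$length < 1 | enc$length > table$max_k))
    stop("tuple lengths must be in [1, max_k]")
  out <- numeric(length(tuples))
  for (l in unique(enc$length)) {
    idx <- which(enc$length == l)
    sp <- table$counts[[l]]
    m <- match(enc$code[idx], sp$code)
    out[idx] <- ifelse(is.na(m), 0, sp$count[m])
  }
  names(out) <- tuples
  out
}

#' @export
print.tuple_counts <- function(x, ...) {
  tot <- vapply(x$counts, function(s) sum(s$count), numeric(1))
  cat("k-tuple count table: sample '", x$sample_id, "'\n", sep = "")
  cat("  reads: ", x$n_reads, "  strand: ", x$strand,
      "  max_k: ", x$max_k, "\n", sep = "")
  cat("  total 1-tuples: ", tot[1],
      "; distinct ", x$max_k, "-tuples: ",
      length(x$counts[[x$max_k]]$code), "\n", sep = "")
  invisible(x)
}

# Element-wise sum of two count tables (same max_k and strand mode).
#' Combine two tuple-count tables
#'
#' Element-wise sum, equivalent to counting the concatenation of the two
#' read sets.
#' @param a,b \code{tuple_counts} with identical \code{max_k} and strand.
#' @param sample_id label of the merged table.
#' @export
merge_counts <- function(a, b, sample_id = a$sample_id) {
  stopifnot(inherits(a, "tuple_counts"), inherits(b, "tuple_counts"))
  if (a$max_k != b$max_k || a$strand != b$strand)
    stop("tables must share max_k and strand mode")
  counts <- vector("list", a$max_k)
  for (k in seq_len(a$max_k)) {
    code <- sort(unique(c(a$counts[[k]]$code, b$counts[[k]]$code)))
    cnt <- numeric(length(code))
    ma <- match(a$counts[[k]]$code, code)
    mb <- match(b$counts[[k]]$code, code)
    cnt[ma] <- cnt[ma] + a$counts[[k]]$count
    cnt[mb] <- cnt[mb] + b$counts[[k]]$count
    counts[[k]] <- list(code = code, count = cnt)
  }
  structure(
    list(sample_id = sample_id, max_k = a$max_k, strand = a$strand,
         n_reads = a$n_reads + b$n_reads, counts = counts),
    class = "tuple_counts"
  )
}

#' Write / read a tuple-count table as TSV
#'
#' Plain-text round-trip format: header lines \code{#sample=}, \code{#max_k=},
#' \code{#strand=}, \code{#n_reads=} followed by \code{tuple<TAB>count} rows.
#' @param table a \code{tuple_counts} object.
#' @param path output / input file path.
#' @rdname counts_io
#' @export
write_counts <- function(table, path) {
  stopifnot(inherits(table, "tuple_counts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#sample=", table$sample_id),
               paste0("#max_k=", table$max_k),
               paste0("#strand=", table$strand),
               paste0("#n_reads=", table$n_reads)), con)
  for (k in seq_len(table$max_k)) {
    sp <- table$counts[[k]]
    if (length(sp$code))
      writeLines(paste(.decode(sp$code, k),
                       format(sp$count, scientific = FALSE, trim = TRUE),
                       sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname counts_io
#' @export
read_counts <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  get_hdr <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("#", key, "="))]
    if (length(ln) != 1L) stop("missing header #", key, " in ", path)
    sub(paste0("^#", key, "="), "", ln)
  }
  max_k <- as.integer(get_hdr("max_k"))
  parts <- strsplit(body, "\t", fixed = TRUE)
  tup <- vapply(parts, `[`, character(1), 1L)
  cnt <- as.numeric(vapply(parts, `[`, character(1), 2L))
  enc <- .encode(tup)
  counts <- vector("list", max_k)
  for (k in seq_len(max_k)) {
    idx <- which(enc$length == k)
    o <- order(enc$code[idx])
    counts[[k]] <- list(code = enc$code[idx][o], count = cnt[idx][o])
  }
  structure(
    list(sample_id = get_hdr("sample"), max_k = max_k,
         strand = get_hdr("strand"), n_reads = as.integer(get_hdr("n_reads")),
         counts = counts),
    class = "tuple_counts"
  )
}
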