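# Synthetic metatranscriptomic community simulator: mock gene catalogs,
# fold-change designs, lognormal group/sample expression noise,
# negative-binomial read depths and error-free read emission.  Everything
# is deterministic under its seed, so the full analysis stack can be
# exercised without downloading data.

#' Generate a mock gene catalog
#'
#' Draws i.i.d. random gene sequences for a community of
#' \code{n_genomes} genomes with \code{genes_per_genome} genes each.
#' Genomes receive distinct GC contents (by default evenly spaced over
#' 0.35-0.65, mimicking the compositional spread of gut bacteria) so
#' that genome-level sequence signatures differ.
#'
#' @param n_genomes number of genomes (default 5).
#' @param genes_per_genome genes per genome (default 1000).
#' @param gene_length_range min/max gene length, drawn uniformly.
#' @param gc_content scalar or per-genome vector of GC fractions;
#'   \code{NULL} for the evenly spaced default.
#' @param seed RNG seed.
#' @return object of class \code{mock_community}: data frame
#'   \code{genes} (gene_id, genome, length, sequence).
#' @export
make_community <- function(n_genomes = 5L, genes_per_genome = 1000L,
                           gene_length_range = c(200L, 1500L),
                           gc_content = NULL, seed = 1L) {
  if (n_genomes < 1L || genes_per_genome < 1L) stop("sizes must be >= 1")
  if (is.null(gc_content)) {
    gc_content <- if (n_genomes == 1L) 0.5 else
      seq(0.35, 0.65, length.out = n_genomes)
  }
  gc_content <- rep_len(gc_content, n_genomes)
  .with_seed(seed, {
    rows <- lapply(seq_len(n_genomes), function(g) {
      len <- sample(gene_length_range[1]:gene_length_range[2],
                    genes_per_genome, replace = TRUE)
      p <- c(A = (1 - gc_content[g]) / 2, C = gc_content[g] / 2,
             G = gc_content[g] / 2, T = (1 - gc_content[g]) / 2)
      seqs <- vapply(len, function(L)
        paste(sample(.BASES, L, replace = TRUE, prob = p), collapse = ""),
        character(1))
      data.frame(
        gene_id = sprintf("g%d_%04d", g, seq_len(genes_per_genome)),
        genome = paste0("genome", g), length = len, sequence = seqs,
        stringsAsFactors = FALSE)
    })
    structure(list(genes = do.call(rbind, rows),
                   n_genomes = n_genomes,
                   genes_per_genome = genes_per_genome,
                   gc_content = gc_content, seed = seed),
              class = "mock_community")
  })
}

#' @export
print.mock_community <- function(x, ...) {
  cat("mock community: ", x$n_genomes, " genomes x ", x$genes_per_genome,
      " genes (", nrow(x$genes), " genes total)\n", sep = "")
  cat("  gene lengths ", min(x$genes$length), "-", max(x$genes$length),
      " bp; GC ", paste(format(x$gc_content, digits = 2), collapse = "/"),
      "\n", sep = "")
  invisible(x)
}

#' Basic fold-change vector of a differential-expression design
#'
#' Assigns exactly \code{round(frac_up * n)} genes the fold change
#' \code{fold}, \code{round(frac_down * n)} genes \code{1/fold}, and 1 to
#' the rest (the defaults give 20\% up at fold 4, 20\% down at fold 1/4,
#' 60\% unchanged); positions are shuffled by the seed.
#'
#' @param n_genes number of genes.
#' @param frac_up,frac_down fractions of up-/down-regulated genes.
#' @param fold fold change of the regulated genes (> 0).
#' @param seed RNG seed.
#' @return numeric vector of length \code{n_genes} over
#'   \{fold, 1/fold, 1\}.
#' @export
basic_fold_change_vector <- function(n_genes, frac_up = 0.2,
                                     frac_down = 0.2, fold = 4,
                                     seed = 1L) {
  if (frac_up < 0 || frac_down < 0 || frac_up + frac_down > 1)
    stop("need frac_up, frac_down >= 0 and frac_up + frac_down <= 1")
  if (fold <= 0) stop("fold must be positive")
  n_up <- round(frac_up * n_genes)
  n_down <- round(frac_down * n_genes)
  A <- c(rep(fold, n_up), rep(1 / fold, n_down),
         rep(1, n_genes - n_up - n_down))
  .with_seed(seed, sample(A))
}

#' Group and sample expression vectors with lognormal noise
#'
#' Group centers perturb the basic fold-change vector element-wise by
#' \code{exp(Normal(0, sigma_group^2))}; each sample perturbs its group
#' center by \code{exp(Normal(0, sigma_sample^2))}.
#'
#' @param A basic fold-change vector.
#' @param n_groups,samples_per_group design size (defaults 3 x 30).
#' @param sigma_group,sigma_sample lognormal noise scales on the log
#'   scale (defaults 0.3 and 0.1).
#' @param seed RNG seed.
#' @return list with \code{centers} (genes x groups matrix),
#'   \code{expression} (genes x samples matrix) and \code{group} (group
#'   label per sample).
#' @export
group_and_sample_expression <- function(A, n_groups = 3L,
                                        samples_per_group = 30L,
                                        sigma_group = 0.3,
                                        sigma_sample = 0.1, seed = 1L) {
  if (sigma_group < 0 || sigma_sample < 0) stop("sigma must be >= 0")
  n <- length(A)
  .with_seed(seed, {
    centers <- vapply(seq_len(n_groups), function(g)
      A * exp(stats::rnorm(n, 0, sigma_group)), numeric(n))
    expr <- matrix(0, n, n_groups * samples_per_group)
    group <- character(n_groups * samples_per_group)
    for (g in seq_len(n_groups)) for (s in seq_len(samples_per_group)) {
      j <- (g - 1L) * samples_per_group + s
      expr[, j] <- centers[, g] * exp(stats::rnorm(n, 0, sigma_sample))
      group[j] <- paste0("G", g)
    }
    colnames(expr) <- paste0(group, "_s",
                             rep(seq_len(samples_per_group), n_groups))
    colnames(centers) <- paste0("G", seq_len(n_groups))
    list(centers = centers, expression = expr, group = group)
  })
}

#' Simulate error-free reads from a community at given expression
#'
#' Per gene, the read count is a negative-binomial baseline
#' (\code{mean = nb_mean}, \code{size = nb_dispersion}) multiplied by the
#' gene's expression level and rounded; each read is an error-free
#' substring of length \code{read_length} at a uniform start position on
#' a uniform strand.
#'
#' @param community a \code{mock_community}.
#' @param expression per-gene expression vector (length = total genes).
#' @param nb_mean baseline negative-binomial mean (default 300).
#' @param nb_dispersion negative-binomial size parameter; the default
#'   \code{nb_mean / 3} mirrors the RNA-seq simulators this design
#'   emulates and gives variance = 4 x mean at every depth.
#' @param read_length read length in bp (default 76).
#' @param seed RNG seed.
#' @param out optional output stem: writes \code{<out>.fasta} and the
#'   truth table \code{<out>.truth.tsv}.
#' @return list with \code{reads} (character vector) and \code{truth}
#'   (data frame gene_id, genome, expression, baseline, n_reads).
#' @export
simulate_reads <- function(community, expression, nb_mean = 300,
                           nb_dispersion = nb_mean / 3, read_length = 76L,
                           seed = 1L, out = NULL) {
  stopifnot(inherits(community, "mock_community"))
  genes <- community$genes
  if (length(expression) != nrow(genes))
    stop("expression length must equal the number of genes")
  if (any(genes$length < read_length))
    stop("all genes must be at least read_length long")
  .with_seed(seed, {
    baseline <- stats::rnbinom(nrow(genes), mu = nb_mean,
                               size = nb_dispersion)
    n_reads <- as.integer(round(baseline * expression))
    gene_idx <- rep.int(seq_len(nrow(genes)), n_reads)
    total <- length(gene_idx)
    reads <- character(0)
    if (total > 0) {
      start <- floor(stats::runif(total) *
                       (genes$length[gene_idx] - read_length + 1)) + 1
      fwd <- stats::runif(total) < 0.5
      reads <- substr(rep(genes$sequence, n_reads), start,
                      start + read_length - 1L)
      if (any(!fwd)) reads[!fwd] <- reverse_complement(reads[!fwd])
    }
    truth <- data.frame(gene_id = genes$gene_id, genome = genes$genome,
                        expression = expression, baseline = baseline,
                        n_reads = n_reads, stringsAsFactors = FALSE)
    if (!is.null(out)) {
      fa <- Biostrings::DNAStringSet(reads)
      names(fa) <- if (total > 0)
        paste0("read", seq_len(total), "|", genes$gene_id[gene_idx])
        else character(0)
      Biostrings::writeXStringSet(fa, paste0(out, ".fasta"))
      utils::write.table(truth, paste0(out, ".truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    list(reads = reads, truth = truth)
  })
}

#' Simulate a full multi-group community experiment
#'
#' Convenience wrapper reproducing the benchmark design end to end at a
#' configurable scale: mock community, fold-change vector, group/sample
#' expression noise, then one read set per sample.  Defaults follow the
#' reference design (5 genomes x 1000 genes, 3 groups x 30 samples,
#' negative-binomial baseline mean 300, 76 bp reads); tests and examples
#' scale the counts down.
#'
#' @param n_genomes,genes_per_genome,gene_length_range,gc_content
#'   community parameters (see \code{\link{make_community}}).
#' @param n_groups,samples_per_group design size.
#' @param frac_up,frac_down,fold fold-change design.
#' @param sigma_group,sigma_sample lognormal noise scales.
#' @param nb_mean,nb_dispersion,read_length read-depth parameters.
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir optional directory: per-sample FASTA + truth TSV plus a
#'   \code{design.json} echoing every parameter.
#' @return list with \code{community}, \code{design} (parameters),
#'   \code{expression}, \code{group} and \code{samples} (named list of
#'   read vectors).
#' @export
simulate_experiment <- function(n_genomes = 5L, genes_per_genome = 1000L,
                                gene_length_range = c(200L, 1500L),
                                gc_content = NULL,
                                n_groups = 3L, samples_per_group = 30L,
                                frac_up = 0.2, frac_down = 0.2, fold = 4,
                                sigma_group = 0.3, sigma_sample = 0.1,
                                nb_mean = 300, nb_dispersion = nb_mean / 3,
                                read_length = 76L, seed = 1L,
                                out_dir = NULL) {
  seeds <- .with_seed(seed, sample.int(2^31 - 1L, 3L))
  comm <- make_community(n_genomes, genes_per_genome, gene_length_range,
                         gc_content, seed = seeds[1])
  n_genes <- nrow(comm$genes)
  A <- basic_fold_change_vector(n_genes, frac_up, frac_down, fold,
                                seed = seeds[2])
  ge <- group_and_sample_expression(A, n_groups, samples_per_group,
                                    sigma_group, sigma_sample,
                                    seed = seeds[3])
  read_seeds <- .with_seed(seeds[3], sample.int(2^31 - 1L, ncol(ge$expression)))
  samples <- vector("list", ncol(ge$expression))
  names(samples) <- colnames(ge$expression)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  for (j in seq_len(ncol(ge$expression))) {
    sim <- simulate_reads(comm, ge$expression[, j], nb_mean, nb_dispersion,
                          read_length, seed = read_seeds[j],
                          out = if (is.null(out_dir)) NULL else
                            file.path(out_dir, names(samples)[j]))
    samples[[j]] <- sim$reads
  }
  design <- list(n_genomes = n_genomes, genes_per_genome = genes_per_genome,
                 gene_length_range = gene_length_range,
                 gc_content = comm$gc_content, n_groups = n_groups,
                 samples_per_group = samples_per_group, frac_up = frac_up,
                 frac_down = frac_down, fold = fold,
                 sigma_group = sigma_group, sigma_sample = sigma_sample,
                 nb_mean = nb_mean, nb_dispersion = nb_dispersion,
                 read_length = read_length, seed = seed,
                 stage_seeds = as.integer(seeds))
  if (!is.null(out_dir))
    jsonlite::write_json(design, file.path(out_dir, "design.json"),
                         auto_unbox = TRUE, digits = NA)
  list(community = comm, design = design, fold_change = A,
       expression = ge$expression, group = ge$group, samples = samples)
}
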