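# Orchestration: count -> fit background models -> dissimilarity
# matrices -> UPGMA trees -> evaluation against a reference tree.

#' Run the full comparison pipeline
#'
#' For every combination of measure, background model and tuple length,
#' computes the pairwise dissimilarity matrix over the samples, clusters
#' it with UPGMA and, when a reference tree is supplied, scores the
#' clustering tree by the rooted triples distance.  Each sample's
#' background model is fitted from that sample's own reads and reused
#' across measures and k.
#'
#' @param config a named list, or a path to a YAML/JSON file, with
#'   fields:
#'   \describe{
#'     \item{samples}{named list: label -> read file path(s) or read
#'       character vector (required, >= 2 samples).}
#'     \item{k}{tuple lengths (default \code{2:9}).}
#'     \item{measures}{subset of d2s, d2star, d2, ma, eu, ch (default
#'       \code{"d2s"}).}
#'     \item{models}{background specs for the normalised measures:
#'       \code{"vlmc"} (auto K), \code{"vlmc:<K>"} or \code{"fomc:<r>"}
#'       (default \code{"vlmc"}).}
#'     \item{max_depth}{context-tree depth (default 10); requires
#'       \code{max(k) <= max_depth - 1}.}
#'     \item{strand}{counting strand mode (default \code{"both"}).}
#'     \item{min_count}{full-tree node threshold (default 1).}
#'     \item{reference_tree}{optional Newick path/string or \code{phylo}.}
#'     \item{null_trees}{optional: draw this many random trees for a
#'       triples-distance p-value.}
#'     \item{seed}{seed for the null draw (default 1).}
#'     \item{out_dir}{optional: write matrices (TSV), trees (Newick) and
#'       the results table.}
#'   }
#' @return list with \code{results} (one row per measure/model/k:
#'   distance, p-value, best flag), \code{matrices}, \code{trees},
#'   \code{models} and the expanded \code{config}.
#' @export
run_pipeline <- function(config) {
  cfg <- .load_config(config)
  labels <- names(cfg$samples)
  t_all <- proc.time()[3]

  message("[count] ", length(labels), " samples, max_k = ",
          cfg$max_depth + 1L)
  counts <- lapply(labels, function(s) {
    count_tuples(cfg$samples[[s]], max_k = cfg$max_depth + 1L,
                 strand = cfg$strand, sample_id = s)
  })
  names(counts) <- labels

  needs_bg <- any(cfg$measures %in% c("d2s", "d2star"))
  models <- list()
  if (needs_bg) {
    for (spec in cfg$models) {
      t0 <- proc.time()[3]
      models[[spec]] <- lapply(labels, function(s)
        .fit_background(spec, counts[[s]], cfg$samples[[s]], cfg))
      names(models[[spec]]) <- labels
      info <- if (startsWith(spec, "vlmc")) {
        ks <- vapply(models[[spec]], function(m) m$K %||% NA_real_,
                     numeric(1))
        cards <- vapply(models[[spec]], n_contexts, numeric(1))
        paste0("median K = ", format(stats::median(ks), digits = 4),
               ", median card = ", stats::median(cards))
      } else ""
      message("[fit] ", spec, " on ", length(labels), " samples (",
              round(proc.time()[3] - t0, 1), " s) ", info)
    }
  }

  ref <- cfg$reference_tree
  combos <- .measure_model_combos(cfg$measures, cfg$models)
  results <- NULL
  matrices <- list()
  trees <- list()
  if (!is.null(cfg$out_dir) && !dir.exists(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE)
  for (ci in seq_len(nrow(combos))) {
    measure <- combos$measure[ci]
    mspec <- combos$model[ci]
    for (k in cfg$k) {
      tag <- paste0(measure, ".", gsub(":", "", mspec), ".k", k)
      m <- dissimilarity_matrix(counts, measure, k,
                                models = models[[mspec]])
      tr <- upgma(m)
      matrices[[tag]] <- m
      trees[[tag]] <- tr
      row <- data.frame(measure = measure, model = mspec, k = k,
                        triples = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE)
      if (!is.null(ref)) {
        row$triples <- triples_distance(tr, ref)
        if (!is.null(cfg$null_trees)) {
          row$p_value <- random_tree_null(tr, ref,
                                          n_trees = cfg$null_trees,
                                          seed = cfg$seed)$p_value
        }
      }
      results <- rbind(results, row)
      if (!is.null(cfg$out_dir)) {
        write_diss_matrix(m, file.path(cfg$out_dir,
                                       paste0(tag, ".dist.tsv")))
        to_newick(tr, file.path(cfg$out_dir, paste0(tag, ".nwk")))
      }
      message("[compare] ", tag,
              if (!is.na(row$triples)) paste0(" triples = ", row$triples))
    }
  }
  if (!is.null(ref) && nrow(results) > 0) {
    results$best <- !is.na(results$triples) &
      results$triples == min(results$triples, na.rm = TRUE)
  }
  if (!is.null(cfg$out_dir))
    utils::write.table(results, file.path(cfg$out_dir, "results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  message("[done] ", nrow(combos) * length(cfg$k), " settings in ",
          round(proc.time()[3] - t_all, 1), " s")
  list(results = results, matrices = matrices, trees = trees,
       models = models, config = cfg)
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config)
    else jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path")
  cfg <- list(
    samples = config$samples,
    k = config$k %||% 2:9,
    measures = config$measures %||% "d2s",
    models = config$models %||% "vlmc",
    max_depth = config$max_depth %||% 10L,
    strand = config$strand %||% "both",
    min_count = config$min_count %||% 1L,
    reference_tree = config$reference_tree,
    null_trees = config$null_trees,
    seed = config$seed %||% 1L,
    out_dir = config$out_dir
  )
  if (is.null(cfg$samples) || length(cfg$samples) < 2L)
    stop("config$samples must name at least 2 samples")
  if (is.null(names(cfg$samples)) || anyDuplicated(names(cfg$samples)))
    stop("sample labels must be unique")
  cfg$measures <- match.arg(cfg$measures,
                            c("d2s", "d2star", "d2", "ma", "eu", "ch"),
                            several.ok = TRUE)
  bad <- !grepl("^(vlmc(:[0-9.eE+-]+)?|fomc:[0-4])$", cfg$models)
  if (any(bad)) stop("invalid model spec: ", cfg$models[bad][1])
  if (any(cfg$measures %in% c("d2s", "d2star")) &&
      max(cfg$k) > cfg$max_depth - 1L)
    stop("background-normalised measures need k <= max_depth - 1 ",
         "(got k = ", max(cfg$k), ", max_depth = ", cfg$max_depth, ")")
  if (!is.null(cfg$reference_tree) && !inherits(cfg$reference_tree, "phylo")) {
    cfg$reference_tree <- if (file.exists(cfg$reference_tree))
      from_newick(path = cfg$reference_tree)
    else from_newick(cfg$reference_tree)
  }
  cfg
}

.fit_background <- function(spec, counts, reads, cfg) {
  if (spec == "vlmc" || startsWith(spec, "vlmc:")) {
    K <- if (spec == "vlmc") "auto" else as.numeric(sub("^vlmc:", "", spec))
    vlmc(reads, max_depth = cfg$max_depth, K = K, counts = counts,
         min_count = cfg$min_count, sample_id = counts$sample_id)
  } else {
    fomc(counts, order = as.integer(sub("^fomc:", "", spec)))
  }
}

.measure_model_combos <- function(measures, models) {
  rows <- list()
  for (m in measures) {
    if (m %in% c("d2s", "d2star")) {
      for (sp in models) rows[[length(rows) + 1L]] <-
          data.frame(measure = m, model = sp, stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <-
        data.frame(measure = m, model = "none", stringsAsFactors = FALSE)
    }
  }
  unique(do.call(rbind, rows))
}
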