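test_that("the full prefix tree matches hand enumeration", {
  tc <- count_tuples("AAAA", max_k = 3)
  tr <- build_prefix_tree(tc, max_depth = 2)
  ctx <- contexts(tr)
  expect_setequal(ctx$context, c("", "A", "T", "AA", "TT"))
  expect_equal(ctx[ctx$context == "A", "A"], 1)
  expect_equal(ctx[ctx$context == "TT", "T"], 1)
  expect_equal(n_contexts(tr), 4)
  # node-count bound: non-root nodes <= distinct observed tuples per level
  reads <- random_reads(10, 25, seed = 2)
  tc2 <- count_tuples(reads, max_k = 4)
  tr2 <- build_prefix_tree(tc2, max_depth = 3)
  for (l in 1:3)
    expect_lte(length(tr2$levels[[l + 1]]$code),
               length(tc2$counts[[l]]$code))
  expect_error(build_prefix_tree(tc2, max_depth = 4), "max_k")
  empty <- manual_table(c(A = 0), max_k = 2)
  empty$counts[[1]] <- list(code = numeric(0), count = numeric(0))
  expect_error(build_prefix_tree(empty, 1), "empty")
})

test_that("KL pruning statistic reproduces the worked value and scales", {
  # child A: extensions (4,4,0,0), N=8; parent root uniform
  tab <- manual_table(c(A = 10, C = 10, G = 10, T = 10,
                        AA = 4, AC = 4), max_k = 2)
  tr <- build_prefix_tree(tab, max_depth = 1)
  expect_equal(kl_statistic(tr, "A"), 8 * log(2), tolerance = 1e-12)
  # doubling child counts doubles the statistic
  tab2 <- manual_table(c(A = 10, C = 10, G = 10, T = 10,
                         AA = 8, AC = 8), max_k = 2)
  tr2 <- build_prefix_tree(tab2, max_depth = 1)
  expect_equal(kl_statistic(tr2, "A"), 16 * log(2), tolerance = 1e-12)
  # identical child and parent distributions give 0
  tab3 <- manual_table(c(A = 8, C = 8, G = 8, T = 8,
                         AA = 2, AC = 2, AG = 2, AT = 2), max_k = 2)
  expect_equal(kl_statistic(build_prefix_tree(tab3, 1), "A"), 0)
  expect_error(kl_statistic(tr, "GG"), "not in tree")
})

test_that("pruning behaves at the limits and around the worked threshold", {
  reads <- random_reads(40, 50, seed = 11)
  tc <- count_tuples(reads, max_k = 4)
  full <- build_prefix_tree(tc, max_depth = 3)
  expect_equal(n_contexts(prune_tree(full, 0)), n_contexts(full))
  root_only <- prune_tree(full, Inf)
  expect_equal(n_contexts(root_only), 0)
  # root-only tree gives i.i.d. products
  f1 <- frequency_vector(tc, 1); f1 <- f1 / sum(f1)
  expect_equal(tuple_probability(root_only, "ACG"),
               unname(f1["A"] * f1["C"] * f1["G"]), tolerance = 1e-12)
  # card is non-increasing in K
  deltas <- sort(unique(unlist(vlmcsig:::.kl_all(full)[-1])))
  grid <- unique(stats::quantile(deltas, c(0, .2, .5, .8, 1)))
  cards <- vapply(c(grid, Inf), function(K)
    n_contexts(prune_tree(full, K)), numeric(1))
  expect_true(all(diff(cards) <= 0))
  # worked 8*ln2 node: kept at K=5, pruned at K=6
  tab <- manual_table(c(A = 10, C = 10, G = 10, T = 10,
                        AA = 4, AC = 4), max_k = 2)
  tr <- build_prefix_tree(tab, max_depth = 1)
  expect_true("A" %in% contexts(prune_tree(tr, 5))$context)
  expect_false("A" %in% contexts(prune_tree(tr, 6))$context)
  trace <- attr(prune_tree(tr, 6), "prune_trace")
  expect_true(all(trace$delta < 6))
  expect_true(all(trace$iteration >= 1))
  expect_error(prune_tree(full, -1), "non-negative")
})

test_that("pruned-tree probabilities use the longest suffix context", {
  # tree with nodes {root, T}: P(TA) = P(T|root) * P(A|T)
  tab <- manual_table(c(A = 2, C = 1, G = 1, T = 4,
                        TA = 2, TT = 2), max_k = 2)
  tr <- build_prefix_tree(tab, max_depth = 1)
  expect_equal(tuple_probability(tr, "TA"), (4 / 8) * (2 / 4),
               tolerance = 1e-12)
  # deeper suffices win: unpruned depth-2 tree vs hand product
  tab2 <- manual_table(c(A = 6, G = 6,
                         AG = 3, GA = 3, GG = 2,
                         AGA = 2, AGG = 1), max_k = 3)
  tr2 <- build_prefix_tree(tab2, max_depth = 2)
  # P(AGA) = P(A|root) P(G|A) P(A|AG)
  expect_equal(tuple_probability(tr2, "AGA"),
               (6 / 12) * (3 / 3) * (2 / 3), tolerance = 1e-12)
})

test_that("unpruned depth-r trees coincide with order-r chains", {
  reads <- random_reads(60, 60, seed = 13, p = c(0.35, 0.15, 0.2, 0.3))
  tc <- count_tuples(reads, max_k = 4)
  w <- c("ACGTA", "GGG", "TACGTT", "AAAAA")
  for (r in 1:3) {
    tr <- build_prefix_tree(tc, max_depth = r)
    m <- fomc(tc, r)
    expect_equal(tuple_probability(tr, w), tuple_probability(m, w),
                 tolerance = 1e-12)
  }
})

test_that("tuple probabilities stay normalised after pruning", {
  reads <- random_reads(50, 40, seed = 17)
  tc <- count_tuples(reads, max_k = 5)
  full <- build_prefix_tree(tc, max_depth = 4)
  for (K in c(0, 2, 10, Inf)) {
    tr <- prune_tree(full, K)
    for (k in c(1, 3, 6))
      expect_equal(sum(probability_profile(tr, k)), 1, tolerance = 1e-9)
  }
})

test_that("log pseudo-likelihood matches hand values and is additive", {
  tcu <- count_tuples(c("ACGT", "TGCA"), max_k = 2, strand = "forward")
  root_only <- prune_tree(build_prefix_tree(tcu, 1), Inf)
  expect_equal(log_pseudo_likelihood(root_only, "AC"), log(0.25),
               tolerance = 1e-12)
  expect_equal(log_pseudo_likelihood(root_only, character(0)), 0)
  expect_equal(log_pseudo_likelihood(root_only, c("ACGT", "GGTA")),
               log_pseudo_likelihood(root_only, "ACGT") +
                 log_pseudo_likelihood(root_only, "GGTA"),
               tolerance = 1e-12)
  # ambiguity splits a read: first base of each fragment contributes no term
  expect_equal(log_pseudo_likelihood(root_only, "ACNGT"),
               log_pseudo_likelihood(root_only, c("AC", "GT")),
               tolerance = 1e-12)
  # AIC worked value and per-node penalty increment
  expect_equal(aic_read(root_only, "AC"), -2 * log(0.25),
               tolerance = 1e-12)
  reads <- random_reads(10, 30, seed = 23)
  tc <- count_tuples(reads, max_k = 3)
  full <- build_prefix_tree(tc, 2)
  pruned <- prune_tree(full, Inf)
  expect_equal((aic_read(full, reads) + 2 * log_pseudo_likelihood(full, reads)) -
                 (aic_read(pruned, reads) +
                    2 * log_pseudo_likelihood(pruned, reads)),
               6 * n_contexts(full))
  # a foreign tree can assign probability zero -> informative error
  foreign <- build_prefix_tree(count_tuples("AAAA", max_k = 3,
                                            strand = "forward"), 2)
  expect_error(log_pseudo_likelihood(foreign, "ACGT"), "refit")
})

test_that("threshold selection minimises AIC over its candidate set", {
  reads <- random_reads(200, 60, seed = 29, p = c(0.4, 0.1, 0.15, 0.35))
  tc <- count_tuples(reads, max_k = 5)
  sel <- select_threshold(tc, reads, max_depth = 4)
  expect_equal(min(sel$diagnostics$aic),
               sel$diagnostics$aic[sel$diagnostics$K == sel$K])
  expect_equal(n_contexts(sel$tree),
               sel$diagnostics$card[sel$diagnostics$K == sel$K])
  # exhaustive fallback for tiny trees
  tiny <- count_tuples("ACGTAC", max_k = 3)
  sel2 <- select_threshold(tiny, "ACGTAC", max_depth = 2)
  expect_true(sel2$K %in% sel2$diagnostics$K)
  expect_equal(min(sel2$diagnostics$aic),
               sel2$diagnostics$aic[sel2$diagnostics$K == sel2$K])
})

test_that("model selection recovers a strong order-1 chain", {
  truth <- matrix(0.1, 4, 4); diag(truth) <- 0.7
  gen <- structure(list(order = 1L, initial = rep(0.25, 4), trans = truth,
                        start_trans = list(matrix(0.25, 1, 4)),
                        source_sample = "truth"), class = "fomc")
  reads <- simulate(gen, nsim = 400, seed = 31, read_length = 100)
  fit <- vlmc(reads, max_depth = 6, sample_id = "chain")
  per_depth <- vapply(fit$levels, function(lv) length(lv$code), numeric(1))
  expect_equal(per_depth[2], 4)     # all four depth-1 contexts kept
  expect_lt(sum(per_depth[4:7]), 0.05 * sum(4^(3:6)))
  expect_lt(max(abs(fit$levels[[2]]$trans - truth)), 0.03)
  # i.i.d. uniform data: most of the full tree is pruned (what survives
  # is the chi-square tail of noise nodes) and low-order tuple
  # probabilities stay near the i.i.d. product
  iid <- random_reads(400, 100, seed = 37)
  fit2 <- vlmc(iid, max_depth = 6, sample_id = "iid")
  full2 <- build_prefix_tree(count_tuples(iid, max_k = 7), 6)
  expect_lt(n_contexts(fit2), 0.5 * n_contexts(full2))
  expect_lt(max(abs(tuple_probability(fit2, c("ACG", "TTT", "GAC")) -
                      1 / 64)), 0.02)
  # parameter economy relative to a same-depth fixed-order chain (soft log)
  ratio <- (4^6 * 3) / max(1, n_parameters(fit))
  message("parameter-economy ratio vs order-6 chain: ",
          round(ratio, 1), "x")
  expect_gt(ratio, 1)
})

test_that("the vlmc front end stores likelihood, AIC and diagnostics", {
  reads <- random_reads(100, 50, seed = 41)
  fit <- vlmc(reads, max_depth = 4, sample_id = "s")
  expect_s3_class(fit, "vlmc")
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 3 * n_contexts(fit))
  expect_equal(AIC(fit), -2 * as.numeric(ll) + 6 * n_contexts(fit))
  expect_equal(as.numeric(ll), log_pseudo_likelihood(fit, reads),
               tolerance = 1e-9)
  expect_true(!is.null(fit$selection$diagnostics))
  fixed <- vlmc(reads, max_depth = 4, K = 3, sample_id = "s")
  expect_equal(fixed$K, 3)
  # serialization preserves probability queries
  f <- tempfile(fileext = ".tsv")
  write_vlmc(fit, f)
  back <- read_vlmc(f)
  w <- c("ACGTA", "TTGCA", "GGG")
  expect_equal(tuple_probability(back, w), tuple_probability(fit, w),
               tolerance = 1e-12)
  expect_equal(back$K, fit$K, tolerance = 1e-12)
})
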