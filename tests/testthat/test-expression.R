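test_that("regulated-transcript calling applies both thresholds jointly", {
  expr <- tibble::tibble(
    transcript_id = c("a", "b", "c", "d"),
    timepoint = 2,
    log2_fc = log2(c(1.6, 1.4, 2.0, 1 / 1.7)),
    diff_p = c(0.005, 0.001, 0.02, 0.004))
  calls <- call_regulated(expr)
  expect_equal(calls$direction, c("up", "none", "none", "down"))

  # passing at any one time point is enough; direction from the lowest p
  multi <- tibble::tibble(
    transcript_id = "t", timepoint = c(2, 6, 24),
    log2_fc = c(0.1, 1.2, -1.3), diff_p = c(0.5, 0.004, 0.002))
  expect_equal(regulated_transcripts(call_regulated(multi))$direction, "down")
  expect_equal(regulated_transcripts(call_regulated(multi))$first_timepoint, 6)

  # monotone in the fold-change threshold
  withr::with_seed(71, {
    big <- tibble::tibble(transcript_id = sprintf("t%03d", 1:300),
                          timepoint = 2,
                          log2_fc = rnorm(300, 0, 1),
                          diff_p = runif(300, 0, 0.02))
  })
  for (fc_pair in list(c(2, 1.5), c(1.5, 1.2), c(1.2, 1))) {
    hi <- regulated_transcripts(call_regulated(big, fc_threshold = fc_pair[1]))
    lo <- regulated_transcripts(call_regulated(big, fc_threshold = fc_pair[2]))
    expect_true(all(hi$transcript_id %in% lo$transcript_id))
  }

  # missing values: skipped with a warning count
  withna <- dplyr::mutate(expr, diff_p = replace(diff_p, 2, NA))
  expect_warning(out <- call_regulated(withna), "skipped")
  expect_equal(attr(out, "n_skipped"), 1)
})

test_that("SOM clustering: degenerate cases and determinism", {
  profiles <- matrix(rep(c(1, 2, 3), each = 10), nrow = 10)
  rownames(profiles) <- sprintf("t%d", 1:10)
  res <- som_cluster(profiles, grid = c(2, 2), n_iter = 200, seed = 4)
  expect_equal(length(unique(res$labels)), 1)  # identical profiles, one node

  one <- som_cluster(profiles, grid = c(1, 1), n_iter = 50, seed = 4)
  expect_true(all(one$labels == 1))

  withr::with_seed(73, real <- matrix(rnorm(60), nrow = 20,
                                      dimnames = list(sprintf("t%d", 1:20),
                                                      NULL)))
  a <- som_cluster(real, seed = 9)
  b <- som_cluster(real, seed = 9)
  expect_identical(a$labels, b$labels)
  expect_identical(a$codes, b$codes)
  expect_error(som_cluster(real[1:5, ], grid = c(3, 3)), "grid larger")
})

test_that("SOM separates planted profile groups and reduces quantization error", {
  withr::with_seed(79, {
    up_early <- matrix(rep(c(2, 1.5, 1), each = 60), nrow = 60) +
      matrix(rnorm(180, 0, 0.2), nrow = 60)
    down_late <- matrix(rep(c(0, -1, -2), each = 60), nrow = 60) +
      matrix(rnorm(180, 0, 0.2), nrow = 60)
  })
  profiles <- rbind(up_early, down_late)
  rownames(profiles) <- sprintf("t%03d", 1:120)
  res <- som_cluster(profiles, grid = c(1, 2), n_iter = 1000, seed = 7)
  truth <- rep(c(1, 2), each = 60)
  tab <- table(res$labels, truth)
  agreement <- max(sum(diag(tab)), sum(tab[1, 2], tab[2, 1])) / 120
  expect_gte(agreement, 0.95)
  # training reduces the logged quantization error
  expect_lt(tail(res$qe_trace, 1), res$qe_trace[1])
})

test_that("cluster distance test behaves under null and planted grouping", {
  h <- cluster_distance_test(
    stats::setNames(rep(1:2, each = 3), sprintf("t%d", 1:6)),
    stats::setNames(c(1, 2, 3, 4, 5, 6), sprintf("t%d", 1:6)))
  expect_equal(h$statistic, 3.857143, tolerance = 1e-6)

  withr::with_seed(83, {
    labels <- stats::setNames(sample(1:3, 90, TRUE), sprintf("t%d", 1:90))
    dists <- stats::setNames(rexp(90, 1 / 5e4), sprintf("t%d", 1:90))
  })
  expect_gt(cluster_distance_test(labels, dists)$p.value, 0.01)
  expect_error(cluster_distance_test(
    stats::setNames(1:2, c("a", "b")),
    stats::setNames(c(1, 2), c("a", "b"))), ">= 2 clusters")
})

test_that("regulation deltas partition the namespace", {
  d <- regulation_delta(c("a", "b"), c("b", "c"))
  expect_equal(d$lost, "a")
  expect_equal(d$gained, "c")
  expect_equal(d$conserved, "b")

  same <- regulation_delta(c("x", "y"), c("x", "y"))
  expect_equal(length(same$lost), 0)
  expect_equal(length(same$gained), 0)

  withr::with_seed(89, {
    pool <- sprintf("t%03d", 1:200)
    base <- sample(pool, 80)
    cond <- sample(pool, 95)
  })
  d2 <- regulation_delta(base, cond)
  expect_equal(length(d2$lost) + length(d2$conserved), length(unique(base)))
  expect_equal(length(d2$gained) + length(d2$conserved), length(unique(cond)))
  expect_equal(intersect(d2$lost, d2$gained), character(0))
  expect_equal(intersect(d2$gained, d2$conserved), character(0))
  brute_lost <- pool[pool %in% base & !pool %in% cond]
  expect_equal(sort(d2$lost), sort(brute_lost))
})

test_that("delta distance analysis detects a planted offset for gained genes", {
  withr::with_seed(97, {
    n <- 200
    genes <- tibble::tibble(
      gene_id = sprintf("g%03d", 1:(3 * n)),
      chrom = "chr1", strand = "+",
      tss = as.integer(seq(2e5, 3e8, length.out = 3 * n)))
    genes$tes <- genes$tss + 10000L
    # one region per gene; gained-class regions sit ~30 kb further out
    base_d <- round(abs(rnorm(3 * n, 20000, 8000)))
    extra <- rep(c(0L, 30000L, 0L), each = n)  # lost, gained, conserved
    regions <- tibble::tibble(
      chrom = "chr1",
      start = genes$tss + base_d + extra,
      end = genes$tss + base_d + extra + 200L)
  })
  delta <- structure(list(lost = genes$gene_id[1:n],
                          gained = genes$gene_id[(n + 1):(2 * n)],
                          conserved = genes$gene_id[(2 * n + 1):(3 * n)]),
                     class = "regulation_delta")
  res <- delta_distance_analysis(delta, regions, genes)
  gl <- res$tests[res$tests$class_a == "gained" | res$tests$class_b == "gained", ]
  expect_lt(max(gl$p.value), 0.01)
  # identical distance lists: p = 1
  cs <- res$tests[res$tests$class_a == "lost" & res$tests$class_b == "conserved", ]
  expect_gt(cs$p.value, 0.01)
  # density equals the brute-force per-gene window count
  pg <- res$per_gene
  mid <- floor((regions$start + regions$end) / 2)
  idx <- match(pg$gene_id, genes$gene_id)
  brute <- vapply(idx, function(i) sum(abs(mid - genes$tss[i]) <= 1e5),
                  integer(1))
  expect_equal(pg$n_regions_window, brute)
})

test_that("transcriptome overlap counts and percentages are consistent", {
  expect_equal(transcriptome_overlap(c("a", "b"), c("c", "d"))$common, 0)
  expect_equal(transcriptome_overlap(c("a", "b"), c("c", "d"))$pct_of_union, 0)
  full <- transcriptome_overlap(c("a", "b"), c("a", "b"))
  expect_equal(full$pct_of_union, 100)
  empty <- transcriptome_overlap(character(0), character(0))
  expect_true(is.na(empty$pct_of_union))

  withr::with_seed(101, {
    a <- sample(sprintf("t%03d", 1:300), 120)
    b <- sample(sprintf("t%03d", 1:300), 150)
  })
  ov <- transcriptome_overlap(a, b)
  expect_equal(ov$common, length(intersect(a, b)))
  expect_lte(ov$common, min(ov$n_a, ov$n_b))
  expect_lte(ov$pct_of_union, min(ov$pct_of_a, ov$pct_of_b))
  expect_equal(ov$n_a - ov$common, ov$unique_a)
})
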