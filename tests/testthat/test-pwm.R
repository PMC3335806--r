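test_that("pwm_score matches closed forms and per-position lookup", {
  # deterministic matrix, zero pseudocount: perfect match scores w*log2(4)
  det <- pwm(diag(4)[, c(1, 2, 3, 4)], pseudocount = 0)
  expect_equal(pwm_score(det, "ACGT"), 4 * log2(4))
  # matrix equal to background scores 0 everywhere
  flat <- pwm(matrix(0.25, 4, 6), pseudocount = 0)
  expect_equal(pwm_score(flat, "ACGTAC"), 0)
  # ambiguous base: skip-window signal
  expect_true(is.na(pwm_score(flat, "ACGTAN")))

  withr::with_seed(2, {
    m <- random_pwm(6)
    win <- random_dna(6)
  })
  naive <- sum(vapply(1:6, function(k) {
    b <- substr(win, k, k)
    log2(m$probs[b, k] / m$background[b])
  }, numeric(1)))
  expect_equal(pwm_score(m, win), naive, tolerance = 1e-12)
})

test_that("pwm_pvalue: boundary values and exhaustive-enumeration oracle", {
  # width-2 deterministic matrix: single max word, uniform bg
  det <- pwm(cbind(c(1, 0, 0, 0), c(1, 0, 0, 0)), pseudocount = 0)
  max_score <- pwm_score(det, "AA")
  expect_equal(pwm_pvalue(det, max_score), 1 / 16)

  flat <- pwm(matrix(0.25, 4, 4), pseudocount = 0)
  expect_equal(pwm_pvalue(flat, 0), 1)  # every window attains the only score

  withr::with_seed(6, pwms <- lapply(c(4, 5, 6, 8), random_pwm))
  bases <- c("A", "C", "G", "T")
  for (m in pwms) {
    words <- do.call(expand.grid,
                     c(rep(list(bases), m$width), stringsAsFactors = FALSE))
    scores <- apply(as.matrix(words), 1,
                    function(w) pwm_score(m, paste(w, collapse = "")))
    bgp <- apply(as.matrix(words), 1,
                 function(w) prod(m$background[w]))
    for (q in quantile(scores, c(0.1, 0.5, 0.9, 1))) {
      oracle <- sum(bgp[scores >= q - 1e-9])
      expect_equal(pwm_pvalue(m, q), oracle, tolerance = 1e-6)
    }
    # minimum attainable score has p = 1
    expect_equal(pwm_pvalue(m, min(scores)), 1, tolerance = 1e-12)
  }
})

test_that("pwm_pvalue is monotone non-increasing, also for wide matrices", {
  withr::with_seed(16, m <- random_pwm(8))
  qs <- seq(-20, 15, by = 0.5)
  ps <- pwm_pvalue(m, qs)
  expect_true(all(diff(ps) <= 1e-15))
  expect_true(all(ps >= 0 & ps <= 1))

  # discretized branch (width 15): monotone, and strong scores get small p
  wide <- pre_pwm()
  ps_wide <- pwm_pvalue(wide, seq(-10, 17, by = 0.5))
  expect_true(all(diff(ps_wide) <= 1e-15))
  consensus_score <- pwm_score(wide, "AGTACAGGGTGTACT")
  expect_lt(pwm_pvalue(wide, consensus_score), 1e-5)
})

test_that("strength classes honour the published p-value boundaries", {
  expect_equal(as.character(classify_strength(1e-6)), "strong")
  expect_equal(as.character(classify_strength(1e-4)), "moderate")
  expect_equal(as.character(classify_strength(0.01)), "weak_absent")
  # boundaries: 1e-5 is moderate (strict < for strong), 1e-3 is moderate
  expect_equal(as.character(classify_strength(c(1e-5, 1e-3))),
               c("moderate", "moderate"))
  expect_error(classify_strength(0), "\\(0, 1]")
})

test_that("match_iupac agrees with the naive set-membership scan", {
  expect_equal(match_iupac("RG", "AG")$offset, 0L)
  hit <- match_iupac(pre_consensus(), "AGTACAGGGTGTACT")
  expect_true(0L %in% hit$offset)

  withr::with_seed(19, seqs <- replicate(10, random_dna(60)))
  pattern <- "RGNACA"
  sets <- cistromer:::IUPAC_SETS
  naive_match <- function(pattern, s) {
    chars <- strsplit(pattern, "")[[1]]
    hits <- integer(0)
    for (o in 0:(nchar(s) - length(chars))) {
      ok <- all(vapply(seq_along(chars), function(k) {
        substr(s, o + k, o + k) %in% sets[[chars[k]]]
      }, logical(1)))
      if (ok) hits <- c(hits, o)
    }
    hits
  }
  rc <- function(p) as.character(Biostrings::reverseComplement(Biostrings::DNAString(p)))
  for (s in seqs) {
    got <- match_iupac(pattern, s)
    expect_equal(sort(got$offset[got$strand == "+"]), naive_match(pattern, s))
    expect_equal(sort(got$offset[got$strand == "-"]), naive_match(rc(pattern), s))
  }
})

test_that("scan_regions finds planted consensus words and respects report_p", {
  withr::with_seed(27, {
    seqs <- planted_sequences(12, rep(0, 12), pre_consensus())
  })
  hits <- scan_regions(pre_pwm(), seqs, report_p = 0.01)
  best <- hits[hits$best, ]
  expect_equal(sort(unique(hits$region_id)), sort(names(seqs)))
  # planted at the centre: best hit offset near 0 for every region
  expect_true(all(abs(best$offset) <= 1))
  expect_true(all(best$strength == "strong"))

  # vanishing report threshold: no hits from random sequence
  withr::with_seed(28, rnd <- stats::setNames(replicate(5, random_dna(400)),
                                              paste0("s", 1:5)))
  expect_equal(nrow(scan_regions(pre_pwm(), rnd, report_p = 1e-12)), 0)

  # short regions are skipped with a warning count
  short <- c(seqs, tooshort = "ACGT")
  expect_warning(h2 <- scan_regions(pre_pwm(), short), "skipped")
  expect_equal(attr(h2, "n_skipped"), 1)
})

test_that("scanning is reverse-complement symmetric", {
  withr::with_seed(29, {
    seqs <- planted_sequences(6, round(rnorm(6, 0, 30)), pre_consensus())
  })
  rc <- vapply(seqs, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1))
  names(rc) <- names(seqs)
  fwd <- scan_regions(pre_pwm(), seqs, report_p = 0.001)
  rev <- scan_regions(pre_pwm(), rc, report_p = 0.001)
  f <- dplyr::arrange(fwd, region_id, offset)
  r <- dplyr::arrange(dplyr::mutate(rev, offset = -offset), region_id, offset)
  expect_equal(nrow(f), nrow(r))
  expect_equal(f$offset, r$offset)
  expect_equal(f$score, r$score, tolerance = 1e-9)
  expect_equal(f$pvalue, r$pvalue, tolerance = 1e-9)
})

test_that("matched background preserves lengths, avoids overlap, matches GC", {
  withr::with_seed(33, {
    genome <- c(chr1 = random_dna(60000), chr2 = random_dna(60000))
    fg <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 12, TRUE),
                         start = sample.int(50000, 12))
    fg$end <- fg$start + sample(c(200L, 300L, 400L), 12, TRUE)
  })
  bg <- build_matched_background(fg, genome, n_per_region = 2, seed = 99)
  expect_equal(nrow(bg), 24)
  expect_equal(sort(rep(fg$end - fg$start, each = 2)), sort(bg$end - bg$start))
  expect_equal(intersect_regions(bg, fg)$n_common_a, 0)
  expect_lte(mean(abs(bg$gc - bg$source_gc)), 0.05)
  # reproducible under seed
  bg2 <- build_matched_background(fg, genome, n_per_region = 2, seed = 99)
  expect_equal(bg, bg2)
})

test_that("enrichment_test equals the tail formula and a permutation oracle", {
  expect_equal(enrichment_test(5, 5, 0, 5)$p.value, 1 / 252, tolerance = 1e-12)
  expect_gte(enrichment_test(2, 10, 2, 10)$p.value, 0.5)

  # Monte-Carlo: draw fg labels without replacement, count hit overlap
  withr::with_seed(37, {
    fg_total <- 15; bg_total <- 25; hits_total <- 12; fg_hits <- 8
    p <- enrichment_test(fg_hits, fg_total, hits_total - fg_hits, bg_total)$p.value
    pop <- c(rep(1, hits_total), rep(0, fg_total + bg_total - hits_total))
    perm <- replicate(100000, sum(sample(pop, fg_total)) >= fg_hits)
  })
  p_mc <- mean(perm)
  se <- sqrt(p_mc * (1 - p_mc) / 100000)
  expect_lt(abs(p - p_mc), 3 * se)
})

test_that("cooccurrence counts match per-region membership checks", {
  hits <- list(A = c("r1", "r2"), B = c("r2", "r3"))
  tab <- cooccurrence_table(hits, universe = c("r1", "r2", "r3", "r4"))
  expect_equal(tab$n_regions[tab$combo == "A+B"], 1)
  expect_equal(tab$n_regions[tab$combo == "A"], 2)
  disjoint <- cooccurrence_table(list(A = "r1", B = "r2"), c("r1", "r2"))
  expect_equal(disjoint$n_regions[disjoint$combo == "A+B"], 0)

  withr::with_seed(43, {
    universe <- sprintf("r%02d", 1:30)
    sets <- lapply(1:3, function(i) sample(universe, sample(5:20, 1)))
    names(sets) <- c("m1", "m2", "m3")
  })
  tab <- cooccurrence_table(sets, universe,
                            combos = list("m1", c("m1", "m2"),
                                          c("m1", "m2", "m3")))
  brute <- vapply(universe, function(r) {
    all(vapply(sets[c("m1", "m2", "m3")], function(s) r %in% s, logical(1)))
  }, logical(1))
  expect_equal(tab$n_regions[3], sum(brute))
  expect_equal(tab$n_regions[1], length(sets$m1))
})

test_that("positional_distribution accepts normal offsets and rejects uniform", {
  withr::with_seed(47, {
    hits_norm <- tibble::tibble(region_id = sprintf("r%d", 1:500),
                                offset = rnorm(500, 0, 50),
                                pvalue = runif(500, 0, 0.009), best = TRUE)
    hits_unif <- dplyr::mutate(hits_norm, offset = runif(500, -400, 400))
  })
  expect_gt(positional_distribution(hits_norm)$test$p.value, 0.05)
  expect_lt(positional_distribution(hits_unif)$test$p.value, 0.05)
  few <- hits_norm[1:5, ]
  expect_error(positional_distribution(few), ">= 8")
  flat <- dplyr::mutate(hits_norm[1:20, ], offset = 3)
  expect_error(positional_distribution(flat), "degenerate")
})
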