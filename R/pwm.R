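# Position weight matrices: construction, log-odds scoring, exact p-values
# by dynamic programming over the background score distribution, and the
# hormone response element (PRE) strength classes.

DNA_BASES <- c("A", "C", "G", "T")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Build a position weight matrix
#'
#' @param probs Base-probability matrix: 4 rows (A, C, G, T) by width columns
#'   (a width x 4 matrix is transposed automatically).  Each column must sum
#'   to 1 before pseudocount adjustment (small deviations are renormalized).
#' @param background Background base frequencies (named A/C/G/T, default
#'   uniform).
#' @param pseudocount Added to every probability and renormalized, keeping
#'   log-odds finite (default 0.001).
#' @param name Optional motif name.
#' @return A `cistromer_pwm`: list with `probs` (adjusted), `log_odds`
#'   (log2 p/bg), `width`, `background`, `pseudocount`, `name`.
#' @examples
#' m <- consensus_to_pwm("RGNACANNNTGTNCY", name = "PRE")
#' m$width
#' @export
pwm <- function(probs, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                pseudocount = 0.001, name = NULL) {
  probs <- as.matrix(probs)
  if (ncol(probs) == 4 && nrow(probs) != 4) probs <- t(probs)
  if (nrow(probs) != 4) abort("`probs` must have 4 rows (A, C, G, T)")
  if (any(probs < 0)) abort("probabilities must be non-negative")
  background <- background[DNA_BASES]
  if (any(is.na(background)) || abs(sum(background) - 1) > 1e-6) {
    abort("`background` must be named A/C/G/T frequencies summing to 1")
  }
  probs <- sweep(probs, 2, colSums(probs), "/")
  dimnames(probs) <- list(DNA_BASES, NULL)
  adj <- sweep(probs + pseudocount, 2, 1 + 4 * pseudocount, "/")
  structure(
    list(probs = adj, raw_probs = probs, log_odds = log2(adj / background),
         width = ncol(adj), background = background,
         pseudocount = pseudocount, name = name),
    class = "cistromer_pwm"
  )
}

#' @export
print.cistromer_pwm <- function(x, ...) {
  cat(sprintf("PWM%s: width %d, pseudocount %g\n",
              if (is.null(x$name)) "" else paste0(" ", x$name), x$width,
              x$pseudocount))
  print(round(x$probs, 3))
  invisible(x)
}

#' Build a PWM from an IUPAC consensus
#'
#' Degenerate positions are split evenly over their IUPAC base set, so e.g.
#' `R` becomes A/G at 0.5 each and `N` all four bases at 0.25.
#'
#' @param consensus IUPAC string (case-insensitive).
#' @inheritParams pwm
#' @return A `cistromer_pwm`.
#' @export
consensus_to_pwm <- function(consensus,
                             background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                             pseudocount = 0.001, name = NULL) {
  chars <- strsplit(str_to_upper(consensus), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad) > 0) {
    abort(sprintf("invalid IUPAC character(s): %s", paste(unique(bad), collapse = ", ")))
  }
  probs <- vapply(chars, function(ch) {
    p <- setNames(numeric(4), DNA_BASES)
    p[IUPAC_SETS[[ch]]] <- 1 / length(IUPAC_SETS[[ch]])
    p
  }, numeric(4))
  pwm(probs, background = background, pseudocount = pseudocount, name = name)
}

#' The progesterone response element and cofactor motifs
#'
#' `pre_consensus()` returns the full-length PRE inverted repeat
#' `RGNACANNNTGTNCY`; `pre_pwm()` the matrix built from it with degenerate
#' positions split evenly; `pre_core_pattern()` the short core element as an
#' IUPAC pattern (`CWNNNTGTNC`); `cofactor_consensus()` canonical consensus
#' sites for the FOXA1, NF1 and AP-1 cofactors.
#'
#' @return Character scalar / `cistromer_pwm` / named character vector.
#' @export
pre_consensus <- function() "RGNACANNNTGTNCY"

#' @rdname pre_consensus
#' @inheritParams pwm
#' @export
pre_pwm <- function(background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                    pseudocount = 0.001) {
  consensus_to_pwm(pre_consensus(), background = background,
                   pseudocount = pseudocount, name = "PRE")
}

#' @rdname pre_consensus
#' @export
pre_core_pattern <- function() "CWNNNTGTNC"

#' @rdname pre_consensus
#' @export
cofactor_consensus <- function() {
  c(foxa1 = "TGTTTAC", nf1 = "TTGGCNNNNNGCCAA", ap1 = "TGASTCA")
}

seq_to_code <- function(sequence) {
  match(strsplit(str_to_upper(sequence), "")[[1]], DNA_BASES)
}

revcomp_code <- function(code) rev(5L - code)

#' Score a window against a PWM
#'
#' Sum over positions of `log2(p_pos(base) / background(base))` with
#' pseudocount-adjusted probabilities.  Windows containing ambiguous bases
#' score `NA` (skip-window signal).
#'
#' @param x A `cistromer_pwm`.
#' @param window DNA string of length `x$width`.
#' @return Log-odds score in bits, or `NA`.
#' @export
pwm_score <- function(x, window) {
  stopifnot(inherits(x, "cistromer_pwm"))
  code <- seq_to_code(window)
  if (length(code) != x$width) abort("`window` length must equal PWM width")
  if (anyNA(code)) return(NA_real_)
  sum(x$log_odds[cbind(code, seq_len(x$width))])
}

# --- background score distribution -----------------------------------------
# Exact distinct-sum DP for widths <= pwm_exact_width_limit (the state space
# is the full 4^w lattice); discretized DP (floor rounding at `bin` bits,
# conservative p) beyond that.

pwm_exact_width_limit <- 10L

.pwm_dist_cache <- new.env(parent = emptyenv())

pwm_cache_key <- function(x) {
  paste(c(signif(as.vector(x$probs), 12), signif(x$background, 12)), collapse = ",")
}

pwm_score_distribution <- function(x, bin = 0.001) {
  key <- pwm_cache_key(x)
  hit <- .pwm_dist_cache[[key]]
  if (!is.null(hit)) return(hit)
  bg <- x$background
  if (x$width <= pwm_exact_width_limit) {
    scores <- 0
    probs <- 1
    for (j in seq_len(x$width)) {
      scores <- as.vector(outer(scores, x$log_odds[, j], "+"))
      probs <- as.vector(outer(probs, bg, "*"))
    }
    o <- order(scores)
    scores <- scores[o]; probs <- probs[o]
    tail_p <- rev(cumsum(rev(probs)))
    dist <- list(exact = TRUE, scores = scores, tail_p = tail_p)
  } else {
    kb <- floor(x$log_odds / bin)
    d <- 1; off <- 0
    for (j in seq_len(x$width)) {
      k <- kb[, j]
      newmin <- off + min(k)
      nd <- numeric(length(d) - 1 + max(k) - min(k) + 1)
      for (b in 1:4) {
        sft <- off + k[b] - newmin
        idx <- seq_along(d) + sft
        nd[idx] <- nd[idx] + d * bg[b]
      }
      d <- nd; off <- newmin
    }
    tail_p <- rev(cumsum(rev(d)))
    dist <- list(exact = FALSE, bin = bin, offset = off, tail_p = tail_p)
  }
  .pwm_dist_cache[[key]] <- dist
  dist
}

dist_pvalue <- function(dist, score) {
  vapply(score, function(s) {
    if (is.na(s)) return(NA_real_)
    if (dist$exact) {
      i <- findInterval(s - 1e-9, dist$scores) + 1
      if (i > length(dist$scores)) return(0)
      dist$tail_p[i]
    } else {
      qbin <- floor(s / dist$bin)
      i <- qbin - dist$offset + 1
      if (i <= 1) return(1)
      if (i > length(dist$tail_p)) return(min(dist$tail_p[dist$tail_p > 0]))
      max(dist$tail_p[i], .Machine$double.xmin)
    }
  }, numeric(1))
}

#' Exact p-value of a PWM score
#'
#' `P(S >= score)` for the score of a random window drawn from the PWM's
#' background model.  For widths up to 10 the full lattice of window scores
#' is evaluated (exact); for wider matrices the score distribution is built
#' by dynamic programming on a 0.001-bit grid with floor rounding, which
#' under- rather than over-states significance.  Monotone non-increasing in
#' `score`; the distribution is cached per matrix.
#'
#' @inheritParams pwm_score
#' @param score Numeric vector of log-odds scores (bits).
#' @return P-values in `(0, 1]` (0 only for scores above the attainable
#'   maximum).
#' @export
pwm_pvalue <- function(x, score) {
  stopifnot(inherits(x, "cistromer_pwm"))
  dist_pvalue(pwm_score_distribution(x), score)
}

#' Classify motif-match strength from its p-value
#'
#' Strength bins: strong (`p < 1e-5`), moderate (`1e-5 <= p <= 1e-3`,
#' closed interval), weak/absent (`p > 1e-3`).
#'
#' @param pvalue Numeric vector of p-values in `(0, 1]`.
#' @return Factor with levels `strong`, `moderate`, `weak_absent`.
#' @export
classify_strength <- function(pvalue) {
  if (any(!is.na(pvalue) & (pvalue <= 0 | pvalue > 1))) {
    abort("p-values must lie in (0, 1]")
  }
  factor(case_when(
    pvalue < 1e-5 ~ "strong",
    pvalue <= 1e-3 ~ "moderate",
    TRUE ~ "weak_absent"
  ), levels = c("strong", "moderate", "weak_absent"))
}

#' Scan region sequences for motif hits
#'
#' Both strands are scanned at every offset; windows with ambiguous bases
#' are skipped.  Hits with `p < report_p` are reported, same-window
#' opposite-strand duplicates are collapsed to the better (lower-p) strand
#' (ties to `+`), offsets are measured from the sequence centre, and the
#' best hit per region is flagged.
#'
#' @inheritParams pwm_score
#' @param seqs Named character vector of region sequences (names are region
#'   ids), e.g. from [region_sequences()].
#' @param report_p Report threshold on the match p-value (default 0.01).
#' @param background Optional background base frequencies for scoring; by
#'   default the 0-order base composition of `seqs` is used.
#' @return Tibble of motif hits: `region_id`, `offset` (bp from sequence
#'   centre), `strand`, `score`, `pvalue`, `strength`, `best`.  Regions
#'   shorter than the matrix width are skipped; their count is attached as
#'   attribute `n_skipped` (with a warning).
#' @export
scan_regions <- function(x, seqs, report_p = 0.01, background = NULL) {
  stopifnot(inherits(x, "cistromer_pwm"))
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    abort("`seqs` must be a named character vector (names = region ids)")
  }
  if (is.null(background)) {
    counts <- colSums(Biostrings::letterFrequency(
      Biostrings::DNAStringSet(unname(seqs)), DNA_BASES))
    if (sum(counts) == 0) abort("`seqs` contain no unambiguous bases")
    background <- counts / sum(counts)
  }
  x <- pwm(x$probs, background = background, pseudocount = 0,
           name = x$name)  # probs already pseudocount-adjusted
  dist <- pwm_score_distribution(x)
  w <- x$width
  too_short <- nchar(seqs) < w
  if (any(too_short)) {
    warn(sprintf("%d region(s) shorter than the PWM width were skipped",
                 sum(too_short)))
  }
  hits <- imap(seqs[!too_short], function(s, id) {
    code <- seq_to_code(s)
    L <- length(code)
    n_win <- L - w + 1
    score_strand <- function(cd) {
      sc <- numeric(n_win)
      for (k in seq_len(w)) {
        b <- cd[k:(k + n_win - 1)]
        v <- x$log_odds[cbind(b, k)]
        v[is.na(b)] <- NA_real_
        sc <- sc + v
      }
      sc
    }
    fwd <- score_strand(code)
    rev_sc <- score_strand(revcomp_code(code))
    # reverse-strand window starting at position o on the revcomp maps to
    # forward start L - o - w + 2
    starts <- c(seq_len(n_win), L - seq_len(n_win) - w + 2L)
    tibble(start = starts,
           strand = rep(c("+", "-"), each = n_win),
           score = c(fwd, rev_sc)) |>
      filter(!is.na(.data$score)) |>
      mutate(pvalue = dist_pvalue(dist, .data$score),
             region_id = id,
             offset = .data$start + (w - 1) / 2 - (L + 1) / 2)
  }) |> list_rbind()
  if (nrow(hits) == 0 || all(hits$pvalue >= report_p)) {
    out <- tibble(region_id = character(), offset = numeric(),
                  strand = character(), score = numeric(), pvalue = numeric(),
                  strength = classify_strength(numeric(0)), best = logical())
    attr(out, "n_skipped") <- sum(too_short)
    return(out)
  }
  out <- hits |>
    filter(.data$pvalue < report_p) |>
    group_by(.data$region_id, .data$start) |>
    arrange(.data$pvalue, factor(.data$strand, levels = c("+", "-")),
            .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    mutate(strength = classify_strength(.data$pvalue)) |>
    group_by(.data$region_id) |>
    mutate(best = row_number() ==
             order(.data$pvalue, abs(.data$offset), .data$offset)[1]) |>
    ungroup() |>
    arrange(.data$region_id, .data$offset) |>
    select("region_id", "offset", "strand", "score", "pvalue", "strength",
           "best")
  attr(out, "n_skipped") <- sum(too_short)
  out
}

#' Extract region sequences around summits
#'
#' @param genome Named character vector of chromosome sequences.
#' @param regions Region tibble; the anchor is `summit` when present, else
#'   the interval midpoint.
#' @param flank Half-window in bp (default 400, giving sequences of
#'   `2 * flank` bp, clipped at chromosome ends).
#' @return Named character vector keyed by `region_id`.
#' @export
region_sequences <- function(genome, regions, flank = 400) {
  check_intervals(regions)
  regions <- ensure_region_ids(regions)
  anchor <- if ("summit" %in% names(regions)) regions$summit
    else region_midpoint(regions)
  chrom_nchar <- vapply(genome, nchar, integer(1))
  out <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    chr <- regions$chrom[i]
    if (is.na(match(chr, names(genome)))) {
      abort(sprintf("chromosome %s absent from genome", chr))
    }
    s <- max(1, anchor[i] - flank + 1)
    e <- min(chrom_nchar[[chr]], anchor[i] + flank)
    out[i] <- substr(genome[[chr]], s, e)
  }
  setNames(out, regions$region_id)
}

#' Match an IUPAC pattern on both strands
#'
#' All offsets (0-based) where every sequence base falls in the pattern
#' position's IUPAC set, on the given sequence and its reverse complement
#' (reported in forward coordinates).
#'
#' @param pattern IUPAC string.
#' @param sequence DNA string.
#' @return Tibble with `offset` (0-based forward start) and `strand`.
#' @export
match_iupac <- function(pattern, sequence) {
  chars <- strsplit(str_to_upper(pattern), "")[[1]]
  if (!all(chars %in% names(IUPAC_SETS))) abort("invalid IUPAC pattern")
  subj <- Biostrings::DNAString(str_to_upper(sequence))
  fwd <- Biostrings::matchPattern(pattern, subj, fixed = FALSE)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
  rev <- Biostrings::matchPattern(rc, subj, fixed = FALSE)
  bind_rows(
    tibble(offset = Biostrings::start(fwd) - 1L, strand = "+"),
    tibble(offset = Biostrings::start(rev) - 1L, strand = "-")
  ) |> arrange(.data$offset, .data$strand)
}

#' Sample a GC-matched genomic background
#'
#' For each foreground region, `n_per_region` same-length intervals are
#' sampled from the genome, excluding any overlap with the foreground set,
#' with GC content within `gc_tol` of the source region (bounded retries,
#' then the nearest-GC candidate seen is kept).
#'
#' @param regions Foreground region tibble.
#' @param genome Named character vector of chromosome sequences.
#' @param n_per_region Background intervals per foreground region.
#' @param gc_tol Maximum |GC difference| accepted without fallback
#'   (proportion, default 0.05 = 5 percentage points).
#' @param max_tries Sampling attempts per background interval.
#' @param seed Optional RNG seed for reproducible sampling.
#' @return Tibble `chrom`, `start`, `end`, `region_id`, `source_region`,
#'   `gc`, `source_gc`.
#' @export
build_matched_background <- function(regions, genome, n_per_region = 2,
                                     gc_tol = 0.05, max_tries = 100,
                                     seed = NULL) {
  check_intervals(regions)
  regions <- ensure_region_ids(regions)
  if (sum(nchar(genome)) < 4 * sum(regions$end - regions$start)) {
    abort("genome too small to sample a non-overlapping background")
  }
  run <- function() {
    gc_of <- function(chrom, start, end) {
      s <- substr(genome[[chrom]], start + 1, end)
      stringr::str_count(s, "[GCgc]") / nchar(s)
    }
    chrom_len <- nchar(genome)
    fg <- split(regions, regions$chrom)
    rows <- list()
    for (i in seq_len(nrow(regions))) {
      len <- regions$end[i] - regions$start[i]
      src_gc <- gc_of(regions$chrom[i], regions$start[i], regions$end[i])
      for (j in seq_len(n_per_region)) {
        best <- NULL; best_diff <- Inf
        for (try in seq_len(max_tries)) {
          chr <- sample(names(genome), 1, prob = chrom_len)
          if (chrom_len[[chr]] < len + 1) next
          st <- sample.int(chrom_len[[chr]] - len, 1) - 1L
          cand_fg <- fg[[chr]]
          if (!is.null(cand_fg) &&
              any(st < cand_fg$end & st + len > cand_fg$start)) next
          g <- gc_of(chr, st, st + len)
          diff <- abs(g - src_gc)
          if (diff < best_diff) {
            best <- list(chrom = chr, start = st, end = st + len, gc = g)
            best_diff <- diff
          }
          if (diff <= gc_tol) break
        }
        if (is.null(best)) abort("could not place a background interval")
        rows[[length(rows) + 1]] <- tibble(
          chrom = best$chrom, start = best$start, end = best$end,
          region_id = sprintf("bg_%s_%d", regions$region_id[i], j),
          source_region = regions$region_id[i], gc = best$gc,
          source_gc = src_gc)
      }
    }
    list_rbind(rows)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Motif enrichment by the cumulative hypergeometric tail
#'
#' One-sided enrichment p-value for the motif hit rate in foreground regions
#' against a (matched) background: `P(X >= fg_hit_count)` drawing `fg_total`
#' regions from the pooled `fg_total + bg_total` regions of which
#' `fg_hit_count + bg_hit_count` carry the motif.
#'
#' @param fg_hit_count,fg_total Foreground regions with the motif / total.
#' @param bg_hit_count,bg_total Background regions with the motif / total.
#' @return A `cistromer_test` with the fold ratio of rates as `estimate`.
#' @export
enrichment_test <- function(fg_hit_count, fg_total, bg_hit_count, bg_total) {
  if (fg_hit_count > fg_total || bg_hit_count > bg_total) {
    abort("hit counts cannot exceed totals")
  }
  p <- hypergeom_tail(fg_hit_count, fg_hit_count + bg_hit_count, fg_total,
                      fg_total + bg_total)
  rate_fg <- fg_hit_count / fg_total
  rate_bg <- bg_hit_count / bg_total
  new_cistromer_test(fg_hit_count, p,
                     "Cumulative hypergeometric motif enrichment",
                     as.integer(fg_total), as.integer(bg_total),
                     estimate = if (rate_bg > 0) rate_fg / rate_bg else Inf)
}

#' Count regions carrying motif combinations
#'
#' @param hits_by_motif Named list: motif -> character vector of region ids
#'   with at least one hit.
#' @param universe Character vector of all region ids under consideration.
#' @param combos Optional list of motif-name vectors to count; defaults to
#'   every single motif and every pair.
#' @return Tibble `combo`, `motifs` (list-column), `n_regions`, `fraction`
#'   (of the universe).  Single-motif counts equal the hit-set sizes.
#' @export
cooccurrence_table <- function(hits_by_motif, universe, combos = NULL) {
  hits_by_motif <- lapply(hits_by_motif, function(h) intersect(unique(h), universe))
  nm <- names(hits_by_motif)
  if (is.null(combos)) {
    combos <- c(as.list(nm),
                if (length(nm) >= 2) utils::combn(nm, 2, simplify = FALSE))
  }
  map(combos, function(cb) {
    ids <- Reduce(intersect, hits_by_motif[cb], accumulate = FALSE)
    tibble(combo = paste(cb, collapse = "+"), motifs = list(cb),
           n_regions = length(ids),
           fraction = if (length(universe) > 0) length(ids) / length(universe)
             else NA_real_)
  }) |> list_rbind()
}

#' Positional distribution of motif hits about region centres
#'
#' Takes the best hit per region and tests its offsets for normality about
#' the region centre with the one-sample KS test against a fitted normal.
#'
#' @param hits Motif-hit tibble from [scan_regions()] (a `best` column is
#'   used when present, else the lowest-p hit per region).
#' @return List with `offsets` (numeric) and `test` (a `cistromer_test`).
#' @export
positional_distribution <- function(hits) {
  best <- if ("best" %in% names(hits)) filter(hits, .data$best)
    else hits |> group_by(.data$region_id) |> slice_min(.data$pvalue, n = 1,
                                                        with_ties = FALSE) |>
      ungroup()
  offsets <- best$offset
  if (length(offsets) < 8) abort("need >= 8 best hits for a positional test")
  if (sd(offsets) == 0) abort("degenerate offsets: zero spread")
  list(offsets = offsets, test = ks_one_sample_normal(offsets))
}
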