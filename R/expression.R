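# Differential-expression integration: regulated-transcript calling, SOM
# clustering of time-course profiles, regulation deltas between conditions,
# and distance analyses of the delta classes.

#' Call progestin-regulated transcripts
#'
#' A transcript passes at a time point when `diff_p < p_threshold` and the
#' linear fold change reaches `fc_threshold` (i.e. `|log2_fc| >=
#' log2(fc_threshold)`); it is regulated when it passes at one or more time
#' points, with direction taken from the fold-change sign at the
#' lowest-p passing time point.
#'
#' @param expression Tibble with `transcript_id`, `timepoint`, `log2_fc`,
#'   `diff_p` (extra columns pass through).
#' @param p_threshold Differential p-value threshold (default 0.01).
#' @param fc_threshold Linear fold-change threshold (default 1.5).
#' @return Per-row calls: the input plus `passes` and `direction`
#'   (`up`/`down`/`none` per time point).  Summarise per transcript with
#'   [regulated_transcripts()].  Rows with missing `log2_fc`/`diff_p` are
#'   dropped with a warning count attached as attribute `n_skipped`.
#' @export
call_regulated <- function(expression, p_threshold = 0.01,
                           fc_threshold = 1.5) {
  need <- c("transcript_id", "timepoint", "log2_fc", "diff_p")
  miss <- setdiff(need, names(expression))
  if (length(miss) > 0) {
    abort(sprintf("`expression` is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  bad <- is.na(expression$log2_fc) | is.na(expression$diff_p)
  if (any(bad)) {
    warn(sprintf("%d expression row(s) with missing values skipped", sum(bad)))
  }
  out <- expression[!bad, , drop = FALSE] |>
    mutate(passes = .data$diff_p < p_threshold &
             abs(.data$log2_fc) >= log2(fc_threshold),
           direction = case_when(
             .data$passes & .data$log2_fc > 0 ~ "up",
             .data$passes & .data$log2_fc < 0 ~ "down",
             TRUE ~ "none"))
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Summarise regulated transcripts over time points
#'
#' @param calls Output of [call_regulated()].
#' @return Tibble of regulated transcripts: `transcript_id`, `direction`
#'   (from the lowest-p passing time point), `first_timepoint`,
#'   `n_timepoints`.
#' @export
regulated_transcripts <- function(calls) {
  calls <- filter(calls, .data$passes)
  if (nrow(calls) == 0) {
    return(tibble(transcript_id = character(), direction = character(),
                  first_timepoint = numeric(), n_timepoints = integer()))
  }
  calls |>
    group_by(.data$transcript_id) |>
    summarise(direction = .data$direction[which.min(.data$diff_p)],
              first_timepoint = min(.data$timepoint),
              n_timepoints = dplyr::n(), .groups = "drop")
}

#' Self-organizing map of regulation profiles
#'
#' A seeded online Kohonen SOM on a `rows x cols` grid: codebooks are
#' initialized from sampled data rows, then updated over `n_iter` single-
#' profile presentations with exponentially decaying learning rate and
#' Gaussian neighbourhood.  Deterministic given `seed`.
#'
#' @param profiles Numeric matrix (transcripts x time points) with row
#'   names, or a tibble with a `transcript_id` column and numeric profile
#'   columns.
#' @param grid `c(rows, cols)` of the map (default `c(3, 3)`, nine
#'   clusters).
#' @param n_iter Training presentations (default 2000).
#' @param alpha Initial and final learning rate (default 0.05 to 0.01).
#' @param radius Initial neighbourhood radius; defaults to half the grid
#'   diagonal, decaying to 0.5.
#' @param seed RNG seed (default 1).
#' @return A `cistromer_som`: list with `labels` (named node index per
#'   transcript, 1..rows*cols), `codes` (node x feature codebook), `grid`,
#'   `qe_trace` (mean quantization error logged every 50 presentations).
#' @export
som_cluster <- function(profiles, grid = c(3, 3), n_iter = 2000,
                        alpha = c(0.05, 0.01), radius = NULL, seed = 1) {
  if (is.data.frame(profiles)) {
    ids <- profiles$transcript_id
    profiles <- as.matrix(profiles[setdiff(names(profiles), "transcript_id")])
    rownames(profiles) <- ids
  }
  if (is.null(rownames(profiles))) {
    rownames(profiles) <- sprintf("t%d", seq_len(nrow(profiles)))
  }
  n_nodes <- prod(grid)
  if (nrow(profiles) < n_nodes) {
    abort("grid larger than the number of profiles")
  }
  node_xy <- cbind(rep(seq_len(grid[1]), grid[2]),
                   rep(seq_len(grid[2]), each = grid[1]))
  if (is.null(radius)) radius <- max(1, sqrt(sum((grid - 1)^2)) / 2)
  withr::with_seed(seed, {
    codes <- profiles[sample.int(nrow(profiles), n_nodes), , drop = FALSE]
    rownames(codes) <- NULL
    qe_trace <- c()
    pick <- sample.int(nrow(profiles), n_iter, replace = TRUE)
    for (it in seq_len(n_iter)) {
      frac <- (it - 1) / max(1, n_iter - 1)
      a <- alpha[1] * (alpha[2] / alpha[1])^frac
      r <- radius * (0.5 / radius)^frac
      xi <- profiles[pick[it], ]
      d2 <- rowSums(sweep(codes, 2, xi)^2)
      bmu <- which.min(d2)
      g2 <- rowSums(sweep(node_xy, 2, node_xy[bmu, ])^2)
      h <- a * exp(-g2 / (2 * r^2))
      codes <- codes + h * sweep(codes, 2, xi) * -1
      if (it %% 50 == 0 || it == n_iter) {
        assign_d2 <- apply(profiles, 1, function(p) {
          min(rowSums(sweep(codes, 2, p)^2))
        })
        qe_trace <- c(qe_trace, mean(assign_d2))
      }
    }
    labels <- apply(profiles, 1, function(p) {
      which.min(rowSums(sweep(codes, 2, p)^2))
    })
  })
  structure(list(labels = labels, codes = codes, grid = grid,
                 qe_trace = qe_trace, n_iter = n_iter),
            class = "cistromer_som")
}

#' @export
print.cistromer_som <- function(x, ...) {
  cat(sprintf("SOM %dx%d: %d profiles, %d occupied nodes\n", x$grid[1],
              x$grid[2], length(x$labels), length(unique(x$labels))))
  print(table(x$labels))
  invisible(x)
}

#' @export
tidy.cistromer_som <- function(x, ...) {
  tibble(transcript_id = names(x$labels), node = unname(x$labels))
}

#' @export
glance.cistromer_som <- function(x, ...) {
  tibble(n_profiles = length(x$labels), n_nodes = prod(x$grid),
         n_occupied = length(unique(x$labels)),
         quantization_error = tail(x$qe_trace, 1))
}

#' Test binding-distance differences between expression clusters
#'
#' Kruskal-Wallis test of transcript-to-nearest-region distances across
#' cluster labels.
#'
#' @param labels Named vector of cluster labels (names = transcript ids), or
#'   a `cistromer_som`.
#' @param distances Named numeric vector: transcript id -> distance in bp to
#'   the nearest binding region.
#' @return A `cistromer_test` (H, p).
#' @export
cluster_distance_test <- function(labels, distances) {
  if (inherits(labels, "cistromer_som")) labels <- labels$labels
  common <- intersect(names(labels), names(distances))
  if (length(common) == 0) abort("no shared transcript ids")
  groups <- split(unname(distances[common]), unname(labels[common]))
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) < 2) abort("need >= 2 clusters with >= 2 members")
  kruskal_wallis(groups)
}

#' Lost / gained / conserved regulation between conditions
#'
#' @param baseline_regulated,condition_regulated Character vectors of
#'   regulated transcript ids in the two conditions.
#' @return A `regulation_delta`: list of disjoint sets `lost`
#'   (baseline only), `gained` (condition only), `conserved` (both).
#' @export
regulation_delta <- function(baseline_regulated, condition_regulated) {
  b <- unique(baseline_regulated); cnd <- unique(condition_regulated)
  structure(list(lost = setdiff(b, cnd), gained = setdiff(cnd, b),
                 conserved = intersect(b, cnd)),
            class = "regulation_delta")
}

#' @export
print.regulation_delta <- function(x, ...) {
  cat(sprintf("regulation delta: %d lost, %d gained, %d conserved\n",
              length(x$lost), length(x$gained), length(x$conserved)))
  invisible(x)
}

#' Distance and density analysis of regulation-delta classes
#'
#' For each delta class, each gene's distance to its nearest binding region
#' and its count of regions within `window` bp of the TSS; Welch t-tests
#' compare distances between classes (classes with fewer than 3 measurable
#' genes are skipped with a notice).
#'
#' @param delta A [regulation_delta()].
#' @param regions Region tibble.
#' @param genes Gene-model tibble.
#' @param window Density window in bp (default 100 kb).
#' @return List: `per_gene` (tibble class/gene_id/distance/n_regions_window),
#'   `class_summary` (mean distance, density = regions per gene with >= 1
#'   region), `tests` (tibble of pairwise Welch results).
#' @export
delta_distance_analysis <- function(delta, regions, genes, window = 100000) {
  stopifnot(inherits(delta, "regulation_delta"))
  check_intervals(regions)
  check_genes(genes)
  mid <- region_midpoint(regions)
  mid_by_chrom <- split(mid, regions$chrom)
  per_gene <- imap(list(lost = delta$lost, gained = delta$gained,
                        conserved = delta$conserved), function(ids, cls) {
    g <- filter(genes, .data$gene_id %in% ids)
    if (nrow(g) == 0) return(NULL)
    tibble(class = cls, gene_id = g$gene_id,
           distance = gene_min_region_distance(g, regions),
           n_regions_window = vapply(seq_len(nrow(g)), function(i) {
             m <- mid_by_chrom[[g$chrom[i]]]
             if (is.null(m)) 0L else sum(abs(m - g$tss[i]) <= window)
           }, integer(1)))
  }) |> list_rbind()
  class_summary <- per_gene |>
    group_by(.data$class) |>
    summarise(n_genes = dplyr::n(),
              mean_distance = mean(.data$distance, na.rm = TRUE),
              genes_with_region = sum(.data$n_regions_window > 0),
              regions_per_gene = sum(.data$n_regions_window) /
                max(1, sum(.data$n_regions_window > 0)),
              .groups = "drop")
  combos <- utils::combn(unique(per_gene$class), 2, simplify = FALSE)
  tests <- map(combos, function(cb) {
    a <- per_gene$distance[per_gene$class == cb[1]]
    b <- per_gene$distance[per_gene$class == cb[2]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 3 || length(b) < 3) {
      warn(sprintf("comparison %s vs %s skipped: too few genes", cb[1], cb[2]))
      return(NULL)
    }
    wt <- welch_t(a, b)
    tibble(class_a = cb[1], class_b = cb[2], t = unname(wt$statistic),
           p.value = wt$p.value, mean_a = mean(a), mean_b = mean(b))
  }) |> list_rbind()
  list(per_gene = per_gene, class_summary = class_summary, tests = tests)
}

#' Overlap between two regulated-transcript sets
#'
#' @param set_a,set_b Character vectors of transcript ids.
#' @return One-row tibble: `n_a`, `n_b`, `common`, `unique_a`, `unique_b`,
#'   `pct_of_union`, `pct_of_a`, `pct_of_b` (percentages rounded to nearest
#'   integer; NA when both sets are empty).
#' @export
transcriptome_overlap <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  common <- length(intersect(a, b))
  uni <- length(union(a, b))
  pct <- function(num, den) if (den > 0) round(100 * num / den) else NA_real_
  tibble(n_a = length(a), n_b = length(b), common = common,
         unique_a = length(a) - common, unique_b = length(b) - common,
         pct_of_union = pct(common, uni), pct_of_a = pct(common, length(a)),
         pct_of_b = pct(common, length(b)))
}
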