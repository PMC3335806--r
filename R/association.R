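# Peak-to-gene association accounting, distance-distribution tests,
# peak-height comparisons and per-chromosome regression.

window_class_of <- function(distance, windows = c(1, 10, 50, 100) * 1000) {
  labels <- c(sprintf("<=%dkb", windows / 1000), "none")
  cut(abs(distance), breaks = c(-1, windows, Inf), labels = labels)
}

normalize_regulated <- function(regulated) {
  if (is.null(regulated)) {
    return(tibble(gene_id = character(), direction = character()))
  }
  if (!is.data.frame(regulated)) {
    regulated <- tibble(gene_id = names(regulated),
                        direction = unname(regulated))
  }
  if (!all(c("gene_id", "direction") %in% names(regulated))) {
    abort("`regulated` needs columns gene_id and direction")
  }
  if (!all(regulated$direction %in% c("up", "down"))) {
    abort("`regulated$direction` must be 'up' or 'down'")
  }
  distinct(as_tibble(regulated), .data$gene_id, .keep_all = TRUE)
}

#' Associate binding regions with genes
#'
#' Produces one record per region and role: the nearest gene overall
#' (`role = "any"`) and, when a regulated-gene table is given, the nearest
#' regulated gene within the largest window (`role = "regulated"`).  Signed
#' distances are midpoint-to-TSS (negative upstream); `window_class` is the
#' smallest window containing the absolute distance.
#'
#' @param regions Region tibble.
#' @param genes Gene-model tibble.
#' @param regulated Optional tibble (`gene_id`, `direction`) of regulated
#'   genes (or a named direction vector).
#' @param windows Distance windows in bp (default 1, 10, 50, 100 kb).
#' @return Tibble: `region_id`, `role`, `gene_id`, `signed_distance`,
#'   `window_class`, `gene_regulation`.
#' @export
associate <- function(regions, genes, regulated = NULL,
                      windows = c(1, 10, 50, 100) * 1000) {
  check_intervals(regions)
  check_genes(genes)
  regions <- ensure_region_ids(regions)
  regulated <- normalize_regulated(regulated)
  windows <- sort(windows)
  any_nt <- nearest_tss(regions, genes) |>
    mutate(role = "any", gene_regulation = "unregulated")
  if (nrow(regulated) > 0) {
    any_nt$gene_regulation[any_nt$gene_id %in% regulated$gene_id] <-
      regulated$direction[match(any_nt$gene_id, regulated$gene_id)][
        any_nt$gene_id %in% regulated$gene_id]
  }
  out <- any_nt
  if (nrow(regulated) > 0) {
    reg_genes <- filter(genes, .data$gene_id %in% regulated$gene_id)
    if (nrow(reg_genes) > 0) {
      reg_nt <- nearest_tss(regions, reg_genes) |>
        filter(!is.na(.data$distance), abs(.data$distance) <= max(windows)) |>
        mutate(role = "regulated",
               gene_regulation = regulated$direction[
                 match(.data$gene_id, regulated$gene_id)])
      out <- bind_rows(out, reg_nt)
    }
  }
  out |>
    mutate(window_class = window_class_of(.data$distance, windows)) |>
    select("region_id", "role", "gene_id",
           signed_distance = "distance", "window_class", "gene_regulation") |>
    arrange(.data$role, .data$region_id)
}

# Minimum |TSS - region midpoint| per gene, NA when no region on the
# gene's chromosome.
gene_min_region_distance <- function(genes, regions) {
  mid <- region_midpoint(regions)
  by_chrom <- split(mid, regions$chrom)
  vapply(seq_len(nrow(genes)), function(i) {
    m <- by_chrom[[genes$chrom[i]]]
    if (is.null(m) || length(m) == 0) return(NA_real_)
    min(abs(m - genes$tss[i]))
  }, numeric(1))
}

#' Binding-characteristics summary report
#'
#' The full statistic bundle of a cistrome against its transcriptome:
#' regions within 1/10/50/100 kb of a TSS, regions near regulated genes,
#' regulated genes with regions at each window, region-to-gene densities
#' (regions within 100 kb over genes with at least one region within
#' 100 kb), up/down splits, and PRE content of regulation-associated
#' regions.  Every row is a numerator/denominator pair with
#' `value = numerator/denominator` and `percent = 100 * value` (densities
#' print their ratio in `value`).
#'
#' @inheritParams associate
#' @param pre_region_ids Optional character vector of region ids carrying at
#'   least one PRE motif hit.
#' @return Tibble: `statistic`, `numerator`, `denominator`, `value`,
#'   `percent` (NA value/percent on zero denominators).
#' @export
summarize_binding <- function(regions, genes, regulated = NULL,
                              pre_region_ids = NULL,
                              windows = c(1, 10, 50, 100) * 1000) {
  check_intervals(regions)
  check_genes(genes)
  regions <- ensure_region_ids(regions)
  regulated <- normalize_regulated(regulated)
  windows <- sort(windows)
  wmax <- max(windows)
  nt <- nearest_tss(regions, genes)
  d_any <- abs(nt$distance)
  n_regions <- nrow(regions)

  reg_genes <- filter(genes, .data$gene_id %in% regulated$gene_id)
  if (nrow(reg_genes) > 0) {
    reg_nt <- nearest_tss(regions, reg_genes)
    d_reg <- abs(reg_nt$distance)
    near_reg <- !is.na(d_reg) & d_reg <= wmax
    reg_dir <- regulated$direction[match(reg_nt$gene_id, regulated$gene_id)]
    gene_d <- gene_min_region_distance(reg_genes, regions)
    gdir <- regulated$direction[match(reg_genes$gene_id, regulated$gene_id)]
    assoc <- !is.na(gene_d) & gene_d <= wmax
  } else {
    near_reg <- logical(n_regions)
    reg_dir <- character(0)
    gene_d <- numeric(0)
    gdir <- character(0)
    assoc <- logical(0)
  }
  all_gene_d <- gene_min_region_distance(genes, regions)
  genes_with_region <- sum(!is.na(all_gene_d) & all_gene_d <= wmax)
  has_pre <- regions$region_id %in% (pre_region_ids %||% character(0))

  row <- function(statistic, numerator, denominator) {
    tibble(statistic = statistic, numerator = numerator,
           denominator = denominator,
           value = if (denominator > 0) numerator / denominator else NA_real_,
           percent = if (denominator > 0) 100 * numerator / denominator
             else NA_real_)
  }
  n_up_total <- sum(regulated$direction == "up")
  n_down_total <- sum(regulated$direction == "down")
  bind_rows(
    row("regions_total", n_regions, n_regions),
    row("regions_within_100kb", sum(d_any <= 100000, na.rm = TRUE), n_regions),
    row("regions_within_50kb", sum(d_any <= 50000, na.rm = TRUE), n_regions),
    row("regions_within_10kb", sum(d_any <= 10000, na.rm = TRUE), n_regions),
    row("regions_near_regulated", sum(near_reg), n_regions),
    row("regulated_genes_with_region_100kb", sum(assoc), nrow(regulated)),
    row("regulated_genes_with_region_50kb",
        sum(assoc & gene_d <= 50000), sum(assoc)),
    row("regulated_genes_with_region_10kb",
        sum(assoc & gene_d <= 10000), sum(assoc)),
    row("regulated_genes_with_region_1kb",
        sum(assoc & gene_d <= 1000), sum(assoc)),
    row("region_to_gene_density",
        sum(d_any <= 100000, na.rm = TRUE), genes_with_region),
    row("region_to_regulated_gene_density", sum(near_reg), sum(assoc)),
    row("region_to_up_gene_density",
        sum(near_reg & reg_dir == "up"), sum(assoc & gdir == "up")),
    row("region_to_down_gene_density",
        sum(near_reg & reg_dir == "down"), sum(assoc & gdir == "down")),
    row("regions_near_regulated_with_pre",
        sum(near_reg & has_pre), sum(near_reg)),
    row("up_genes_associated", sum(assoc & gdir == "up"), n_up_total),
    row("down_genes_associated", sum(assoc & gdir == "down"), n_down_total)
  )
}

#' Compare TSS-distance distributions of up- vs down-regulated genes
#'
#' Two-sample KS test on absolute distances, with both medians.
#'
#' @param dists_up,dists_down Numeric vectors of signed or absolute
#'   distances in bp (>= 5 values each).
#' @return A `cistromer_test` (D statistic, p-value) carrying `median_up`
#'   and `median_down` (of absolute distances).
#' @export
compare_distance_distributions <- function(dists_up, dists_down) {
  if (length(dists_up) < 5 || length(dists_down) < 5) {
    abort("need >= 5 distances per group")
  }
  a <- abs(dists_up); b <- abs(dists_down)
  ks <- ks_two_sample(a, b)
  new_cistromer_test(ks$statistic, ks$p.value, ks$method, ks$n_a, ks$n_b,
                     median_up = median(a), median_down = median(b))
}

#' Peak-height comparison between region classes
#'
#' Welch's unpaired t-test between heights of regulation-associated and
#' non-associated binding regions.
#'
#' @param heights_assoc,heights_nonassoc Numeric vectors (>= 3 values each)
#'   of peak heights in RPM.
#' @return A `cistromer_test` (t statistic, two-sided p).
#' @export
peak_height_comparison <- function(heights_assoc, heights_nonassoc) {
  if (length(heights_assoc) < 3 || length(heights_nonassoc) < 3) {
    abort("need >= 3 heights per group")
  }
  welch_t(heights_assoc, heights_nonassoc)
}

#' Regress per-chromosome binding-region counts on gene counts
#'
#' Ordinary least squares of region count against gene count across
#' chromosomes.
#'
#' @param region_counts,gene_counts Numeric vectors (aligned by position or
#'   by names) with one entry per chromosome, >= 3 chromosomes.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `n` (NA slope
#'   when gene counts are constant).
#' @export
chromosome_binding_regression <- function(region_counts, gene_counts) {
  if (!is.null(names(region_counts)) && !is.null(names(gene_counts))) {
    common <- intersect(names(region_counts), names(gene_counts))
    region_counts <- region_counts[common]
    gene_counts <- gene_counts[common]
  }
  if (length(region_counts) != length(gene_counts) ||
      length(region_counts) < 3) {
    abort("need aligned counts for >= 3 chromosomes")
  }
  ols_fit(gene_counts, region_counts)
}
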