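# Peak-to-gene geometry and interval algebra.

# Signed midpoint-to-TSS distance: negative values are upstream of the gene
# (5' of the TSS on the gene's strand).
signed_tss_distance <- function(midpoint, tss, strand) {
  ifelse(strand == "+", midpoint - tss, tss - midpoint)
}

#' Nearest TSS for each binding region
#'
#' For every region the gene minimizing the absolute midpoint-to-TSS distance
#' on the region's chromosome is reported, with the signed distance
#' (negative = upstream of the gene on its own strand).  Equidistant genes are
#' broken by lexicographically smallest `gene_id`; regions on chromosomes
#' without genes get `gene_id = NA` and `distance = NA` rather than an error.
#'
#' @param regions Region tibble (`chrom`, `start`, `end`, optionally
#'   `region_id`).
#' @param genes Gene-model tibble (`gene_id`, `chrom`, `strand`, `tss`, `tes`).
#' @return Tibble with one row per region: `region_id`, `chrom`, `midpoint`,
#'   `gene_id`, `distance`.
#' @export
nearest_tss <- function(regions, genes) {
  check_intervals(regions)
  check_genes(genes)
  regions <- ensure_region_ids(regions)
  if (nrow(genes) == 0) abort("`genes` is empty: need at least one gene")
  mid <- region_midpoint(regions)
  out <- tibble(region_id = regions$region_id, chrom = regions$chrom,
                midpoint = mid, gene_id = NA_character_, distance = NA_real_)
  gsplit <- split(genes, genes$chrom)
  for (i in seq_len(nrow(out))) {
    g <- gsplit[[out$chrom[i]]]
    if (is.null(g)) next
    # candidates near the two flanking TSSs in sorted order, then resolve
    # exact ties by gene_id
    d_abs <- abs(g$tss - out$midpoint[i])
    dmin <- min(d_abs)
    cand <- g[d_abs == dmin, ]
    pick <- cand[order(cand$gene_id)[1], ]
    out$gene_id[i] <- pick$gene_id
    out$distance[i] <- signed_tss_distance(out$midpoint[i], pick$tss, pick$strand)
  }
  out
}

#' Classify region location relative to its nearest gene
#'
#' The region midpoint is placed relative to the gene returned by
#' [nearest_tss()]: within `flank` bp upstream of the TSS (strand-adjusted)
#' gives `"upstream_5utr"`, within the gene body `"intragenic"`, within
#' `flank` bp past the TES `"downstream_3"`, anything else `"intergenic"`.
#'
#' @inheritParams nearest_tss
#' @param flank Upstream/downstream window in bp (default 10 kb).
#' @return The [nearest_tss()] tibble with an added `location` factor column.
#' @export
classify_location <- function(regions, genes, flank = 10000) {
  nt <- nearest_tss(regions, genes)
  gidx <- match(nt$gene_id, genes$gene_id)
  loc <- rep("intergenic", nrow(nt))
  for (i in seq_len(nrow(nt))) {
    gi <- gidx[i]
    if (is.na(gi)) { loc[i] <- NA_character_; next }
    m <- nt$midpoint[i]
    tss <- genes$tss[gi]; tes <- genes$tes[gi]
    if (genes$strand[gi] == "+") {
      loc[i] <- if (m >= tss - flank && m < tss) "upstream_5utr"
        else if (m >= tss && m < tes) "intragenic"
        else if (m >= tes && m < tes + flank) "downstream_3"
        else "intergenic"
    } else {
      loc[i] <- if (m > tss && m <= tss + flank) "upstream_5utr"
        else if (m <= tss && m > tes) "intragenic"
        else if (m <= tes && m > tes - flank) "downstream_3"
        else "intergenic"
    }
  }
  nt$location <- factor(loc, levels = c("upstream_5utr", "intragenic",
                                        "downstream_3", "intergenic"))
  nt
}

as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' Partition two interval sets by 1-bp overlap
#'
#' Mirrors `intersectBed` default semantics: an interval of A is "common" iff
#' it overlaps any interval of B by at least 1 bp under half-open coordinates,
#' and symmetrically for B.
#'
#' @param set_a,set_b Interval tibbles (`chrom`, `start`, `end`, extra columns
#'   preserved).
#' @return List with tibbles `common_a`, `unique_a`, `common_b`, `unique_b`
#'   and counts `n_common_a` etc.  `nrow(common_a) + nrow(unique_a) ==
#'   nrow(set_a)` always.
#' @export
intersect_regions <- function(set_a, set_b) {
  check_intervals(set_a, "set_a")
  check_intervals(set_b, "set_b")
  if (nrow(set_a) == 0 || nrow(set_b) == 0) {
    hit_a <- logical(nrow(set_a))
    hit_b <- logical(nrow(set_b))
  } else {
    ov <- GenomicRanges::findOverlaps(as_granges(set_a), as_granges(set_b),
                                      minoverlap = 1L)
    hit_a <- seq_len(nrow(set_a)) %in% S4Vectors::queryHits(ov)
    hit_b <- seq_len(nrow(set_b)) %in% S4Vectors::subjectHits(ov)
  }
  list(
    common_a = set_a[hit_a, , drop = FALSE],
    unique_a = set_a[!hit_a, , drop = FALSE],
    common_b = set_b[hit_b, , drop = FALSE],
    unique_b = set_b[!hit_b, , drop = FALSE],
    n_common_a = sum(hit_a), n_unique_a = sum(!hit_a),
    n_common_b = sum(hit_b), n_unique_b = sum(!hit_b)
  )
}
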