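# Average tag-density metaprofiles of one factor's tags around another
# factor's peak set.

#' Average tag-density profile around anchor regions
#'
#' For each anchor (summit when available, else interval midpoint) the
#' weighted, shift-corrected tags are counted per bin relative to the
#' anchor, averaged over anchors and normalized per bp, giving weighted
#' tags per bp per region.
#'
#' @param tags Tag tibble.
#' @param anchors Region tibble (>= 1 row).
#' @param window Half-window in bp (default 2000); must be a multiple of
#'   `bin`.
#' @param bin Bin width in bp (default 25).
#' @param shift Strand shift applied to tag positions before counting
#'   (default 0).
#' @return A `cistromer_profile` tibble: `offset` (bin centre relative to
#'   anchor, bp) and `density`; attributes `window`, `bin`, `n_anchors`,
#'   `library_size`.
#' @export
tag_density_profile <- function(tags, anchors, window = 2000, bin = 25,
                                shift = 0) {
  check_tags(tags)
  check_intervals(anchors, "anchors")
  if (nrow(anchors) == 0) abort("`anchors` is empty")
  if (window %% bin != 0) abort("`window` must be a multiple of `bin`")
  anchor_pos <- if ("summit" %in% names(anchors)) anchors$summit
    else region_midpoint(anchors)
  pos <- tags$pos + ifelse(tags$strand == "+", shift, -shift)
  w <- tag_weights(tags)
  n_bins <- 2 * window / bin
  counts <- numeric(n_bins)
  ord <- order(tags$chrom, pos)
  pos_s <- pos[ord]; w_s <- w[ord]; chrom_s <- tags$chrom[ord]
  for (chr in unique(anchors$chrom)) {
    sel <- which(chrom_s == chr)
    if (length(sel) == 0) next
    p <- pos_s[sel]; pw <- w_s[sel]
    for (a in anchor_pos[anchors$chrom == chr]) {
      lo <- findInterval(a - window - 0.5, p) + 1
      hi <- findInterval(a + window - 0.5, p)
      if (hi < lo) next
      off <- p[lo:hi] - a
      b <- floor((off + window) / bin) + 1
      ok <- b >= 1 & b <= n_bins
      if (any(ok)) {
        agg <- rowsum(pw[lo:hi][ok], b[ok])
        counts[as.integer(rownames(agg))] <-
          counts[as.integer(rownames(agg))] + agg[, 1]
      }
    }
  }
  out <- tibble(offset = seq(-window + bin / 2, window - bin / 2, by = bin),
                density = counts / nrow(anchors) / bin)
  attr(out, "window") <- window
  attr(out, "bin") <- bin
  attr(out, "n_anchors") <- nrow(anchors)
  attr(out, "library_size") <- tag_library_size(tags)
  class(out) <- c("cistromer_profile", class(out))
  out
}

#' Contrast two tag-density profiles
#'
#' Elementwise ratio (with a pseudo-density added to both sides so empty
#' bins stay finite) plus per-profile summaries: maximum density and the
#' central/flank ratio (mean of the central 10% of bins over the mean of
#' the outer 20%).
#'
#' @param profile_a,profile_b `cistromer_profile`s with identical geometry.
#' @param pseudo Pseudo-density floor (default 1e-9).
#' @return List: `ratio` tibble (`offset`, `ratio`), `summary` tibble with
#'   `max_density` and `central_flank_ratio` per profile.
#' @export
profile_contrast <- function(profile_a, profile_b, pseudo = 1e-9) {
  if (!isTRUE(all.equal(profile_a$offset, profile_b$offset))) {
    abort("profiles have mismatched window/bin geometry")
  }
  central_flank <- function(p) {
    n <- nrow(p)
    k <- max(1, round(0.05 * n))      # central 10% = 2k bins about centre
    fl <- max(1, round(0.10 * n))     # outer 20% = fl bins at each end
    centre <- mean(p$density[(n / 2 - k + 1):(n / 2 + k)])
    flank <- mean(p$density[c(seq_len(fl), seq(n - fl + 1, n))])
    centre / max(flank, pseudo)
  }
  list(
    ratio = tibble(offset = profile_a$offset,
                   ratio = (profile_a$density + pseudo) /
                     (profile_b$density + pseudo)),
    summary = tibble(
      profile = c("a", "b"),
      max_density = c(max(profile_a$density), max(profile_b$density)),
      central_flank_ratio = c(central_flank(profile_a),
                              central_flank(profile_b)))
  )
}
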