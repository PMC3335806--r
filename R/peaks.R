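# Input-controlled peak calling: strand-shift learning, 1/multiplicity
# weighted pileup, RPM and fold-over-input thresholds, swap-based FDR.

#' Learn the tag strand shift
#'
#' Candidate pileups are 1 kb windows holding at least `min_rpm` unshifted
#' weighted tags (RPM) with tags on both strands.  For each candidate the
#' half-distance between the weighted modes of the - and + strand tag
#' positions is computed; the median over candidates, rounded to integer, is
#' returned (floored at 0).
#'
#' @param chip Tag tibble (`chrom`, `pos`, `strand`, `multiplicity`).
#' @param min_rpm Minimum weighted tags (reads per million) in a window for
#'   it to seed a candidate pileup (default 10).
#' @param window Candidate window size in bp (default 1000).
#' @param min_tags Absolute floor on a candidate's weighted tag count, with
#'   at least 2 tags required per strand (default 8).  Strand-mode
#'   estimation is meaningless on a handful of tags, so sparse windows are
#'   never candidates regardless of library size.
#' @return Learned shift in bp (integer scalar).
#' @export
learn_shift <- function(chip, min_rpm = 10, window = 1000, min_tags = 8) {
  check_tags(chip, "chip")
  total <- tag_library_size(chip)
  if (total == 0) abort("empty tag library")
  w <- tag_weights(chip)
  win <- paste(chip$chrom, chip$pos %/% window)
  wsum <- rowsum(w, win)
  cand <- rownames(wsum)[wsum[, 1] / total * 1e6 >= min_rpm &
                           wsum[, 1] >= min_tags]
  shifts <- c()
  for (cw in cand) {
    idx <- win == cw
    # widen to +-window/2 around the candidate's weighted centre so a pileup
    # straddling a window boundary is seen whole
    centre <- stats::weighted.mean(chip$pos[idx], w[idx])
    sel <- chip$chrom == chip$chrom[idx][1] &
      abs(chip$pos - centre) <= window / 2
    plus <- sel & chip$strand == "+"
    minus <- sel & chip$strand == "-"
    if (sum(plus) < 2 || sum(minus) < 2) next
    shifts <- c(shifts, (weighted_mode(chip$pos[minus], w[minus]) -
                           weighted_mode(chip$pos[plus], w[plus])) / 2)
  }
  if (length(shifts) == 0) {
    abort("no candidate pileups with both-strand tags: supply a fixed shift")
  }
  max(0L, as.integer(round(median(shifts))))
}

#' Call binding regions against an input control
#'
#' Tags are recentred by `shift` (+ strand moved right, - strand left),
#' weighted 1/multiplicity, and clustered into maximal runs separated by
#' gaps of at most `merge_gap` bp.  A candidate is kept iff its weighted tag
#' sum normalized to RPM by the ChIP library size reaches `min_rpm` and its
#' fold enrichment over the library-size-scaled control count (floored at 1
#' pseudo-tag) reaches `fold_threshold`.  The summit is the position of
#' maximum weighted coverage (leftmost on ties).
#'
#' @param chip,control Tag tibbles.
#' @param shift Non-negative integer shift in bp, or `"learn"` to call
#'   [learn_shift()].
#' @param fold_threshold Minimum ChIP/control fold enrichment (default 4).
#' @param min_rpm Minimum weighted tags in RPM per region (default 10).
#' @param merge_gap Maximum within-region gap between shifted tag positions
#'   in bp (default 200, roughly the minimum fragment length).
#' @return Binding-region tibble sorted by (chrom, start): `region_id`,
#'   `chrom`, `start`, `end`, `summit`, `height_rpm`, `fold_enrichment`,
#'   `n_tags`.  The applied shift is attached as attribute `shift`.
#' @export
call_peaks <- function(chip, control, shift = "learn", fold_threshold = 4,
                       min_rpm = 10, merge_gap = 200) {
  check_tags(chip, "chip"); check_tags(control, "control")
  if (fold_threshold <= 0 || min_rpm <= 0) {
    abort("fold_threshold and min_rpm must be positive")
  }
  n_chip <- tag_library_size(chip)
  n_ctrl <- tag_library_size(control)
  if (n_chip == 0 || n_ctrl == 0) abort("zero-size tag library")
  if (identical(shift, "learn")) shift <- learn_shift(chip, min_rpm = min_rpm)
  if (shift < 0) abort("negative shift")
  pos <- chip$pos + ifelse(chip$strand == "+", shift, -shift)
  w <- tag_weights(chip)
  size_ratio <- n_chip / n_ctrl
  ctrl_w_all <- tag_weights(control)
  regions <- list()
  for (chr in unique(chip$chrom)) {
    sel <- chip$chrom == chr
    o <- order(pos[sel])
    p <- pos[sel][o]; pw <- w[sel][o]
    cl <- cumsum(c(1L, as.integer(diff(p) > merge_gap)))
    first <- which(c(TRUE, diff(p) > merge_gap))
    last <- c(first[-1] - 1L, length(p))
    starts <- p[first]; ends <- p[last] + 1L
    wsum <- unname(rowsum(pw, cl)[, 1])
    rpm <- wsum / n_chip * 1e6
    ctrl_sel <- control$chrom == chr
    co <- order(control$pos[ctrl_sel])
    ctrl_pos <- control$pos[ctrl_sel][co]
    ctrl_cum <- c(0, cumsum(ctrl_w_all[ctrl_sel][co]))
    ctrl_sum <- ctrl_cum[findInterval(ends - 0.5, ctrl_pos) + 1] -
      ctrl_cum[findInterval(starts - 0.5, ctrl_pos) + 1]
    fold <- wsum / pmax(ctrl_sum * size_ratio, 1)
    keep <- which(rpm >= min_rpm & fold >= fold_threshold)
    for (k in keep) {
      g <- first[k]:last[k]
      regions[[length(regions) + 1]] <- tibble(
        chrom = chr, start = as.integer(starts[k]),
        end = as.integer(ends[k]),
        summit = as.integer(weighted_mode(p[g], pw[g])),
        height_rpm = rpm[k], fold_enrichment = fold[k],
        n_tags = length(g))
    }
  }
  out <- if (length(regions) == 0) {
    tibble(chrom = character(), start = integer(), end = integer(),
           summit = integer(), height_rpm = numeric(),
           fold_enrichment = numeric(), n_tags = integer())
  } else {
    arrange(list_rbind(regions), .data$chrom, .data$start)
  }
  out <- mutate(out, region_id = sprintf("peak_%04d", row_number())) |>
    select("region_id", "chrom", "start", "end", "summit", "height_rpm",
           "fold_enrichment", "n_tags")
  attr(out, "shift") <- shift
  out
}

#' Swap-based false discovery rate
#'
#' Calls peaks with the ChIP and control roles exchanged; the FDR estimate
#' is the swapped peak count over the forward peak count.
#'
#' @inheritParams call_peaks
#' @return List: `fdr` (NA when no forward peaks), `n_chip_peaks`,
#'   `n_swap_peaks`, `shift`.
#' @export
estimate_fdr <- function(chip, control, shift = "learn", fold_threshold = 4,
                         min_rpm = 10, merge_gap = 200) {
  fwd <- call_peaks(chip, control, shift = shift,
                    fold_threshold = fold_threshold, min_rpm = min_rpm,
                    merge_gap = merge_gap)
  used_shift <- attr(fwd, "shift")
  swap <- call_peaks(control, chip, shift = used_shift,
                     fold_threshold = fold_threshold, min_rpm = min_rpm,
                     merge_gap = merge_gap)
  n_fwd <- nrow(fwd); n_swap <- nrow(swap)
  list(fdr = if (n_fwd == 0) NA_real_ else n_swap / n_fwd,
       n_chip_peaks = n_fwd, n_swap_peaks = n_swap, shift = used_shift)
}
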