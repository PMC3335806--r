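# Internal helpers shared across modules.

# Validate a region/interval tibble: chrom, start, end with 0-based half-open
# coordinates.  Extra columns (summit, height_rpm, ...) pass through untouched.
check_intervals <- function(x, arg = "regions") {
  if (!is.data.frame(x)) abort(sprintf("`%s` must be a data frame", arg))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("`%s` is missing column(s): %s", arg, paste(miss, collapse = ", ")))
  }
  if (nrow(x) > 0) {
    if (any(is.na(x$start) | is.na(x$end)) || any(x$start < 0) || any(x$start >= x$end)) {
      abort(sprintf("`%s` has invalid coordinates: need 0 <= start < end", arg))
    }
    if (any(is.na(x$chrom) | x$chrom == "")) {
      abort(sprintf("`%s` has empty chromosome labels", arg))
    }
  }
  invisible(x)
}

check_genes <- function(genes) {
  if (!is.data.frame(genes)) abort("`genes` must be a data frame")
  need <- c("gene_id", "chrom", "strand", "tss", "tes")
  miss <- setdiff(need, names(genes))
  if (length(miss) > 0) {
    abort(sprintf("`genes` is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (nrow(genes) > 0) {
    if (any(genes$tss == genes$tes)) abort("`genes` has tss == tes")
    bad <- (genes$strand == "+" & genes$tss > genes$tes) |
      (genes$strand == "-" & genes$tss < genes$tes)
    if (any(bad)) abort("`genes` strand/tss/tes orientation inconsistent")
    if (anyDuplicated(genes$gene_id)) abort("`genes` has duplicated gene_id")
  }
  invisible(genes)
}

check_tags <- function(tags, arg = "tags") {
  if (!is.data.frame(tags)) abort(sprintf("`%s` must be a data frame", arg))
  need <- c("chrom", "pos", "strand", "multiplicity")
  miss <- setdiff(need, names(tags))
  if (length(miss) > 0) {
    abort(sprintf("`%s` is missing column(s): %s", arg, paste(miss, collapse = ", ")))
  }
  if (nrow(tags) > 0 && any(tags$multiplicity < 1)) {
    abort(sprintf("`%s` multiplicities must be >= 1", arg))
  }
  invisible(tags)
}

# Tag library size: number of aligned tag records (not the weighted sum).
tag_library_size <- function(tags) nrow(tags)

tag_weights <- function(tags) 1 / tags$multiplicity

region_midpoint <- function(regions) {
  floor((regions$start + regions$end) / 2)
}

# Ensure regions carry a region_id column; autogenerate when absent.
ensure_region_ids <- function(regions) {
  if (!"region_id" %in% names(regions)) {
    regions <- mutate(regions, region_id = sprintf("region_%d", row_number()))
  }
  regions
}

# log(sum(exp(x))) without overflow; -Inf for empty input.
log_sum_exp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0 || all(x == -Inf)) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Deterministic stage sub-seed derived from a master seed (kept below 2^31).
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 1009L + stage * 97L
}

# Weighted mode of integer positions; ties broken leftmost.
weighted_mode <- function(pos, w) {
  if (length(pos) == 0) return(NA_real_)
  agg <- rowsum(w, pos)
  keys <- as.numeric(rownames(agg))
  keys[which.max(agg[, 1])]
}

round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

new_cistromer_test <- function(statistic, p.value, method, n_a = NA_integer_,
                               n_b = NA_integer_, ...) {
  structure(
    list(statistic = statistic, p.value = p.value, method = method,
         n_a = n_a, n_b = n_b, ...),
    class = "cistromer_test"
  )
}

#' @export
print.cistromer_test <- function(x, ...) {
  cat(sprintf("%s\n  statistic = %.6g, p = %.4g (n = %s, %s)\n",
              x$method, x$statistic, x$p.value,
              ifelse(is.na(x$n_a), "?", x$n_a),
              ifelse(is.na(x$n_b), "-", x$n_b)))
  invisible(x)
}

#' @export
tidy.cistromer_test <- function(x, ...) {
  tibble(statistic = unname(x$statistic), p.value = x$p.value,
         method = x$method, n_a = x$n_a, n_b = x$n_b)
}

#' @export
glance.cistromer_test <- function(x, ...) tidy(x)
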