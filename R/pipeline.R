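# End-to-end orchestration on synthetic data and the report rendering.

#' Run the full cistrome-transcriptome pipeline on synthetic data
#'
#' Generates the experiment from `config`, then for each cell line: learns
#' the tag shift, calls peaks against the input control with swap FDR,
#' scans peak sequences for the PRE and cofactor motifs, calls regulated
#' transcripts, and builds the binding-characteristics summary.  Across
#' cell lines it computes the cistrome overlap partition and the
#' transcriptome overlap, and per line the up/down TSS-distance comparison
#' and the peak-height comparison.
#'
#' @param config A [sim_config()].
#' @param report_p Motif report threshold (default 0.01).
#' @param scan_flank Sequence half-window around summits in bp
#'   (default 400).
#' @return A `cistromer_pipeline` list: `per_line` (peaks, fdr, shift,
#'   pre_hits, cofactor_hits, regulated, summary, distance_test,
#'   height_test), `cistrome_overlap`, `transcriptome_overlap`, `sim`,
#'   `config`.
#' @export
run_pipeline <- function(config = sim_config(), report_p = 0.01,
                         scan_flank = 400) {
  sim <- simulate_experiment(config)
  cof <- cofactor_consensus()
  per_line <- list()
  for (line in config$cell_lines) {
    chip <- sim$tags[[line]]$chip
    input <- sim$tags[[line]]$input
    shift <- learn_shift(chip)
    peaks <- call_peaks(chip, input, shift = shift)
    swap <- call_peaks(input, chip, shift = shift)
    fdr <- if (nrow(peaks) == 0) NA_real_ else nrow(swap) / nrow(peaks)
    seqs <- region_sequences(sim$genome, peaks, flank = scan_flank)
    pre_hits <- scan_regions(pre_pwm(), seqs, report_p = report_p)
    seqset <- Biostrings::DNAStringSet(seqs)
    cofactor_hits <- imap(cof, function(pattern, motif) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(pattern)))
      n_fwd <- S4Vectors::elementNROWS(
        Biostrings::vmatchPattern(pattern, seqset, fixed = FALSE))
      n_rev <- S4Vectors::elementNROWS(
        Biostrings::vmatchPattern(rc, seqset, fixed = FALSE))
      tibble(motif = motif, region_id = names(seqs)[n_fwd + n_rev > 0])
    }) |> list_rbind()
    calls <- call_regulated(
      filter(sim$expression, .data$cell_line == !!line))
    regulated <- regulated_transcripts(calls) |>
      rename(gene_id = "transcript_id") |>
      select("gene_id", "direction")
    # a region "contains a PRE" when it holds a strong (p < 1e-5) match:
    # over an 800 bp scan the report threshold alone would flag nearly every
    # region by chance, while planted consensus instances always score strong
    pre_region_ids <- unique(pre_hits$region_id[pre_hits$strength == "strong"])
    summary <- summarize_binding(peaks, sim$genes, regulated,
                                 pre_region_ids = pre_region_ids)
    assoc <- associate(peaks, sim$genes, regulated)
    reg_assoc <- filter(assoc, .data$role == "regulated")
    d_up <- abs(reg_assoc$signed_distance[reg_assoc$gene_regulation == "up"])
    d_down <- abs(reg_assoc$signed_distance[reg_assoc$gene_regulation == "down"])
    distance_test <- if (length(d_up) >= 5 && length(d_down) >= 5) {
      compare_distance_distributions(d_up, d_down)
    } else NULL
    near_reg <- peaks$region_id %in% reg_assoc$region_id
    height_test <- if (sum(near_reg) >= 3 && sum(!near_reg) >= 3) {
      peak_height_comparison(peaks$height_rpm[near_reg],
                             peaks$height_rpm[!near_reg])
    } else NULL
    per_line[[line]] <- list(
      shift = shift, peaks = peaks, fdr = fdr,
      n_swap_peaks = nrow(swap), pre_hits = pre_hits,
      pre_region_ids = pre_region_ids,
      cofactor_hits = cofactor_hits, regulated = regulated,
      summary = summary, distance_test = distance_test,
      height_test = height_test)
  }
  lines <- config$cell_lines
  cistrome_overlap <- intersect_regions(per_line[[lines[1]]]$peaks,
                                        per_line[[lines[2]]]$peaks)
  structure(
    list(per_line = per_line,
         cistrome_overlap = cistrome_overlap,
         transcriptome_overlap = transcriptome_overlap(
           per_line[[lines[1]]]$regulated$gene_id,
           per_line[[lines[2]]]$regulated$gene_id),
         sim = sim, config = config),
    class = "cistromer_pipeline"
  )
}

#' @export
print.cistromer_pipeline <- function(x, ...) {
  for (line in names(x$per_line)) {
    pl <- x$per_line[[line]]
    cat(sprintf("%s: %d peaks (shift %d bp, FDR %.3g), %d regulated genes\n",
                line, nrow(pl$peaks), pl$shift, pl$fdr, nrow(pl$regulated)))
  }
  ov <- x$cistrome_overlap
  cat(sprintf("cistrome overlap: %d/%d and %d/%d regions common\n",
              ov$n_common_a, ov$n_common_a + ov$n_unique_a,
              ov$n_common_b, ov$n_common_b + ov$n_unique_b))
  invisible(x)
}

table1_labels <- c(
  regions_total = "Regions total",
  regions_within_100kb = "Regions within 100 kb of a TSS",
  regions_within_50kb = "Regions within 50 kb of a TSS",
  regions_within_10kb = "Regions within 10 kb of a TSS",
  regions_near_regulated = "Regions near to regulated genes total",
  regulated_genes_with_region_100kb = "Regulated genes with regions within 100 kb",
  regulated_genes_with_region_50kb = "Regulated genes with region within 50 kb of TSS",
  regulated_genes_with_region_10kb = "Regulated genes with region within 10 kb of TSS",
  regulated_genes_with_region_1kb = "Regulated genes with region within 1 kb of TSS",
  region_to_gene_density = "Region to gene density overall",
  region_to_regulated_gene_density = "Region to regulated gene density",
  region_to_up_gene_density = "Region to up-regulated gene density",
  region_to_down_gene_density = "Region to down-regulated gene density",
  regions_near_regulated_with_pre = "Regions near regulated genes that contain PREs",
  up_genes_associated = "Up-regulated genes associated with binding",
  down_genes_associated = "Down-regulated genes associated with binding"
)

#' Render a summary report as a text table
#'
#' Rows in the canonical order of the binding-characteristics table, with
#' `n/denominator` and the percentage to 1 decimal (densities additionally
#' print their ratio to 2 decimals, rounded half-up).  Missing statistics
#' render as `NA` with a warning.
#'
#' @param report Output of [summarize_binding()].
#' @param title Optional heading line.
#' @return Character scalar (multi-line text table).
#' @export
render_table1 <- function(report, title = NULL) {
  lines <- character(0)
  if (!is.null(title)) lines <- c(title, strrep("-", nchar(title)))
  for (key in names(table1_labels)) {
    r <- report[report$statistic == key, ]
    if (nrow(r) == 0) {
      warn(sprintf("summary statistic %s missing from report", key))
      cell <- "NA"; pct <- "NA"
    } else if (is.na(r$value)) {
      cell <- sprintf("%d/%d", r$numerator, r$denominator)
      pct <- "NA"
    } else {
      cell <- if (grepl("density", key)) {
        sprintf("%d/%d (%.2f)", r$numerator, r$denominator,
                round_half_up(r$value, 2))
      } else sprintf("%d/%d", r$numerator, r$denominator)
      pct <- sprintf("%.1f", round_half_up(r$percent, 1))
    }
    lines <- c(lines, sprintf("%-50s %-18s %s", table1_labels[[key]], cell, pct))
  }
  paste(lines, collapse = "\n")
}

#' Parse a rendered summary back into numbers
#'
#' Inverse of [render_table1()] for round-trip checks: recovers statistic,
#' numerator, denominator and percent from the text table.
#'
#' @param text Output of [render_table1()].
#' @return Tibble: `statistic`, `numerator`, `denominator`, `percent`.
#' @export
parse_table1 <- function(text) {
  lines <- unlist(str_split(text, "\n"))
  out <- list()
  for (key in names(table1_labels)) {
    ln <- lines[startsWith(lines, table1_labels[[key]])]
    if (length(ln) != 1) next
    rest <- trimws(str_sub(ln, 51))
    toks <- strsplit(rest, "\\s+")[[1]]
    nd <- as.numeric(strsplit(toks[1], "/")[[1]])
    pct <- suppressWarnings(as.numeric(toks[length(toks)]))
    out[[key]] <- tibble(statistic = key, numerator = nd[1],
                         denominator = nd[2], percent = pct)
  }
  list_rbind(out)
}
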