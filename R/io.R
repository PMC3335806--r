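# Plain-text I/O: BED intervals, gene-model TSV, tag TSV, FASTA, MEME minimal
# motifs.  All coordinates are 0-based half-open, matching native BED.

#' Parse BED-format text into an interval tibble
#'
#' Coordinates are taken verbatim: BED is already 0-based half-open.  Track
#' and browser lines and empty lines are skipped; field 4 becomes `name`,
#' field 5 `score`, field 6 `strand` when present.
#'
#' @param text Character scalar (possibly multi-line) or character vector of
#'   BED lines.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present in
#'   the input, `name`, `score`, `strand`.  Row order follows line order.
#' @examples
#' parse_bed("chr1\t100\t200\nchr2\t0\t50")
#' @export
parse_bed <- function(text) {
  lines <- unlist(str_split(paste(text, collapse = "\n"), "\n"))
  keep <- !grepl("^\\s*$", lines) & !grepl("^(track|browser|#)", lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- str_split(lines[idx], "\t")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("BED parse error: line %d has fewer than 3 tab-separated fields",
                  idx[which(nf < 3)[1]]))
  }
  chrom <- map_chr(fields, 1)
  start <- suppressWarnings(as.integer(map_chr(fields, 2)))
  end <- suppressWarnings(as.integer(map_chr(fields, 3)))
  if (any(is.na(start) | is.na(end))) {
    abort(sprintf("BED parse error: line %d has non-integral coordinates",
                  idx[which(is.na(start) | is.na(end))[1]]))
  }
  if (any(start >= end)) {
    abort(sprintf("BED validation error: line %d has start >= end",
                  idx[which(start >= end)[1]]))
  }
  out <- tibble(chrom = chrom, start = start, end = end)
  if (all(nf >= 4)) out$name <- map_chr(fields, 4)
  if (all(nf >= 5)) out$score <- suppressWarnings(as.numeric(map_chr(fields, 5)))
  if (all(nf >= 6)) out$strand <- map_chr(fields, 6)
  check_intervals(out, "parsed BED")
  out
}

#' Read a BED file
#' @param path File path.
#' @return See [parse_bed()].
#' @export
read_bed <- function(path) parse_bed(readLines(path))

#' Write binding regions (or plain intervals) as BED6 text
#'
#' Emits `chrom start end name score strand` with `score` the peak height in
#' RPM rounded to integer (0 when absent) and strand `"."`.  Round-trips
#' through [parse_bed()] losslessly for coordinates.
#'
#' @param regions Tibble with `chrom`, `start`, `end`; optionally `region_id`
#'   (used as name) and `height_rpm` (used as score).
#' @param path Optional file path; when given the text is also written there.
#' @return BED text as a character scalar, invisibly when `path` is given.
#' @export
write_bed <- function(regions, path = NULL) {
  check_intervals(regions)
  if (nrow(regions) == 0) {
    txt <- ""
  } else {
    regions <- ensure_region_ids(regions)
    score <- if ("height_rpm" %in% names(regions)) round(regions$height_rpm) else 0L
    txt <- paste(sprintf("%s\t%d\t%d\t%s\t%d\t.", regions$chrom,
                         as.integer(regions$start), as.integer(regions$end),
                         regions$region_id, as.integer(score)),
                 collapse = "\n")
  }
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read/write gene models as 5-column TSV
#'
#' Columns `gene_id`, `chrom`, `strand`, `tss`, `tes` with a header row;
#' coordinates 0-based.  On the + strand `tss < tes`, on the - strand
#' `tss > tes`.
#'
#' @param path File path.
#' @return A gene-model tibble.
#' @export
read_gene_models <- function(path) {
  genes <- as_tibble(utils::read.delim(path, colClasses = c(
    gene_id = "character", chrom = "character", strand = "character",
    tss = "integer", tes = "integer")))
  check_genes(genes)
  genes
}

#' @rdname read_gene_models
#' @param genes Gene-model tibble.
#' @export
write_gene_models <- function(genes, path) {
  check_genes(genes)
  utils::write.table(genes[, c("gene_id", "chrom", "strand", "tss", "tes")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write aligned-tag libraries as 4-column TSV
#'
#' Columns `chrom`, `pos` (5' position, 0-based), `strand` (+/-),
#' `multiplicity` (number of genomic alignments; tags are weighted
#' 1/multiplicity downstream).
#'
#' @param path File path.
#' @return A tag tibble.
#' @export
read_tag_library <- function(path) {
  tags <- as_tibble(utils::read.delim(path, colClasses = c(
    chrom = "character", pos = "integer", strand = "character",
    multiplicity = "integer")))
  check_tags(tags)
  tags
}

#' @rdname read_tag_library
#' @param tags Tag tibble.
#' @export
write_tag_library <- function(tags, path) {
  check_tags(tags)
  utils::write.table(tags[, c("chrom", "pos", "strand", "multiplicity")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write genome sequences as FASTA
#'
#' Thin wrappers over Biostrings returning/accepting a named character vector
#' of chromosome sequences, the representation used by the simulator and the
#' motif scanner.
#'
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' @rdname read_genome_fasta
#' @param genome Named character vector of chromosome sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read motifs in MEME minimal format
#'
#' Parses the MEME minimal motif format (version line, optional alphabet /
#' background lines, `MOTIF` blocks with letter-probability matrices) into a
#' list of [pwm()] objects.
#'
#' @param path File path.
#' @param pseudocount Pseudocount passed to [pwm()].
#' @return Named list of `pwm` objects.
#' @export
read_meme <- function(path, pseudocount = 0.001) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) == 1 && bg_at < length(lines)) {
    toks <- strsplit(trimws(lines[bg_at + 1]), "\\s+")[[1]]
    vals <- as.numeric(toks[seq(2, length(toks), by = 2)])
    names(vals) <- toks[seq(1, length(toks), by = 2)]
    bg[names(vals)] <- vals
  }
  starts <- grep("^MOTIF", lines)
  if (length(starts) == 0) abort("no MOTIF blocks found in MEME file")
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    hdr <- grep("^letter-probability matrix", lines[seq(s, length(lines))])[1]
    if (is.na(hdr)) abort(sprintf("motif %s lacks a letter-probability matrix", name))
    hdr <- s + hdr - 1
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[seq(hdr + 1, hdr + w)]
    mat <- do.call(rbind, lapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }))
    out[[name]] <- pwm(t(mat), background = bg, pseudocount = pseudocount,
                       name = name)
  }
  out
}

#' Write motifs in MEME minimal format
#' @param pwms A `pwm` object or (named) list of them.
#' @param path File path.
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "cistromer_pwm")) pwms <- list(pwms)
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
             "Background letter frequencies",
             paste(sprintf("%s %.5f", names(pwms[[1]]$background),
                           pwms[[1]]$background), collapse = " "), "")
  for (i in seq_along(pwms)) {
    m <- pwms[[i]]
    nm <- m$name %||% names(pwms)[i] %||% sprintf("motif_%d", i)
    lines <- c(lines, sprintf("MOTIF %s", nm),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       m$width),
               apply(m$raw_probs %||% m$probs, 2,
                     function(p) paste(sprintf("%.6f", p), collapse = " ")),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}
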