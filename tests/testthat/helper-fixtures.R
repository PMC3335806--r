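# Shared fixtures built in code.

# A random DNA string of length n (uses the current RNG state).
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random interval tibble on a small chromosome set.
random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                             max_len = 500) {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(max_len, n, replace = TRUE))
}

# Random gene models with unique ids.
random_genes <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6) {
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tss <- sample.int(max_pos, n) + 50000L
  len <- sample(5000:20000, n, replace = TRUE)
  tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    strand = strand,
    tss = tss,
    tes = ifelse(strand == "+", tss + len, tss - len))
}

# Tag tibble from vectors, defaulting to unit multiplicity.
make_tags <- function(pos, strand, chrom = "chr1", multiplicity = 1L) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), strand = strand,
                 multiplicity = as.integer(multiplicity))
}

# Brute-force 1bp-overlap indicator matrix oracle.
brute_overlap <- function(a, b) {
  hit_a <- logical(nrow(a))
  hit_b <- logical(nrow(b))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] && a$start[i] < b$end[j] &&
          b$start[j] < a$end[i]) {
        hit_a[i] <- TRUE
        hit_b[j] <- TRUE
      }
    }
  }
  list(hit_a = hit_a, hit_b = hit_b)
}

# Random PWM with Dirichlet-ish columns.
random_pwm <- function(width, pseudocount = 0.001) {
  m <- matrix(stats::rexp(4 * width), nrow = 4)
  cistromer::pwm(sweep(m, 2, colSums(m), "/"), pseudocount = pseudocount)
}

# Plant motif instances into random sequences at given centre offsets;
# returns named character vector of region sequences.
planted_sequences <- function(n, offsets, pattern, len = 800) {
  stopifnot(length(offsets) == n)
  out <- character(n)
  w <- nchar(pattern)
  for (i in seq_len(n)) {
    s <- random_dna(len)
    centre <- len / 2
    start <- round(centre + offsets[i] - w / 2)
    start <- max(1, min(len - w, start))
    inst <- paste(vapply(strsplit(pattern, "")[[1]], function(ch) {
      set <- cistromer:::IUPAC_SETS[[ch]]
      if (length(set) == 1) set else sample(set, 1)
    }, character(1)), collapse = "")
    substr(s, start + 1, start + w) <- inst
    out[i] <- s
  }
  names(out) <- sprintf("r%03d", seq_len(n))
  out
}
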