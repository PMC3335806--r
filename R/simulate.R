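# Synthetic-data generator with planted ground truth: genome + gene models,
# two largely disjoint binding-site sets ("cell lines") carrying planted
# PRE/cofactor motifs, strand-shifted ChIP/input tag libraries, and linked
# regulated-gene expression over three treatment time points.

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a two-cell-line hormone-receptor
#' ChIP-seq experiment at desk scale: sonication fragments of 200-400 bp,
#' multireads capped at multiplicity 10 and weighted 1/m downstream, 60% of
#' regulated genes linked to a binding site within 100 kb, up-regulated
#' genes drawn closer to their site (exponential decay, 44 kb mean) than
#' down-regulated ones (75 kb), and treatment time points at 2, 6 and 24 h.
#'
#' @param seed Master RNG seed; every stage derives its own sub-seed from it
#'   so partial re-runs are reproducible.
#' @param n_chroms,chrom_length Number of chromosomes and their common
#'   length in bp.
#' @param n_genes Genes placed on the genome (collision-free TSSs).
#' @param n_sites Binding sites per cell line.
#' @param shared_site_fraction Fraction of each line's sites placed at
#'   identical coordinates in both lines.
#' @param pre_plant_prob Probability a site receives a planted PRE.
#' @param cofactor_plant_probs Named list per cell line of cofactor planting
#'   probabilities (`foxa1`, `nf1`, `ap1`); defaults mirror a FOXA1-rich
#'   cancer-like line and an NF1/AP-1-rich immortalized-normal-like line.
#' @param fragment_length_range Sonication fragment length range in bp.
#' @param n_chip_tags,n_input_tags Tags per ChIP / input library.
#' @param multiread_fraction Fraction of tags given multiplicity in
#'   `[2, multiplicity_cap]`.
#' @param multiplicity_cap Maximum alignment multiplicity (default 10).
#' @param background_rate Fraction of ChIP tags drawn uniformly from the
#'   genome rather than from sites.
#' @param frac_regulated_genes Fraction of genes regulated per cell line.
#' @param frac_regulated_with_site_100kb Fraction of regulated genes linked
#'   to a binding site within 100 kb of their TSS (default 0.60).
#' @param up_down_ratio Named vector per cell line: probability a regulated
#'   gene is up- rather than down-regulated.
#' @param timepoints Treatment time points in hours.
#' @param de_fc_effect Minimum linear fold change of regulated transcripts.
#' @param de_p_noise SD of null log2 fold-change noise.
#' @param site_width Planted site width in bp.
#' @param pre_offset_sd SD (bp) of the normal placement of planted PREs
#'   about the site centre.
#' @param dist_decay_mean_up,dist_decay_mean_down Mean of the exponential
#'   TSS-to-site distance for up-/down-regulated linked genes (bp).
#' @param cell_lines Labels of the two cell lines.
#' @param sequence Generate chromosome sequences (default TRUE).  Set FALSE
#'   for geometry-only runs (tags, peaks, associations) that need no DNA:
#'   motif planting and scanning are then unavailable.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 4,
                       chrom_length = 25000000,
                       n_genes = 300,
                       n_sites = 120,
                       shared_site_fraction = 0.25,
                       pre_plant_prob = 0.6,
                       cofactor_plant_probs = list(
                         cell_a = c(foxa1 = 0.44, nf1 = 0.10, ap1 = 0.11),
                         cell_b = c(foxa1 = 0.10, nf1 = 0.23, ap1 = 0.28)),
                       fragment_length_range = c(200, 400),
                       n_chip_tags = 20000,
                       n_input_tags = 20000,
                       multiread_fraction = 0.05,
                       multiplicity_cap = 10,
                       background_rate = 0.5,
                       frac_regulated_genes = 0.3,
                       frac_regulated_with_site_100kb = 0.60,
                       up_down_ratio = c(cell_a = 0.85, cell_b = 0.47),
                       timepoints = c(2, 6, 24),
                       de_fc_effect = 2,
                       de_p_noise = 0.15,
                       site_width = 300,
                       pre_offset_sd = 50,
                       dist_decay_mean_up = 44000,
                       dist_decay_mean_down = 75000,
                       cell_lines = c("cell_a", "cell_b"),
                       sequence = TRUE) {
  cfg <- as.list(environment())
  probs <- c(cfg$shared_site_fraction, cfg$pre_plant_prob,
             unlist(cfg$cofactor_plant_probs), cfg$multiread_fraction,
             cfg$background_rate, cfg$frac_regulated_genes,
             cfg$frac_regulated_with_site_100kb, cfg$up_down_ratio)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must lie in [0, 1]")
  if (cfg$fragment_length_range[1] < 50 || cfg$fragment_length_range[2] > 1000 ||
      diff(cfg$fragment_length_range) < 0) {
    abort("fragment_length_range must be increasing and within [50, 1000]")
  }
  counts <- c(cfg$n_chroms, cfg$chrom_length, cfg$n_chip_tags,
              cfg$n_input_tags, cfg$n_sites, cfg$site_width)
  if (any(counts <= 0)) abort("counts must be positive")
  if (length(cfg$cell_lines) != 2) abort("exactly two cell lines are supported")
  structure(cfg, class = "sim_config")
}

#' Simulate a genome with gene models
#'
#' Chromosome sequences are i.i.d. uniform over A/C/G/T; genes are placed
#' with collision-free TSSs (minimum 2 kb apart), random strands and body
#' lengths of 5-20 kb, truncated at chromosome ends.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_genome` with `genome` (named character vector)
#'   and `genes` (gene-model tibble).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  base_raw <- charToRaw(paste(DNA_BASES, collapse = ""))
  withr::with_seed(stage_seed(config$seed, 1L), {
    genome <- setNames(
      vapply(seq_len(config$n_chroms), function(i) {
        if (!config$sequence) return("")
        rawToChar(base_raw[sample.int(4L, config$chrom_length, replace = TRUE)])
      }, character(1)),
      sprintf("chr%d", seq_len(config$n_chroms)))
    genes <- simulate_gene_models(config)
  })
  structure(list(genome = genome, genes = genes,
                 chrom_length = setNames(rep(config$chrom_length,
                                             config$n_chroms),
                                         names(genome))),
            class = "sim_genome")
}

simulate_gene_models <- function(config) {
  n <- config$n_genes
  if (n == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  strand = character(), tss = integer(), tes = integer()))
  }
  margin <- min(25000L, max(1L, config$chrom_length %/% 10L))
  min_gap <- min(2000L, max(10L, (config$chrom_length - 2L * margin) %/%
                              max(1L, 2L * n)))
  placed <- list()
  tss_by_chrom <- setNames(vector("list", config$n_chroms),
                           sprintf("chr%d", seq_len(config$n_chroms)))
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(200)) {
      chr <- sprintf("chr%d", sample.int(config$n_chroms, 1))
      tss <- sample(seq(margin, config$chrom_length - margin), 1)
      if (any(abs(tss_by_chrom[[chr]] - tss) < min_gap)) next
      strand <- sample(c("+", "-"), 1)
      len <- sample(5000:20000, 1)
      tes <- if (strand == "+") min(tss + len, config$chrom_length - 1L)
        else max(tss - len, 1L)
      placed[[i]] <- tibble(gene_id = sprintf("gene_%04d", i), chrom = chr,
                            strand = strand, tss = as.integer(tss),
                            tes = as.integer(tes))
      tss_by_chrom[[chr]] <- c(tss_by_chrom[[chr]], tss)
      ok <- TRUE
      break
    }
    if (!ok) abort("could not place genes without TSS collisions")
  }
  arrange(list_rbind(placed), .data$chrom, .data$tss)
}

#' Draw signed TSS-to-site linkage distances
#'
#' The generator's distance-decay model: exponential with mean
#' `dist_decay_mean_up` for up-regulated genes and `dist_decay_mean_down`
#' for down-regulated ones, with a random sign (upstream/downstream).  The
#' model itself is unbounded; when placing linked sites the generator
#' passes `max_dist = 99000` so planted sites respect the 100 kb
#' association window (truncation by redraw).
#'
#' @param n Number of draws.
#' @param direction Character vector (`"up"`/`"down"`), recycled to `n`.
#' @param config A [sim_config()].
#' @param max_dist Optional truncation bound in bp (default none).
#' @return Integer vector of signed distances in bp.
#' @export
draw_linkage_distance <- function(n, direction, config, max_dist = Inf) {
  direction <- rep_len(direction, n)
  mean_d <- ifelse(direction == "up", config$dist_decay_mean_up,
                   config$dist_decay_mean_down)
  d <- rexp(n, rate = 1 / mean_d)
  over <- which(d > max_dist)
  while (length(over) > 0) {
    d[over] <- rexp(length(over), rate = 1 / mean_d[over])
    over <- which(d > max_dist)
  }
  as.integer(round(d)) * sample(c(-1L, 1L), n, replace = TRUE)
}

instantiate_iupac <- function(pattern) {
  chars <- strsplit(str_to_upper(pattern), "")[[1]]
  paste(vapply(chars, function(ch) {
    s <- IUPAC_SETS[[ch]]
    if (length(s) == 1) s else sample(s, 1)
  }, character(1)), collapse = "")
}

revcomp_string <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Plant binding sites, motifs and regulated genes
#'
#' Selects regulated genes (with up/down direction and onset time point) for
#' each cell line, links the configured fraction of them to a binding site
#' within 100 kb of their TSS (distance exponential, up-regulated genes
#' closer than down-regulated), places the configured shared fraction of
#' sites at intersecting coordinates in both lines plus line-unique
#' background sites, and writes instantiated PRE/FOXA1/NF1/AP-1 motifs into
#' the genome sequence at recorded offsets from the site centres (PRE
#' offsets normal about the centre).
#'
#' @param sim_genome A `sim_genome` from [simulate_genome()].
#' @param config The [sim_config()].
#' @return List of class `sim_truth`: `genome` (the mutated `sim_genome`),
#'   `sites` (one row per cell line x site), `motifs` (planted instances
#'   with offsets), `regulated` (per-line regulated genes with direction,
#'   onset, linked site and signed distance).
#' @export
plant_binding_sites <- function(sim_genome, config) {
  stopifnot(inherits(sim_genome, "sim_genome"), inherits(config, "sim_config"))
  genome <- sim_genome$genome
  genes <- sim_genome$genes
  half <- floor(config$site_width / 2)
  chrom_len <- sim_genome$chrom_length %||% nchar(genome)
  withr::with_seed(stage_seed(config$seed, 2L), {
    n_shared <- round(config$shared_site_fraction * config$n_sites)
    regulated <- list()
    site_rows <- list()
    centre_by_chrom <- list()  # occupied site centres, shared across lines
    place_ok <- function(chr, centre) {
      if (centre < half + 1 || centre > chrom_len[[chr]] - half - 1) return(FALSE)
      occ <- centre_by_chrom[[chr]]
      is.null(occ) || all(abs(occ - centre) >= 2 * config$site_width)
    }
    register <- function(chr, centre) {
      centre_by_chrom[[chr]] <<- c(centre_by_chrom[[chr]], centre)
    }

    for (line in config$cell_lines) {
      n_reg <- round(config$frac_regulated_genes * nrow(genes))
      reg_genes <- genes[sample.int(nrow(genes), n_reg), ]
      dir <- ifelse(runif(n_reg) < config$up_down_ratio[[line]], "up", "down")
      onset <- sample(config$timepoints, n_reg, replace = TRUE,
                      prob = c(0.5, 0.3, 0.2)[seq_along(config$timepoints)])
      n_link <- round(config$frac_regulated_with_site_100kb * n_reg)
      if (n_link + n_shared > config$n_sites) {
        abort(sprintf(
          "not enough sites to satisfy linkage: need %d linked + %d shared > %d sites",
          n_link, n_shared, config$n_sites))
      }
      link_idx <- sample.int(n_reg, n_link)
      linked_site <- rep(NA_character_, n_reg)
      distance <- rep(NA_real_, n_reg)
      k <- 0
      for (i in link_idx) {
        k <- k + 1
        sid <- sprintf("%s_site_%03d", line, k)
        placed <- FALSE
        for (try in seq_len(200)) {
          d <- draw_linkage_distance(1, dir[i], config, max_dist = 99000)
          centre <- reg_genes$tss[i] + d
          if (!place_ok(reg_genes$chrom[i], centre)) next
          register(reg_genes$chrom[i], centre)
          site_rows[[length(site_rows) + 1]] <- tibble(
            cell_line = line, site_id = sid, chrom = reg_genes$chrom[i],
            centre = as.integer(centre), shared = FALSE,
            linked_gene = reg_genes$gene_id[i])
          linked_site[i] <- sid
          distance[i] <- d
          placed <- TRUE
          break
        }
        if (!placed) abort("could not place a linked site after bounded retries")
      }
      regulated[[line]] <- tibble(
        cell_line = line, gene_id = reg_genes$gene_id, direction = dir,
        onset = onset, linked_site = linked_site, distance = distance)
      n_unique_bg <- config$n_sites - n_shared - n_link
      k <- n_link
      for (j in seq_len(n_unique_bg)) {
        k <- k + 1
        repeat {
          chr <- sample(names(genome), 1, prob = chrom_len)
          centre <- sample.int(chrom_len[[chr]], 1)
          if (place_ok(chr, centre)) break
        }
        register(chr, centre)
        site_rows[[length(site_rows) + 1]] <- tibble(
          cell_line = line, site_id = sprintf("%s_site_%03d", line, k),
          chrom = chr, centre = as.integer(centre), shared = FALSE,
          linked_gene = NA_character_)
      }
    }
    # shared sites: identical coordinates in both lines
    for (j in seq_len(n_shared)) {
      repeat {
        chr <- sample(names(genome), 1, prob = chrom_len)
        centre <- sample.int(chrom_len[[chr]], 1)
        if (place_ok(chr, centre)) break
      }
      register(chr, centre)
      for (line in config$cell_lines) {
        site_rows[[length(site_rows) + 1]] <- tibble(
          cell_line = line, site_id = sprintf("shared_site_%03d", j),
          chrom = chr, centre = as.integer(centre), shared = TRUE,
          linked_gene = NA_character_)
      }
    }
    sites <- list_rbind(site_rows) |>
      mutate(start = .data$centre - half, end = .data$centre + half)
    # site strengths: lognormal, linked sites boosted (peak height tracks
    # regulation association)
    uniq <- distinct(sites, .data$site_id, .keep_all = TRUE)
    strength <- exp(rnorm(nrow(uniq), 0, 0.4)) *
      ifelse(is.na(uniq$linked_gene), 1, 1.5)
    sites <- left_join(sites, tibble(site_id = uniq$site_id,
                                     strength = strength), by = "site_id")

    # plant motifs once per unique genomic site (skipped without sequence);
    # sequence edits are collected and applied in one pass per chromosome
    motif_rows <- list()
    edits <- list()
    plant_motifs <- config$sequence
    max_off <- half - 25L
    cof <- cofactor_consensus()
    shared_cof_prob <- (unlist(config$cofactor_plant_probs[[1]]) +
                          unlist(config$cofactor_plant_probs[[2]])) / 2
    for (i in seq_len(if (plant_motifs) nrow(uniq) else 0)) {
      s <- uniq[i, ]
      probs <- if (s$shared) shared_cof_prob
        else unlist(config$cofactor_plant_probs[[s$cell_line]])
      taken <- list()
      free_offset <- function(width) {
        for (try in seq_len(50)) {
          off <- sample(seq(-max_off, max_off - width), 1)
          hit <- any(vapply(taken, function(t) off < t[2] && off + width > t[1],
                            logical(1)))
          if (!hit) {
            taken[[length(taken) + 1]] <<- c(off, off + width)
            return(off)
          }
        }
        NA_integer_
      }
      plant_one <- function(motif, pattern, off) {
        inst <- instantiate_iupac(pattern)
        strand <- sample(c("+", "-"), 1)
        written <- if (strand == "+") inst else revcomp_string(inst)
        abs_start <- s$centre + off  # 0-based genomic start
        edits[[length(edits) + 1]] <<- tibble(
          chrom = s$chrom, start = abs_start, text = written)
        motif_rows[[length(motif_rows) + 1]] <<- tibble(
          site_id = s$site_id, motif = motif, offset = as.integer(off),
          strand = strand, instance = inst, width = nchar(inst))
      }
      if (runif(1) < config$pre_plant_prob) {
        off <- as.integer(round(rnorm(1, 0, config$pre_offset_sd)))
        off <- max(-max_off, min(max_off - nchar(pre_consensus()), off))
        taken[[length(taken) + 1]] <- c(off, off + nchar(pre_consensus()))
        plant_one("pre", pre_consensus(), off)
      }
      for (m in names(cof)) {
        if (runif(1) < probs[[m]]) {
          off <- free_offset(nchar(cof[[m]]))
          if (!is.na(off)) plant_one(m, cof[[m]], off)
        }
      }
    }
  })
  if (length(edits) > 0) {
    ed <- list_rbind(edits)
    for (chr in unique(ed$chrom)) {
      e <- ed[ed$chrom == chr, ]
      ds <- Biostrings::DNAString(genome[[chr]])
      at <- IRanges::IRanges(start = e$start + 1L, width = nchar(e$text))
      genome[[chr]] <- as.character(Biostrings::replaceAt(ds, at, e$text))
    }
  }
  sim_genome$genome <- genome
  structure(
    list(genome = sim_genome,
         sites = select(sites, "cell_line", "site_id", "chrom", "start",
                        "end", "centre", "strength", "shared", "linked_gene"),
         motifs = if (length(motif_rows)) list_rbind(motif_rows)
           else tibble(site_id = character(), motif = character(),
                       offset = integer(), strand = character(),
                       instance = character(), width = integer()),
         regulated = list_rbind(unname(regulated))),
    class = "sim_truth"
  )
}

#' Simulate strand-shifted ChIP and input tag libraries
#'
#' ChIP tags arise from sonication fragments of uniform length within the
#' configured range centred on planted sites (allocated proportionally to
#' site strength) or uniformly from the genome at the background rate; each
#' fragment contributes one tag at a uniformly chosen end, + strand at the
#' left end and - strand at the right, so the plus/minus pileup modes are
#' separated by about the mean fragment length.  Input tags are uniform.
#' A `multiread_fraction` of tags receives multiplicity 2..cap.
#'
#' @param truth A `sim_truth` from [plant_binding_sites()].
#' @param config The [sim_config()].
#' @param cell_line Which cell line's site set to use.
#' @return List with `chip` and `input` tag tibbles.
#' @export
simulate_tags <- function(truth, config, cell_line = config$cell_lines[1]) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  genome <- truth$genome$genome
  chrom_len <- truth$genome$chrom_length %||% nchar(genome)
  sites <- filter(truth$sites, .data$cell_line == !!cell_line)
  line_idx <- match(cell_line, config$cell_lines)
  withr::with_seed(stage_seed(config$seed, 3L + line_idx), {
    n_bg <- round(config$background_rate * config$n_chip_tags)
    n_sig <- config$n_chip_tags - n_bg
    if (nrow(sites) == 0) { n_bg <- config$n_chip_tags; n_sig <- 0 }
    chip <- list()
    if (n_sig > 0) {
      alloc <- as.vector(stats::rmultinom(1, n_sig,
                                          sites$strength / sum(sites$strength)))
      frag_from <- rep(seq_len(nrow(sites)), alloc)
      L <- sample(seq(config$fragment_length_range[1],
                      config$fragment_length_range[2]),
                  n_sig, replace = TRUE)
      centre <- sites$centre[frag_from]
      left <- centre - floor(L / 2)
      plus <- runif(n_sig) < 0.5
      chip[["signal"]] <- tibble(
        chrom = sites$chrom[frag_from],
        pos = as.integer(ifelse(plus, left, left + L)),
        strand = ifelse(plus, "+", "-"))
    }
    uniform_tags <- function(n) {
      chr <- sample(names(genome), n, replace = TRUE, prob = chrom_len)
      tibble(chrom = chr,
             pos = as.integer(floor(runif(n) * chrom_len[chr])),
             strand = sample(c("+", "-"), n, replace = TRUE))
    }
    if (n_bg > 0) chip[["background"]] <- uniform_tags(n_bg)
    chip <- list_rbind(chip)
    chip$pos <- pmin(pmax(chip$pos, 0L), chrom_len[chip$chrom] - 1L)
    input <- uniform_tags(config$n_input_tags)
    add_multireads <- function(tags) {
      m <- rep(1L, nrow(tags))
      n_multi <- round(config$multiread_fraction * nrow(tags))
      if (n_multi > 0) {
        idx <- sample.int(nrow(tags), n_multi)
        m[idx] <- sample(2:config$multiplicity_cap, n_multi, replace = TRUE)
      }
      mutate(tags, multiplicity = m)
    }
    list(chip = add_multireads(chip), input = add_multireads(input))
  })
}

#' Simulate differential-expression calls
#'
#' Regulated transcripts get `|FC| >= de_fc_effect` in their planted
#' direction from their onset time point onward, with low p-values;
#' unregulated transcripts get near-null fold changes and uniform p-values.
#'
#' @param truth A `sim_truth`.
#' @param config The [sim_config()].
#' @return Tibble: `transcript_id`, `cell_line`, `timepoint`, `log2_fc`,
#'   `diff_p`.
#' @export
simulate_expression <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  genes <- truth$genome$genes
  withr::with_seed(stage_seed(config$seed, 7L), {
    out <- list()
    for (line in config$cell_lines) {
      reg <- filter(truth$regulated, .data$cell_line == !!line)
      grid <- tidyr::expand_grid(transcript_id = genes$gene_id,
                                 timepoint = config$timepoints)
      ridx <- match(grid$transcript_id, reg$gene_id)
      active <- !is.na(ridx) & grid$timepoint >= reg$onset[ridx]
      n <- nrow(grid)
      lfc <- rnorm(n, 0, config$de_p_noise)
      p <- runif(n)
      dir_sign <- ifelse(!is.na(ridx) & reg$direction[ridx] == "up", 1, -1)
      lfc[active] <- dir_sign[active] *
        (log2(config$de_fc_effect) + rexp(sum(active), rate = 4))
      p[active] <- runif(sum(active), 0, 0.005)
      out[[line]] <- mutate(grid, cell_line = line, log2_fc = lfc, diff_p = p)
    }
    list_rbind(out) |>
      select("transcript_id", "cell_line", "timepoint", "log2_fc", "diff_p")
  })
}

#' Run the full generator
#'
#' Convenience wrapper: genome, planted sites/motifs/regulated genes, tag
#' libraries for both cell lines, and the expression table.
#'
#' @param config A [sim_config()].
#' @return List of class `cistromer_simulation` with `genome`, `genes`,
#'   `truth`, `tags` (per cell line: `chip`, `input`), `expression`,
#'   `config`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  sg <- simulate_genome(config)
  truth <- plant_binding_sites(sg, config)
  tags <- setNames(
    lapply(config$cell_lines, function(cl) simulate_tags(truth, config, cl)),
    config$cell_lines)
  expression <- simulate_expression(truth, config)
  structure(
    list(genome = truth$genome$genome, genes = truth$genome$genes,
         truth = truth, tags = tags, expression = expression, config = config),
    class = "cistromer_simulation"
  )
}
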