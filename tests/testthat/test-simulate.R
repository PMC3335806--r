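# Geometry-only config used by most checks (no sequence needed).
small_cfg <- function(...) {
  defaults <- list(n_chroms = 2, chrom_length = 5e6, n_genes = 60,
                   n_sites = 40, n_chip_tags = 4000, n_input_tags = 4000,
                   sequence = FALSE)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("simulation is fully deterministic under a seed", {
  cfg <- small_cfg(seed = 5)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$genes, b$genes)
  expect_identical(a$truth$sites, b$truth$sites)
  expect_identical(a$tags$cell_a$chip, b$tags$cell_a$chip)
  expect_identical(a$expression, b$expression)
})

test_that("genome base composition is uniform and genes respect invariants", {
  cfg <- sim_config(seed = 2, n_chroms = 1, chrom_length = 10000,
                    n_genes = 20)
  sg <- simulate_genome(cfg)
  counts <- table(strsplit(sg$genome[[1]], "")[[1]])
  se <- sqrt(0.25 * 0.75 * 10000)
  expect_true(all(abs(counts - 2500) <= 3 * se))
  expect_silent(cistromer:::check_genes(sg$genes))
  expect_equal(anyDuplicated(sg$genes$tss), 0)

  empty <- simulate_genome(sim_config(seed = 2, n_chroms = 1,
                                      chrom_length = 10000, n_genes = 0))
  expect_equal(nrow(empty$genes), 0)
})

test_that("planted site sets honour the shared fraction and limits", {
  cfg <- small_cfg(seed = 7, shared_site_fraction = 1,
                   frac_regulated_with_site_100kb = 0)
  truth <- plant_binding_sites(simulate_genome(cfg), cfg)
  sa <- dplyr::filter(truth$sites, cell_line == "cell_a")
  sb <- dplyr::filter(truth$sites, cell_line == "cell_b")
  expect_equal(sa$centre, sb$centre)  # all shared: identical coordinates

  cfg2 <- small_cfg(seed = 7, shared_site_fraction = 0.3)
  truth2 <- plant_binding_sites(simulate_genome(cfg2), cfg2)
  sa2 <- dplyr::filter(truth2$sites, cell_line == "cell_a")
  expect_equal(sum(sa2$shared), round(0.3 * 40))
  expect_equal(nrow(sa2), 40)

  # impossible linkage demand errors with the shortfall
  cfg3 <- small_cfg(seed = 7, n_sites = 5, frac_regulated_genes = 0.9,
                    frac_regulated_with_site_100kb = 1)
  expect_error(plant_binding_sites(simulate_genome(cfg3), cfg3),
               "not enough sites")
})

test_that("PRE planting frequency matches the configured probability", {
  cfg <- sim_config(seed = 9, n_chroms = 2, chrom_length = 4e6,
                    n_genes = 40, n_sites = 250, pre_plant_prob = 0.6,
                    cofactor_plant_probs = list(
                      cell_a = c(foxa1 = 0, nf1 = 0, ap1 = 0),
                      cell_b = c(foxa1 = 0, nf1 = 0, ap1 = 0)),
                    frac_regulated_with_site_100kb = 0.2)
  truth <- plant_binding_sites(simulate_genome(cfg), cfg)
  n_unique <- dplyr::n_distinct(truth$sites$site_id)
  n_pre <- sum(truth$motifs$motif == "pre")
  se <- sqrt(0.6 * 0.4 * n_unique)
  expect_lt(abs(n_pre - 0.6 * n_unique), 3 * se)
  # planted instances actually sit in the sequence at the recorded offsets
  uniq <- dplyr::distinct(truth$sites, site_id, .keep_all = TRUE)
  pre_rows <- dplyr::inner_join(truth$motifs, uniq, by = "site_id") |>
    dplyr::filter(motif == "pre") |> head(20)
  for (i in seq_len(nrow(pre_rows))) {
    r <- pre_rows[i, ]
    written <- substr(truth$genome$genome[[r$chrom]],
                      r$centre + r$offset + 1, r$centre + r$offset + r$width)
    expected <- if (r$strand == "+") r$instance
      else cistromer:::revcomp_string(r$instance)
    expect_equal(written, expected)
    expect_gt(nrow(match_iupac(pre_consensus(), written)), 0)
  }

  # pre_plant_prob = 0: no planted PREs
  cfg0 <- sim_config(seed = 9, n_chroms = 2, chrom_length = 4e6,
                     n_genes = 40, n_sites = 50, pre_plant_prob = 0)
  truth0 <- plant_binding_sites(simulate_genome(cfg0), cfg0)
  expect_equal(sum(truth0$motifs$motif == "pre"), 0)
})

test_that("tag libraries show the built-in strand shift and determinism", {
  cfg <- small_cfg(seed = 13, background_rate = 0, n_sites = 1,
                   n_chip_tags = 10000, shared_site_fraction = 0,
                   frac_regulated_with_site_100kb = 0)
  truth <- plant_binding_sites(simulate_genome(cfg), cfg)
  tags <- simulate_tags(truth, cfg, "cell_a")
  site <- dplyr::filter(truth$sites, cell_line == "cell_a")
  ctr <- site$centre[1]
  plus <- tags$chip$pos[tags$chip$strand == "+"]
  minus <- tags$chip$pos[tags$chip$strand == "-"]
  expect_true(all(plus < ctr))
  expect_true(all(minus > ctr))
  expect_lt(median(plus), ctr)
  expect_gt(median(minus), ctr)
  # plus/minus separation approximates the mean fragment length
  expect_lt(abs((mean(minus) - mean(plus)) - 300), 10)

  tags2 <- simulate_tags(truth, cfg, "cell_a")
  expect_identical(tags$chip, tags2$chip)
  expect_identical(tags$input, tags2$input)

  # multiread fraction and cap
  cfgm <- small_cfg(seed = 13, multiread_fraction = 0.2)
  tm <- simulate_tags(plant_binding_sites(simulate_genome(cfgm), cfgm),
                      cfgm, "cell_a")
  expect_equal(sum(tm$chip$multiplicity > 1), round(0.2 * cfgm$n_chip_tags))
  expect_lte(max(tm$chip$multiplicity), 10)
  expect_lte(sum(1 / tm$chip$multiplicity), nrow(tm$chip))
})

test_that("expression tables encode the planted regulation", {
  cfg <- small_cfg(seed = 17)
  sim <- simulate_experiment(cfg)
  calls <- call_regulated(dplyr::filter(sim$expression, cell_line == "cell_a"))
  reg <- regulated_transcripts(calls)
  truth_reg <- dplyr::filter(sim$truth$regulated, cell_line == "cell_a")
  # every planted regulated gene is called, directions agree
  expect_true(all(truth_reg$gene_id %in% reg$transcript_id))
  m <- match(truth_reg$gene_id, reg$transcript_id)
  expect_equal(reg$direction[m], truth_reg$direction)
  # false positives stay near the nominal rate
  fp <- setdiff(reg$transcript_id, truth_reg$gene_id)
  expect_lte(length(fp), 3)

  # null case: no regulated genes, no calls beyond the false-positive rate
  cfg0 <- small_cfg(seed = 17, frac_regulated_genes = 0)
  sim0 <- simulate_experiment(cfg0)
  reg0 <- regulated_transcripts(call_regulated(
    dplyr::filter(sim0$expression, cell_line == "cell_a")))
  expect_lte(nrow(reg0), 3)
})

test_that("regulated-gene linkage stays within 100 kb and tracks the target", {
  cfg <- sim_config(seed = 19, n_chroms = 4, chrom_length = 2e7,
                    n_genes = 500, n_sites = 400,
                    frac_regulated_genes = 0.5, sequence = FALSE,
                    frac_regulated_with_site_100kb = 0.6)
  truth <- plant_binding_sites(simulate_genome(cfg), cfg)
  reg <- dplyr::filter(truth$regulated, cell_line == "cell_a")
  linked <- dplyr::filter(reg, !is.na(linked_site))
  expect_equal(nrow(linked), round(0.6 * nrow(reg)))
  expect_true(all(abs(linked$distance) <= 100000))
  # linked sites really are where the truth says, near the right genes
  sites <- dplyr::filter(truth$sites, cell_line == "cell_a")
  gidx <- match(linked$gene_id, truth$genome$genes$gene_id)
  sidx <- match(linked$linked_site, sites$site_id)
  expect_equal(sites$centre[sidx] - truth$genome$genes$tss[gidx],
               linked$distance)
})

test_that("linkage distances follow the up/down decay model", {
  cfg <- sim_config(seed = 23)
  withr::with_seed(101, {
    d_up <- abs(draw_linkage_distance(2000, "up", cfg))
    d_down <- abs(draw_linkage_distance(2000, "down", cfg))
    d_cap <- abs(draw_linkage_distance(2000, "down", cfg, max_dist = 99000))
  })
  expect_lt(abs(mean(d_up) - 44000), 3 * sd(d_up) / sqrt(2000))
  expect_lt(abs(mean(d_down) - 75000), 3 * sd(d_down) / sqrt(2000))
  # the bounded form used at planting time respects the 100 kb window
  expect_true(all(d_cap <= 99000))
  expect_gt(max(d_down), 99000)  # the unbounded model has a tail
})
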