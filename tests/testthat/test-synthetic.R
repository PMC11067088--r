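test_that("identical config and seed reproduce the simulation exactly", {
  cfg <- small_sim_config(seed = 17)
  a <- simulate_mqtl_study(cfg)
  b <- simulate_mqtl_study(cfg)
  expect_identical(a$catalog, b$catalog)
  expect_identical(lapply(a$maps, as.data.frame),
                   lapply(b$maps, as.data.frame))
  expect_identical(a$marker_physical, b$marker_physical)
  expect_identical(a$genes, b$genes)
  # a different seed changes the draw
  c2 <- simulate_mqtl_study(small_sim_config(seed = 18))
  expect_false(identical(a$catalog$peak_cm, c2$catalog$peak_cm))
})

test_that("noise-free maps are monotone subsets of the latent truth", {
  cfg <- small_sim_config(seed = 2, map_noise_sd_cm = 0, swap_rate = 0)
  m <- gen_maps(cfg)
  truth <- m$true_map
  for (mp in m$maps) {
    expect_true(all(mp$marker %in% truth$marker))
    idx <- match(mp$marker, truth$marker)
    expect_equal(mp$pos_cm, truth$pos_cm[idx])
    for (g in unique(mp$lg)) {
      expect_true(!is.unsorted(mp$pos_cm[mp$lg == g]))
    }
  }
})

test_that("anchor_fraction 1 makes every map carry every marker", {
  cfg <- small_sim_config(seed = 3, anchor_fraction = 1)
  m <- gen_maps(cfg)
  sets <- lapply(m$maps, function(mp) sort(mp$marker))
  expect_true(all(vapply(sets, identical, TRUE, sets[[1]])))
})

test_that("adjacent swaps inject ordering conflicts at roughly the set rate", {
  cfg <- small_sim_config(seed = 5, swap_rate = 0.1, map_noise_sd_cm = 0)
  m <- gen_maps(cfg)
  g <- order_graph(m$maps, "CaLG01")
  expect_gt(nrow(attr(g, "conflicts")), 0)
})

test_that("a fixed RIL design echoes the CI formula exactly", {
  cfg <- simulation_config(seed = 4, n_linkage_groups = 2,
                           markers_per_lg = 20, n_maps = 2, n_studies = 3,
                           qtl_per_study = 10,
                           pop_size_range = c(163, 163),
                           pop_type_mix = c(RIL = 1),
                           pve_mix = list(weights = 1,
                                          ranges = list(c(10, 10))),
                           ci_reported_fraction = 0)
  sim <- simulate_mqtl_study(cfg)
  out <- impute_ci(sim$catalog, sim$studies)
  # width 163 / (0.10 * 163) = 10 cM everywhere (up to 0-truncation)
  full <- out$ci_lo_cm > 0
  expect_true(all(abs(out$ci_width_cm[full] - 10) < 1e-9))
})

test_that("catalog scale and PVE shape match the configured study design", {
  sim <- simulate_mqtl_study(simulation_config(seed = 6))
  expect_equal(nrow(sim$catalog), 21 * 72)
  expect_equal(length(unique(sim$catalog$study_id)), 21)
  expect_true(all(sim$studies$population_size >= 126 &
                    sim$studies$population_size <= 1200))
  expect_true(all(sim$catalog$lod >= 2 & sim$catalog$lod <= 54.9))
  expect_true(all(sim$catalog$r2_pct > 0 & sim$catalog$r2_pct <= 76.715))
  s <- summarize_catalog(sim$catalog)
  expect_equal(names(which.max(s$pve_hist)), "[5,10)")
})

test_that("every non-background QTL traces to a true component", {
  cfg <- small_sim_config(seed = 7, background_rate = 0)
  sim <- simulate_mqtl_study(cfg)
  expect_true(all(sim$origin >= 1))
  expect_true(all(sim$origin <= cfg$mqtl_per_lg))
})

test_that("the physical layer is monotone in cM and gene counts track density", {
  sim <- simulate_mqtl_study(small_sim_config(seed = 8))
  for (g in unique(sim$true_map$lg)) {
    tm <- sim$true_map[sim$true_map$lg == g, ]
    chrom <- sub("LG0?", "", g)
    bp <- sim$marker_physical$bp[match(tm$marker, sim$marker_physical$marker)]
    expect_true(all(diff(bp[order(tm$pos_cm)]) > 0))
  }
  # Poisson-mean check on gene counts (loose, 5 sd)
  total_mb <- sum(sim$chrom_lengths) / 1e6
  lambda <- sim$config$genes_per_mb * total_mb
  expect_lt(abs(nrow(sim$genes) - lambda), 5 * sqrt(lambda))
})

test_that("written simulation files round-trip through the package readers", {
  sim <- simulate_mqtl_study(small_sim_config(seed = 9))
  dir <- tempfile("simout")
  paths <- write_simulation(sim, dir)
  cat_in <- read_qtl_table(paths$catalog)
  expect_equal(nrow(cat_in), nrow(sim$catalog))
  expect_equal(nrow(attr(cat_in, "rejections")), 0)
  studies_in <- read_study_table(paths$studies)
  expect_equal(studies_in$population_size, sim$studies$population_size)
  map_in <- read_genetic_map(paths$maps[[1]])
  expect_equal(nrow(map_in), nrow(sim$maps[[1]]))
  phys_in <- read_marker_physical(paths$marker_physical)
  expect_equal(phys_in$bp, sim$marker_physical$bp)
  mta_in <- read_mta_table(paths$mta)
  expect_equal(mta_in$start_bp, sim$mta$start_bp)
  ann <- read_gene_annotation(paths$gff)
  expect_equal(length(ann), nrow(sim$genes))
})
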