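#' Configuration for the synthetic meta-QTL study generator
#'
#' Bundles every knob of the simulated multi-study design. Defaults emulate
#' the statistical structure of the published chickpea abiotic-stress QTL
#' compendium: 8 linkage groups of 139.64-392.7 cM, 21 studies with
#' population sizes 126-1200 (mostly RIL, some F2:3 and MAGIC), LOD scores
#' 2-54.9, and a PVE distribution concentrated in 5-10% with a thin tail up
#' to 76.715%.
#'
#' @param seed master seed; every downstream draw derives from it.
#' @param n_linkage_groups default 8.
#' @param lg_length_range cM range the group lengths are spread across,
#'   default `c(139.64, 392.7)`.
#' @param markers_per_lg markers on the latent true map per group.
#' @param n_maps number of study genetic maps.
#' @param anchor_fraction fraction of true markers present in every map.
#' @param extra_fraction fraction of the remaining markers each map samples.
#' @param map_noise_sd_cm Gaussian position noise per map.
#' @param swap_rate probability of swapping an adjacent marker pair in a map
#'   (creates ordering conflicts), default 0.
#' @param n_studies default 21.
#' @param qtl_per_study default 72 (21 x 72 = 1512).
#' @param pop_size_range default `c(126, 1200)`.
#' @param pop_type_mix named probabilities over `RIL`, `F2_3`, `MAGIC`.
#' @param mqtl_per_lg true MQTL components per group, default 3.
#' @param mqtl_quantiles relative positions of the true MQTL along each
#'   group, default evenly spread over `[0.2, 0.8]` of the length.
#' @param pve_mix list of `weights` and `ranges` for the PVE mixture;
#'   default 0.75 on U(2,10), 0.20 on U(10,25), 0.05 on U(25,76.715).
#' @param lod_range default `c(2, 54.9)`.
#' @param ci_reported_fraction fraction of QTL with explicit CI bounds (the
#'   rest go through imputation), default 0.5.
#' @param background_rate fraction of QTL placed uniformly rather than at a
#'   true component, default 0.05.
#' @param stress_mix named probabilities over the four stress classes.
#' @param bp_per_cm mean physical-to-genetic scale, default 1e6.
#' @param mta_per_true_mqtl MTA hits scattered around each true MQTL.
#' @param mta_sd_bp scatter of those hits, default 2e5.
#' @param background_mta background MTAs per chromosome, default 2.
#' @param genes_per_mb gene density for the synthetic annotation.
#' @param uncharacterized_rate fraction of genes with an "uncharacterized
#'   protein" description, default 0.2.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1,
                              n_linkage_groups = 8,
                              lg_length_range = c(139.64, 392.7),
                              markers_per_lg = 80,
                              n_maps = 4,
                              anchor_fraction = 0.6,
                              extra_fraction = 0.5,
                              map_noise_sd_cm = 0.5,
                              swap_rate = 0,
                              n_studies = 21,
                              qtl_per_study = 72,
                              pop_size_range = c(126, 1200),
                              pop_type_mix = c(RIL = 0.8, F2_3 = 0.1,
                                               MAGIC = 0.1),
                              mqtl_per_lg = 3,
                              mqtl_quantiles = NULL,
                              pve_mix = list(weights = c(0.75, 0.20, 0.05),
                                             ranges = list(c(2, 10),
                                                           c(10, 25),
                                                           c(25, 76.715))),
                              lod_range = c(2, 54.9),
                              ci_reported_fraction = 0.5,
                              background_rate = 0.05,
                              stress_mix = c(DROUGHT = 0.6, HEAT = 0.15,
                                             COLD = 0.05, SALINITY = 0.2),
                              bp_per_cm = 1e6,
                              mta_per_true_mqtl = 3,
                              mta_sd_bp = 2e5,
                              background_mta = 2,
                              genes_per_mb = 10,
                              uncharacterized_rate = 0.2) {
  if (is.null(mqtl_quantiles)) {
    mqtl_quantiles <- if (mqtl_per_lg == 1) 0.5 else
      seq(0.2, 0.8, length.out = mqtl_per_lg)
  }
  cfg <- as.list(environment())
  stopifnot(cfg$n_linkage_groups >= 1, all(cfg$lg_length_range > 0),
            cfg$anchor_fraction >= 0, cfg$anchor_fraction <= 1,
            abs(sum(cfg$pve_mix$weights) - 1) < 1e-8)
  class(cfg) <- "simulation_config"
  cfg
}

.lg_names <- function(n) sprintf("CaLG%02d", seq_len(n))

.draw_pve <- function(n, pve_mix) {
  comp <- sample.int(length(pve_mix$weights), n, replace = TRUE,
                     prob = pve_mix$weights)
  vapply(comp, function(k) {
    r <- pve_mix$ranges[[k]]
    runif(1, r[1], r[2])
  }, 0)
}

#' Generate study genetic maps with known truth
#'
#' Draws a latent "true" map per linkage group (uniform marker positions over
#' the group length), then builds each study map as a marker subset (anchors
#' shared by every map, plus a private sample of the rest) with Gaussian
#' position noise, re-sorted; optionally adjacent pairs are swapped to
#' inject ordering conflicts.
#'
#' @param config a [simulation_config()].
#' @return list with `maps` (list of `genetic_map`), `true_map` (data.frame
#'   `marker, lg, pos_cm`), `lg_lengths` (named vector).
#' @export
gen_maps <- function(config) {
  with_seed(derive_seed(config$seed, "maps"), {
    lgs <- .lg_names(config$n_linkage_groups)
    lens <- setNames(
      seq(config$lg_length_range[1], config$lg_length_range[2],
          length.out = max(config$n_linkage_groups, 2))[
            seq_len(config$n_linkage_groups)],
      lgs)
    true_list <- lapply(lgs, function(g) {
      pos <- sort(runif(config$markers_per_lg, 0, lens[[g]]))
      pos[1] <- 0
      data.frame(marker = sprintf("M%s_%03d", gsub("\\D", "", g),
                                  seq_along(pos)),
                 lg = g, pos_cm = pos, stringsAsFactors = FALSE)
    })
    true_map <- do.call(rbind, true_list)
    maps <- lapply(seq_len(config$n_maps), function(m) {
      rows <- lapply(true_list, function(tl) {
        n <- nrow(tl)
        n_anchor <- max(2, round(config$anchor_fraction * n))
        anchors <- seq_len(n_anchor)  # same low indices in every map
        rest <- setdiff(seq_len(n), anchors)
        extra <- if (length(rest)) {
          sort(sample(rest, round(config$extra_fraction * length(rest))))
        } else integer(0)
        idx <- sort(union(anchors, extra))
        pos <- tl$pos_cm[idx] + rnorm(length(idx), 0, config$map_noise_sd_cm)
        pos <- pmax(pos, 0)
        ord <- order(pos)
        pos <- pos[ord]
        mk <- tl$marker[idx][ord]
        if (config$swap_rate > 0 && length(pos) > 1) {
          for (i in seq_len(length(pos) - 1)) {
            if (runif(1) < config$swap_rate) {
              mk[c(i, i + 1)] <- mk[c(i + 1, i)]
            }
          }
        }
        data.frame(marker = mk, lg = tl$lg[1], pos_cm = pos,
                   stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, rows)
      genetic_map(df$marker, df$lg, df$pos_cm,
                  map_id = sprintf("map%02d", m))
    })
    list(maps = maps, true_map = true_map, lg_lengths = lens)
  })
}

#' Generate a multi-study QTL catalog around known true MQTL
#'
#' Each study gets a population size and design drawn from the configured
#' mix; each QTL picks a linkage group and (unless it is background) one of
#' the true MQTL components, and its peak is the component position plus
#' normal noise whose standard deviation is implied by the population-design
#' CI formula at the drawn (N, R2). Explicit CI bounds are written for a
#' configurable fraction of records (MAGIC records always get them, since no
#' imputation constant exists for that design).
#'
#' @param config a [simulation_config()].
#' @param maps result of [gen_maps()].
#' @return list with `catalog` (a `qtl_catalog`), `studies` (a
#'   `study_meta`), `truth` (data.frame of true components: `lg, component,
#'   pos_cm`), `origin` (per-QTL generating component, 0 = background),
#'   `study_maps` (study to map-id assignment).
#' @export
gen_qtl_catalog <- function(config, maps) {
  with_seed(derive_seed(config$seed, "qtl"), {
    lgs <- .lg_names(config$n_linkage_groups)
    lens <- maps$lg_lengths
    truth <- do.call(rbind, lapply(lgs, function(g) {
      data.frame(lg = g, component = seq_len(config$mqtl_per_lg),
                 pos_cm = config$mqtl_quantiles * lens[[g]],
                 stringsAsFactors = FALSE)
    }))
    study_ids <- sprintf("study%02d", seq_len(config$n_studies))
    studies <- data.frame(
      study_id = study_ids,
      population_type = sample(names(config$pop_type_mix),
                               config$n_studies, replace = TRUE,
                               prob = config$pop_type_mix),
      population_size = round(runif(config$n_studies,
                                    config$pop_size_range[1],
                                    config$pop_size_range[2])),
      stringsAsFactors = FALSE)
    class(studies) <- c("study_meta", "data.frame")
    study_maps <- setNames(
      sprintf("map%02d", (seq_len(config$n_studies) - 1) %% config$n_maps + 1),
      study_ids)
    traits <- c("YLD", "100SW", "DF", "DM", "PHT", "HI", "BM", "RLD",
                "SN", "NP/P", "DTI", "RSA")
    rows <- list()
    origin <- integer(0)
    for (s in seq_len(config$n_studies)) {
      n_q <- config$qtl_per_study
      ptype <- studies$population_type[s]
      N <- studies$population_size[s]
      const <- if (ptype %in% c("F2_3", "BACKCROSS")) 530 else 163
      for (q in seq_len(n_q)) {
        g <- sample(lgs, 1)
        len <- lens[[g]]
        r2 <- .draw_pve(1, config$pve_mix)
        width <- const / ((r2 / 100) * N)
        sigma <- width / 3.92
        bg <- runif(1) < config$background_rate
        if (bg) {
          peak <- runif(1, 0, len)
          comp <- 0L
        } else {
          comp <- sample.int(config$mqtl_per_lg, 1)
          mu <- truth$pos_cm[truth$lg == g & truth$component == comp]
          peak <- min(max(rnorm(1, mu, sigma), 0), len)
        }
        report_ci <- ptype == "MAGIC" ||
          runif(1) < config$ci_reported_fraction
        rows[[length(rows) + 1]] <- data.frame(
          qtl_id = sprintf("Q%02d_%03d", s, q),
          study_id = study_ids[s],
          trait = sample(traits, 1),
          stress = sample(names(config$stress_mix), 1,
                          prob = config$stress_mix),
          lg = g, peak_cm = peak,
          ci_lo_cm = if (report_ci) max(0, peak - width / 2) else NA_real_,
          ci_hi_cm = if (report_ci) peak + width / 2 else NA_real_,
          lod = runif(1, config$lod_range[1], config$lod_range[2]),
          r2_pct = r2,
          flank_left = NA_character_, flank_right = NA_character_,
          env = "E1", stringsAsFactors = FALSE)
        origin <- c(origin, comp)
      }
    }
    catalog <- do.call(rbind, rows)
    catalog$ci_source <- ifelse(is.na(catalog$ci_lo_cm), "to_impute",
                                "reported")
    class(catalog) <- c("qtl_catalog", "data.frame")
    list(catalog = catalog, studies = studies, truth = truth,
         origin = origin, study_maps = study_maps)
  })
}

#' Generate the physical layer: marker positions, MTAs and gene annotation
#'
#' Builds a monotone piecewise-linear cM-to-bp mapping per linkage group
#' (about `bp_per_cm` with segment-wise jitter), places every true-map
#' marker physically, scatters MTA hits normally around the true MQTL
#' physical positions plus a uniform background, and lays out genes at the
#' configured density with descriptions drawn from a vocabulary that
#' includes stress-related families and "uncharacterized protein".
#'
#' @param config a [simulation_config()].
#' @param maps result of [gen_maps()].
#' @param qtl result of [gen_qtl_catalog()].
#' @return list with `marker_physical`, `mta`, `genes` (data.frame
#'   `gene_id, chrom, start_bp, end_bp, description`), `chrom_lengths`,
#'   `cm_to_bp` (list of per-LG interpolation tables), `truth_bp` (true MQTL
#'   physical positions).
#' @export
gen_physical_layer <- function(config, maps, qtl) {
  with_seed(derive_seed(config$seed, "physical"), {
    lgs <- .lg_names(config$n_linkage_groups)
    chrom_of <- function(g) sub("LG0?", "", g)
    cm_to_bp <- list()
    marker_rows <- list()
    chrom_lengths <- numeric(0)
    for (g in lgs) {
      len <- maps$lg_lengths[[g]]
      knots <- seq(0, len, length.out = max(4, ceiling(len / 50)))
      slopes <- config$bp_per_cm * runif(length(knots) - 1, 0.5, 1.5)
      bp_knots <- cumsum(c(1, slopes * diff(knots)))
      tab <- data.frame(cm = knots, bp = bp_knots)
      cm_to_bp[[g]] <- tab
      chrom <- chrom_of(g)
      chrom_lengths[chrom] <- max(bp_knots)
      tm <- maps$true_map[maps$true_map$lg == g, , drop = FALSE]
      marker_rows[[g]] <- data.frame(
        marker = tm$marker, chrom = chrom,
        bp = round(approx(tab$cm, tab$bp, xout = tm$pos_cm,
                          rule = 2)$y),
        stringsAsFactors = FALSE)
    }
    marker_physical <- do.call(rbind, marker_rows)
    rownames(marker_physical) <- NULL

    truth <- qtl$truth
    truth$chrom <- chrom_of(truth$lg)
    truth$bp <- NA_real_
    for (i in seq_len(nrow(truth))) {
      tab <- cm_to_bp[[truth$lg[i]]]
      truth$bp[i] <- approx(tab$cm, tab$bp, xout = truth$pos_cm[i],
                            rule = 2)$y
    }

    mta_rows <- list()
    for (i in seq_len(nrow(truth))) {
      n <- config$mta_per_true_mqtl
      if (n > 0) {
        mta_rows[[length(mta_rows) + 1]] <- data.frame(
          chrom = truth$chrom[i],
          bp = round(rnorm(n, truth$bp[i], config$mta_sd_bp)),
          stringsAsFactors = FALSE)
      }
    }
    for (chrom in names(chrom_lengths)) {
      n <- config$background_mta
      if (n > 0) {
        mta_rows[[length(mta_rows) + 1]] <- data.frame(
          chrom = chrom,
          bp = round(runif(n, 1, chrom_lengths[[chrom]])),
          stringsAsFactors = FALSE)
      }
    }
    mta <- do.call(rbind, mta_rows)
    mta$bp <- pmax(mta$bp, 1)
    mta <- data.frame(mta_id = sprintf("MTA%04d", seq_len(nrow(mta))),
                      chrom = mta$chrom, start_bp = mta$bp, end_bp = mta$bp,
                      trait = "abiotic", stringsAsFactors = FALSE)

    vocab <- c("class I heat shock protein", "peroxidase 12",
               "aquaporin PIP2-like", "gibberellin 20 oxidase",
               "abscisic acid-insensitive 5-like protein",
               "IAA-amino acid hydrolase ILR1-like",
               "cytochrome P450 71A1", "F-box/kelch-repeat protein",
               "zinc finger CCCH domain protein",
               "Casparian strip membrane protein 2",
               "cinnamoyl-CoA reductase 1-like",
               "chaperone dnaJ-like protein",
               "trichome birefringence-like protein",
               "potassium channel AKT1", "UDP-glycosyltransferase 85A2",
               "pentatricopeptide repeat-containing protein",
               "40S ribosomal protein S3", "actin-depolymerizing factor",
               "serine/threonine-protein phosphatase 7",
               "cell division cycle protein 48")
    gene_rows <- list()
    for (chrom in names(chrom_lengths)) {
      L <- chrom_lengths[[chrom]]
      n <- rpois(1, config$genes_per_mb * L / 1e6)
      if (n == 0) next
      start <- round(sort(runif(n, 1, L - 5000)))
      width <- round(runif(n, 1000, 5000))
      unchar <- runif(n) < config$uncharacterized_rate
      desc <- ifelse(unchar, "uncharacterized protein",
                     sample(vocab, n, replace = TRUE))
      gene_rows[[chrom]] <- data.frame(
        gene_id = sprintf("%s.g%04d", chrom, seq_len(n)),
        chrom = chrom, start_bp = start, end_bp = start + width,
        description = desc, stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, gene_rows)
    rownames(genes) <- NULL
    list(marker_physical = marker_physical, mta = mta, genes = genes,
         chrom_lengths = chrom_lengths, cm_to_bp = cm_to_bp,
         truth_bp = truth)
  })
}

#' Simulate a complete multi-study meta-QTL data set
#'
#' One call producing every pipeline input with known ground truth:
#' study genetic maps, the QTL catalog and study table, the marker
#' physical-position table, MTA list and gene annotation. Identical
#' config (including seed) gives identical output.
#'
#' @param config a [simulation_config()].
#' @return a `mqtl_simulation` list: `maps`, `true_map`, `lg_lengths`,
#'   `catalog`, `studies`, `study_maps`, `truth` (cM), `truth_bp`, `origin`,
#'   `marker_physical`, `mta`, `genes`, `chrom_lengths`, `config`.
#' @export
simulate_mqtl_study <- function(config = simulation_config()) {
  m <- gen_maps(config)
  q <- gen_qtl_catalog(config, m)
  p <- gen_physical_layer(config, m, q)
  out <- c(m, q, p, list(config = config))
  class(out) <- "mqtl_simulation"
  out
}

#' Write a simulated data set to pipeline input files
#'
#' Maps as per-map TSV, QTL catalog and study table and marker positions as
#' CSV, MTAs as a BED-like file, genes as GFF3, and the ground truth as
#' JSON.
#'
#' @param sim a [simulate_mqtl_study()] result.
#' @param dir output directory (created).
#' @return invisibly, a named list of the written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  paths$maps <- vapply(sim$maps, function(m) {
    p <- file.path(dir, paste0(attr(m, "map_id"), ".tsv"))
    write_genetic_map(m, p)
    p
  }, "")
  paths$catalog <- file.path(dir, "qtl_catalog.csv")
  utils::write.csv(as.data.frame(sim$catalog), paths$catalog,
                   row.names = FALSE, na = "")
  paths$studies <- file.path(dir, "studies.csv")
  utils::write.csv(as.data.frame(sim$studies), paths$studies,
                   row.names = FALSE)
  paths$marker_physical <- file.path(dir, "marker_physical.csv")
  utils::write.csv(sim$marker_physical, paths$marker_physical,
                   row.names = FALSE)
  paths$mta <- file.path(dir, "mta.bed")
  utils::write.table(
    data.frame(sim$mta$chrom, sim$mta$start_bp - 1, sim$mta$end_bp,
               sim$mta$mta_id, sim$mta$trait),
    paths$mta, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  paths$gff <- file.path(dir, "genes.gff3")
  lines <- c("##gff-version 3",
             sprintf("%s\tsim\tgene\t%d\t%d\t.\t+\t.\tID=%s;description=%s",
                     sim$genes$chrom, sim$genes$start_bp, sim$genes$end_bp,
                     sim$genes$gene_id, sim$genes$description))
  writeLines(lines, paths$gff)
  paths$truth <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(truth_cm = sim$truth, truth_bp = sim$truth_bp,
         lg_lengths = as.list(sim$lg_lengths),
         study_maps = as.list(sim$study_maps)),
    paths$truth, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}
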