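toy_gff <- function() {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "Ca1\ttoy\tgene\t1000\t2000\t.\t+\t.\tID=g1;description=class I heat shock protein",
    "Ca1\ttoy\tgene\t3000\t4000\t.\t-\t.\tID=g2;description=uncharacterized protein",
    "Ca1\ttoy\tgene\t5000\t6000\t.\t+\t.\tID=g3;description=40S ribosomal protein",
    "Ca1\ttoy\tgene\t20000\t21000\t.\t+\t.\tID=g4;description=aquaporin PIP2",
    "Ca1\ttoy\tgene\t30000\t31000\t.\t+\t.\tID=g5;description=peroxidase 12"
  ), path)
  path
}

test_that("physical intervals are absolute and symmetric", {
  expect_equal(physical_interval(14038103, 13991104), 46999)
  expect_equal(physical_interval(432233, 702233), 270000)
  expect_equal(physical_interval(5, 5), 0)
  set.seed(2)
  a <- runif(10, 1, 1e7); b <- runif(10, 1, 1e7)
  expect_equal(physical_interval(a, b), physical_interval(b, a))
})

test_that("anchoring resolves markers and marks unlocated MQTL not validated", {
  mq <- data.frame(mqtl_id = c("M1", "M2"), lg = "CaLG01",
                   position_cm = c(5, 9), pve_pct = c(12, 40), n_qtl = c(3, 8),
                   flank_left = c("a", "missing"), flank_right = c("b", "c"),
                   stringsAsFactors = FALSE)
  phys <- data.frame(marker = c("a", "b", "c"), chrom = "Ca1",
                     bp = c(100, 200, 900), stringsAsFactors = FALSE)
  anc <- anchor_mqtl(mq, phys)
  expect_equal(anc$validated, c(TRUE, FALSE))
  expect_equal(anc$interval_bp[1], 100)
  expect_true(is.na(anc$interval_bp[2]))
})

test_that("MTA co-location uses closed intervals and widens monotonically", {
  anc <- data.frame(mqtl_id = "M1", chrom = "Ca1",
                    start_bp = 100, stop_bp = 200, validated = TRUE,
                    stringsAsFactors = FALSE)
  mtas <- data.frame(mta_id = c("t1", "t2", "t3", "t4", "t5", "t6"),
                     chrom = "Ca1",
                     start_bp = c(150, 201, 100, 200, 99, 500),
                     end_bp = c(150, 201, 100, 200, 99, 500),
                     trait = "x", stringsAsFactors = FALSE)
  hits <- overlap_mta(anc, mtas)
  expect_setequal(hits$mta_id, c("t1", "t3", "t4"))
  expect_equal(unname(attr(hits, "hit_counts")["M1"]), 3L)
  # widening the interval never loses hits
  anc2 <- anc; anc2$stop_bp <- 600
  hits2 <- overlap_mta(anc2, mtas)
  expect_true(all(hits$mta_id %in% hits2$mta_id))
  # inverted start/stop are normalised before the test
  anc3 <- anc; anc3$start_bp <- 200; anc3$stop_bp <- 100
  expect_setequal(overlap_mta(anc3, mtas)$mta_id, hits$mta_id)
})

test_that("the breeder rule is strict on both thresholds", {
  anc <- data.frame(mqtl_id = c("A", "B", "C", "D"), validated = TRUE,
                    interval_bp = c(1.9e6, 2.0e6, 1.5e6, 2.5e6),
                    pve_pct = c(10, 50, 11, 50), stringsAsFactors = FALSE)
  out <- select_breeder_mqtl(anc)
  expect_equal(out$breeder_flag, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("published validated MQTL yield exactly the five breeder's MQTL", {
  v <- ref_validated_mqtl()
  v$validated <- TRUE
  out <- select_breeder_mqtl(v)
  expect_setequal(out$mqtl_id[out$breeder_flag],
                  c("CaMQAST1.1", "CaMQAST4.1", "CaMQAST4.4",
                    "CaMQAST7.8", "CaMQAST8.2"))
})

test_that("candidate-gene windows follow the 2 Mb / 1 Mb flank rule", {
  anc <- data.frame(
    mqtl_id = c("narrow", "wide", "weak"), lg = "CaLG01",
    chrom = "Ca1", validated = TRUE,
    position_cm = c(10, 50, 20),
    pve_pct = c(66, 35, 29),
    flank_left = c("a", "w1", "a"), flank_right = c("b", "w2", "b"),
    start_bp = c(1e6, 1e7, 1e6), stop_bp = c(2.4e6, 3e7, 2.4e6),
    interval_bp = c(1.4e6, 2e7, 1.4e6), stringsAsFactors = FALSE)
  cons <- genetic_map(c("a", "b", "w1", "w2"), rep("CaLG01", 4),
                      c(8, 12, 40, 60), "cons")
  out <- cg_window(anc, cons)
  # narrow interval: the whole marker interval
  expect_equal(c(out$window_lo_bp[1], out$window_hi_bp[1]), c(1e6, 2.4e6))
  # wide interval: 2 Mb centred on the interpolated peak
  peak_bp <- 1e7 + (50 - 40) / (60 - 40) * (3e7 - 1e7)
  expect_equal(c(out$window_lo_bp[2], out$window_hi_bp[2]),
               c(peak_bp - 1e6, peak_bp + 1e6))
  # PVE at or below the gate: no window
  expect_true(is.na(out$window_lo_bp[3]))
  # window width never exceeds max(marker interval, 2 Mb)
  w <- out$window_hi_bp - out$window_lo_bp
  expect_true(all(w <= pmax(anc$interval_bp, 2e6) + 1e-9, na.rm = TRUE))
})

test_that("gene mining keeps annotated genes in the window and flags keywords", {
  ann <- read_gene_annotation(toy_gff())
  expect_equal(length(ann), 5)
  out <- genes_in_window(c(500, 6500), "Ca1", ann)
  # 3 genes overlap, one of them uncharacterized and dropped
  expect_setequal(out$gene_id, c("g1", "g3"))
  expect_equal(out$stress_related[out$gene_id == "g1"], TRUE)
  expect_equal(out$stress_related[out$gene_id == "g3"], FALSE)
  expect_warning(res <- genes_in_window(c(1, 10), "Ca9", ann),
                 "no annotation")
  expect_equal(nrow(res), 0)
})

test_that("MTA files read with BED start conversion", {
  p <- tempfile(fileext = ".bed")
  writeLines(c("Ca1\t99\t150\tmta1\tyield", "Ca2\t0\t1\tmta2"), p)
  mta <- read_mta_table(p)
  expect_equal(mta$start_bp, c(100, 1))
  expect_equal(mta$end_bp, c(150, 1))
  expect_equal(mta$trait[1], "yield")
})
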