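#' Reference tables for the chickpea abiotic-stress MQTL catalog
#'
#' Small published reference tables shipped with the package, transcribed
#' from the chickpea abiotic-stress meta-QTL literature (the `CaMQAST` MQTL
#' catalog on the `CaConsensusMap_2022` consensus map). They serve as fixed
#' inputs for report arithmetic and for regression tests of the anchoring
#' and breeder-rule logic; they are not outputs of this package.
#'
#' * `ref_mqtl_table()`: the 59 reported MQTL with consensus position, 95%
#'   CI bounds, PVE and flanking markers.
#' * `ref_validated_mqtl()`: the 23 MQTL validated by marker-trait
#'   associations, with the physical (bp) positions of their flanking
#'   markers (start/stop as published, i.e. possibly inverted).
#' * `ref_consensus_summary()`: per-linkage-group marker counts and genetic
#'   lengths of the consensus map, as input for [map_summary()].
#'
#' @return a data.frame (see above for columns).
#' @name reference_tables
NULL

.extdata <- function(name) {
  system.file("extdata", name, package = "mqtlmeta", mustWork = TRUE)
}

#' @rdname reference_tables
#' @export
ref_mqtl_table <- function() {
  df <- utils::read.csv(.extdata("camqast_mqtl.csv"),
                        stringsAsFactors = FALSE)
  df$ci_width_cm <- df$ci_hi_cm - df$ci_lo_cm
  df
}

#' @rdname reference_tables
#' @export
ref_validated_mqtl <- function() {
  df <- utils::read.csv(.extdata("camqast_validated.csv"),
                        stringsAsFactors = FALSE)
  df$interval_bp <- physical_interval(df$start_bp, df$stop_bp)
  df
}

#' @rdname reference_tables
#' @export
ref_consensus_summary <- function() {
  utils::read.csv(.extdata("caconsensus_summary.csv"),
                  stringsAsFactors = FALSE)
}
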