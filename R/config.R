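#' Triage configuration
#'
#' Bundles every tunable threshold of the triage pipeline. Defaults are
#' community-standard values for trio-based rare-disease analysis; all are
#' overridable.
#'
#' @param min_dp Minimum read depth required in every trio member (reads).
#' @param het_vaf_range Admissible child ALT allele fraction for a
#'   heterozygous call.
#' @param hom_vaf_min Minimum child ALT allele fraction for homozygous or
#'   hemizygous calls.
#' @param denovo_parent_vaf_max De novo candidates additionally require both
#'   parents' ALT allele fraction below this.
#' @param denovo_parent_min_dp ...and at least this parental depth.
#' @param splice_window Interpretation scope extends this many bp beyond
#'   exon boundaries into the intron (splice-region window).
#' @param include_noncoding Include non-coding exons and UTRs in scope.
#' @param af_dominant Population allele-frequency gate for de novo /
#'   dominant candidates.
#' @param af_recessive Frequency gate for homozygous, hemizygous and
#'   compound-heterozygous candidates.
#' @param max_pop_hom Maximum population homozygote count for recessive
#'   candidates (applied only when the count is supplied).
#' @param include_inherited_dominant Report inherited heterozygous P/LP
#'   variants in autosomal-dominant genes as candidates.
#' @param reciprocal_overlap Reciprocal-overlap fraction above which a
#'   parental CNV call of the same type counts as the same event.
#' @param caller_merge_overlap Reciprocal overlap at which duplicate CNV
#'   calls from different callers are collapsed (higher quality kept).
#' @param cnv_large_min Strict minimum length (bp) for the
#'   "large exon-containing CNV" triage category (`length > cnv_large_min`).
#' @param panel_any_overlap If `TRUE` (default) any overlap with a panel
#'   gene, including intronic-only, fires the panel category; if `FALSE`
#'   exon overlap is required.
#' @param soc_cnv_floor Detectability floor (bp) of the emulated
#'   standard-of-care pathway view: CNVs shorter than this are dropped from
#'   that view.
#' @param premutation_reportable Treat repeat alleles in the
#'   intermediate/premutation range as reportable (diagnosis-supporting).
#' @param roh Run-of-homozygosity parameters, see [roh_params()].
#' @return A list of class `triage_config`.
#' @export
triage_config <- function(min_dp = 10,
                          het_vaf_range = c(0.25, 0.75),
                          hom_vaf_min = 0.90,
                          denovo_parent_vaf_max = 0.05,
                          denovo_parent_min_dp = 10,
                          splice_window = 8,
                          include_noncoding = TRUE,
                          af_dominant = 0.001,
                          af_recessive = 0.01,
                          max_pop_hom = 0,
                          include_inherited_dominant = FALSE,
                          reciprocal_overlap = 0.5,
                          caller_merge_overlap = 0.8,
                          cnv_large_min = 10000,
                          panel_any_overlap = TRUE,
                          soc_cnv_floor = 10000,
                          premutation_reportable = TRUE,
                          roh = roh_params()) {
  stopifnot(
    splice_window >= 0, length(het_vaf_range) == 2,
    het_vaf_range[1] <= het_vaf_range[2],
    reciprocal_overlap > 0, reciprocal_overlap <= 1
  )
  structure(
    list(
      min_dp = min_dp, het_vaf_range = het_vaf_range,
      hom_vaf_min = hom_vaf_min,
      denovo_parent_vaf_max = denovo_parent_vaf_max,
      denovo_parent_min_dp = denovo_parent_min_dp,
      splice_window = splice_window, include_noncoding = include_noncoding,
      af_dominant = af_dominant, af_recessive = af_recessive,
      max_pop_hom = max_pop_hom,
      include_inherited_dominant = include_inherited_dominant,
      reciprocal_overlap = reciprocal_overlap,
      caller_merge_overlap = caller_merge_overlap,
      cnv_large_min = cnv_large_min,
      panel_any_overlap = panel_any_overlap,
      soc_cnv_floor = soc_cnv_floor,
      premutation_reportable = premutation_reportable,
      roh = roh
    ),
    class = "triage_config"
  )
}

# rank order for pathogenicity labels: lower = more pathogenic
label_rank <- function(label) {
  r <- c(P = 1, LP = 2, VUS = 3, unclassified = 4, LB = 5, B = 6)
  unname(r[ifelse(label %in% names(r), label, "unclassified")])
}
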