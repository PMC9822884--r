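# Bundled worked-example data: the conclusive-diagnosis variant table of a
# published 150-trio NDD cohort in which every patient went through two
# diagnostic pathways in parallel (an exome-based standard-of-care pathway,
# "SOC", and a genome-sequencing pathway, "GS").

#' Conclusive diagnoses of a 150-trio NDD cohort
#'
#' Returns the bundled table of conclusive diagnostic variants (SNVs, indels,
#' CNVs and one repeat expansion) for a cohort of 150 patient-parent trios
#' analysed through two diagnostic pathways in parallel. Each row is one
#' reported variant; a patient may carry more than one (rows appear in the
#' published order, which downstream tie-breaking preserves).
#'
#' @details The `concordance` column records pathway visibility: `"both"` for
#' variants identified by both the exome-based standard-of-care (SOC) and the
#' genome-sequencing (GS) pathway, `"gs_only"` for variants identified by GS
#' alone (all of which are CNVs). CNV rows carry ISCN-like coordinate strings
#' parseable with [parse_iscn_cnv()]; the repeat expansion row is parseable
#' with [parse_str_notation()].
#'
#' @return A tibble with columns `patient`, `sex`, `concordance`, `gene`,
#'   `variant_class` (`snv`/`indel`/`cnv`/`str`), `notation`, `cdna`,
#'   `protein`, `size_label`, `inheritance`.
#' @examples
#' dx <- ndd150_conclusive()
#' dplyr::count(dx, variant_class)
#' @export
ndd150_conclusive <- function() {
  path <- system.file("extdata", "ndd150_conclusive_diagnoses.tsv",
    package = "triotriage", mustWork = TRUE
  )
  readr::read_tsv(path,
    col_types = readr::cols(
      patient = readr::col_integer(),
      .default = readr::col_character()
    ),
    na = "NA", progress = FALSE
  )
}

#' Pathway-specific diagnostic outcomes from the bundled diagnosis table
#'
#' Projects the bundled conclusive-diagnosis table onto one diagnostic
#' pathway: variants flagged `gs_only` are dropped from the SOC view, then
#' every patient retaining at least one variant is a conclusive diagnosis in
#' that pathway.
#'
#' @param pathway `"gs"` or `"soc"`.
#' @return A tibble of outcomes (one row per diagnosed patient) with a
#'   `support` list-column of that patient's supporting variants, suitable for
#'   [tally_diagnoses()].
#' @examples
#' nrow(ndd150_outcomes("soc")) # 43 conclusively diagnosed patients
#' nrow(ndd150_outcomes("gs"))  # 45
#' @export
ndd150_outcomes <- function(pathway = c("gs", "soc")) {
  pathway <- match.arg(pathway)
  dx <- ndd150_conclusive()
  if (pathway == "soc") dx <- dplyr::filter(dx, .data$concordance == "both")
  dx %>%
    mutate(
      type = .data$variant_class,
      tier = 1L, label = "P", pop_af = 0, input_order = row_number()
    ) %>%
    tidyr::nest(support = !"patient") %>%
    mutate(pathway = pathway, outcome = "conclusive", .after = "patient") %>%
    rename(patient_id = "patient")
}
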