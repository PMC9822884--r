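# Short-tandem-repeat triage: the six NDD repeat loci, locus-specific
# expansion thresholds, and classification of repeat genotypes against them.

#' Default repeat-locus catalog for the six NDD loci
#'
#' Literature-standard expansion thresholds for the six repeat loci with
#' NDD-associated phenotypes: \emph{AFF2} (Fragile XE), \emph{ARX}
#' (infantile epileptic encephalopathy), \emph{CSTB} (progressive myoclonic
#' epilepsy 1A), \emph{EIF4A3} (Richieri-Costa-Pereira), \emph{DMPK}
#' (myotonic dystrophy) and \emph{FMR1} (Fragile X). `premutation` is the
#' repeat-unit count from which an allele is flagged for confirmation;
#' `pathogenic` is the full-mutation threshold. Loci without a recognised
#' premutation range have `premutation = NA`. Regions are 1-based inclusive
#' GRCh37 reference repeat tracts. All values are overridable by supplying
#' your own catalog ([read_str_catalog()]).
#'
#' @return Catalog tibble: `gene`, `chrom`, `start`, `end`, `motif`,
#'   `premutation`, `pathogenic`.
#' @export
default_str_catalog <- function() {
  tibble(
    gene = c("AFF2", "ARX", "CSTB", "EIF4A3", "DMPK", "FMR1"),
    chrom = c("X", "X", "21", "17", "19", "X"),
    start = c(147582151, 25031767, 45196324, 78090904, 46273463, 146993568),
    end = c(147582211, 25031814, 45196360, 78091034, 46273522, 146993628),
    motif = c(
      "CCG", "GCG", "CCCCGCCCCGCG", "CCTCGCTGTGCCGCTGCCGA", "CTG", "CGG"
    ),
    premutation = c(NA, NA, NA, NA, NA, 55),
    pathogenic = c(200, 20, 30, 14, 50, 200)
  )
}

#' Classify repeat genotypes against locus thresholds
#'
#' Joins repeat genotypes to a locus catalog and classifies each call from
#' its larger allele: `expanded` when it reaches the full-mutation
#' (`pathogenic`) threshold, `intermediate_or_premutation` when it reaches
#' the `premutation` threshold but not the full threshold, `normal`
#' otherwise, and `unevaluated` for loci absent from the catalog or lacking
#' thresholds. Any allele at or above the premutation threshold (or the
#' pathogenic threshold where no premutation range exists) raises
#' `needs_confirmation`, mirroring the practice of manually curating and
#' PCR-confirming putative expansions.
#'
#' Classification is restricted to catalog loci; genotypes at other loci
#' pass through unevaluated.
#'
#' @param genotypes Repeat genotype tibble ([read_str_calls()] schema:
#'   `trio_id`, `gene`, `motif`, `allele1`, `allele2`, flags). `allele2` may
#'   be `NA` for single-allele male X calls.
#' @param catalog Locus catalog tibble; defaults to [default_str_catalog()].
#' @return The input plus `max_allele`, `status`, `needs_confirmation`, and
#'   the catalog's `premutation`/`pathogenic` thresholds.
#' @export
classify_str <- function(genotypes, catalog = default_str_catalog()) {
  g <- as_tibble(genotypes) %>%
    left_join(
      select(catalog, "gene", "premutation", "pathogenic"),
      by = "gene"
    ) %>%
    mutate(
      max_allele = pmax(.data$allele1, .data$allele2, na.rm = TRUE),
      max_allele = if_else(is.finite(.data$max_allele), .data$max_allele, NA_real_),
      flag_threshold = dplyr::coalesce(.data$premutation, .data$pathogenic),
      status = case_when(
        is.na(.data$pathogenic) | is.na(.data$max_allele) ~ "unevaluated",
        .data$max_allele >= .data$pathogenic ~ "expanded",
        !is.na(.data$premutation) & .data$max_allele >= .data$premutation ~
          "intermediate_or_premutation",
        TRUE ~ "normal"
      ),
      needs_confirmation = !is.na(.data$flag_threshold) &
        !is.na(.data$max_allele) & .data$max_allele >= .data$flag_threshold
    ) %>%
    select(-"flag_threshold")
  g
}
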