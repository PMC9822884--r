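# Shared in-code fixtures for the test suite.

# a minimal two-gene model set: one autosomal panel gene, one AR disease
# gene, one X-linked gene, one 'other' gene with a non-coding exon
toy_gene_models <- function() {
  triotriage:::validate_gene_models(dplyr::bind_rows(
    tibble::tibble(
      gene = "GENEA", chrom = "1",
      start = c(1000, 5000, 9000), end = c(1200, 5200, 9200),
      coding = TRUE, gene_class = "ndd_panel", moi = "AD"
    ),
    tibble::tibble(
      gene = "GENEB", chrom = "2",
      start = c(1000, 20000, 40000), end = c(1300, 20300, 40300),
      coding = c(TRUE, TRUE, FALSE), gene_class = "disease_gene", moi = "AR"
    ),
    tibble::tibble(
      gene = "GENEX", chrom = "X",
      start = c(5e6, 5.01e6), end = c(5e6 + 300, 5.01e6 + 300),
      coding = TRUE, gene_class = "disease_gene", moi = "XL"
    ),
    tibble::tibble(
      gene = "GENEO", chrom = "3",
      start = c(1000, 30000), end = c(1500, 30500),
      coding = c(TRUE, FALSE), gene_class = "other", moi = "unknown"
    )
  ))
}

toy_pedigree <- function(sex = "male") {
  tibble::tibble(
    family_id = "F1", child_id = "C1", father_id = "D1", mother_id = "M1",
    child_sex = sex, child_affected = TRUE,
    father_affected = FALSE, mother_affected = FALSE
  )
}

# one trio-genotype row with sane defaults, overridable field by field
toy_variant <- function(...) {
  defaults <- tibble::tibble(
    trio_id = "C1", chrom = "1", pos = 1100, ref = "A", alt = "G",
    gt_child = "het", gt_father = "hom_ref", gt_mother = "hom_ref",
    dp_child = 40, dp_father = 40, dp_mother = 40,
    vaf_child = 0.48, vaf_father = 0, vaf_mother = 0,
    qual = 90, gene = "GENEA", consequence = "missense",
    pop_af = 0, ih_af = 0, n_hom = 0,
    class_label = "P", missing_parent = FALSE
  )
  over <- list(...)
  for (nm in names(over)) defaults[[nm]] <- over[[nm]]
  defaults
}

toy_cnv <- function(...) {
  defaults <- tibble::tibble(
    trio_id = "C1", chrom = "1", start = 4000, end = 20000, svtype = "DEL",
    copy_number = 1, carrier_child = "present", carrier_father = "absent",
    carrier_mother = "absent", qual = 60, caller = "depth_based",
    class_label = "P"
  )
  over <- list(...)
  for (nm in names(over)) defaults[[nm]] <- over[[nm]]
  defaults
}

# genotype category from allele count, for oracle tables
gt_from_count <- function(k) c("hom_ref", "het", "hom_alt")[k + 1]
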