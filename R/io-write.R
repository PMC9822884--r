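# Writers for the cohort bundle: per-trio small-variant and SV VCFs (4.2),
# PED, gene-model/catalog/truth TSVs — the exact formats the readers parse,
# so a written cohort round-trips.

fmt_num <- function(x) {
  ifelse(is.na(x), ".", sprintf("%.10g", x))
}

gt_string <- function(cat) {
  # reconstruct a VCF GT string from a genotype category
  switch(cat,
    hom_ref = "0/0", het = "0/1", hom_alt = "1/1", hemi = "1",
    missing = "./.", "./."
  )
}

sample_field <- function(cat, dp, vaf) {
  if (cat == "missing" || is.na(dp)) {
    return(sprintf("%s:.:.", gt_string(cat)))
  }
  alt <- if (is.na(vaf)) 0L else as.integer(round(vaf * dp))
  sprintf("%s:%d:%d,%d", gt_string(cat), as.integer(dp),
    as.integer(dp) - alt, alt)
}

#' Write a trio's small variants as a VCF 4.2 file
#'
#' Emits one 3-sample VCF (child, father, mother) with `GT:DP:AD` sample
#' fields and the annotation INFO keys the reader parses (`GENE`, `CSQ`,
#' `AF`, `AFIH`, `NHOM`, `CLASS`). Allele-depth fields are integers derived
#' from depth and allele fraction, so fractions recompute exactly on read.
#'
#' @param variants Trio genotype rows of one trio (simulator schema).
#' @param trio One pedigree row.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(variants, trio, path) {
  v <- arrange(as_tibble(variants), .data$chrom, .data$pos, .data$alt)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Population allele frequency\">",
    "##INFO=<ID=AFIH,Number=A,Type=Float,Description=\"In-house allele frequency\">",
    "##INFO=<ID=NHOM,Number=A,Type=Float,Description=\"Population homozygote count\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Pathogenicity label\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste0(
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
      trio$child_id, "\t", trio$father_id, "\t", trio$mother_id
    )
  )
  lines <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    info <- sprintf(
      "GENE=%s;CSQ=%s;AF=%s;AFIH=%s;NHOM=%s;CLASS=%s",
      ifelse(is.na(v$gene[i]), ".", v$gene[i]),
      ifelse(is.na(v$consequence[i]), ".", v$consequence[i]),
      fmt_num(v$pop_af[i]), fmt_num(v$ih_af[i]), fmt_num(v$n_hom[i]),
      v$class_label[i]
    )
    lines[i] <- paste(
      v$chrom[i], as.integer(v$pos[i]), ".", v$ref[i], v$alt[i],
      fmt_num(v$qual[i]), "PASS", info, "GT:DP:AD",
      sample_field(v$gt_child[i], v$dp_child[i], v$vaf_child[i]),
      sample_field(v$gt_father[i], v$dp_father[i], v$vaf_father[i]),
      sample_field(v$gt_mother[i], v$dp_mother[i], v$vaf_mother[i]),
      sep = "\t"
    )
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write a trio's CNV calls as an SV VCF
#'
#' VCF 4.2 with symbolic `<DEL>`/`<DUP>` ALT alleles and INFO keys
#' `SVTYPE`, `END`, `SVLEN`, `CN`, `CALLER`, `CLASS`; per-sample GT encodes
#' carrier status (`0/1` present, `0/0` absent, `./.` unknown).
#'
#' @param cnvs CNV call rows of one trio.
#' @inheritParams write_trio_vcf
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(cnvs, trio, path) {
  cv <- arrange(as_tibble(cnvs), .data$chrom, .data$start, .data$end)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position (1-based inclusive)\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=CN,Number=1,Type=Float,Description=\"Copy number\">",
    "##INFO=<ID=CALLER,Number=1,Type=String,Description=\"Calling approach\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Pathogenicity label\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0(
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
      trio$child_id, "\t", trio$father_id, "\t", trio$mother_id
    )
  )
  carrier_gt <- function(st) {
    c(present = "0/1", absent = "0/0", unknown = "./.")[st]
  }
  lines <- character(nrow(cv))
  for (i in seq_len(nrow(cv))) {
    len <- cv$end[i] - cv$start[i] + 1
    info <- sprintf(
      "SVTYPE=%s;END=%d;SVLEN=%s;CN=%s;CALLER=%s;CLASS=%s",
      cv$svtype[i], as.integer(cv$end[i]),
      if (cv$svtype[i] == "DEL") -as.integer(len) else as.integer(len),
      fmt_num(cv$copy_number[i]), cv$caller[i], cv$class_label[i]
    )
    lines[i] <- paste(
      cv$chrom[i], as.integer(cv$start[i]), ".", "N",
      sprintf("<%s>", cv$svtype[i]), fmt_num(cv$qual[i]), "PASS", info, "GT",
      carrier_gt(cv$carrier_child[i]), carrier_gt(cv$carrier_father[i]),
      carrier_gt(cv$carrier_mother[i]),
      sep = "\t"
    )
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write a cohort bundle to a directory
#'
#' Materialises a [simulate_cohort()] bundle in the external formats the
#' package reads: `pedigree.ped` (6-column PED), `gene_models.tsv`,
#' `str_calls.tsv`, `str_catalog.tsv`, `phenotype_match.tsv`, `truth.tsv`,
#' `config.yaml` (key-value), and per-trio `trios/<id>.vcf` /
#' `trios/<id>.sv.vcf`.
#'
#' @param bundle A `trio_cohort` bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(file.path(dir, "trios"), recursive = TRUE, showWarnings = FALSE)
  ped <- bundle$pedigree
  ped_rows <- bind_rows(
    tibble(
      family_id = ped$family_id, id = ped$child_id,
      father_id = ped$father_id, mother_id = ped$mother_id,
      sex = if_else(ped$child_sex == "male", 1L, 2L),
      phenotype = if_else(ped$child_affected, 2L, 1L)
    ),
    tibble(
      family_id = ped$family_id, id = ped$father_id,
      father_id = "0", mother_id = "0", sex = 1L,
      phenotype = if_else(ped$father_affected, 2L, 1L)
    ),
    tibble(
      family_id = ped$family_id, id = ped$mother_id,
      father_id = "0", mother_id = "0", sex = 2L,
      phenotype = if_else(ped$mother_affected, 2L, 1L)
    )
  )
  readr::write_tsv(ped_rows, file.path(dir, "pedigree.ped"), col_names = FALSE)
  readr::write_tsv(bundle$gene_models, file.path(dir, "gene_models.tsv"))
  readr::write_tsv(
    rename(bundle$strs, sample = "trio_id") %>% select(-dplyr::any_of("flagged")),
    file.path(dir, "str_calls.tsv")
  )
  readr::write_tsv(default_str_catalog(), file.path(dir, "str_catalog.tsv"))
  readr::write_tsv(bundle$phenotype_match, file.path(dir, "phenotype_match.tsv"))
  readr::write_tsv(bundle$truth, file.path(dir, "truth.tsv"))
  cfg <- bundle$config
  writeLines(
    c(
      sprintf("n_trios: %d", cfg$n_trios),
      sprintf("n_background: %d", cfg$n_background),
      sprintf("male_fraction: %.10g", cfg$male_fraction),
      sprintf("genotype_error_rate: %.10g", cfg$genotype_error_rate),
      sprintf("parental_dropout_rate: %.10g", cfg$parental_dropout_rate),
      sprintf("depth_mean: %.10g", cfg$depth_mean),
      sprintf("seed: %d", cfg$seed)
    ),
    file.path(dir, "config.yaml")
  )
  for (t in seq_len(nrow(ped))) {
    trio <- ped[t, ]
    write_trio_vcf(
      filter(bundle$variants, .data$trio_id == trio$child_id),
      trio, file.path(dir, "trios", paste0(trio$child_id, ".vcf"))
    )
    write_sv_vcf(
      filter(bundle$cnvs, .data$trio_id == trio$child_id),
      trio, file.path(dir, "trios", paste0(trio$child_id, ".sv.vcf"))
    )
  }
  invisible(dir)
}

#' Read a written cohort back into tibbles
#'
#' Re-reads a [write_cohort()] directory through the package's format
#' readers. The small-variant stream contains one record per child-carried
#' ALT allele (sites where the child is homozygous reference are part of
#' the VCFs but not of the triage stream).
#'
#' @param dir Cohort directory.
#' @return A list of class `trio_cohort` (without `config`).
#' @export
read_cohort <- function(dir) {
  ped <- read_pedigree(file.path(dir, "pedigree.ped"))
  gm <- read_gene_models(file.path(dir, "gene_models.tsv"))
  variants <- purrr::map(seq_len(nrow(ped)), function(t) {
    read_trio_vcf(file.path(dir, "trios", paste0(ped$child_id[t], ".vcf")), ped[t, ])
  }) %>% bind_rows()
  cnvs <- purrr::map(seq_len(nrow(ped)), function(t) {
    read_sv_calls(file.path(dir, "trios", paste0(ped$child_id[t], ".sv.vcf")), ped[t, ])
  }) %>% bind_rows()
  strs <- read_str_calls(file.path(dir, "str_calls.tsv"))
  pm <- read_phenotype_match(file.path(dir, "phenotype_match.tsv"))
  truth <- readr::read_tsv(file.path(dir, "truth.tsv"), col_types = readr::cols(
    start = "d", end = "d", .default = "c"
  ), progress = FALSE)
  structure(
    list(
      pedigree = ped, gene_models = gm, variants = variants, cnvs = cnvs,
      strs = strs, phenotype_match = pm, truth = truth
    ),
    class = "trio_cohort"
  )
}
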