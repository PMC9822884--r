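# Readers for the external formats the pipeline consumes: 6-column PED,
# BED/TSV gene models, small-variant trio VCFs, SV/CNV VCFs, repeat-genotype
# tables and the catalog TSVs. All coordinates are normalised to 1-based
# inclusive on read (BED input is 0-based half-open and converted).

#' Read a 6-column PED pedigree file and extract trios
#'
#' @param path Path to a whitespace-delimited PED file with columns
#'   family id, individual id, father id, mother id, sex (1 = male,
#'   2 = female), affected status (2 = affected).
#' @return A tibble with one row per child that has both parents in the file:
#'   `family_id`, `child_id`, `father_id`, `mother_id`, `child_sex`
#'   (`"male"`/`"female"`), `child_affected`, `father_affected`,
#'   `mother_affected`.
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_table(path,
    col_names = c("family_id", "id", "father_id", "mother_id", "sex", "phenotype"),
    col_types = "ccccii", progress = FALSE
  )
  as_trio_pedigree(ped)
}

#' @rdname read_pedigree
#' @param ped A data frame already in 6-column PED layout (columns
#'   `family_id`, `id`, `father_id`, `mother_id`, `sex`, `phenotype`).
#' @export
as_trio_pedigree <- function(ped) {
  ped <- as_tibble(ped)
  aff <- setNames(ped$phenotype == 2, ped$id)
  trios <- ped %>%
    filter(.data$father_id != "0", .data$mother_id != "0") %>%
    mutate(
      child_sex = dplyr::recode(.data$sex, `1` = "male", `2` = "female"),
      child_affected = .data$phenotype == 2,
      father_affected = unname(aff[.data$father_id]),
      mother_affected = unname(aff[.data$mother_id])
    ) %>%
    select("family_id",
      child_id = "id", "father_id", "mother_id",
      "child_sex", "child_affected", "father_affected", "mother_affected"
    )
  bad <- trios$child_id == trios$father_id | trios$child_id == trios$mother_id |
    trios$father_id == trios$mother_id
  if (any(bad)) {
    abort(sprintf(
      "pedigree with non-distinct trio members: %s",
      paste(trios$child_id[bad], collapse = ", ")
    ))
  }
  trios
}

#' Read a gene/exon model table
#'
#' Accepts either a TSV with 1-based inclusive exon coordinates and columns
#' `gene`, `chrom`, `start`, `end`, `coding`, `gene_class`, `moi`, or a
#' BED-like file (`chrom`, 0-based half-open `start`/`end`, `gene`) which is
#' converted to 1-based inclusive on read; BED input takes `gene_class` and
#' `moi` from optional extra columns, defaulting to `other`/`unknown`.
#'
#' `gene_class` is one of `ndd_panel`, `disease_gene`, `candidate_gene`,
#' `other`; `moi` (mode of inheritance annotation) one of `AD`, `AR`, `XL`,
#' `unknown`. Overlapping exons of one gene are merged; output is sorted.
#'
#' @param path File path.
#' @param format `"tsv"` or `"bed"`.
#' @return Tibble with one row per (merged) exon: `gene`, `chrom`, `start`,
#'   `end`, `coding`, `gene_class`, `moi`.
#' @export
read_gene_models <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    gm <- readr::read_tsv(path, col_types = readr::cols(
      gene = "c", chrom = "c", start = "d", end = "d", coding = "l",
      gene_class = "c", moi = "c"
    ), progress = FALSE)
  } else {
    gm <- readr::read_tsv(path,
      col_names = c("chrom", "start", "end", "gene", "gene_class", "moi")[
        seq_len(min(6, ncol(readr::read_tsv(path, n_max = 1, col_names = FALSE,
          col_types = readr::cols(.default = "c"), progress = FALSE
        ))))
      ],
      col_types = readr::cols(start = "d", end = "d", .default = "c"),
      progress = FALSE
    ) %>%
      mutate(start = .data$start + 1, coding = TRUE) # 0-based half-open -> 1-based inclusive
    if (!"gene_class" %in% names(gm)) gm$gene_class <- "other"
    if (!"moi" %in% names(gm)) gm$moi <- "unknown"
  }
  validate_gene_models(gm)
}

validate_gene_models <- function(gm) {
  gm <- as_tibble(gm)
  stopifnot(
    all(c("gene", "chrom", "start", "end", "coding", "gene_class", "moi") %in% names(gm)),
    all(gm$start >= 1), all(gm$end >= gm$start),
    all(gm$gene_class %in% c("ndd_panel", "disease_gene", "candidate_gene", "other")),
    all(gm$moi %in% c("AD", "AR", "XL", "unknown"))
  )
  # merge overlapping exons within a gene, keep coding if any merged part coding
  gm %>%
    arrange(.data$gene, .data$chrom, .data$start, .data$end) %>%
    group_by(.data$gene, .data$chrom, .data$gene_class, .data$moi) %>%
    mutate(grp = cumsum(.data$start > lag(cummax(.data$end), default = -Inf) + 0)) %>%
    group_by(.data$grp, .add = TRUE) %>%
    summarise(
      start = min(.data$start), end = max(.data$end),
      coding = any(.data$coding), .groups = "drop"
    ) %>%
    select("gene", "chrom", "start", "end", "coding", "gene_class", "moi") %>%
    arrange(.data$chrom, .data$start, .data$gene)
}

# ---- genotype string helpers -------------------------------------------------

# classify a VCF GT string with respect to ALT allele index k (1-based among ALTs)
gt_category <- function(gt, k) {
  gt <- ifelse(is.na(gt), "./.", gt)
  alleles <- stringr::str_split(gt, "[/|]")
  k <- rep_len(as.character(k), length(alleles))
  vapply(seq_along(alleles), function(i) {
    a <- alleles[[i]]
    if (any(a == ".")) return("missing")
    n_alt <- sum(a == k[i])
    if (length(a) == 1) {
      # haploid call (male X/Y or MT)
      if (n_alt == 1) "hemi" else "hom_ref"
    } else if (n_alt == 0) {
      "hom_ref"
    } else if (n_alt == length(a)) {
      "hom_alt"
    } else {
      "het"
    }
  }, character(1))
}

carries_alt <- function(cat) cat %in% c("het", "hom_alt", "hemi")

parse_ad_vaf <- function(ad, k) {
  # ad: comma-separated ref,alt1,alt2... counts; returns alt_k fraction
  purrr::map2_dbl(ad, k, function(s, kk) {
    if (is.na(s) || s == ".") return(NA_real_)
    v <- suppressWarnings(as.numeric(stringr::str_split(s, ",")[[1]]))
    tot <- sum(v, na.rm = TRUE)
    if (!is.finite(tot) || tot == 0 || length(v) < kk + 1) return(NA_real_)
    v[kk + 1] / tot
  })
}

#' Read a patient-parent trio small-variant VCF
#'
#' Reads a 3-sample VCF 4.2 file and returns one record per child-carried ALT
#' allele, with multi-allelic sites decomposed (one row per ALT). Sites where
#' the child carries no ALT allele are dropped; missing parental genotypes
#' are retained and flagged (`missing_parent`), never silently removed.
#'
#' Annotations the pipeline consumes, when present as INFO keys, are parsed:
#' `GENE`, `CSQ` (consequence), `AF` (population allele frequency), `AFIH`
#' (in-house frequency), `NHOM` (population homozygote count), `CLASS`
#' (pathogenicity label `P`/`LP`/`VUS`/`LB`/`B`/`unclassified`). Per-ALT
#' comma-separated INFO values are decomposed with the site.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param pedigree One row of a pedigree tibble ([read_pedigree()]) naming
#'   `child_id`, `father_id`, `mother_id`; all three must be VCF samples.
#' @return Tibble of trio genotypes: identifiers, site coordinates/alleles,
#'   per-member genotype category (`hom_ref`/`het`/`hom_alt`/`hemi`/
#'   `missing`), per-member depth and ALT allele fraction, site quality and
#'   annotations.
#' @export
read_trio_vcf <- function(path, pedigree) {
  stopifnot(nrow(pedigree) == 1)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  need <- c(pedigree$child_id, pedigree$father_id, pedigree$mother_id)
  if (!all(need %in% samples)) {
    abort(sprintf(
      "pedigree sample(s) absent from VCF header: %s",
      paste(setdiff(need, samples), collapse = ", ")
    ), class = "triotriage_config_error")
  }
  if (nrow(v@fix) == 0) {
    return(empty_trio_genotypes(pedigree))
  }
  fix <- as_tibble(as.data.frame(v@fix, stringsAsFactors = FALSE))
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
  info_key <- function(key) as.character(vcfR::extract.info(v, element = key))

  site <- tibble(
    chrom = sub("^chr", "", fix$CHROM),
    pos = as.numeric(fix$POS),
    ref = fix$REF,
    alt_all = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    gene = dplyr::na_if(info_key("GENE"), "."),
    consequence = dplyr::na_if(info_key("CSQ"), "."),
    pop_af_all = info_key("AF"),
    ih_af_all = info_key("AFIH"),
    nhom_all = info_key("NHOM"),
    class_label = info_key("CLASS"),
    gt_c_raw = unname(gt[, pedigree$child_id]),
    gt_f_raw = unname(gt[, pedigree$father_id]),
    gt_m_raw = unname(gt[, pedigree$mother_id]),
    dp_child = unname(dp[, pedigree$child_id]),
    dp_father = unname(dp[, pedigree$father_id]),
    dp_mother = unname(dp[, pedigree$mother_id]),
    ad_c = if (is.null(ad)) NA_character_ else unname(ad[, pedigree$child_id]),
    ad_f = if (is.null(ad)) NA_character_ else unname(ad[, pedigree$father_id]),
    ad_m = if (is.null(ad)) NA_character_ else unname(ad[, pedigree$mother_id])
  )

  # decompose multi-allelic sites: one row per ALT allele
  site$alt_split <- stringr::str_split(site$alt_all, ",")
  long <- tidyr::unnest_longer(
    mutate(site, k = purrr::map(.data$alt_split, seq_along)),
    c("alt_split", "k")
  ) %>% rename(alt = "alt_split")
  per_alt <- function(all_vals, k) {
    v <- stringr::str_split(ifelse(is.na(all_vals), "", all_vals), ",")
    out <- purrr::map2_dbl(v, k, function(x, i) {
      if (length(x) >= i && nzchar(x[i])) suppressWarnings(as.numeric(x[i])) else
        if (length(x) == 1 && nzchar(x[1])) suppressWarnings(as.numeric(x[1])) else NA_real_
    })
    out
  }
  out <- long %>%
    mutate(
      gt_child = gt_category(.data$gt_c_raw, .data$k),
      gt_father = gt_category(.data$gt_f_raw, .data$k),
      gt_mother = gt_category(.data$gt_m_raw, .data$k),
      vaf_child = parse_ad_vaf(.data$ad_c, .data$k),
      vaf_father = parse_ad_vaf(.data$ad_f, .data$k),
      vaf_mother = parse_ad_vaf(.data$ad_m, .data$k),
      pop_af = per_alt(.data$pop_af_all, .data$k),
      ih_af = per_alt(.data$ih_af_all, .data$k),
      n_hom = per_alt(.data$nhom_all, .data$k),
      class_label = if_else(is.na(.data$class_label), "unclassified", .data$class_label),
      missing_parent = .data$gt_father == "missing" | .data$gt_mother == "missing",
      trio_id = pedigree$child_id
    ) %>%
    filter(carries_alt(.data$gt_child)) %>%
    select(
      "trio_id", "chrom", "pos", "ref", "alt",
      "gt_child", "gt_father", "gt_mother",
      "dp_child", "dp_father", "dp_mother",
      "vaf_child", "vaf_father", "vaf_mother",
      "qual", "gene", "consequence", "pop_af", "ih_af", "n_hom",
      "class_label", "missing_parent"
    ) %>%
    arrange(.data$chrom, .data$pos, .data$alt)
  out
}

empty_trio_genotypes <- function(pedigree) {
  tibble(
    trio_id = character(), chrom = character(), pos = numeric(),
    ref = character(), alt = character(),
    gt_child = character(), gt_father = character(), gt_mother = character(),
    dp_child = numeric(), dp_father = numeric(), dp_mother = numeric(),
    vaf_child = numeric(), vaf_father = numeric(), vaf_mother = numeric(),
    qual = numeric(), gene = character(), consequence = character(),
    pop_af = numeric(), ih_af = numeric(), n_hom = numeric(),
    class_label = character(), missing_parent = logical()
  )
}

#' Read SV/CNV calls for a trio
#'
#' Reads VCF-style structural-variant records and returns 1-based inclusive
#' deletion/duplication calls with per-member carrier status. Records whose
#' `SVTYPE` is not `DEL`/`DUP` (e.g. `BND`, `INV`), and records with no
#' resolvable end coordinate, are skipped; the counts are reported in a
#' warning and as attributes `n_skipped_type` / `n_skipped_noend`.
#'
#' The end coordinate is taken from INFO `END`, else derived as
#' `pos + |SVLEN| - 1`. Copy number is INFO `CN` when present; an optional
#' INFO `CLASS` pathogenicity label and `CALLER` tag are carried through.
#'
#' @inheritParams read_trio_vcf
#' @return Tibble of CNV calls: `trio_id`, `chrom`, `start`, `end`, `svtype`,
#'   `copy_number`, carrier status per member (`present`/`absent`/`unknown`),
#'   `qual`, `caller`, `class_label`.
#' @export
read_sv_calls <- function(path, pedigree) {
  stopifnot(nrow(pedigree) == 1)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  need <- c(pedigree$child_id, pedigree$father_id, pedigree$mother_id)
  if (!all(need %in% samples)) {
    abort(sprintf(
      "pedigree sample(s) absent from SV VCF header: %s",
      paste(setdiff(need, samples), collapse = ", ")
    ), class = "triotriage_config_error")
  }
  if (nrow(v@fix) == 0) {
    out <- empty_cnv_calls()
    attr(out, "n_skipped_type") <- 0L
    attr(out, "n_skipped_noend") <- 0L
    return(out)
  }
  fix <- as_tibble(as.data.frame(v@fix, stringsAsFactors = FALSE))
  gt <- vcfR::extract.gt(v, element = "GT")
  carrier <- function(g) {
    case_when(
      is.na(g) | stringr::str_detect(g, "\\.") ~ "unknown",
      stringr::str_detect(g, "1") ~ "present",
      TRUE ~ "absent"
    )
  }
  svtype <- vcfR::extract.info(v, element = "SVTYPE")
  endv <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "END")))
  svlen <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "SVLEN")))
  cn <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "CN")))
  cls <- vcfR::extract.info(v, element = "CLASS")
  caller <- vcfR::extract.info(v, element = "CALLER")

  pos <- as.numeric(fix$POS)
  end_res <- if_else(!is.na(endv), endv, pos + abs(svlen) - 1)
  keep_type <- !is.na(svtype) & svtype %in% c("DEL", "DUP")
  n_skipped_type <- sum(!keep_type)
  keep_end <- !is.na(end_res)
  n_skipped_noend <- sum(keep_type & !keep_end)
  keep <- keep_type & keep_end
  if (n_skipped_type + n_skipped_noend > 0) {
    warn(sprintf(
      "skipped %d non-DEL/DUP and %d end-less SV record(s) in %s",
      n_skipped_type, n_skipped_noend, path
    ))
  }
  out <- tibble(
    trio_id = pedigree$child_id,
    chrom = sub("^chr", "", fix$CHROM)[keep],
    start = pos[keep],
    end = end_res[keep],
    svtype = svtype[keep],
    copy_number = cn[keep],
    carrier_child = carrier(unname(gt[keep, pedigree$child_id])),
    carrier_father = carrier(unname(gt[keep, pedigree$father_id])),
    carrier_mother = carrier(unname(gt[keep, pedigree$mother_id])),
    qual = suppressWarnings(as.numeric(fix$QUAL))[keep],
    caller = if_else(is.na(caller[keep]), "unknown", caller[keep]),
    class_label = if_else(is.na(cls[keep]), "unclassified", cls[keep])
  ) %>% arrange(.data$chrom, .data$start, .data$end)
  attr(out, "n_skipped_type") <- n_skipped_type
  attr(out, "n_skipped_noend") <- n_skipped_noend
  out
}

empty_cnv_calls <- function() {
  tibble(
    trio_id = character(), chrom = character(), start = numeric(),
    end = numeric(), svtype = character(), copy_number = numeric(),
    carrier_child = character(), carrier_father = character(),
    carrier_mother = character(), qual = numeric(), caller = character(),
    class_label = character()
  )
}

#' Read a repeat-genotype table
#'
#' Reads a TSV of repeat (STR) genotypes, one row per sample per locus, with
#' columns `sample`, `gene`, `motif`, `allele1`, `allele2` (blank/NA for
#' single-allele male X calls) and optional `coverage_flag` / `mq_flag`
#' (`ok`/`review`). Rows lacking a motif are retained and flagged.
#'
#' @param path TSV path.
#' @return Tibble of repeat genotypes with `flagged` marking incomplete rows.
#' @export
read_str_calls <- function(path) {
  g <- readr::read_tsv(path, col_types = readr::cols(
    sample = "c", gene = "c", motif = "c", allele1 = "d", allele2 = "d",
    .default = "c"
  ), progress = FALSE, na = c("", "NA"))
  if (!"coverage_flag" %in% names(g)) g$coverage_flag <- "ok"
  if (!"mq_flag" %in% names(g)) g$mq_flag <- "ok"
  g %>%
    rename(trio_id = "sample") %>%
    mutate(flagged = is.na(.data$motif) | is.na(.data$allele1))
}

#' Read a repeat-locus catalog
#'
#' @param path TSV with columns `gene`, `chrom`, `start`, `end`, `motif`,
#'   `premutation` (repeat units, NA when the locus has no premutation
#'   range), `pathogenic` (repeat units).
#' @return Tibble catalog for [classify_str()].
#' @seealso [default_str_catalog()]
#' @export
read_str_catalog <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene = "c", chrom = "c", start = "d", end = "d", motif = "c",
    premutation = "d", pathogenic = "d"
  ), progress = FALSE, na = c("", "NA"))
}

#' Read a mitochondrial pathogenic-variant catalog
#'
#' @param path TSV with columns `pos` (1-based position on the mitochondrial
#'   genome, 1..16569), `ref`, `alt`, `phenotype`.
#' @return Tibble catalog for [match_mito()].
#' @export
read_mito_catalog <- function(path) {
  cat <- readr::read_tsv(path, col_types = readr::cols(
    pos = "d", ref = "c", alt = "c", phenotype = "c"
  ), progress = FALSE)
  stopifnot(all(cat$pos >= 1 & cat$pos <= 16569))
  cat
}

#' Read a per-patient phenotype-match table
#'
#' Phenotype fit is expert judgment supplied as data: one row per
#' (patient, gene) pair judged compatible with the patient's phenotype.
#'
#' @param path TSV with columns `trio_id`, `gene`, and optional logical
#'   `phenotype_match` (default `TRUE` for listed pairs).
#' @return Tibble with `trio_id`, `gene`, `phenotype_match`.
#' @export
read_phenotype_match <- function(path) {
  pm <- readr::read_tsv(path, col_types = readr::cols(
    trio_id = "c", gene = "c", .default = "l"
  ), progress = FALSE)
  if (!"phenotype_match" %in% names(pm)) pm$phenotype_match <- TRUE
  pm
}

# ---- X-chromosome helpers ----------------------------------------------------

#' Pseudoautosomal regions of the X chromosome (GRCh37)
#'
#' Variants in PAR1/PAR2 are diploid in males and are treated as autosomal by
#' the segregation rules; X positions outside them are hemizygous in males.
#'
#' @return Tibble with `region`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
par_regions <- function() {
  tibble(
    region = c("PAR1", "PAR2"),
    chrom = "X",
    start = c(60001, 154931044),
    end = c(2699520, 155260560)
  )
}

#' Is a position on X outside the pseudoautosomal regions?
#'
#' @param chrom,pos Vectors of chromosome names and 1-based positions.
#' @return Logical vector.
#' @export
is_x_nonpar <- function(chrom, pos) {
  par <- par_regions()
  on_x <- sub("^chr", "", chrom) == "X"
  in_par <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(par))) {
    in_par <- in_par | (on_x & pos >= par$start[i] & pos <= par$end[i])
  }
  on_x & !in_par
}
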