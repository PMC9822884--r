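# Synthetic trio-cohort generator: Mendelian background variation plus
# planted causal variants of every type and inheritance mode, with a truth
# table, so the whole triage pipeline is testable without patient data.

#' Deterministic synthetic gene models
#'
#' A fixed panel of synthetic genes used by the cohort generator: NDD-panel
#' genes (`PANEL01`..), other established disease genes (`DIS01`..),
#' candidate disease genes (`CAND01`..) and genes of no established disease
#' relevance (`OTH01`..), spread over the autosomes and (for X-linked genes)
#' the non-pseudoautosomal X. Every gene has 10 exons of 200 bp separated by
#' 3 kb introns; exon 10 is non-coding (3'UTR), so deletions confined to it
#' exercise the non-coding-exon rules. The six NDD repeat-locus genes are
#' appended as single-exon disease genes at their catalog coordinates.
#'
#' @return A gene-model tibble ([read_gene_models()] schema).
#' @export
synthetic_gene_models <- function() {
  spec <- dplyr::bind_rows(
    tibble(
      gene = sprintf("PANEL%02d", 1:15), gene_class = "ndd_panel",
      moi = c(rep("AD", 10), rep("AR", 3), rep("XL", 2))
    ),
    tibble(
      gene = sprintf("DIS%02d", 1:10), gene_class = "disease_gene",
      moi = c(rep("AD", 6), rep("AR", 2), rep("XL", 2))
    ),
    tibble(
      gene = sprintf("CAND%02d", 1:8), gene_class = "candidate_gene",
      moi = "AD"
    ),
    tibble(
      gene = sprintf("OTH%02d", 1:7), gene_class = "other", moi = "unknown"
    )
  )
  autos <- as.character(1:22)
  n_x <- 0L
  n_a <- 0L
  chrom <- character(nrow(spec))
  g_start <- numeric(nrow(spec))
  for (i in seq_len(nrow(spec))) {
    if (spec$moi[i] == "XL") {
      n_x <- n_x + 1L
      chrom[i] <- "X"
      g_start[i] <- 10e6 + n_x * 2e6 # well outside both PARs
    } else {
      n_a <- n_a + 1L
      chrom[i] <- autos[(n_a - 1L) %% 22L + 1L]
      g_start[i] <- 5e6 + ((n_a - 1L) %/% 22L) * 50e6 + ((n_a - 1L) %% 22L) * 1e6
    }
  }
  exons <- purrr::map(seq_len(nrow(spec)), function(i) {
    ex_start <- g_start[i] + (0:9) * 3200
    tibble(
      gene = spec$gene[i], chrom = chrom[i],
      start = ex_start, end = ex_start + 199,
      coding = c(rep(TRUE, 9), FALSE),
      gene_class = spec$gene_class[i], moi = spec$moi[i]
    )
  }) %>% bind_rows()
  str_genes <- default_str_catalog() %>%
    mutate(
      gene_class = "disease_gene",
      moi = if_else(.data$chrom == "X", "XL", "AR"),
      coding = TRUE
    ) %>%
    select("gene", "chrom", "start", "end", "coding", "gene_class", "moi")
  validate_gene_models(bind_rows(exons, str_genes))
}

#' Synthetic cohort configuration
#'
#' Defines the study conditions the generator emulates. Defaults mirror the
#' published marginals of a 150-trio NDD cohort analysed through two
#' pathways: 101/150 male probands; 45 conclusive diagnoses (26 SNVs, 13
#' indels, 5 CNVs of which 2 detectable only by genome sequencing, 1 repeat
#' expansion), 35 possible diagnoses (4 CNVs GS-only) and 70 undiagnosed;
#' small-variant inheritance 35 de novo / 1 homozygous / 3 hemizygous;
#' 50-fold mean depth. The generator is noise-free by default
#' (`genotype_error_rate = 0`), the condition under which planted-diagnosis
#' recovery is exact.
#'
#' @param n_trios Number of patient-parent trios.
#' @param n_background Background (non-causal) small-variant sites per trio.
#' @param male_fraction Fraction of male probands.
#' @param type_props Proportions of conclusive diagnoses over variant types
#'   `snv`, `indel`, `cnv`, `str`, `mito` (must sum to 1).
#' @param mode_props Proportions of small-variant (snv/indel) conclusive
#'   diagnoses over inheritance modes `de_novo`, `homozygous`,
#'   `compound_het`, `hemizygous` (must sum to 1).
#' @param outcome_props Proportions of trios over intended outcomes
#'   `conclusive`, `possible`, `none` (must sum to 1).
#' @param n_gs_only_conclusive_cnv,n_gs_only_possible_cnv How many planted
#'   conclusive/possible diagnoses are CNVs visible to the GS pathway only
#'   (below the standard-of-care detectability floor or confined to a
#'   non-coding exon).
#' @param depth_mean,depth_size Negative-binomial read-depth model (mean,
#'   dispersion size).
#' @param vaf_shape Symmetric Beta shape for the heterozygous allele
#'   fraction (centered on 0.5).
#' @param genotype_error_rate Per-site probability that the child's
#'   background genotype is replaced by a random different genotype
#'   (creates Mendelian errors).
#' @param parental_dropout_rate Per-site probability that a parental
#'   genotype is missing.
#' @param seed Integer seed; a fixed seed makes the cohort byte-identical
#'   across runs.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_trios = 150,
                          n_background = 120,
                          male_fraction = 101 / 150,
                          type_props = c(
                            snv = 26, indel = 13, cnv = 5, str = 1, mito = 0
                          ) / 45,
                          mode_props = c(
                            de_novo = 35, homozygous = 1,
                            compound_het = 0, hemizygous = 3
                          ) / 39,
                          outcome_props = c(
                            conclusive = 45, possible = 35, none = 70
                          ) / 150,
                          n_gs_only_conclusive_cnv = 2,
                          n_gs_only_possible_cnv = 4,
                          depth_mean = 50,
                          depth_size = 20,
                          vaf_shape = 20,
                          genotype_error_rate = 0,
                          parental_dropout_rate = 0,
                          seed = 1L) {
  chk_props <- function(p, nm) {
    if (abs(sum(p) - 1) > 1e-9) {
      abort(sprintf("%s must sum to 1 (got %.12f)", nm, sum(p)))
    }
    if (any(p < 0)) abort(sprintf("%s must be non-negative", nm))
  }
  chk_props(type_props, "type_props")
  chk_props(mode_props, "mode_props")
  chk_props(outcome_props, "outcome_props")
  stopifnot(
    n_trios >= 0, n_background >= 0,
    male_fraction >= 0, male_fraction <= 1,
    genotype_error_rate >= 0, genotype_error_rate <= 1,
    parental_dropout_rate >= 0, parental_dropout_rate <= 1
  )
  structure(
    list(
      n_trios = as.integer(n_trios), n_background = as.integer(n_background),
      male_fraction = male_fraction,
      type_props = type_props, mode_props = mode_props,
      outcome_props = outcome_props,
      n_gs_only_conclusive_cnv = as.integer(n_gs_only_conclusive_cnv),
      n_gs_only_possible_cnv = as.integer(n_gs_only_possible_cnv),
      depth_mean = depth_mean, depth_size = depth_size,
      vaf_shape = vaf_shape,
      genotype_error_rate = genotype_error_rate,
      parental_dropout_rate = parental_dropout_rate,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# largest-remainder apportionment of n into integer counts proportional to p
apportion <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# ---- planting ----------------------------------------------------------------

# QC-clean per-member sequencing metrics for a planted genotype
planted_metrics <- function(gt, cfg) {
  dp <- max(20L, stats::rnbinom(1, size = cfg$depth_size, mu = cfg$depth_mean))
  alt <- switch(gt,
    hom_ref = 0L,
    het = as.integer(round(dp * stats::runif(1, 0.42, 0.58))),
    hom_alt = dp,
    hemi = dp,
    missing = NA_integer_
  )
  list(dp = dp, alt = alt, vaf = if (is.na(alt)) NA_real_ else alt / dp)
}

planted_variant_row <- function(trio, gene_row, pos, ref, alt, gts, label, cfg) {
  m <- purrr::map(gts, planted_metrics, cfg = cfg)
  tibble(
    trio_id = trio$child_id, chrom = gene_row$chrom[1], pos = pos,
    ref = ref, alt = alt,
    gt_child = gts[[1]], gt_father = gts[[2]], gt_mother = gts[[3]],
    dp_child = m[[1]]$dp, dp_father = m[[2]]$dp, dp_mother = m[[3]]$dp,
    vaf_child = m[[1]]$vaf, vaf_father = m[[2]]$vaf, vaf_mother = m[[3]]$vaf,
    qual = 100, gene = gene_row$gene[1], consequence = "planted_coding",
    pop_af = 0, ih_af = 0, n_hom = 0,
    class_label = label, missing_parent = FALSE
  )
}

#' Plant one causal variant into a trio
#'
#' Produces the call-file rows (small variants, CNV calls or repeat
#' genotypes) that realise one planted diagnosis in one trio, together with
#' its truth record. Planted variants are constructed to pass the triage
#' stage appropriate to their type: QC-clean metrics, in-scope coordinates,
#' rare frequency, and genotypes realising the intended inheritance mode
#' (compound-het plants produce exactly one paternal-origin and one
#' maternal-origin heterozygote in the same gene).
#'
#' @param trio One pedigree row.
#' @param spec A one-row tibble: `var_type` (`snv`/`indel`/`cnv`/`str`/
#'   `mito`), `mode`, `gene`, `label`, `outcome`, `visibility` (`both` or,
#'   for CNVs only, `gs_only`), and for CNVs `cnv_kind`
#'   (`small_coding`/`noncoding_exon`/`multi_exon`/`whole_gene`/`dup`).
#' @param gene_models Gene models hosting the plant; the gene must exist
#'   (with exons) or planting errors.
#' @param cfg A [cohort_config()] (noise model parameters).
#' @return List of tibbles: `variants`, `cnvs`, `strs`, `truth`.
#' @export
plant_causal_variant <- function(trio, spec, gene_models, cfg = cohort_config()) {
  g <- filter(gene_models, .data$gene == spec$gene)
  if (nrow(g) == 0 && spec$var_type != "mito") {
    abort(sprintf("plant target gene '%s' not in gene models", spec$gene))
  }
  out <- list(
    variants = NULL, cnvs = NULL, strs = NULL
  )
  truth <- tibble(
    trio_id = trio$child_id, var_type = spec$var_type, mode = spec$mode,
    gene = spec$gene, chrom = g$chrom[1], start = NA_real_, end = NA_real_,
    label = spec$label, outcome = spec$outcome, visibility = spec$visibility
  )

  if (spec$var_type %in% c("snv", "indel")) {
    coding <- filter(g, .data$coding)
    if (nrow(coding) == 0) {
      abort(sprintf("gene '%s' has no coding exon to host a small variant", spec$gene))
    }
    pos <- coding$start[min(3, nrow(coding))] + 50
    if (spec$var_type == "snv") {
      ref <- "A"; alt <- "G"
    } else {
      ref <- "ATCT"; alt <- "A"
    }
    gts <- switch(spec$mode,
      de_novo = list("het", "hom_ref", "hom_ref"),
      homozygous = list("hom_alt", "het", "het"),
      hemizygous = list("hemi", "hom_ref", "het"),
      compound_het = NULL,
      abort(sprintf("unsupported small-variant mode '%s'", spec$mode))
    )
    if (spec$mode == "compound_het") {
      p1 <- coding$start[1] + 20
      p2 <- coding$start[min(5, nrow(coding))] + 20
      out$variants <- bind_rows(
        planted_variant_row(trio, g, p1, ref, alt, list("het", "het", "hom_ref"),
          spec$label, cfg),
        planted_variant_row(trio, g, p2, ref, alt, list("het", "hom_ref", "het"),
          spec$label, cfg)
      )
      truth$start <- p1
      truth$end <- p2
    } else {
      if (spec$mode == "hemizygous" && trio$child_sex != "male") {
        abort("hemizygous plant requires a male proband")
      }
      if (spec$mode == "hemizygous" && g$chrom[1] != "X") {
        abort(sprintf("hemizygous plant requires an X-linked gene, not %s", spec$gene))
      }
      out$variants <- planted_variant_row(trio, g, pos, ref, alt, gts, spec$label, cfg)
      truth$start <- pos
      truth$end <- pos + nchar(ref) - 1
    }
  } else if (spec$var_type == "cnv") {
    ex <- arrange(g, .data$start)
    kind <- spec$cnv_kind
    if (kind == "noncoding_exon" && !any(!ex$coding)) {
      abort(sprintf("gene '%s' has no non-coding exon to host this deletion", spec$gene))
    }
    reg <- switch(kind,
      small_coding = c(ex$start[4] - 800, ex$end[5] + 800), # ~5 kb, 2 coding exons
      noncoding_exon = { # ~36 kb confined to the 3'UTR exon and downstream
        nc <- filter(ex, !.data$coding)
        c(nc$start[1] - 100, nc$start[1] - 100 + 36232 - 1)
      },
      multi_exon = c(ex$start[2] - 500, ex$end[6] + 500), # ~14 kb, exons 2-6
      whole_gene = c(min(ex$start) - 10000, max(ex$end) + 10000),
      dup = c(min(ex$start) - 5000, max(ex$end) + 150000),
      abort(sprintf("unknown cnv_kind '%s'", kind))
    )
    svtype <- if (kind == "dup") "DUP" else "DEL"
    out$cnvs <- tibble(
      trio_id = trio$child_id, chrom = g$chrom[1],
      start = reg[1], end = reg[2], svtype = svtype,
      copy_number = if (svtype == "DEL") 1 else 3,
      carrier_child = "present", carrier_father = "absent",
      carrier_mother = "absent",
      qual = 60, caller = "depth_based", class_label = spec$label
    )
    truth$start <- reg[1]
    truth$end <- reg[2]
  } else if (spec$var_type == "str") {
    single <- trio$child_sex == "male" && g$chrom[1] == "X"
    out$strs <- tibble(
      trio_id = trio$child_id, gene = spec$gene,
      motif = default_str_catalog()$motif[default_str_catalog()$gene == spec$gene],
      allele1 = if (single) 94 else 30, allele2 = if (single) NA_real_ else 94,
      coverage_flag = "ok", mq_flag = "ok"
    )
    truth$start <- g$start[1]
    truth$end <- g$end[1]
    truth$mode <- spec$mode
  } else if (spec$var_type == "mito") {
    entry <- synthetic_mito_catalog()[2, ] # m.3243A>G
    out$variants <- tibble(
      trio_id = trio$child_id, chrom = "MT", pos = entry$pos,
      ref = entry$ref, alt = entry$alt,
      gt_child = "het", gt_father = "hom_ref", gt_mother = "het",
      dp_child = 500, dp_father = 500, dp_mother = 500,
      vaf_child = 0.62, vaf_father = 0, vaf_mother = 0.31,
      qual = 100, gene = "MT", consequence = "mito",
      pop_af = 0, ih_af = 0, n_hom = 0,
      class_label = spec$label, missing_parent = FALSE
    )
    truth$chrom <- "MT"
    truth$start <- entry$pos
    truth$end <- entry$pos
  }
  out$truth <- truth
  out
}

# plant specification table for one cohort (deterministic given counts)
build_plant_specs <- function(cfg, gene_models) {
  n_conc <- apportion(cfg$n_trios, cfg$outcome_props)
  names(n_conc) <- names(cfg$outcome_props)
  type_n <- apportion(n_conc[["conclusive"]], cfg$type_props)
  names(type_n) <- names(cfg$type_props)
  sv_n <- type_n[["snv"]] + type_n[["indel"]]
  mode_n <- apportion(sv_n, cfg$mode_props)
  names(mode_n) <- names(cfg$mode_props)

  pick_genes <- function(class, moi = NULL, chrom_x = NULL, noncoding = NULL) {
    g <- distinct(gene_models, .data$gene, .data$chrom, .data$gene_class, .data$moi)
    g <- filter(g, .data$gene_class == class, !grepl("^(FMR1|AFF2|ARX|CSTB|EIF4A3|DMPK)$", .data$gene))
    if (!is.null(moi)) g <- filter(g, .data$moi == !!moi)
    if (!is.null(chrom_x)) g <- filter(g, (.data$chrom == "X") == chrom_x)
    if (!is.null(noncoding)) {
      nc <- unique(gene_models$gene[!gene_models$coding])
      g <- filter(g, .data$gene %in% nc)
    }
    g$gene
  }
  cyc <- function(genes, n) if (n == 0) character(0) else rep(genes, length.out = n)

  # conclusive small variants: modes paired with snv/indel types in order
  sv_types <- rep(c("snv", "indel"), times = c(type_n[["snv"]], type_n[["indel"]]))
  sv_modes <- rep(names(mode_n), times = mode_n)
  if (length(sv_modes) < length(sv_types)) {
    sv_modes <- c(sv_modes, rep("de_novo", length(sv_types) - length(sv_modes)))
  }
  sv_specs <- tibble(
    var_type = sv_types, mode = sv_modes[seq_along(sv_types)],
    outcome = "conclusive", visibility = "both", label = "P",
    cnv_kind = NA_character_
  ) %>%
    mutate(gene = dplyr::case_when(
      mode == "de_novo" ~ cyc(pick_genes("ndd_panel", moi = "AD"), n())[row_number()],
      mode == "homozygous" ~ cyc(pick_genes("ndd_panel", moi = "AR"), n())[row_number()],
      mode == "compound_het" ~ cyc(pick_genes("ndd_panel", moi = "AR"), n())[row_number()],
      mode == "hemizygous" ~ cyc(pick_genes("ndd_panel", moi = "XL", chrom_x = TRUE), n())[row_number()]
    ))

  # conclusive CNVs: first the GS-only archetypes, then SOC-visible ones
  n_cnv <- type_n[["cnv"]]
  n_gs <- min(cfg$n_gs_only_conclusive_cnv, n_cnv)
  kinds <- c(
    rep(c("small_coding", "noncoding_exon"), length.out = n_gs),
    cyc(c("multi_exon", "whole_gene", "dup"), n_cnv - n_gs)
  )
  cnv_specs <- tibble(
    var_type = "cnv", mode = "de_novo", outcome = "conclusive",
    visibility = c(rep("gs_only", n_gs), rep("both", n_cnv - n_gs)),
    label = "P", cnv_kind = kinds
  ) %>%
    mutate(gene = if_else(
      .data$cnv_kind == "noncoding_exon",
      cyc(pick_genes("disease_gene", noncoding = TRUE), n()),
      cyc(pick_genes("ndd_panel", moi = "AD"), n())
    ))

  str_specs <- if (type_n[["str"]] > 0) {
    tibble(
      var_type = "str", mode = "expansion", outcome = "conclusive",
      visibility = "both", label = "P", cnv_kind = NA_character_,
      gene = rep("FMR1", type_n[["str"]])
    )
  } else NULL
  mito_specs <- if (type_n[["mito"]] > 0) {
    tibble(
      var_type = "mito", mode = "mito", outcome = "conclusive",
      visibility = "both", label = "P", cnv_kind = NA_character_,
      gene = rep("MT", type_n[["mito"]])
    )
  } else NULL

  # possible diagnoses: GS-only small VUS CNVs first, then VUS in disease
  # genes alternating with P/LP in candidate genes
  n_poss <- n_conc[["possible"]]
  n_gs_p <- min(cfg$n_gs_only_possible_cnv, n_poss)
  n_rest <- n_poss - n_gs_p
  poss_cnv <- if (n_gs_p > 0) {
    tibble(
      var_type = "cnv", mode = "de_novo", outcome = "possible",
      visibility = "gs_only", label = "VUS", cnv_kind = "small_coding",
      gene = cyc(pick_genes("disease_gene", moi = "AD"), n_gs_p)
    )
  } else NULL
  poss_rest <- if (n_rest > 0) {
    half <- ceiling(n_rest / 2)
    bind_rows(
      tibble(
        var_type = "snv", mode = "de_novo", outcome = "possible",
        visibility = "both", label = "VUS", cnv_kind = NA_character_,
        gene = cyc(pick_genes("disease_gene", moi = "AD"), half)
      ),
      tibble(
        var_type = "snv", mode = "de_novo", outcome = "possible",
        visibility = "both", label = "P", cnv_kind = NA_character_,
        gene = cyc(pick_genes("candidate_gene"), n_rest - half)
      )
    )
  } else NULL

  bind_rows(sv_specs, cnv_specs, str_specs, mito_specs, poss_cnv, poss_rest)
}

# ---- background generation ---------------------------------------------------

simulate_background <- function(trio, cfg, gene_models) {
  n <- cfg$n_background
  if (n == 0) return(NULL)
  exons <- filter(gene_models, .data$chrom %in% as.character(1:22))
  pick <- exons[sample.int(nrow(exons), n, replace = TRUE), ]
  in_exon <- stats::runif(n) < 0.8
  pos <- ifelse(
    in_exon,
    pick$start + floor(stats::runif(n) * (pick$end - pick$start + 1)),
    pick$end + 2500 + floor(stats::runif(n) * 400) # deep intronic (> 8 bp window)
  )
  rare <- stats::runif(n) < 0.3
  af <- round(ifelse(rare, stats::runif(n, 0, 0.005), stats::runif(n, 0.02, 0.5)), 6)

  draw_parent <- function() rbinom(n, 2, af)
  nf <- draw_parent()
  nm <- draw_parent()
  child <- rbinom(n, 1, nf / 2) + rbinom(n, 1, nm / 2)
  # genotype-error noise: replace the child's genotype by a random different one
  err <- stats::runif(n) < cfg$genotype_error_rate
  if (any(err)) {
    child[err] <- (child[err] + sample(1:2, sum(err), replace = TRUE)) %% 3
  }
  gt_of <- function(k) c("hom_ref", "het", "hom_alt")[k + 1]

  member <- function(k) {
    dp <- pmax(1L, stats::rnbinom(n, size = cfg$depth_size, mu = cfg$depth_mean))
    p <- ifelse(
      k == 0, stats::rbeta(n, 2, 98),
      ifelse(k == 1, stats::rbeta(n, cfg$vaf_shape, cfg$vaf_shape),
        stats::rbeta(n, 98, 2))
    )
    alt <- rbinom(n, dp, p)
    list(dp = dp, alt = alt, vaf = alt / dp)
  }
  mc <- member(child)
  mf <- member(nf)
  mm <- member(nm)

  gt_f <- gt_of(nf)
  gt_m <- gt_of(nm)
  drop_f <- stats::runif(n) < cfg$parental_dropout_rate
  drop_m <- stats::runif(n) < cfg$parental_dropout_rate
  gt_f[drop_f] <- "missing"
  gt_m[drop_m] <- "missing"

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))

  tibble(
    trio_id = trio$child_id, chrom = pick$chrom, pos = pos,
    ref = ref, alt = unname(alt),
    gt_child = gt_of(child), gt_father = gt_f, gt_mother = gt_m,
    dp_child = mc$dp, dp_father = mf$dp, dp_mother = mm$dp,
    vaf_child = mc$vaf, vaf_father = mf$vaf, vaf_mother = mm$vaf,
    qual = round(stats::runif(n, 40, 100)),
    gene = if_else(in_exon, pick$gene, NA_character_),
    consequence = if_else(in_exon, "exonic", "intronic"),
    pop_af = af, ih_af = af, n_hom = round(af^2 * 1e5),
    class_label = sample(c("unclassified", "B", "LB"), n,
      replace = TRUE, prob = c(0.7, 0.2, 0.1)
    ),
    missing_parent = gt_f == "missing" | gt_m == "missing",
    genotype_error = err # simulator truth annotation, not written to VCF
  ) %>%
    distinct(.data$chrom, .data$pos, .keep_all = TRUE)
}

# common population CNVs shared across trios (inherited; never diagnostic)
background_cnvs <- function(trio, gene_models) {
  oth <- filter(gene_models, .data$gene == "OTH01")
  tibble(
    trio_id = trio$child_id,
    chrom = c(oth$chrom[1], "2"),
    start = c(min(oth$start) - 2000, 2.2e6),
    end = c(min(oth$start) + 13000, 2.203e6),
    svtype = "DEL",
    copy_number = 1,
    carrier_child = "present",
    carrier_father = c("present", "absent"),
    carrier_mother = c("absent", "present"),
    qual = c(45, 40), caller = "depth_based", class_label = "unclassified"
  )
}

normal_str_genotypes <- function(trio) {
  cat <- default_str_catalog()
  normals <- c(AFF2 = 16, ARX = 12, CSTB = 4, EIF4A3 = 8, DMPK = 9, FMR1 = 24)
  single <- trio$child_sex == "male" & cat$chrom == "X"
  a1 <- unname(normals[cat$gene]) + sample(-2:2, nrow(cat), replace = TRUE)
  a2 <- ifelse(single, NA_real_,
    unname(normals[cat$gene]) + sample(-2:2, nrow(cat), replace = TRUE))
  tibble(
    trio_id = trio$child_id, gene = cat$gene, motif = cat$motif,
    allele1 = pmax(1, a1), allele2 = pmax(1, a2),
    coverage_flag = "ok", mq_flag = "ok"
  )
}

#' Simulate a synthetic trio cohort
#'
#' Generates a full cohort bundle under a [cohort_config()]: pedigree,
#' deterministic gene models, Mendelian background small variants with the
#' configured noise, planted causal variants of the configured spectrum
#' (with QC-clean metrics), background and planted CNV calls, repeat
#' genotypes at the six NDD loci, a phenotype-match table (true exactly for
#' planted genes) and a truth table. All randomness flows from a single
#' generator seeded with `config$seed`, so a fixed config reproduces the
#' cohort exactly.
#'
#' @param config A [cohort_config()].
#' @return A list of class `trio_cohort`: `config`, `pedigree`,
#'   `gene_models`, `variants`, `cnvs`, `strs`, `phenotype_match`, `truth`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  cfg <- config
  withr::with_seed(cfg$seed, {
    gm <- synthetic_gene_models()
    specs <- build_plant_specs(cfg, gm)

    n <- cfg$n_trios
    n_male <- apportion(n, c(cfg$male_fraction, 1 - cfg$male_fraction))[1]
    sexes <- sample(c(rep("male", n_male), rep("female", n - n_male)))
    ped <- tibble(
      family_id = sprintf("F%03d", seq_len(n)),
      child_id = sprintf("T%03d", seq_len(n)),
      father_id = sprintf("T%03dF", seq_len(n)),
      mother_id = sprintf("T%03dM", seq_len(n)),
      child_sex = sexes,
      child_affected = TRUE, father_affected = FALSE, mother_affected = FALSE
    )
    if (n == 0) ped <- ped[0, ]

    # assign plant specs to trios: male-requiring plants need male probands
    needs_male <- !is.na(specs$mode) & specs$mode == "hemizygous" |
      (specs$var_type == "str" & specs$gene == "FMR1")
    if (sum(needs_male & specs$mode == "hemizygous") > sum(ped$child_sex == "male")) {
      abort("config plants hemizygous variants but the cohort has too few male probands")
    }
    if (nrow(specs) > n) {
      abort(sprintf(
        "config plants %d diagnoses but the cohort has only %d trios",
        nrow(specs), n
      ))
    }
    males <- which(ped$child_sex == "male")
    females <- which(ped$child_sex == "female")
    assign_idx <- integer(nrow(specs))
    mi <- 1
    fi <- 1
    for (i in order(!needs_male)) { # male-requiring specs first
      if (needs_male[i] && mi <= length(males)) {
        assign_idx[i] <- males[mi]; mi <- mi + 1
      } else if (fi <= length(females)) {
        assign_idx[i] <- females[fi]; fi <- fi + 1
      } else {
        assign_idx[i] <- males[mi]; mi <- mi + 1
      }
    }

    variants <- list()
    cnvs <- list()
    strs <- list()
    truth <- list()
    for (t in seq_len(n)) {
      trio <- ped[t, ]
      variants[[length(variants) + 1]] <- simulate_background(trio, cfg, gm)
      cnvs[[length(cnvs) + 1]] <- background_cnvs(trio, gm)
      strs[[length(strs) + 1]] <- normal_str_genotypes(trio)
    }
    for (i in seq_len(nrow(specs))) {
      trio <- ped[assign_idx[i], ]
      planted <- plant_causal_variant(trio, specs[i, ], gm, cfg)
      variants[[length(variants) + 1]] <- planted$variants
      cnvs[[length(cnvs) + 1]] <- planted$cnvs
      if (!is.null(planted$strs)) {
        # replace the background genotype at that locus
        strs <- purrr::map(strs, function(s) {
          filter(s, !(s$trio_id == trio$child_id & s$gene == planted$strs$gene[1]))
        })
        strs[[length(strs) + 1]] <- planted$strs
      }
      truth[[length(truth) + 1]] <- planted$truth
    }

    variants <- bind_rows(variants)
    if (ncol(variants) == 0) variants <- empty_trio_genotypes(ped[0, ])
    variants <- arrange(variants, .data$trio_id, .data$chrom, .data$pos, .data$alt)
    cnvs <- bind_rows(cnvs)
    if (ncol(cnvs) == 0) cnvs <- mutate(empty_cnv_calls(), trio_id = character())
    cnvs <- arrange(cnvs, .data$trio_id, .data$chrom, .data$start, .data$end)
    strs <- bind_rows(strs)
    if (ncol(strs) == 0) {
      strs <- tibble(
        trio_id = character(), gene = character(), motif = character(),
        allele1 = numeric(), allele2 = numeric(),
        coverage_flag = character(), mq_flag = character()
      )
    }
    strs <- arrange(strs, .data$trio_id, .data$gene)
    truth <- if (length(truth)) bind_rows(truth) else tibble(
      trio_id = character(), var_type = character(), mode = character(),
      gene = character(), chrom = character(), start = numeric(),
      end = numeric(), label = character(), outcome = character(),
      visibility = character()
    )
    pm <- truth %>%
      distinct(.data$trio_id, .data$gene) %>%
      mutate(phenotype_match = TRUE)

    structure(
      list(
        config = cfg, pedigree = ped, gene_models = gm,
        variants = variants, cnvs = cnvs, strs = strs,
        phenotype_match = pm, truth = truth
      ),
      class = "trio_cohort"
    )
  })
}

#' @method print trio_cohort
#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic trio cohort: %d trios, %d small-variant records, %d CNV calls, %d repeat genotypes, %d planted diagnoses\n",
    nrow(x$pedigree), nrow(x$variants), nrow(x$cnvs), nrow(x$strs),
    dplyr::n_distinct(x$truth$trio_id)
  ))
  invisible(x)
}

#' Emulated standard-of-care view of a cohort
#'
#' Projects a cohort bundle onto the detectability of an exome-based
#' standard-of-care pathway: CNV calls shorter than `soc_cnv_floor` and CNV
#' calls whose exon overlap is confined to non-coding exons are removed
#' (small events and untargeted non-coding exons are what exome-based CNV
#' calling misses); all other evidence is unchanged.
#'
#' @param bundle A `trio_cohort` bundle.
#' @param config A [triage_config()] (`soc_cnv_floor`).
#' @return The bundle with the filtered CNV set and attribute
#'   `pathway = "SOC"`.
#' @export
soc_view <- function(bundle, config = triage_config()) {
  cv <- bundle$cnvs
  if (nrow(cv) > 0) {
    gm <- bundle$gene_models
    keep <- vapply(seq_len(nrow(cv)), function(i) {
      len <- cv$end[i] - cv$start[i] + 1
      if (len < config$soc_cnv_floor) return(FALSE)
      ex <- gm[gm$chrom == cv$chrom[i] & gm$start <= cv$end[i] &
        gm$end >= cv$start[i], , drop = FALSE]
      if (nrow(ex) > 0 && !any(ex$coding)) return(FALSE) # non-coding exons only
      TRUE
    }, logical(1))
    cv <- cv[keep, , drop = FALSE]
  }
  bundle$cnvs <- cv
  attr(bundle, "pathway") <- "SOC"
  bundle
}
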