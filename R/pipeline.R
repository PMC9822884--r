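# End-to-end triage: per-trio candidate generation across all variant types,
# cohort-wide outcome classification, and the two-pathway comparison.

#' Run the full triage pipeline over a cohort
#'
#' Applies every triage stage to a cohort bundle and classifies each
#' patient's diagnostic outcome:
#' \enumerate{
#'   \item small variants: genotype QC, interpretation-scope restriction
#'     (exons + splice window), mode-of-inheritance segregation,
#'     compound-het detection, frequency gates and tiered prioritization;
#'   \item CNVs: caller merging, inheritance segregation, three-category
#'     assessment, CNV-SNV compound heterozygotes in recessive genes —
#'     candidate CNVs are de novo, homozygous, hemizygous or one side of a
#'     compound heterozygote, in a category other than `none`;
#'   \item repeat loci: threshold classification; expanded alleles become
#'     `P` candidates, premutation-range alleles become `P` when
#'     `premutation_reportable` is set (else `VUS`);
#'   \item mitochondrial variants: exact catalog matches become `P`
#'     candidates;
#'   \item outcome classification per patient ([classify_patient()]) using
#'     the supplied phenotype-match table.
#' }
#'
#' @param bundle A `trio_cohort` bundle ([simulate_cohort()] /
#'   [read_cohort()]), optionally projected with [soc_view()].
#' @param config A [triage_config()].
#' @param pathway Pathway label recorded on outcomes (defaults to the
#'   bundle's `pathway` attribute, else `"GS"`).
#' @param str_catalog Repeat-locus catalog for [classify_str()].
#' @param mito_catalog Catalog for [match_mito()].
#' @return List of class `triage_result`: `candidates` (all candidate rows,
#'   one per variant-mode, with `input_order` within patient), `outcomes`
#'   ([classify_cohort()] tibble), `str_report`, `roh` (empty tibble
#'   placeholder unless genotype sequences are supplied downstream), and
#'   `pathway`.
#' @export
triage_cohort <- function(bundle, config = triage_config(),
                          pathway = NULL,
                          str_catalog = default_str_catalog(),
                          mito_catalog = synthetic_mito_catalog()) {
  if (is.null(pathway)) {
    pathway <- attr(bundle, "pathway")
    if (is.null(pathway)) pathway <- "GS"
  }
  ped <- bundle$pedigree
  gm <- bundle$gene_models
  gene_info <- distinct(gm, .data$gene, .data$gene_class, .data$moi)
  tier_map <- c(ndd_panel = 1L, disease_gene = 2L, candidate_gene = 3L, other = 4L)

  # ---- small variants --------------------------------------------------------
  v <- filter(bundle$variants, carries_alt(.data$gt_child))
  mito_rows <- filter(v, sub("^chr", "", .data$chrom) %in% c("MT", "M"))
  v <- anti_join(v, mito_rows, by = names(v))
  snv_cand <- NULL
  v_seg <- NULL
  if (nrow(v) > 0) {
    v <- genotype_qc(v, config) %>% filter(.data$qc_pass)
    v <- in_scope(v, gm, config) %>% filter(.data$in_scope)
    v_seg <- segregate_trio(v, ped)
    pri <- prioritize_small_variants(v_seg, gm, config)
    if (nrow(pri) > 0) {
      snv_cand <- pri %>%
        mutate(label = .data$class_label, start = .data$pos, end = .data$pos) %>%
        select(
          "trio_id", "var_id", "type", "gene", "gene_class", "moi", "mode",
          "label", "pop_af", "tier", "partner_id", "chrom", "pos", "start", "end"
        )
    }
  }

  # ---- CNVs ------------------------------------------------------------------
  cnv_cand <- NULL
  if (nrow(bundle$cnvs) > 0) {
    cv <- merge_cnv_callers(bundle$cnvs, config) %>%
      segregate_cnv(ped, config) %>%
      categorize_cnv(gm, config)
    pairs <- if (!is.null(v_seg)) {
      find_cnv_snv_compound_het(cv, v_seg, gm)
    } else NULL
    cv <- cv %>% mutate(
      id = cnv_id(.data$chrom, .data$start, .data$end, .data$svtype),
      mode_hit = purrr::map_chr(.data$modes, function(m) {
        hit <- intersect(c("de_novo", "homozygous", "hemizygous"), m)
        if (length(hit)) hit[1] else NA_character_
      }),
      in_pair = if (!is.null(pairs) && nrow(pairs) > 0) {
        .data$id %in% pairs$cnv_id
      } else FALSE
    )
    keep <- cv %>% filter(
      .data$category != "none",
      !is.na(.data$mode_hit) | .data$in_pair
    )
    if (nrow(keep) > 0) {
      cnv_cand <- keep %>%
        left_join(gene_info, by = "gene") %>%
        mutate(
          type = "cnv",
          mode = if_else(is.na(.data$mode_hit), "compound_het", .data$mode_hit),
          label = .data$class_label,
          gene_class = tidyr::replace_na(.data$gene_class, "other"),
          tier = unname(tier_map[.data$gene_class]),
          pop_af = 0, pos = .data$start, partner_id = NA_character_
        ) %>%
        select(
          "trio_id", var_id = "id", "type", "gene", "gene_class", "moi",
          "mode", "label", "pop_af", "tier", "partner_id", "chrom", "pos",
          "start", "end"
        )
      # the SNV side of a CNV-SNV pair becomes a compound_het candidate too
      if (!is.null(pairs) && nrow(pairs) > 0 && !is.null(v_seg)) {
        snv_side <- v_seg %>%
          mutate(var_id = variant_id(.data$chrom, .data$pos, .data$ref, .data$alt)) %>%
          inner_join(
            distinct(pairs, .data$trio_id, .data$gene, .data$var_id,
              partner_id = .data$cnv_id),
            by = c("trio_id", "gene", "var_id")
          ) %>%
          left_join(gene_info, by = "gene") %>%
          mutate(
            type = if_else(nchar(.data$ref) == 1 & nchar(.data$alt) == 1,
              "snv", "indel"),
            mode = "compound_het", label = .data$class_label,
            tier = unname(tier_map[.data$gene_class]),
            start = .data$pos, end = .data$pos
          ) %>%
          select(
            "trio_id", "var_id", "type", "gene", "gene_class", "moi", "mode",
            "label", "pop_af", "tier", "partner_id", "chrom", "pos", "start",
            "end"
          )
        cnv_cand <- bind_rows(cnv_cand, snv_side)
      }
    }
  }

  # ---- repeat loci -----------------------------------------------------------
  str_report <- classify_str(bundle$strs, str_catalog)
  str_cand <- str_report %>%
    filter(.data$status %in% c("expanded", "intermediate_or_premutation")) %>%
    mutate(
      type = "str",
      label = if_else(
        .data$status == "expanded" | config$premutation_reportable, "P", "VUS"
      ),
      mode = "expansion"
    ) %>%
    left_join(gene_info, by = "gene") %>%
    mutate(
      gene_class = tidyr::replace_na(.data$gene_class, "disease_gene"),
      tier = unname(tier_map[.data$gene_class]),
      pop_af = 0, var_id = sprintf("%s[%g]", .data$gene, .data$max_allele),
      partner_id = NA_character_, chrom = NA_character_,
      pos = NA_real_, start = NA_real_, end = NA_real_
    ) %>%
    select(
      "trio_id", "var_id", "type", "gene", "gene_class", "moi", "mode",
      "label", "pop_af", "tier", "partner_id", "chrom", "pos", "start", "end"
    )

  # ---- mitochondrial ---------------------------------------------------------
  mito_cand <- NULL
  if (nrow(mito_rows) > 0) {
    mm <- match_mito(mito_rows, mito_catalog)
    if (nrow(mm) > 0) {
      mito_cand <- mm %>% mutate(
        var_id = variant_id("MT", .data$pos, .data$ref, .data$alt),
        type = "mito", gene = "MT", gene_class = "disease_gene",
        moi = "unknown", mode = "mito", label = "P", pop_af = 0, tier = 2L,
        partner_id = NA_character_, start = .data$pos, end = .data$pos
      ) %>%
        select(
          "trio_id", "var_id", "type", "gene", "gene_class", "moi", "mode",
          "label", "pop_af", "tier", "partner_id", "chrom", "pos", "start",
          "end"
        )
    }
  }

  candidates <- bind_rows(snv_cand, cnv_cand, str_cand, mito_cand)
  if (nrow(candidates) == 0) {
    candidates <- tibble(
      trio_id = character(), var_id = character(), type = character(),
      gene = character(), gene_class = character(), moi = character(),
      mode = character(), label = character(), pop_af = numeric(),
      tier = integer(), partner_id = character(), chrom = character(),
      pos = numeric(), start = numeric(), end = numeric()
    )
  }
  candidates <- candidates %>%
    left_join(bundle$phenotype_match, by = c("trio_id", "gene")) %>%
    mutate(phenotype_match = tidyr::replace_na(.data$phenotype_match, FALSE)) %>%
    arrange(.data$trio_id, .data$tier, label_rank(.data$label), .data$var_id) %>%
    group_by(.data$trio_id) %>%
    mutate(input_order = row_number()) %>%
    ungroup()

  outcomes <- classify_cohort(candidates, ped$child_id, pathway = pathway)
  structure(
    list(
      candidates = candidates, outcomes = outcomes,
      str_report = str_report, pathway = pathway
    ),
    class = "triage_result"
  )
}

#' @method print triage_result
#' @export
print.triage_result <- function(x, ...) {
  cat(sprintf(
    "Triage result (%s pathway): %d candidates over %d patients\n",
    x$pathway, nrow(x$candidates), nrow(x$outcomes)
  ))
  print(count(x$outcomes, .data$outcome))
  invisible(x)
}

#' Run both diagnostic pathway views and compare them
#'
#' Runs [triage_cohort()] on the full (genome-sequencing) view of a cohort
#' and on its emulated standard-of-care projection ([soc_view()]), then
#' cross-tabulates outcomes.
#'
#' @param bundle A `trio_cohort` bundle.
#' @param config A [triage_config()].
#' @return List: `gs`, `soc` (both `triage_result`) and `concordance`
#'   (a [compare_pathways()] object with SOC rows and GS columns).
#' @export
run_two_pathways <- function(bundle, config = triage_config()) {
  gs <- triage_cohort(bundle, config, pathway = "GS")
  soc <- triage_cohort(soc_view(bundle, config), config, pathway = "SOC")
  conc <- compare_pathways(soc$outcomes, gs$outcomes, labels = c("SOC", "GS"))
  list(gs = gs, soc = soc, concordance = conc)
}

#' Evaluate planted-diagnosis recovery against the truth table
#'
#' For each truth record, checks that the pipeline produced a candidate in
#' the planted gene with the planted inheritance mode, and that the
#' patient's outcome equals the intended outcome class.
#'
#' @param bundle The simulated bundle (supplies `truth`).
#' @param result A `triage_result` from [triage_cohort()] on that bundle.
#' @return List: `per_plant` (truth table plus logical `candidate_found`,
#'   `outcome_ok`), `recovery_rate` (fraction of plants with a matching
#'   candidate), `outcome_accuracy` (fraction of *all* trios whose outcome
#'   matches the intended class, intended `none` for unplanted trios).
#' @export
evaluate_recovery <- function(bundle, result) {
  truth <- bundle$truth
  cand <- result$candidates
  out <- result$outcomes
  per <- truth %>% mutate(
    candidate_found = purrr::pmap_lgl(
      list(.data$trio_id, .data$gene, .data$mode),
      function(id, g, m) {
        any(cand$trio_id == id & cand$gene == g & cand$mode == m)
      }
    ),
    outcome_ok = purrr::map2_lgl(.data$trio_id, .data$outcome, function(id, oc) {
      out$outcome[out$patient_id == id] == oc
    })
  )
  intended <- bundle$pedigree %>%
    left_join(
      truth %>% group_by(.data$trio_id) %>%
        summarise(intended = dplyr::first(.data$outcome), .groups = "drop"),
      by = c(child_id = "trio_id")
    ) %>%
    mutate(intended = tidyr::replace_na(.data$intended, "none")) %>%
    left_join(select(out, "patient_id", "outcome"), by = c(child_id = "patient_id"))
  list(
    per_plant = per,
    recovery_rate = mean(per$candidate_found),
    outcome_accuracy = mean(intended$intended == intended$outcome)
  )
}
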