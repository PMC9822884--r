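# Diagnostic outcome classification (conclusive / possible / none) from
# prioritized candidates, two-pathway concordance analysis, exact tests and
# per-type diagnosis tallies.

outcome_levels <- c("conclusive", "possible", "none")

# moi-consistency of a candidate's mode with its gene's inheritance annotation
moi_consistent <- function(moi, mode) {
  case_when(
    mode %in% c("expansion", "mito") ~ TRUE, # dosage handled at the locus level
    is.na(moi) | moi %in% c("AD", "unknown") ~ TRUE,
    moi == "AR" ~ mode %in% c("homozygous", "compound_het"),
    moi == "XL" ~ mode %in% c("hemizygous", "de_novo", "homozygous", "compound_het"),
    TRUE ~ TRUE
  )
}

#' Classify a patient's diagnostic outcome
#'
#' Maps one patient's prioritized candidate variants to one of three
#' outcome classes:
#' \describe{
#'   \item{conclusive}{a (likely) pathogenic (`P`/`LP`) variant in an
#'     established disease gene (NDD panel or other disease gene) matching
#'     the phenotype — with biallelic support (homozygous or compound
#'     heterozygous, including CNV+SNV pairs) required in recessive genes;}
#'   \item{possible}{a variant of unknown significance (`VUS`) in a disease
#'     gene matching the phenotype, or a `P`/`LP` variant in a candidate
#'     disease gene;}
#'   \item{none}{otherwise.}
#' }
#' Conclusive dominates possible. Candidates without a pathogenicity label
#' are treated as `unclassified` and can never trigger a conclusive
#' outcome. A `P`/`LP` disease-gene candidate failing only the biallelic
#' requirement yields rationale `monoallelic_recessive`.
#'
#' Phenotype match is expert judgment supplied as data (a logical
#' `phenotype_match` column on the candidates), never computed here.
#'
#' @param candidates Tibble of one patient's candidates with columns
#'   `type`, `gene`, `gene_class`, `moi`, `mode`, `label`,
#'   `phenotype_match`, and (for tallies) `tier`, `pop_af`, `input_order`.
#' @return One-row tibble: `outcome`, `rationale`, `n_support`, `support`
#'   (list-column of the qualifying candidate rows; empty when `none`).
#' @export
classify_patient <- function(candidates) {
  cand <- as_tibble(candidates)
  if (nrow(cand) == 0) {
    return(tibble(
      outcome = "none", rationale = "no_candidates", n_support = 0L,
      support = list(cand)
    ))
  }
  cand <- cand %>% mutate(
    label = if_else(is.na(.data$label), "unclassified", .data$label),
    phenotype_match = tidyr::replace_na(.data$phenotype_match, FALSE),
    disease_gene = .data$gene_class %in% c("ndd_panel", "disease_gene"),
    moi_ok = moi_consistent(.data$moi, .data$mode)
  )
  conclusive <- cand$label %in% c("P", "LP") & cand$disease_gene &
    cand$phenotype_match & cand$moi_ok
  monoallelic <- cand$label %in% c("P", "LP") & cand$disease_gene &
    cand$phenotype_match & !cand$moi_ok
  possible_vus <- cand$label == "VUS" & cand$disease_gene &
    cand$phenotype_match & cand$moi_ok
  possible_cand <- cand$label %in% c("P", "LP") &
    cand$gene_class == "candidate_gene" & cand$phenotype_match

  drop_aux <- function(d) select(d, -"disease_gene", -"moi_ok")
  if (any(conclusive)) {
    sup <- drop_aux(cand[conclusive, , drop = FALSE])
    tibble(
      outcome = "conclusive", rationale = "plp_disease_gene",
      n_support = nrow(sup), support = list(sup)
    )
  } else if (any(possible_vus | possible_cand)) {
    sup <- drop_aux(cand[possible_vus | possible_cand, , drop = FALSE])
    tibble(
      outcome = "possible",
      rationale = if (any(possible_vus)) "vus_disease_gene" else "plp_candidate_gene",
      n_support = nrow(sup), support = list(sup)
    )
  } else {
    tibble(
      outcome = "none",
      rationale = if (any(monoallelic)) "monoallelic_recessive" else "no_qualifying_variant",
      n_support = 0L, support = list(drop_aux(cand)[0, , drop = FALSE])
    )
  }
}

#' Classify every patient of a cohort
#'
#' @param candidates Candidate tibble for the whole cohort (must carry
#'   `trio_id`).
#' @param trio_ids All patient identifiers of the cohort; patients without
#'   candidates are classified `none`.
#' @param pathway Label recorded on the outcome rows.
#' @return Outcome tibble: `patient_id`, `pathway`, `outcome`, `rationale`,
#'   `n_support`, `support` (list-column).
#' @export
classify_cohort <- function(candidates, trio_ids, pathway = "GS") {
  cand <- as_tibble(candidates)
  res <- purrr::map(trio_ids, function(id) {
    classify_patient(cand[cand$trio_id == id, , drop = FALSE]) %>%
      mutate(patient_id = id, .before = 1)
  }) %>% bind_rows()
  mutate(res, pathway = pathway, .after = "patient_id")
}

#' Cross-tabulate two pathways' diagnostic outcomes
#'
#' Builds the 3x3 concordance matrix of outcomes (`conclusive`, `possible`,
#' `none`) between two diagnostic pathways over the same cohort, together
#' with the list of discordant patients.
#'
#' @param outcomes_a,outcomes_b Outcome tibbles ([classify_cohort()] or
#'   [ndd150_outcomes()] schema, matched on `patient_id`; patients absent
#'   from an outcome tibble that appear in the other raise an error naming
#'   the symmetric difference — except that tibbles containing only
#'   diagnosed patients can be completed first with [complete_outcomes()]).
#' @param labels Length-2 character vector naming the pathways (rows =
#'   first, columns = second).
#' @return An object of class `pathway_concordance`: the count matrix, the
#'   cohort size, pathway labels, and a `discordant` tibble naming each
#'   off-diagonal patient with both outcomes and supporting variant types.
#' @export
compare_pathways <- function(outcomes_a, outcomes_b, labels = c("A", "B")) {
  a <- as_tibble(outcomes_a)
  b <- as_tibble(outcomes_b)
  sym <- c(setdiff(a$patient_id, b$patient_id), setdiff(b$patient_id, a$patient_id))
  if (length(sym) > 0) {
    abort(sprintf(
      "patient id sets differ between pathways: %s",
      paste(sort(unique(sym)), collapse = ", ")
    ))
  }
  stopifnot(!anyDuplicated(a$patient_id), !anyDuplicated(b$patient_id))
  j <- inner_join(
    select(a, "patient_id", outcome_a = "outcome", support_a = dplyr::any_of("support")),
    select(b, "patient_id", outcome_b = "outcome", support_b = dplyr::any_of("support")),
    by = "patient_id"
  )
  m <- table(
    factor(j$outcome_a, levels = outcome_levels),
    factor(j$outcome_b, levels = outcome_levels)
  )
  m <- matrix(as.integer(m), 3, 3, dimnames = dimnames(m))
  names(dimnames(m)) <- labels
  types_of <- function(sup) {
    if (is.null(sup)) return(NA_character_)
    paste(unique(sup$type), collapse = ";")
  }
  disc <- j %>%
    filter(.data$outcome_a != .data$outcome_b) %>%
    mutate(
      types_a = if ("support_a" %in% names(j)) purrr::map_chr(.data$support_a, types_of) else NA_character_,
      types_b = if ("support_b" %in% names(j)) purrr::map_chr(.data$support_b, types_of) else NA_character_
    ) %>%
    select("patient_id", "outcome_a", "outcome_b", "types_a", "types_b")
  structure(
    list(matrix = m, n = nrow(j), labels = labels, discordant = disc),
    class = "pathway_concordance"
  )
}

#' Complete an outcome tibble to a full cohort
#'
#' Adds `outcome = "none"` rows for cohort patients absent from an outcome
#' tibble that lists only diagnosed patients.
#'
#' @param outcomes Outcome tibble with `patient_id`, `pathway`, `outcome`.
#' @param patient_ids Full cohort identifier vector.
#' @return Outcome tibble covering every patient.
#' @export
complete_outcomes <- function(outcomes, patient_ids) {
  missing_ids <- setdiff(patient_ids, outcomes$patient_id)
  if (length(missing_ids) == 0) return(outcomes)
  pw <- if (nrow(outcomes)) outcomes$pathway[1] else NA_character_
  empty_support <- if ("support" %in% names(outcomes)) {
    proto <- outcomes$support[[1]][0, , drop = FALSE]
    list(support = purrr::map(missing_ids, ~proto))
  } else NULL
  filler <- tibble(patient_id = missing_ids, pathway = pw, outcome = "none")
  if (!is.null(empty_support)) filler$support <- empty_support$support
  bind_rows(outcomes, filler) %>% arrange(.data$patient_id)
}

#' @method print pathway_concordance
#' @export
print.pathway_concordance <- function(x, ...) {
  cat(sprintf(
    "Concordance of diagnostic outcomes (%s rows vs %s columns), n = %d\n\n",
    x$labels[1], x$labels[2], x$n
  ))
  print(stats::addmargins(as.table(x$matrix)))
  if (nrow(x$discordant) > 0) {
    cat(sprintf("\n%d discordant patient(s):\n", nrow(x$discordant)))
    print(as.data.frame(x$discordant), row.names = FALSE)
  }
  invisible(x)
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Exact hypergeometric test; the two-sided p-value sums all tables with
#' point probability not exceeding the observed one. An all-zero table
#' yields p = 1 by convention.
#'
#' @param a,b,c,d Non-negative cell counts, row-wise
#'   (`matrix(c(a, b, c, d), 2, byrow = TRUE)`).
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return The p-value (numeric scalar).
#' @export
fisher_exact <- function(a, b, c, d, alternative = "two.sided") {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (a + b + c + d == 0) return(1)
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  stats::fisher.test(m, alternative = alternative)$p.value
}

#' Per-type diagnosis tallies
#'
#' Counts diagnosed patients by the variant type of their *primary*
#' supporting variant. For patients with several supporting variants the
#' primary is chosen by tier, then pathogenicity label, then lower
#' population allele frequency, then input order (so a deliberately ordered
#' support table, e.g. a published variant list, keeps its published
#' precedence). Each diagnosed patient is counted exactly once.
#'
#' @param outcomes Outcome tibble with `patient_id`, `outcome` and a
#'   `support` list-column whose elements carry `type`, `tier`, `label`,
#'   `pop_af`, `input_order`.
#' @param outcome_class Which outcome class to tally (default
#'   `"conclusive"`).
#' @return Tibble `type` (`snv`, `indel`, `cnv`, `str`, `mito`), `n`
#'   (zero-filled), summing to the number of tallied patients.
#' @export
tally_diagnoses <- function(outcomes, outcome_class = "conclusive") {
  type_levels <- c("snv", "indel", "cnv", "str", "mito")
  dx <- filter(as_tibble(outcomes), .data$outcome == outcome_class)
  primary <- purrr::map_chr(dx$support, function(s) {
    s <- as_tibble(s)
    if (nrow(s) == 0) return(NA_character_)
    if (!"input_order" %in% names(s)) s$input_order <- seq_len(nrow(s))
    if (!"tier" %in% names(s)) s$tier <- 1L
    if (!"pop_af" %in% names(s)) s$pop_af <- 0
    s %>%
      mutate(
        lr = label_rank(.data$label),
        af = tidyr::replace_na(.data$pop_af, 0)
      ) %>%
      arrange(.data$tier, .data$lr, .data$af, .data$input_order) %>%
      pull("type") %>%
      dplyr::first()
  })
  tibble(type = factor(primary[!is.na(primary)], levels = type_levels)) %>%
    count(.data$type, .drop = FALSE) %>%
    mutate(type = as.character(.data$type))
}
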