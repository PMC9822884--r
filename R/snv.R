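# Small-variant triage for patient-parent trios: genotype quality control,
# interpretation-scope restriction (exons plus a splice-region window),
# mode-of-inheritance segregation, compound-heterozygote detection and tiered
# prioritization.

#' Genotype quality control for trio records
#'
#' Applies deterministic depth and allele-fraction gates to each trio
#' genotype record and attaches machine-readable failure reasons. Gates
#' (all configurable via [triage_config()]): depth at least `min_dp` in
#' every member; child heterozygous ALT fraction within `het_vaf_range`;
#' homozygous/hemizygous ALT fraction at least `hom_vaf_min`; de novo
#' candidates (child het, both parents reference) additionally require both
#' parents' ALT fraction below `denovo_parent_vaf_max` at depth at least
#' `denovo_parent_min_dp`. Missing required fields yield reason
#' `missing_data`.
#'
#' @param variants Trio genotype tibble ([read_trio_vcf()] schema).
#' @param config A [triage_config()].
#' @return The input with logical `qc_pass` and character `qc_reasons`
#'   (`;`-separated reason codes, `""` when passing).
#' @export
genotype_qc <- function(variants, config = triage_config()) {
  v <- as_tibble(variants)
  n <- nrow(v)
  reasons <- vector("list", n)
  add <- function(idx, code) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], code)
  }

  dp_na <- is.na(v$dp_child) | is.na(v$dp_father) | is.na(v$dp_mother)
  vaf_c_na <- is.na(v$vaf_child)
  add(dp_na | vaf_c_na, "missing_data")

  low_dp <- !dp_na & (v$dp_child < config$min_dp |
    v$dp_father < config$min_dp | v$dp_mother < config$min_dp)
  add(low_dp, "low_depth")

  het <- v$gt_child == "het"
  hom <- v$gt_child %in% c("hom_alt", "hemi")
  bad_het <- het & !vaf_c_na &
    (v$vaf_child < config$het_vaf_range[1] | v$vaf_child > config$het_vaf_range[2])
  bad_hom <- hom & !vaf_c_na & v$vaf_child < config$hom_vaf_min
  add(bad_het | bad_hom, "allele_fraction")

  dn_cand <- het & v$gt_father == "hom_ref" & v$gt_mother == "hom_ref"
  par_vaf_na <- is.na(v$vaf_father) | is.na(v$vaf_mother)
  add(dn_cand & par_vaf_na, "missing_data")
  dn_support <- dn_cand & !par_vaf_na &
    (v$vaf_father >= config$denovo_parent_vaf_max |
      v$vaf_mother >= config$denovo_parent_vaf_max)
  add(dn_support, "parental_support")
  dn_dp <- dn_cand & !dp_na &
    (v$dp_father < config$denovo_parent_min_dp |
      v$dp_mother < config$denovo_parent_min_dp)
  add(dn_dp, "low_depth")

  v$qc_reasons <- vapply(reasons, function(r) {
    paste(unique(r), collapse = ";")
  }, character(1))
  v$qc_pass <- v$qc_reasons == ""
  v
}

#' Restrict variants to the interpretation scope
#'
#' A variant is in scope when its position lies inside an exon (coding or,
#' by default, also non-coding/UTR) or within `splice_window` bp of an exon
#' boundary. Deep intronic and intergenic positions are out of scope.
#' Variants on chromosomes absent from the gene models are out of scope with
#' a warning.
#'
#' @param variants Trio genotype tibble with `chrom`, `pos`.
#' @param gene_models Gene/exon model tibble ([read_gene_models()] schema).
#' @param config A [triage_config()] (`splice_window`, `include_noncoding`).
#' @return The input with logical `in_scope` and numeric `exon_distance`
#'   (0 inside an exon; otherwise distance in bp to the nearest exon
#'   boundary, `Inf` when no exon exists on that chromosome).
#' @export
in_scope <- function(variants, gene_models, config = triage_config()) {
  v <- as_tibble(variants)
  gm <- gene_models
  if (!config$include_noncoding) gm <- filter(gm, .data$coding)
  v$in_scope <- FALSE
  v$exon_distance <- Inf
  missing_chrom <- setdiff(unique(v$chrom), unique(gm$chrom))
  if (length(missing_chrom) > 0 && nrow(v) > 0) {
    warn(sprintf(
      "chromosome(s) absent from gene models: %s",
      paste(missing_chrom, collapse = ", ")
    ))
  }
  for (ch in intersect(unique(v$chrom), unique(gm$chrom))) {
    iv <- which(v$chrom == ch)
    ex <- filter(gm, .data$chrom == ch)
    q <- IRanges::IRanges(start = v$pos[iv], width = 1)
    s <- IRanges::IRanges(start = ex$start, end = ex$end)
    d <- as.data.frame(IRanges::distanceToNearest(q, s))
    inside <- IRanges::overlapsAny(q, s)
    dist <- rep(Inf, length(iv))
    # gap-based distance -> bp offset from the exon boundary (0 inside)
    dist[d$queryHits] <- d$distance + 1
    dist[inside] <- 0
    v$exon_distance[iv] <- dist
    v$in_scope[iv] <- dist <= config$splice_window
  }
  v
}

# ---- segregation -------------------------------------------------------------

#' Segregate trio genotypes by mode of inheritance
#'
#' Assigns inheritance modes from genotypes, child sex and chromosome alone:
#' \describe{
#'   \item{de_novo}{child heterozygous, both parents homozygous reference
#'     (on male X non-PAR: child hemizygous ALT, mother reference).}
#'   \item{homozygous}{child homozygous ALT, each parent carrying at least
#'     one ALT allele.}
#'   \item{hemizygous}{male child carrying an ALT allele on X outside the
#'     pseudoautosomal regions (genotype coerced to hemizygous).}
#' }
#' Compound heterozygotes are a pairwise property; see
#' [find_compound_hets()]. Inherited heterozygous variants carry their
#' parental `origin` (`paternal`, `maternal`, or `ambiguous` when both
#' parents carry). Child-ALT genotypes incompatible with the parents (e.g.
#' homozygous ALT with a homozygous-reference parent) are flagged
#' `mendelian_inconsistent`; a missing parental genotype suppresses the
#' modes that need that parent and flags `incomplete_segregation`.
#'
#' @param variants Trio genotype tibble.
#' @param pedigree Pedigree tibble ([read_pedigree()]), matched on
#'   `trio_id == child_id`.
#' @return The input plus `modes` (list-column, character vector per row),
#'   `origin`, and logical flags `mendelian_inconsistent`,
#'   `incomplete_segregation`.
#' @export
segregate_trio <- function(variants, pedigree) {
  v <- as_tibble(variants)
  v <- left_join(v,
    select(pedigree, trio_id = "child_id", "child_sex"),
    by = "trio_id"
  )
  male_x <- v$child_sex == "male" & is_x_nonpar(v$chrom, v$pos)

  f_car <- v$gt_father %in% c("het", "hom_alt", "hemi")
  m_car <- v$gt_mother %in% c("het", "hom_alt", "hemi")
  f_ref <- v$gt_father == "hom_ref"
  m_ref <- v$gt_mother == "hom_ref"
  f_miss <- v$gt_father == "missing"
  m_miss <- v$gt_mother == "missing"
  child_alt <- carries_alt(v$gt_child)

  n <- nrow(v)
  modes <- vector("list", n)
  origin <- rep("none", n)
  incons <- rep(FALSE, n)
  incomplete <- rep(FALSE, n)

  for (i in seq_len(n)) {
    if (!child_alt[i]) next
    m <- character(0)
    if (male_x[i]) {
      # male X non-PAR: single-copy; father does not transmit an X
      m <- c(m, "hemizygous")
      if (m_miss[i]) {
        incomplete[i] <- TRUE
      } else if (m_ref[i]) {
        m <- c(m, "de_novo")
        origin[i] <- "de_novo"
      } else {
        origin[i] <- "maternal"
      }
    } else {
      gc <- v$gt_child[i]
      if (gc == "het") {
        if (f_miss[i] || m_miss[i]) {
          incomplete[i] <- TRUE
          if (!f_miss[i] && f_car[i]) origin[i] <- "paternal"
          if (!m_miss[i] && m_car[i]) origin[i] <- "maternal"
        } else if (f_ref[i] && m_ref[i]) {
          m <- c(m, "de_novo")
          origin[i] <- "de_novo"
        } else if (f_car[i] && m_car[i]) {
          origin[i] <- "ambiguous"
        } else if (f_car[i]) {
          origin[i] <- "paternal"
        } else {
          origin[i] <- "maternal"
        }
      } else if (gc %in% c("hom_alt", "hemi")) {
        if (f_miss[i] || m_miss[i]) {
          incomplete[i] <- TRUE
        } else if (f_car[i] && m_car[i]) {
          m <- c(m, "homozygous")
          origin[i] <- "biparental"
        } else {
          # a hom-ref parent cannot have transmitted an ALT allele
          incons[i] <- TRUE
        }
      }
    }
    modes[[i]] <- m
  }
  v$modes <- modes
  v$origin <- origin
  v$mendelian_inconsistent <- incons
  v$incomplete_segregation <- incomplete
  select(v, -"child_sex")
}

# ---- compound heterozygotes --------------------------------------------------

#' Find candidate compound-heterozygous pairs
#'
#' Within each (trio, gene), pairs of child-heterozygous variants compatible
#' with one hit per parental haplotype: one variant of paternal and one of
#' maternal origin, or one de novo plus one inherited heterozygote. Pairs
#' whose two variants both derive from the same parent are never emitted.
#' When either member's origin is ambiguous (both parents carry it) the pair
#' is emitted with `certain = FALSE`.
#'
#' @param variants Output of [segregate_trio()] (QC- and scope-filtered).
#' @return Tibble of pairs: `trio_id`, `gene`, variant ids and origins of
#'   both members (`a` precedes `b` in genomic order), `certain`.
#' @export
find_compound_hets <- function(variants) {
  v <- as_tibble(variants) %>%
    filter(
      .data$gt_child == "het", !is.na(.data$gene),
      .data$origin %in% c("paternal", "maternal", "ambiguous", "de_novo")
    ) %>%
    mutate(var_id = variant_id(.data$chrom, .data$pos, .data$ref, .data$alt)) %>%
    arrange(.data$trio_id, .data$gene, .data$chrom, .data$pos, .data$alt)

  pair_ok <- function(oa, ob) {
    if (oa == "de_novo" && ob == "de_novo") return(c(FALSE, FALSE))
    if (oa == "de_novo" || ob == "de_novo") {
      return(c(TRUE, oa != "ambiguous" && ob != "ambiguous"))
    }
    sa <- if (oa == "ambiguous") c("paternal", "maternal") else oa
    sb <- if (ob == "ambiguous") c("paternal", "maternal") else ob
    trans <- ("paternal" %in% sa && "maternal" %in% sb) ||
      ("maternal" %in% sa && "paternal" %in% sb)
    c(trans, trans && oa != "ambiguous" && ob != "ambiguous")
  }

  out <- v %>%
    group_by(.data$trio_id, .data$gene) %>%
    dplyr::group_map(function(g, key) {
      if (nrow(g) < 2) return(NULL)
      idx <- utils::combn(nrow(g), 2)
      rows <- purrr::map(seq_len(ncol(idx)), function(j) {
        a <- idx[1, j]; b <- idx[2, j]
        ok <- pair_ok(g$origin[a], g$origin[b])
        if (!ok[1]) return(NULL)
        tibble(
          trio_id = key$trio_id, gene = key$gene,
          var_a = g$var_id[a], var_b = g$var_id[b],
          origin_a = g$origin[a], origin_b = g$origin[b],
          certain = ok[2]
        )
      })
      bind_rows(rows)
    }) %>%
    bind_rows()
  if (nrow(out) == 0) {
    return(tibble(
      trio_id = character(), gene = character(), var_a = character(),
      var_b = character(), origin_a = character(), origin_b = character(),
      certain = logical()
    ))
  }
  out
}

#' Canonical variant identifier
#' @param chrom,pos,ref,alt Site fields.
#' @return `chrom:pos:ref>alt` strings.
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  sprintf("%s:%d:%s>%s", chrom, as.integer(pos), ref, alt)
}

# ---- prioritization ----------------------------------------------------------

#' Tiered prioritization of segregated small variants
#'
#' Expands segregated variants into one candidate per inheritance call
#' (including compound-heterozygous pairs from [find_compound_hets()]),
#' applies per-mode population-frequency gates, assigns gene-class tiers and
#' orders candidates.
#'
#' Tiers: 1 = NDD-panel genes, 2 = other established disease genes,
#' 3 = candidate disease genes; variants in genes of class `other` are not
#' reported. Frequency gates: de novo and inherited-dominant candidates
#' require population AF at most `af_dominant`; homozygous, hemizygous and
#' compound-het candidates at most `af_recessive` and, when a population
#' homozygote count is supplied, at most `max_pop_hom` homozygotes. Within a
#' tier, candidates are ordered by pathogenicity label, then lower
#' population frequency, then (chrom, pos, alt) lexicographically.
#'
#' Inherited heterozygous P/LP variants in autosomal-dominant genes are
#' reported as `inherited_dominant_candidate` only when
#' `include_inherited_dominant` is set.
#'
#' @param variants Output of [segregate_trio()], already QC/scope filtered.
#' @param gene_models Gene model tibble (supplies `gene_class`, `moi`).
#' @param config A [triage_config()].
#' @return Candidate tibble: one row per (variant, mode), with `tier`,
#'   `mode`, `partner_id` (compound hets), ordering rank `priority` within
#'   trio, and the originating annotation columns.
#' @export
prioritize_small_variants <- function(variants, gene_models, config = triage_config()) {
  v <- as_tibble(variants)
  gene_info <- distinct(gene_models, .data$gene, .data$gene_class, .data$moi)
  v <- left_join(v, gene_info, by = "gene") %>%
    mutate(
      gene_class = if_else(is.na(.data$gene_class), "other", .data$gene_class),
      var_id = variant_id(.data$chrom, .data$pos, .data$ref, .data$alt)
    )

  base <- v %>%
    mutate(mode_set = .data$modes) %>%
    tidyr::unnest_longer("mode_set", values_to = "mode") %>%
    filter(!is.na(.data$mode)) %>%
    mutate(partner_id = NA_character_)

  if (config$include_inherited_dominant) {
    inh_dom <- v %>%
      filter(
        .data$gt_child == "het",
        .data$origin %in% c("paternal", "maternal", "ambiguous"),
        .data$class_label %in% c("P", "LP"),
        .data$moi %in% "AD"
      ) %>%
      mutate(mode = "inherited_dominant_candidate", partner_id = NA_character_)
    base <- bind_rows(base, inh_dom)
  }

  ch <- find_compound_hets(v)
  if (nrow(ch) > 0) {
    ch_long <- bind_rows(
      select(ch, "trio_id", "gene", var_id = "var_a", partner_id = "var_b"),
      select(ch, "trio_id", "gene", var_id = "var_b", partner_id = "var_a")
    ) %>% distinct()
    ch_rows <- inner_join(v, ch_long, by = c("trio_id", "gene", "var_id")) %>%
      mutate(mode = "compound_het")
    base <- bind_rows(base, ch_rows)
  }

  af <- if_else(is.na(base$pop_af), 0, base$pop_af) # absent from databases = rare
  gate <- case_when(
    base$mode %in% c("de_novo", "inherited_dominant_candidate") ~
      af <= config$af_dominant,
    base$mode %in% c("homozygous", "hemizygous", "compound_het") ~
      af <= config$af_recessive &
        (is.na(base$n_hom) | base$n_hom <= config$max_pop_hom),
    TRUE ~ FALSE
  )
  tier_map <- c(ndd_panel = 1L, disease_gene = 2L, candidate_gene = 3L)

  base %>%
    filter(gate, .data$gene_class %in% names(tier_map)) %>%
    mutate(
      tier = unname(tier_map[.data$gene_class]),
      pop_af_eff = if_else(is.na(.data$pop_af), 0, .data$pop_af),
      label_ord = label_rank(.data$class_label)
    ) %>%
    distinct(.data$trio_id, .data$var_id, .data$mode, .keep_all = TRUE) %>%
    arrange(
      .data$trio_id, .data$tier, .data$label_ord, .data$pop_af_eff,
      .data$chrom, .data$pos, .data$alt
    ) %>%
    group_by(.data$trio_id) %>%
    mutate(priority = row_number()) %>%
    ungroup() %>%
    select(-"label_ord", -"pop_af_eff", -"modes", -dplyr::any_of("mode_set")) %>%
    mutate(type = if_else(
      nchar(.data$ref) == 1 & nchar(.data$alt) == 1, "snv", "indel"
    ), .after = "var_id")
}
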