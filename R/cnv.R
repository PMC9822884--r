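# CNV triage: inheritance filtering with reciprocal-overlap parental
# matching, the three-category assessment rule (panel gene > exonic disease
# gene > large exonic), and CNV-SNV compound-heterozygote detection in
# autosomal-recessive genes.

#' Reciprocal overlap of two interval sets
#'
#' Fraction of overlap relative to the *longer* of the two intervals, i.e.
#' the largest `t` such that the overlap covers at least `t` of both.
#'
#' @param start1,end1,start2,end2 1-based inclusive coordinates (vectors).
#' @return Numeric vector in `[0, 1]`.
#' @export
reciprocal_overlap <- function(start1, end1, start2, end2) {
  ov <- pmin(end1, end2) - pmax(start1, start2) + 1
  ov <- pmax(ov, 0)
  ov / pmax(end1 - start1 + 1, end2 - start2 + 1)
}

cnv_id <- function(chrom, start, end, svtype) {
  sprintf("%s:%d-%d:%s", chrom, as.integer(start), as.integer(end), svtype)
}

#' Collapse duplicate CNV calls from multiple callers
#'
#' Depth-based and paired-end/split-read callers frequently report the same
#' event with slightly different breakpoints. Calls of the same type in the
#' same trio with reciprocal overlap at least `caller_merge_overlap` are
#' collapsed, keeping the highest-quality record.
#'
#' @param cnvs CNV call tibble ([read_sv_calls()] schema).
#' @param config A [triage_config()].
#' @return Deduplicated CNV tibble.
#' @export
merge_cnv_callers <- function(cnvs, config = triage_config()) {
  cnvs %>%
    arrange(dplyr::desc(tidyr::replace_na(.data$qual, -Inf))) %>%
    group_by(.data$trio_id, .data$chrom, .data$svtype) %>%
    dplyr::group_map(function(g, key) {
      keep <- logical(nrow(g))
      for (i in seq_len(nrow(g))) {
        dup <- FALSE
        for (j in which(keep)) {
          if (reciprocal_overlap(g$start[i], g$end[i], g$start[j], g$end[j]) >=
            config$caller_merge_overlap) {
            dup <- TRUE
            break
          }
        }
        keep[i] <- !dup
      }
      bind_cols(key, g[keep, , drop = FALSE])
    }) %>%
    bind_rows() %>%
    arrange(.data$trio_id, .data$chrom, .data$start, .data$end)
}

#' Segregate CNV calls by mode of inheritance
#'
#' A parent "carries" a child event when any CNV call of the same type with
#' that parent marked present (including the child's own record) has
#' reciprocal overlap of at least `reciprocal_overlap` with it. Modes:
#' `de_novo` (child present, neither parent carries; suppressed and flagged
#' when a parental status is unknown), `homozygous` (deletion with copy
#' number 0 and both parents carrying), `hemizygous` (male child, X
#' non-PAR), `inherited` otherwise (with `carrier_parent` recording which).
#'
#' @param cnvs CNV call tibble for one or more trios.
#' @param pedigree Pedigree tibble.
#' @param config A [triage_config()].
#' @return The child-present calls with `modes` (list-column),
#'   `carrier_parent` (`paternal`/`maternal`/`both`/`none`/`unknown`) and
#'   logical `parental_status_unknown`.
#' @export
segregate_cnv <- function(cnvs, pedigree, config = triage_config()) {
  c0 <- as_tibble(cnvs) %>%
    left_join(select(pedigree, trio_id = "child_id", "child_sex"), by = "trio_id")
  child <- filter(c0, .data$carrier_child == "present")
  if (nrow(child) == 0) {
    return(mutate(select(child, -"child_sex"),
      modes = list(), carrier_parent = character(),
      parental_status_unknown = logical()
    ))
  }

  parent_carries <- function(ev, parent_col) {
    cand <- c0[c0$trio_id == ev$trio_id & c0$chrom == ev$chrom &
      c0$svtype == ev$svtype, , drop = FALSE]
    st <- cand[[parent_col]]
    ro <- reciprocal_overlap(ev$start, ev$end, cand$start, cand$end)
    hit <- ro >= config$reciprocal_overlap
    if (any(hit & st == "present")) return("present")
    # unknown status on an overlapping record leaves carriage unresolved
    if (any(hit & st == "unknown") ||
      (nrow(cand) > 0 && all(st[hit] == "unknown") && any(hit))) {
      if (any(hit & st == "unknown")) return("unknown")
    }
    "absent"
  }

  n <- nrow(child)
  modes <- vector("list", n)
  carrier <- character(n)
  unknown_flag <- logical(n)
  for (i in seq_len(n)) {
    ev <- child[i, ]
    f <- parent_carries(ev, "carrier_father")
    m <- parent_carries(ev, "carrier_mother")
    unknown_flag[i] <- f == "unknown" || m == "unknown"
    carrier[i] <- case_when(
      f == "present" & m == "present" ~ "both",
      f == "present" ~ "paternal",
      m == "present" ~ "maternal",
      unknown_flag[i] ~ "unknown",
      TRUE ~ "none"
    )
    mm <- character(0)
    if (f == "absent" && m == "absent") mm <- c(mm, "de_novo")
    if (ev$svtype == "DEL" && !is.na(ev$copy_number) && ev$copy_number == 0 &&
      f == "present" && m == "present") {
      mm <- c(mm, "homozygous")
    }
    if (ev$child_sex == "male" && is_x_nonpar(ev$chrom, ev$start)) {
      mm <- c(mm, "hemizygous")
    }
    if (length(mm) == 0 && carrier[i] %in% c("paternal", "maternal", "both")) {
      mm <- "inherited"
    }
    modes[[i]] <- mm
  }
  child %>%
    mutate(
      modes = modes, carrier_parent = carrier,
      parental_status_unknown = unknown_flag
    ) %>%
    select(-"child_sex")
}

#' Three-category CNV assessment
#'
#' Assigns each CNV the highest-priority satisfied category:
#' \enumerate{
#'   \item `panel_gene` — any overlap with an NDD-panel gene (intronic-only
#'     overlap counts unless `panel_any_overlap = FALSE`);
#'   \item `exonic_disease_gene` — at least 1 bp overlap with an exon
#'     (coding or non-coding) of an established disease gene;
#'   \item `exonic_large` — at least 1 bp exon overlap with any gene and
#'     length strictly greater than `cnv_large_min` (default 10 kb);
#'   \item `none` otherwise.
#' }
#'
#' @param cnvs CNV tibble.
#' @param gene_models Gene model tibble.
#' @param config A [triage_config()].
#' @return The input plus `category`, `genes` (`;`-separated overlapped
#'   genes, exonic first), `gene` (highest-priority overlapped gene), and
#'   `n_exons` (exons overlapped in that gene).
#' @export
categorize_cnv <- function(cnvs, gene_models, config = triage_config()) {
  cv <- as_tibble(cnvs)
  gm <- gene_models
  gene_info <- distinct(gm, .data$gene, .data$gene_class)
  n <- nrow(cv)
  category <- rep("none", n)
  genes_str <- rep("", n)
  top_gene <- rep(NA_character_, n)
  n_exons <- rep(0L, n)

  gene_span <- gm %>%
    group_by(.data$gene, .data$chrom, .data$gene_class) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")

  for (i in seq_len(n)) {
    ch <- cv$chrom[i]
    s <- cv$start[i]
    e <- cv$end[i]
    len <- e - s + 1
    ex <- gm[gm$chrom == ch & gm$start <= e & gm$end >= s, , drop = FALSE]
    sp <- gene_span[gene_span$chrom == ch & gene_span$start <= e &
      gene_span$end >= s, , drop = FALSE]
    exon_counts <- if (nrow(ex)) dplyr::count(ex, .data$gene, .data$gene_class) else
      tibble(gene = character(), gene_class = character(), n = integer())

    panel_hit <- if (config$panel_any_overlap) {
      sp$gene[sp$gene_class == "ndd_panel"]
    } else {
      exon_counts$gene[exon_counts$gene_class == "ndd_panel"]
    }
    disease_hit <- exon_counts$gene[exon_counts$gene_class == "disease_gene"]
    any_exon_hit <- exon_counts$gene

    if (length(panel_hit) > 0) {
      category[i] <- "panel_gene"
      top_gene[i] <- sort(panel_hit)[1]
    } else if (length(disease_hit) > 0) {
      category[i] <- "exonic_disease_gene"
      top_gene[i] <- sort(disease_hit)[1]
    } else if (length(any_exon_hit) > 0 && len > config$cnv_large_min) {
      category[i] <- "exonic_large"
      top_gene[i] <- sort(any_exon_hit)[1]
    }
    genes_str[i] <- paste(sort(unique(c(exon_counts$gene, sp$gene))), collapse = ";")
    if (!is.na(top_gene[i])) {
      k <- exon_counts$n[exon_counts$gene == top_gene[i]]
      n_exons[i] <- if (length(k)) k else 0L
    }
  }
  cv %>% mutate(
    category = category, genes = genes_str, gene = top_gene, n_exons = n_exons
  )
}

#' CNV-SNV compound heterozygotes in recessive genes
#'
#' In autosomal-recessive genes, a single-allele (heterozygous) deletion can
#' form a biallelic genotype with a heterozygous small variant on the other
#' haplotype. A pair is reported when the small variant is inherited from
#' the parent *not* carrying the deletion, or the deletion is de novo. A
#' small variant physically inside the deletion and phased to the same
#' parental haplotype as the deletion is never paired (it would lie on the
#' deleted allele).
#'
#' @param cnvs Output of [segregate_cnv()] (needs `carrier_parent`, `modes`),
#'   typically after [categorize_cnv()].
#' @param variants Output of [segregate_trio()] (needs `origin`).
#' @param gene_models Gene model tibble (supplies `moi`).
#' @return Tibble of pairs: `trio_id`, `gene`, `cnv_id`, `var_id`, origins,
#'   `certain` (FALSE when the SNV origin is ambiguous).
#' @export
find_cnv_snv_compound_het <- function(cnvs, variants, gene_models) {
  gene_info <- distinct(gene_models, .data$gene, .data$moi)
  gm_ar <- filter(gene_info, .data$moi == "AR")
  gene_span <- gene_models %>%
    dplyr::semi_join(gm_ar, by = "gene") %>%
    group_by(.data$gene, .data$chrom) %>%
    summarise(g_start = min(.data$start), g_end = max(.data$end), .groups = "drop")

  dels <- as_tibble(cnvs) %>%
    filter(.data$svtype == "DEL") %>%
    mutate(is_hom = purrr::map_lgl(.data$modes, ~ "homozygous" %in% .x)) %>%
    filter(!.data$is_hom) %>%
    mutate(
      cnv_origin = case_when(
        purrr::map_lgl(.data$modes, ~ "de_novo" %in% .x) ~ "de_novo",
        .data$carrier_parent %in% c("paternal", "maternal") ~ .data$carrier_parent,
        TRUE ~ "unknown"
      )
    ) %>%
    filter(.data$cnv_origin != "unknown")
  if (nrow(dels) == 0 || nrow(variants) == 0) {
    return(tibble(
      trio_id = character(), gene = character(), cnv_id = character(),
      var_id = character(), cnv_origin = character(), snv_origin = character(),
      certain = logical()
    ))
  }

  # deletions overlapping an AR gene (any prior gene assignment is replaced)
  dels <- select(dels, -dplyr::any_of(c("gene", "genes", "n_exons", "category")))
  dels <- inner_join(dels, gene_span,
    by = "chrom", relationship = "many-to-many"
  ) %>%
    filter(.data$start <= .data$g_end, .data$end >= .data$g_start) %>%
    mutate(id = cnv_id(.data$chrom, .data$start, .data$end, .data$svtype))

  snv <- as_tibble(variants) %>%
    filter(
      .data$gt_child == "het",
      .data$origin %in% c("paternal", "maternal", "ambiguous", "de_novo")
    ) %>%
    dplyr::semi_join(gm_ar, by = "gene") %>%
    mutate(var_id = variant_id(.data$chrom, .data$pos, .data$ref, .data$alt))

  pairs <- inner_join(
    select(dels, "trio_id",
      gene = "gene", id = "id", cnv_start = "start",
      cnv_end = "end", "cnv_origin"
    ),
    select(snv, "trio_id", "gene", "var_id", "pos", snv_origin = "origin"),
    by = c("trio_id", "gene"), relationship = "many-to-many"
  ) %>%
    mutate(
      inside = .data$pos >= .data$cnv_start & .data$pos <= .data$cnv_end,
      same_hap = .data$inside & .data$snv_origin == .data$cnv_origin,
      trans_possible = case_when(
        .data$cnv_origin == "de_novo" ~ .data$snv_origin != "de_novo",
        .data$snv_origin == "de_novo" ~ TRUE,
        .data$snv_origin == "ambiguous" ~ TRUE,
        TRUE ~ .data$snv_origin != .data$cnv_origin
      )
    ) %>%
    filter(.data$trans_possible, !.data$same_hap) %>%
    mutate(certain = .data$snv_origin != "ambiguous") %>%
    select(
      "trio_id", "gene",
      cnv_id = "id", "var_id", "cnv_origin", "snv_origin", "certain"
    )
  pairs
}
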