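test_that("reciprocal overlap is symmetric and bounded", {
  expect_equal(reciprocal_overlap(1, 100, 1, 100), 1)
  expect_equal(reciprocal_overlap(1, 100, 51, 150), 0.5)
  expect_equal(reciprocal_overlap(1, 100, 200, 300), 0)
  expect_equal(
    reciprocal_overlap(1, 100, 41, 240),
    reciprocal_overlap(41, 240, 1, 100)
  )
})

test_that("CNV segregation assigns de novo, homozygous and inherited", {
  ped <- toy_pedigree()
  cfg <- triage_config() # 50% reciprocal overlap

  dn <- segregate_cnv(toy_cnv(), ped, cfg)
  expect_equal(dn$modes[[1]], "de_novo")
  expect_equal(dn$carrier_parent, "none")

  hom <- segregate_cnv(
    toy_cnv(copy_number = 0, carrier_father = "present",
      carrier_mother = "present"),
    ped, cfg
  )
  expect_true("homozygous" %in% hom$modes[[1]])

  # father carries an overlapping DEL at 60% reciprocal overlap -> inherited
  child <- toy_cnv(start = 10000, end = 19999)
  pat <- toy_cnv(start = 14000, end = 19999 + 2000,
    carrier_child = "absent", carrier_father = "present")
  expect_gte(reciprocal_overlap(10000, 19999, 14000, 21999), 0.5)
  inh <- segregate_cnv(dplyr::bind_rows(child, pat), ped, cfg)
  expect_equal(inh$modes[[1]], "inherited")
  expect_equal(inh$carrier_parent[1], "paternal")

  # below the 50% threshold the same event is de novo
  pat2 <- toy_cnv(start = 18000, end = 40000,
    carrier_child = "absent", carrier_father = "present")
  dn2 <- segregate_cnv(dplyr::bind_rows(child, pat2), ped, cfg)
  expect_equal(dn2$modes[[1]], "de_novo")
})

test_that("unknown parental status suppresses de novo and flags the call", {
  ped <- toy_pedigree()
  got <- segregate_cnv(toy_cnv(carrier_father = "unknown"), ped, triage_config())
  expect_false("de_novo" %in% got$modes[[1]])
  expect_true(got$parental_status_unknown[1])
})

test_that("male X non-PAR CNVs are hemizygous", {
  ped <- toy_pedigree(sex = "male")
  got <- segregate_cnv(
    toy_cnv(chrom = "X", start = 5e6, end = 5e6 + 5000), ped, triage_config()
  )
  expect_true("hemizygous" %in% got$modes[[1]])
})

test_that("CNV categories follow the three-rule priority", {
  gm <- toy_gene_models()
  cfg <- triage_config()
  got <- categorize_cnv(dplyr::bind_rows(
    # overlaps panel gene GENEA exons: panel_gene
    toy_cnv(start = 4000, end = 9335),
    # intronic-only overlap of the panel gene still fires rule 1
    toy_cnv(start = 6000, end = 8000),
    # overlaps only the non-coding exon 3 of disease gene GENEB
    toy_cnv(chrom = "2", start = 39900, end = 39900 + 36232 - 1),
    # 15 kb over an exon of an 'other'-class gene: exonic_large
    toy_cnv(chrom = "3", start = 500, end = 15499),
    # 5 kb over the same exon: too small for rule 3
    toy_cnv(chrom = "3", start = 500, end = 5499),
    # intergenic
    toy_cnv(chrom = "3", start = 100000, end = 130000)
  ), gm, cfg)
  expect_equal(got$category, c(
    "panel_gene", "panel_gene", "exonic_disease_gene",
    "exonic_large", "none", "none"
  ))
  expect_equal(got$gene[1], "GENEA")
  expect_equal(got$n_exons[1], 2)

  # with panel_any_overlap = FALSE the intronic-only call drops to none
  strict <- categorize_cnv(toy_cnv(start = 6000, end = 8000), gm,
    triage_config(panel_any_overlap = FALSE))
  expect_equal(strict$category, "none")

  # ">10 kb" is strict: exactly 10 kb does not fire rule 3
  ten <- categorize_cnv(toy_cnv(chrom = "3", start = 1000, end = 11000 - 1),
    gm, cfg)
  expect_equal(ten$category, "none")
})

test_that("categorization equals a brute-force interval oracle on random models", {
  cfg <- triage_config()
  withr::with_seed(1234, {
    classes <- c("ndd_panel", "disease_gene", "candidate_gene", "other")
    for (rep in 1:40) {
      ng <- sample(2:5, 1)
      gm <- dplyr::bind_rows(lapply(seq_len(ng), function(g) {
        n_ex <- sample(1:4, 1)
        s <- sort(sample(1:200, n_ex)) * 100
        tibble::tibble(
          gene = paste0("G", g), chrom = "1",
          start = s, end = s + sample(50:500, n_ex, replace = TRUE),
          coding = sample(c(TRUE, FALSE), n_ex, replace = TRUE, prob = c(.8, .2)),
          gene_class = sample(classes, 1), moi = "AD"
        )
      }))
      gm <- triotriage:::validate_gene_models(gm)
      cnvs <- dplyr::bind_rows(lapply(1:25, function(i) {
        s <- sample(1:20000, 1)
        toy_cnv(start = s, end = s + sample(c(100, 5000, 15000, 30000), 1))
      }))
      got <- categorize_cnv(cnvs, gm, cfg)

      for (i in seq_len(nrow(cnvs))) {
        ov <- gm$start <= cnvs$end[i] & gm$end >= cnvs$start[i]
        genes_any <- unique(gm$gene[ov])
        # full gene span overlap for rule 1
        spans <- dplyr::summarise(dplyr::group_by(gm, gene, gene_class),
          s = min(start), e = max(end), .groups = "drop")
        span_ov <- spans$s <= cnvs$end[i] & spans$e >= cnvs$start[i]
        panel <- any(span_ov & spans$gene_class == "ndd_panel")
        dis_ex <- any(ov & gm$gene_class == "disease_gene")
        len <- cnvs$end[i] - cnvs$start[i] + 1
        large <- length(genes_any) > 0 && len > cfg$cnv_large_min
        want <- if (panel) "panel_gene" else if (dis_ex) "exonic_disease_gene"
          else if (large) "exonic_large" else "none"
        expect_equal(got$category[i], want,
          label = sprintf("rep %d cnv %d", rep, i))
      }
    }
  })
})

test_that("every category assignment is unique and total", {
  gm <- toy_gene_models()
  withr::with_seed(7, {
    cnvs <- dplyr::bind_rows(lapply(1:50, function(i) {
      s <- sample(1:50000, 1)
      toy_cnv(chrom = sample(c("1", "2", "3"), 1), start = s,
        end = s + sample(100:40000, 1))
    }))
  })
  got <- categorize_cnv(cnvs, gm, triage_config())
  expect_true(all(got$category %in%
    c("panel_gene", "exonic_disease_gene", "exonic_large", "none")))
  expect_equal(length(got$category), nrow(cnvs))
})

test_that("CNV-SNV compound heterozygotes pair in trans in recessive genes", {
  gm <- toy_gene_models() # GENEB on chr2 is AR
  ped <- toy_pedigree()
  cfg <- triage_config()

  del_pat <- segregate_cnv(dplyr::bind_rows(
    toy_cnv(chrom = "2", start = 500, end = 21000),
    toy_cnv(chrom = "2", start = 500, end = 21000,
      carrier_child = "absent", carrier_father = "present")
  ), ped, cfg)
  snv_mat <- segregate_trio(
    toy_variant(chrom = "2", pos = 40100, gene = "GENEB",
      gt_mother = "het", vaf_mother = 0.5, class_label = "LP"),
    ped
  )
  got <- find_cnv_snv_compound_het(del_pat, snv_mat, gm)
  expect_equal(nrow(got), 1)
  expect_equal(got$cnv_origin, "paternal")
  expect_equal(got$snv_origin, "maternal")

  # paternal DEL + paternal SNV: no pair
  snv_pat <- segregate_trio(
    toy_variant(chrom = "2", pos = 40100, gene = "GENEB",
      gt_father = "het", vaf_father = 0.5),
    ped
  )
  expect_equal(nrow(find_cnv_snv_compound_het(del_pat, snv_pat, gm)), 0)

  # de novo DEL + maternal VUS: pair
  del_dn <- segregate_cnv(toy_cnv(chrom = "2", start = 500, end = 21000),
    ped, cfg)
  got_dn <- find_cnv_snv_compound_het(del_dn, snv_mat, gm)
  expect_equal(nrow(got_dn), 1)

  # SNV inside the DEL on the same parental haplotype: never paired
  snv_in_del <- segregate_trio(
    toy_variant(chrom = "2", pos = 20100, gene = "GENEB",
      gt_father = "het", vaf_father = 0.5),
    ped
  )
  expect_equal(nrow(find_cnv_snv_compound_het(del_pat, snv_in_del, gm)), 0)

  # an AD gene never produces CNV-SNV pairs
  del_a <- segregate_cnv(toy_cnv(chrom = "1", start = 500, end = 10000),
    ped, cfg)
  snv_a <- segregate_trio(
    toy_variant(pos = 5100, gt_mother = "het", vaf_mother = 0.5), ped)
  expect_equal(nrow(find_cnv_snv_compound_het(del_a, snv_a, gm)), 0)
})

test_that("duplicate caller records collapse to the higher-quality call", {
  cfg <- triage_config() # 80% merge overlap
  both <- dplyr::bind_rows(
    toy_cnv(start = 10000, end = 20000, qual = 50, caller = "depth_based"),
    toy_cnv(start = 10100, end = 20050, qual = 70,
      caller = "paired_end_split_read"),
    toy_cnv(start = 50000, end = 60000, qual = 40)
  )
  got <- merge_cnv_callers(both, cfg)
  expect_equal(nrow(got), 2)
  expect_equal(got$caller[got$start < 30000], "paired_end_split_read")
})
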