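test_that("genotype QC passes clean trios and attaches reason codes", {
  cfg <- triage_config()
  ok <- genotype_qc(toy_variant(), cfg)
  expect_true(ok$qc_pass)
  expect_equal(ok$qc_reasons, "")

  # de novo candidate with paternal ALT support fails parental_support
  bad_parent <- genotype_qc(toy_variant(vaf_father = 0.20), cfg)
  expect_false(bad_parent$qc_pass)
  expect_match(bad_parent$qc_reasons, "parental_support")

  low <- genotype_qc(toy_variant(dp_child = 4), cfg)
  expect_false(low$qc_pass)
  expect_match(low$qc_reasons, "low_depth")

  miss <- genotype_qc(toy_variant(vaf_child = NA_real_), cfg)
  expect_false(miss$qc_pass)
  expect_match(miss$qc_reasons, "missing_data")

  skew <- genotype_qc(toy_variant(vaf_child = 0.15), cfg)
  expect_match(skew$qc_reasons, "allele_fraction")
})

test_that("scope covers exons, UTR exons and the splice window boundary", {
  gm <- toy_gene_models()
  cfg <- triage_config() # splice_window 8
  # GENEA exon 1 ends at 1200: intronic offsets 5, 8, 9
  v <- dplyr::bind_rows(
    toy_variant(pos = 1100), # inside exon
    toy_variant(pos = 1205), # 5 bp into intron
    toy_variant(pos = 1208), # exactly 8 bp
    toy_variant(pos = 1209), # 9 bp: out
    toy_variant(chrom = "2", pos = 40100, gene = "GENEB"), # non-coding exon
    toy_variant(pos = 3000) # deep intronic
  )
  got <- in_scope(v, gm, cfg)
  expect_equal(got$in_scope, c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(got$exon_distance[1:4], c(0, 5, 8, 9))
})

test_that("scope is monotone in the splice window", {
  gm <- toy_gene_models()
  withr::with_seed(42, {
    v <- toy_variant()[rep(1, 200), ]
    v$pos <- sample(500:12000, 200)
    prev <- rep(FALSE, 200)
    for (w in c(0, 2, 8, 20, 50)) {
      cur <- in_scope(v, gm, triage_config(splice_window = w))$in_scope
      expect_true(all(cur[prev]), info = sprintf("window %d", w))
      prev <- cur
    }
  })
})

test_that("a chromosome absent from the models is out of scope with a warning", {
  gm <- toy_gene_models()
  expect_warning(
    got <- in_scope(toy_variant(chrom = "7"), gm, triage_config()),
    "absent"
  )
  expect_false(got$in_scope)
})

# independent truth table over all 27 autosomal trio genotype combinations
autosomal_truth_table <- function() {
  g <- expand.grid(child = 0:2, father = 0:2, mother = 0:2)
  g$de_novo <- g$child == 1 & g$father == 0 & g$mother == 0
  g$homozygous <- g$child == 2 & g$father >= 1 & g$mother >= 1
  g$inconsistent <- g$child == 2 & (g$father == 0 | g$mother == 0)
  g$origin <- with(g, ifelse(child != 1, ifelse(g$homozygous, "biparental", "none"),
    ifelse(father == 0 & mother == 0, "de_novo",
      ifelse(father >= 1 & mother >= 1, "ambiguous",
        ifelse(father >= 1, "paternal", "maternal")
      )
    )
  ))
  g
}

test_that("segregation agrees with the 27-state brute-force truth table", {
  tt <- autosomal_truth_table()
  ped <- toy_pedigree()
  v <- dplyr::bind_rows(lapply(seq_len(nrow(tt)), function(i) {
    toy_variant(
      pos = 1000 + i,
      gt_child = gt_from_count(tt$child[i]),
      gt_father = gt_from_count(tt$father[i]),
      gt_mother = gt_from_count(tt$mother[i])
    )
  }))
  got <- segregate_trio(v, ped)
  for (i in seq_len(nrow(tt))) {
    modes <- got$modes[[i]]
    lab <- sprintf("c=%d f=%d m=%d", tt$child[i], tt$father[i], tt$mother[i])
    expect_equal("de_novo" %in% modes, tt$de_novo[i], label = lab)
    expect_equal("homozygous" %in% modes, tt$homozygous[i], label = lab)
    expect_equal(got$mendelian_inconsistent[i], tt$inconsistent[i], label = lab)
    if (tt$child[i] > 0) {
      expect_equal(got$origin[i], tt$origin[i], label = lab)
    }
  }
})

test_that("male X non-PAR genotypes segregate as hemizygous", {
  ped <- toy_pedigree(sex = "male")
  v <- dplyr::bind_rows(
    toy_variant(chrom = "X", pos = 5e6 + 10, gene = "GENEX",
      gt_child = "hemi", gt_father = "hom_ref", gt_mother = "het"),
    toy_variant(chrom = "X", pos = 5e6 + 20, gene = "GENEX",
      gt_child = "hemi", gt_father = "hom_ref", gt_mother = "hom_ref"),
    # PAR1 position is autosomal-like
    toy_variant(chrom = "X", pos = 70000, gt_child = "het",
      gt_father = "hom_ref", gt_mother = "hom_ref")
  )
  got <- segregate_trio(v, ped)
  expect_equal(got$modes[[1]], "hemizygous")
  expect_equal(got$origin[1], "maternal")
  expect_setequal(got$modes[[2]], c("hemizygous", "de_novo"))
  expect_equal(got$modes[[3]], "de_novo") # PAR treated as autosomal

  # female child on X: autosomal rules
  gotf <- segregate_trio(v[1, ], toy_pedigree(sex = "female"))
  expect_false("hemizygous" %in% gotf$modes[[1]])
})

test_that("missing parental genotypes suppress modes and flag the variant", {
  ped <- toy_pedigree()
  v <- toy_variant(gt_father = "missing")
  got <- segregate_trio(v, ped)
  expect_equal(got$modes[[1]], character(0))
  expect_true(got$incomplete_segregation[1])
})

# ---- compound heterozygotes --------------------------------------------------

# independent oracle: origin from raw parental genotypes, pairing by the
# trans rule (one paternal + one maternal assignment must exist, or one
# de novo + one inherited; never two de novos)
comphet_oracle <- function(vars) {
  origin_of <- function(f, m) {
    if (f == 0 && m == 0) return("de_novo")
    if (f >= 1 && m >= 1) return("ambiguous")
    if (f >= 1) return("paternal")
    "maternal"
  }
  o <- mapply(origin_of, vars$father, vars$mother)
  pairs <- list()
  if (nrow(vars) >= 2) {
    for (a in seq_len(nrow(vars) - 1)) {
      for (b in (a + 1):nrow(vars)) {
        oa <- o[a]
        ob <- o[b]
        valid <- if (oa == "de_novo" && ob == "de_novo") {
          FALSE
        } else if (oa == "de_novo" || ob == "de_novo") {
          TRUE
        } else {
          sa <- if (oa == "ambiguous") c("paternal", "maternal") else oa
          sb <- if (ob == "ambiguous") c("paternal", "maternal") else ob
          ("paternal" %in% sa && "maternal" %in% sb) ||
            ("maternal" %in% sa && "paternal" %in% sb)
        }
        if (valid) pairs[[length(pairs) + 1]] <- c(a, b)
      }
    }
  }
  pairs
}

test_that("compound-het pairing matches the spec archetypes", {
  ped <- toy_pedigree()
  mk <- function(pos, f, m) {
    toy_variant(pos = pos, gt_child = "het",
      gt_father = gt_from_count(f), gt_mother = gt_from_count(m))
  }
  # paternal + maternal -> one pair
  got <- find_compound_hets(segregate_trio(
    dplyr::bind_rows(mk(1001, 1, 0), mk(1002, 0, 1)), ped))
  expect_equal(nrow(got), 1)
  expect_true(got$certain)

  # both paternal -> no pair
  got2 <- find_compound_hets(segregate_trio(
    dplyr::bind_rows(mk(1001, 1, 0), mk(1002, 1, 0)), ped))
  expect_equal(nrow(got2), 0)

  # de novo + maternal het -> one pair
  got3 <- find_compound_hets(segregate_trio(
    dplyr::bind_rows(mk(1001, 0, 0), mk(1002, 0, 1)), ped))
  expect_equal(nrow(got3), 1)

  # two de novos -> no pair
  got4 <- find_compound_hets(segregate_trio(
    dplyr::bind_rows(mk(1001, 0, 0), mk(1002, 0, 0)), ped))
  expect_equal(nrow(got4), 0)
})

test_that("compound-het detection equals the enumeration oracle on random gene sets", {
  ped <- toy_pedigree()
  withr::with_seed(99, {
    for (rep in 1:60) {
      nv <- sample(2:6, 1)
      vars <- data.frame(
        father = sample(0:2, nv, replace = TRUE),
        mother = sample(0:2, nv, replace = TRUE)
      )
      v <- dplyr::bind_rows(lapply(seq_len(nv), function(i) {
        toy_variant(pos = 1000 + i, gt_child = "het",
          gt_father = gt_from_count(vars$father[i]),
          gt_mother = gt_from_count(vars$mother[i]))
      }))
      got <- find_compound_hets(segregate_trio(v, ped))
      want <- comphet_oracle(vars)
      expect_equal(nrow(got), length(want), label = sprintf("rep %d", rep))
      # no emitted pair has both members definitely from the same parent
      if (nrow(got) > 0) {
        expect_false(any(
          got$origin_a == got$origin_b &
            got$origin_a %in% c("paternal", "maternal")
        ))
      }
    }
  })
})

# ---- prioritization ----------------------------------------------------------

test_that("prioritization tiers by gene class and gates by mode frequency", {
  gm <- toy_gene_models()
  gm_cand <- dplyr::bind_rows(
    gm,
    tibble::tibble(gene = "GENEC", chrom = "4", start = 1000, end = 2000,
      coding = TRUE, gene_class = "candidate_gene", moi = "AD")
  )
  ped <- toy_pedigree()
  v <- dplyr::bind_rows(
    # de novo P in panel gene: tier 1
    toy_variant(pos = 1100),
    # homozygous with common AF 0.08: excluded by the recessive gate (0.01)
    toy_variant(chrom = "2", pos = 1100, gene = "GENEB", gt_child = "hom_alt",
      gt_father = "het", gt_mother = "het", vaf_child = 0.97, pop_af = 0.08),
    # VUS in candidate gene: tier 3, retained
    toy_variant(chrom = "4", pos = 1500, gene = "GENEC", class_label = "VUS")
  )
  got <- prioritize_small_variants(segregate_trio(v, ped), gm_cand)
  expect_equal(nrow(got), 2)
  expect_equal(got$tier, c(1L, 3L))
  expect_equal(got$gene, c("GENEA", "GENEC"))
  expect_true(all(got$priority == order(got$tier)))

  # same homozygote with rare AF passes
  v_rare <- v[2, ]
  v_rare$pop_af <- 0.001
  v_rare$n_hom <- 0
  got2 <- prioritize_small_variants(segregate_trio(v_rare, ped), gm)
  expect_equal(got2$mode, "homozygous")
})

test_that("inherited dominant P variants are reported only behind the flag", {
  gm <- toy_gene_models()
  ped <- toy_pedigree()
  v <- toy_variant(gt_father = "het", vaf_father = 0.5) # paternal P het in AD gene
  seg <- segregate_trio(v, ped)
  off <- prioritize_small_variants(seg, gm, triage_config())
  expect_equal(nrow(off), 0)
  on <- prioritize_small_variants(
    seg, gm, triage_config(include_inherited_dominant = TRUE)
  )
  expect_equal(on$mode, "inherited_dominant_candidate")
})
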