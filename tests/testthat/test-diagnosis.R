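cand_row <- function(...) {
  defaults <- tibble::tibble(
    trio_id = "P1", var_id = "1:100:A>G", type = "snv", gene = "GENEA",
    gene_class = "ndd_panel", moi = "AD", mode = "de_novo", label = "P",
    pop_af = 0, tier = 1L, phenotype_match = TRUE, input_order = 1L
  )
  over <- list(...)
  for (nm in names(over)) defaults[[nm]] <- over[[nm]]
  defaults
}

test_that("outcome classes follow the conclusive/possible/none definitions", {
  # P de novo in a disease gene with phenotype match -> conclusive
  c1 <- classify_patient(cand_row())
  expect_equal(c1$outcome, "conclusive")
  expect_equal(c1$n_support, 1L)

  # VUS in a disease gene with match -> possible
  c2 <- classify_patient(cand_row(label = "VUS", gene_class = "disease_gene"))
  expect_equal(c2$outcome, "possible")
  expect_equal(c2$rationale, "vus_disease_gene")

  # P in a candidate gene -> possible
  c3 <- classify_patient(cand_row(gene_class = "candidate_gene"))
  expect_equal(c3$outcome, "possible")
  expect_equal(c3$rationale, "plp_candidate_gene")

  # single het LP in an AR disease gene without a partner -> none,
  # rationale monoallelic_recessive
  c4 <- classify_patient(cand_row(
    label = "LP", gene_class = "disease_gene", moi = "AR", mode = "de_novo"
  ))
  expect_equal(c4$outcome, "none")
  expect_equal(c4$rationale, "monoallelic_recessive")
  expect_equal(c4$n_support, 0L)

  # the same LP with compound-het support is conclusive
  c5 <- classify_patient(cand_row(
    label = "LP", gene_class = "disease_gene", moi = "AR", mode = "compound_het"
  ))
  expect_equal(c5$outcome, "conclusive")

  # conclusive dominates possible
  c6 <- classify_patient(dplyr::bind_rows(
    cand_row(label = "VUS", gene_class = "disease_gene"),
    cand_row(var_id = "1:200:A>G")
  ))
  expect_equal(c6$outcome, "conclusive")

  # no phenotype match, unclassified, or benign labels cannot diagnose
  expect_equal(classify_patient(cand_row(phenotype_match = FALSE))$outcome, "none")
  expect_equal(classify_patient(cand_row(label = "unclassified"))$outcome, "none")
  expect_equal(classify_patient(cand_row(label = "B"))$outcome, "none")
  expect_equal(classify_patient(cand_row()[0, ])$outcome, "none")
})

test_that("outcome classes are exhaustive, exclusive and deterministic", {
  withr::with_seed(31, {
    for (i in 1:50) {
      cand <- dplyr::bind_rows(lapply(seq_len(sample(0:4, 1)), function(j) {
        cand_row(
          var_id = paste0("v", j),
          label = sample(c("P", "LP", "VUS", "B", "unclassified"), 1),
          gene_class = sample(
            c("ndd_panel", "disease_gene", "candidate_gene", "other"), 1),
          moi = sample(c("AD", "AR", "XL", "unknown"), 1),
          mode = sample(c("de_novo", "homozygous", "compound_het",
            "hemizygous"), 1),
          phenotype_match = sample(c(TRUE, FALSE), 1)
        )
      }))
      if (nrow(cand) == 0) cand <- cand_row()[0, ]
      o1 <- classify_patient(cand)
      o2 <- classify_patient(cand)
      expect_equal(o1$outcome, o2$outcome)
      expect_true(o1$outcome %in% c("conclusive", "possible", "none"))
      if (o1$outcome == "none") expect_equal(o1$n_support, 0L)
      if (o1$outcome != "none") expect_gte(o1$n_support, 1L)
    }
  })
})

toy_outcomes <- function(ids, outcomes, pathway = "A") {
  tibble::tibble(
    patient_id = ids, pathway = pathway, outcome = outcomes,
    support = lapply(outcomes, function(o) {
      if (o == "none") cand_row()[0, ] else cand_row()
    })
  )
}

test_that("pathway comparison cross-tabulates and lists discordant patients", {
  a <- toy_outcomes(paste0("P", 1:5), c("conclusive", "conclusive", "possible", "none", "none"))
  b <- toy_outcomes(paste0("P", 1:5), c("conclusive", "conclusive", "possible", "conclusive", "none"), "B")
  cc <- compare_pathways(a, b)
  expect_equal(sum(diag(cc$matrix)), 4)
  expect_equal(cc$matrix["none", "conclusive"], 2 - 1) # the (none, conclusive) cell
  expect_equal(cc$n, 5)
  expect_equal(cc$discordant$patient_id, "P4")

  ident <- compare_pathways(a, a)
  expect_equal(sum(diag(ident$matrix)), 5)
  expect_equal(nrow(ident$discordant), 0)

  # permutation invariance
  perm <- compare_pathways(a[c(3, 1, 5, 2, 4), ], b)
  expect_equal(perm$matrix, cc$matrix)

  # mismatched id sets error naming the symmetric difference
  expect_error(compare_pathways(a, b[1:4, ]), "P5")
})

test_that("outcome completion fills undiagnosed patients as none", {
  a <- toy_outcomes(c("P1", "P2"), c("conclusive", "possible"))
  full <- complete_outcomes(a, paste0("P", 1:4))
  expect_equal(nrow(full), 4)
  expect_equal(sort(full$outcome), sort(c("conclusive", "possible", "none", "none")))
})

test_that("tidy and glance summarise a concordance object", {
  a <- toy_outcomes(paste0("P", 1:6),
    c("conclusive", "conclusive", "possible", "none", "none", "none"))
  b <- toy_outcomes(paste0("P", 1:6),
    c("conclusive", "conclusive", "possible", "conclusive", "none", "none"), "B")
  cc <- compare_pathways(a, b, labels = c("SOC", "GS"))
  td <- tidy(cc)
  expect_equal(nrow(td), 9)
  expect_equal(sum(td$n), 6)
  gl <- glance(cc)
  expect_equal(gl$conclusive_a, 2)
  expect_equal(gl$conclusive_b, 3)
  expect_equal(gl$concordant, 5 / 6)
  p <- autoplot(cc)
  expect_s3_class(p, "ggplot")
})

# full-enumeration hypergeometric oracle
fisher_enum <- function(a, b, c, d, alternative = "two.sided") {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(xs, r1, r2, c1)
  obs <- stats::dhyper(a, r1, r2, c1)
  switch(alternative,
    two.sided = sum(probs[probs <= obs * (1 + 1e-7)]),
    greater = sum(probs[xs >= a]),
    less = sum(probs[xs <= a])
  )
}

test_that("Fisher exact matches symmetry and closed-form examples", {
  expect_equal(fisher_exact(1, 1, 1, 1), 1)
  expect_equal(fisher_exact(0, 0, 0, 0), 1) # all-zero convention

  # one-sided closed form: C(15,6)/C(90,6)
  want <- choose(15, 6) / choose(90, 6)
  expect_equal(fisher_exact(6, 0, 9, 75, alternative = "greater"), want,
    tolerance = 1e-10)
  expect_equal(want, 8.04e-6, tolerance = 1e-2)

  # enumeration of the three tables with margins (2,2),(2,2)
  expect_equal(fisher_exact(2, 0, 0, 2), 1 / 3, tolerance = 1e-10)
})

test_that("Fisher exact equals full enumeration for small margins", {
  withr::with_seed(77, {
    for (i in 1:80) {
      cells <- sample(0:20, 4, replace = TRUE)
      if (sum(cells) == 0) cells <- c(1, 0, 0, 1)
      a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
      expect_equal(
        fisher_exact(a, b, c, d),
        fisher_enum(a, b, c, d),
        tolerance = 1e-8, label = paste(cells, collapse = ",")
      )
      # symmetry under row and column swaps
      expect_equal(fisher_exact(a, b, c, d), fisher_exact(c, d, a, b))
      expect_equal(fisher_exact(a, b, c, d), fisher_exact(b, a, d, c))
    }
  })
})

test_that("diagnosis tallies count one primary variant type per patient", {
  # a frameshift duplication is an indel
  t1 <- tally_diagnoses(toy_outcomes("P1", "conclusive") %>%
    dplyr::mutate(support = list(cand_row(type = "indel"))))
  expect_equal(t1$n[t1$type == "indel"], 1)
  expect_equal(sum(t1$n), 1)

  # a complex deletion-duplication patient is counted once as cnv
  sup <- dplyr::bind_rows(
    cand_row(type = "cnv", var_id = "del", input_order = 1L),
    cand_row(type = "cnv", var_id = "dup", input_order = 2L)
  )
  t2 <- tally_diagnoses(toy_outcomes("P1", "conclusive") %>%
    dplyr::mutate(support = list(sup)))
  expect_equal(t2$n[t2$type == "cnv"], 1)
  expect_equal(sum(t2$n), 1)

  # tie on tier/label/AF resolves by input order (published row order)
  sup3 <- dplyr::bind_rows(
    cand_row(type = "indel", input_order = 1L),
    cand_row(type = "snv", var_id = "x", input_order = 2L)
  )
  t3 <- tally_diagnoses(toy_outcomes("P1", "conclusive") %>%
    dplyr::mutate(support = list(sup3)))
  expect_equal(t3$n[t3$type == "indel"], 1)
  expect_equal(t3$n[t3$type == "snv"], 0)
})
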