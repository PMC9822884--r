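# broom-style tidiers for the concordance object.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pathway-concordance matrix
#'
#' @param x A `pathway_concordance` object ([compare_pathways()]).
#' @param ... Unused.
#' @return A tibble in long form: one row per cell with the two pathway
#'   outcomes, the count, and whether the cell is on the diagonal.
#' @export
tidy.pathway_concordance <- function(x, ...) {
  m <- x$matrix
  expand.grid(
    a = rownames(m), b = colnames(m),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  ) %>%
    as_tibble() %>%
    mutate(
      n = as.vector(m),
      concordant = .data$a == .data$b
    ) %>%
    setNames(c(
      paste0("outcome_", tolower(x$labels[1])),
      paste0("outcome_", tolower(x$labels[2])), "n", "concordant"
    ))
}

#' One-row summary of a pathway comparison
#'
#' @param x A `pathway_concordance` object.
#' @param ... Unused.
#' @return A one-row tibble: cohort size, per-pathway conclusive counts and
#'   yields (fractions), overall concordant fraction, and the unpaired
#'   Fisher exact p-value comparing the two conclusive yields
#'   (conclusive vs not, pathway A vs pathway B).
#' @export
glance.pathway_concordance <- function(x, ...) {
  m <- x$matrix
  n <- x$n
  conc_a <- sum(m["conclusive", ])
  conc_b <- sum(m[, "conclusive"])
  tibble(
    n = n,
    conclusive_a = conc_a,
    conclusive_b = conc_b,
    yield_a = conc_a / n,
    yield_b = conc_b / n,
    concordant = sum(diag(m)) / n,
    fisher_p_yield = fisher_exact(conc_a, n - conc_a, conc_b, n - conc_b)
  )
}
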