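# Runs of homozygosity via the classic SNP-count sliding-window algorithm,
# and mitochondrial variant matching against a confirmed-pathogenic catalog.

#' Run-of-homozygosity detection parameters
#'
#' Parameters of the sliding-window ROH scan. Defaults are the standard
#' window scan settings with a 3-het window allowance, 50-SNP / 300-kb
#' segment minima; `window_snp`, `hit_prop` and `window_missing` are the
#' usual defaults of the window algorithm.
#'
#' @param window_het Maximum heterozygous calls tolerated inside one window.
#' @param min_snp Minimum SNPs for a reported segment.
#' @param min_kb Minimum segment length in kb.
#' @param window_snp Window size in SNPs.
#' @param hit_prop Minimum fraction of homozygous windows covering a SNP for
#'   it to support a run.
#' @param window_missing Maximum missing calls tolerated inside one window.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_het = 3, min_snp = 50, min_kb = 300,
                       window_snp = 50, hit_prop = 0.05, window_missing = 5) {
  stopifnot(
    window_het >= 0, min_snp > 0, min_kb > 0, window_snp > 0,
    hit_prop > 0, hit_prop <= 1, window_missing >= 0
  )
  structure(
    list(
      window_het = window_het, min_snp = min_snp, min_kb = min_kb,
      window_snp = window_snp, hit_prop = hit_prop,
      window_missing = window_missing
    ),
    class = "roh_params"
  )
}

#' Detect runs of homozygosity in a genotype sequence
#'
#' Sliding-window scan over biallelic genotypes sorted by position: windows
#' of `window_snp` consecutive SNPs are "homozygous" when they contain at
#' most `window_het` heterozygous and `window_missing` missing calls; a SNP
#' supports a run when the fraction of windows covering it that are
#' homozygous is at least `hit_prop`; maximal runs of supporting SNPs become
#' segments, then filtered by `min_snp` SNPs and `min_kb` kb. Chromosomes
#' with fewer SNPs than one window yield no segments.
#'
#' @param genotypes Tibble with `chrom`, `pos` (sorted within chromosome;
#'   unsorted input is an error) and `gt` (`"het"`, `"missing"`, anything
#'   else counts as homozygous, e.g. `"hom_ref"`/`"hom_alt"`).
#' @param params A [roh_params()].
#' @return Tibble of segments: `chrom`, `start`, `end`, `n_snp`, `n_het`,
#'   `length_bp`.
#' @export
detect_roh <- function(genotypes, params = roh_params()) {
  g <- as_tibble(genotypes)
  stopifnot(all(c("chrom", "pos", "gt") %in% names(g)))
  out <- g %>%
    group_by(.data$chrom) %>%
    dplyr::group_map(function(d, key) {
      if (is.unsorted(d$pos)) {
        abort(sprintf("positions on chromosome %s are not sorted", key$chrom))
      }
      seg <- roh_scan_chrom(d$pos, d$gt, params)
      if (nrow(seg) == 0) return(NULL)
      bind_cols(chrom = key$chrom, seg)
    }) %>%
    bind_rows()
  if (nrow(out) == 0) {
    return(tibble(
      chrom = character(), start = numeric(), end = numeric(),
      n_snp = integer(), n_het = integer(), length_bp = numeric()
    ))
  }
  arrange(out, .data$chrom, .data$start)
}

roh_scan_chrom <- function(pos, gt, params) {
  n <- length(pos)
  W <- params$window_snp
  empty <- tibble(
    start = numeric(), end = numeric(), n_snp = integer(),
    n_het = integer(), length_bp = numeric()
  )
  if (n < W) return(empty)
  het <- as.integer(gt == "het")
  mis <- as.integer(gt == "missing")
  ch <- cumsum(het)
  cm <- cumsum(mis)
  nw <- n - W + 1
  i <- seq_len(nw)
  win_het <- ch[i + W - 1] - c(0, ch)[i]
  win_mis <- cm[i + W - 1] - c(0, cm)[i]
  win_hom <- as.integer(win_het <= params$window_het &
    win_mis <= params$window_missing)
  # windows covering SNP j: indices max(1, j-W+1) .. min(j, nw)
  chom <- c(0, cumsum(win_hom))
  j <- seq_len(n)
  lo <- pmax(1L, j - W + 1L)
  hi <- pmin(j, nw)
  n_cov <- hi - lo + 1L
  n_hom <- chom[hi + 1L] - chom[lo]
  support <- n_cov > 0 & (n_hom / n_cov) >= params$hit_prop

  r <- rle(support)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  if (length(runs) == 0) return(empty)
  seg <- tibble(
    start = pos[starts[runs]],
    end = pos[ends[runs]],
    n_snp = r$lengths[runs],
    n_het = vapply(runs, function(k) {
      sum(het[starts[k]:ends[k]])
    }, integer(1)),
    length_bp = pos[ends[runs]] - pos[starts[runs]] + 1
  )
  filter(seg, .data$n_snp >= params$min_snp,
    .data$length_bp >= params$min_kb * 1000)
}

#' Annotate homozygous candidates inside ROH segments
#'
#' ROH output is annotative: a homozygous candidate inside a run of
#' homozygosity gains support for identity-by-descent, but an ROH alone
#' never constitutes a finding.
#'
#' @param candidates Candidate tibble with `chrom`, `pos`.
#' @param roh_segments Output of [detect_roh()] (may span several trios if
#'   it carries a `trio_id` column matching the candidates).
#' @return `candidates` plus logical `in_roh`.
#' @export
annotate_roh <- function(candidates, roh_segments) {
  cand <- as_tibble(candidates)
  if (nrow(cand) == 0 || nrow(roh_segments) == 0) {
    return(mutate(cand, in_roh = FALSE))
  }
  by_trio <- "trio_id" %in% names(roh_segments) && "trio_id" %in% names(cand)
  cand$in_roh <- vapply(seq_len(nrow(cand)), function(i) {
    seg <- roh_segments[roh_segments$chrom == cand$chrom[i], , drop = FALSE]
    if (by_trio) seg <- seg[seg$trio_id == cand$trio_id[i], , drop = FALSE]
    any(cand$pos[i] >= seg$start & cand$pos[i] <= seg$end)
  }, logical(1))
  cand
}

#' Minimal mitochondrial confirmed-pathogenic catalog
#'
#' A small, synthetic snapshot of well-known confirmed pathogenic
#' mitochondrial point mutations, bundled so the matching step runs without
#' database access. Replace with a current catalog via
#' [read_mito_catalog()] for real analyses.
#'
#' @return Catalog tibble: `pos`, `ref`, `alt`, `phenotype`.
#' @export
synthetic_mito_catalog <- function() {
  tibble(
    pos = c(1555, 3243, 3460, 8344, 8993, 8993, 11778, 14484),
    ref = c("A", "A", "G", "A", "T", "T", "G", "T"),
    alt = c("G", "G", "A", "G", "G", "C", "A", "C"),
    phenotype = c(
      "aminoglycoside-induced deafness", "MELAS", "LHON", "MERRF",
      "NARP/Leigh", "NARP/Leigh", "LHON", "LHON"
    )
  )
}

#' Match mitochondrial variants against a pathogenic catalog
#'
#' Exact (position, ref, alt) matching of variant calls on the
#' mitochondrial contig (`MT`/`M`/`chrM`) against a confirmed-pathogenic
#' catalog. The child ALT allele fraction is carried through as a
#' heteroplasmy proxy.
#'
#' @param variants Trio genotype tibble (only mitochondrial rows are
#'   considered).
#' @param catalog Catalog tibble; defaults to [synthetic_mito_catalog()].
#' @return Matched rows with the catalog `phenotype` and `heteroplasmy`
#'   (child ALT fraction).
#' @export
match_mito <- function(variants, catalog = synthetic_mito_catalog()) {
  v <- as_tibble(variants) %>%
    mutate(chrom_norm = sub("^chr", "", .data$chrom)) %>%
    filter(.data$chrom_norm %in% c("MT", "M"))
  out <- inner_join(v, catalog, by = c("pos", "ref", "alt")) %>%
    mutate(heteroplasmy = .data$vaf_child) %>%
    select(-"chrom_norm")
  out
}
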