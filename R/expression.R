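# Expression machinery: RPKM, the log2-threshold expressed/silent call,
# Cat1/2/3 categorization, TMM normalization, and the two-condition
# differential test.

EXPR_LOG2_THRESHOLD <- 1  # log2(RPKM) >= 1, i.e. RPKM >= 2

#' Reads per kilobase of exon per million library reads
#'
#' `count * 1e9 / (length_bp * library_size)`. Vectorized over genes.
#'
#' @param count Read count(s).
#' @param length_bp Exonic gene length(s) in bp (> 0).
#' @param library_size Library size in reads (> 0).
#' @return RPKM value(s).
#' @export
rpkm <- function(count, length_bp, library_size) {
  if (any(length_bp <= 0)) stop("gene length must be positive")
  if (any(library_size <= 0)) stop("library size must be positive")
  count * 1e9 / (length_bp * library_size)
}

#' Expressed/silent call with reporting floor
#'
#' A gene counts as expressed when log2(RPKM) is at least 1 (RPKM >= 2, the
#' biological-relevance threshold; boundary inclusive). Below the threshold
#' the reported expression value is floored to zero.
#'
#' @param log2rpkm log2(RPKM) value(s); `-Inf` (zero RPKM) is allowed and
#'   counts as silent.
#' @return Logical vector of calls, with attribute-free companion
#'   [floor_expression()] for reporting.
#' @export
expressed_call <- function(log2rpkm) {
  !is.na(log2rpkm) & log2rpkm >= EXPR_LOG2_THRESHOLD
}

#' Reported expression with sub-threshold values set to zero
#'
#' @param rpkm_value RPKM value(s).
#' @return `rpkm_value` with entries below the threshold (RPKM < 2) replaced
#'   by 0.
#' @export
floor_expression <- function(rpkm_value) {
  ifelse(expressed_call(log2(rpkm_value)), rpkm_value, 0)
}

#' Expression category from the two condition calls
#'
#' Cat1: silent at both time points; Cat2: expressed at exactly one
#' (i.e. differentially expressed in the categorical sense); Cat3: expressed
#' at both.
#'
#' @param expressed_24h,expressed_48h Logical vectors.
#' @return Character vector of `"Cat1"`, `"Cat2"`, `"Cat3"`.
#' @export
categorize <- function(expressed_24h, expressed_48h) {
  n <- as.integer(expressed_24h) + as.integer(expressed_48h)
  c("Cat1", "Cat2", "Cat3")[n + 1L]
}

#' TMM (trimmed mean of M-values) scaling factors
#'
#' Between-sample normalization for count matrices. The reference sample is
#' the one whose 75th percentile of library-scaled counts is closest to the
#' mean of those percentiles. For every other sample, genes with a zero count
#' in either sample are dropped, per-gene log-ratios M and average abundances
#' A are computed against the reference, the 30% most extreme M and 5% most
#' extreme A on each side are trimmed, and the factor is the precision
#' (inverse asymptotic variance) weighted mean of the surviving M values.
#' Factors are rescaled to geometric mean 1.
#'
#' @param counts Non-negative integer matrix, genes x samples (>= 2 samples).
#' @param lib_sizes Library sizes; default column sums.
#' @return Numeric vector of scaling factors, one per sample.
#' @export
tmm_factors <- function(counts, lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least two samples")
  if (any(lib_sizes == 0)) stop("sample(s) with all-zero counts")
  scaled <- sweep(counts, 2, lib_sizes, "/")
  q75 <- apply(scaled, 2, stats::quantile, probs = 0.75, names = FALSE)
  ref <- which.min(abs(q75 - mean(q75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    o <- counts[, j]; r <- counts[, ref]
    keep <- o > 0 & r > 0
    o <- o[keep]; r <- r[keep]
    if (length(o) == 0L) return(1)
    lo <- lib_sizes[j]; lr <- lib_sizes[ref]
    M <- log2((o / lo) / (r / lr))
    A <- 0.5 * log2((o / lo) * (r / lr))
    w <- (lo - o) / (lo * o) + (lr - r) / (lr * r)  # delta-method variance of M
    ok <- is.finite(M) & is.finite(A) & w > 0
    M <- M[ok]; A <- A[ok]; w <- w[ok]
    if (length(M) == 0L) return(1)
    qM <- stats::quantile(M, c(0.30, 0.70), names = FALSE)
    qA <- stats::quantile(A, c(0.05, 0.95), names = FALSE)
    keep2 <- M >= qM[1] & M <= qM[2] & A >= qA[1] & A <= qA[2]
    if (!any(keep2)) return(1)
    2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

#' Two-condition differential test for one gene
#'
#' Welch (unequal-variance) two-sample t-test on TMM-normalized log2-CPM, with
#' a pseudo-count of 0.5 reads added before the CPM transform. The fold
#' change is the difference of condition means on the log2-CPM scale
#' (condition B minus condition A). With fewer than two replicates in either
#' condition the p-value is `NA` and the gene is never significant; when both
#' groups are exactly constant the p-value is 1 for equal means and 0
#' otherwise.
#'
#' @param counts_a,counts_b Count vectors for the two conditions (e.g. 24 h
#'   and 48 h replicates).
#' @param lib_a,lib_b Library sizes matching the count vectors.
#' @param factors_a,factors_b TMM factors matching the count vectors
#'   (default 1).
#' @param alpha Significance cut-off on the raw p-value (default 0.05).
#' @param lfc_strong Absolute log2 fold-change for a strong (>= twofold)
#'   call (default 1).
#' @return A list: `log2fc`, `p_value`, `significant`, `strong`.
#' @export
differential <- function(counts_a, counts_b, lib_a, lib_b,
                         factors_a = rep(1, length(counts_a)),
                         factors_b = rep(1, length(counts_b)),
                         alpha = 0.05, lfc_strong = 1) {
  la <- log2((counts_a + 0.5) / (lib_a * factors_a) * 1e6)
  lb <- log2((counts_b + 0.5) / (lib_b * factors_b) * 1e6)
  log2fc <- mean(lb) - mean(la)
  p <- NA_real_
  if (length(la) >= 2L && length(lb) >= 2L) {
    if (stats::sd(la) < 1e-12 && stats::sd(lb) < 1e-12) {
      p <- if (abs(log2fc) < 1e-12) 1 else 0
    } else {
      p <- tryCatch(stats::t.test(la, lb, var.equal = FALSE)$p.value,
                    error = function(e) 1)
    }
  }
  list(log2fc = log2fc, p_value = p,
       significant = !is.na(p) && p < alpha,
       strong = abs(log2fc) >= lfc_strong)
}

#' Per-gene expression records for a two-condition count matrix
#'
#' Computes per-sample RPKM, condition-mean RPKM (replicates averaged before
#' thresholding), log2 values, expressed/silent calls at the RPKM >= 2
#' threshold, Cat1/2/3 categories, and the TMM-normalized differential test
#' (48 h vs 24 h).
#'
#' @param counts Genes x samples count matrix with rownames = gene ids.
#' @param lengths_bp Per-gene exonic lengths (bp), aligned with rows.
#' @param conditions Character vector per sample, values `"24h"` / `"48h"`.
#' @param lib_sizes Library sizes; default column sums.
#' @return A data.frame of expression records (one row per gene): rpkm and
#'   log2rpkm condition means, floored reported values, expressed flags,
#'   category, log2fc, p_value, significant, strong.
#' @export
expression_table <- function(counts, lengths_bp, conditions,
                             lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths_bp) == nrow(counts),
            length(conditions) == ncol(counts))
  if (!all(conditions %in% c("24h", "48h")))
    stop("conditions must be '24h' or '48h'")
  if (!all(c("24h", "48h") %in% conditions))
    stop("need at least one sample per condition")
  gene_id <- rownames(counts)
  if (is.null(gene_id)) gene_id <- paste0("gene_", seq_len(nrow(counts)))

  rp <- sweep(sweep(counts, 1, lengths_bp, "/"), 2, lib_sizes, "/") * 1e9
  a <- conditions == "24h"; b <- conditions == "48h"
  rpkm24 <- rowMeans(rp[, a, drop = FALSE])
  rpkm48 <- rowMeans(rp[, b, drop = FALSE])
  l24 <- log2(rpkm24); l48 <- log2(rpkm48)
  e24 <- expressed_call(l24); e48 <- expressed_call(l48)

  f <- if (ncol(counts) >= 2) tmm_factors(counts, lib_sizes) else rep(1, ncol(counts))
  de <- lapply(seq_len(nrow(counts)), function(i)
    differential(counts[i, a], counts[i, b],
                 lib_sizes[a], lib_sizes[b], f[a], f[b]))
  data.frame(
    gene_id = gene_id,
    rpkm_24h = rpkm24, rpkm_48h = rpkm48,
    rpkm_reported_24h = ifelse(e24, rpkm24, 0),
    rpkm_reported_48h = ifelse(e48, rpkm48, 0),
    log2rpkm_24h = l24, log2rpkm_48h = l48,
    expressed_24h = e24, expressed_48h = e48,
    category = categorize(e24, e48),
    log2fc = vapply(de, `[[`, numeric(1), "log2fc"),
    p_value = vapply(de, `[[`, numeric(1), "p_value"),
    significant = vapply(de, `[[`, logical(1), "significant"),
    strong = vapply(de, `[[`, logical(1), "strong"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Expression records from condition-mean RPKM values
#'
#' Builds the same record layout as [expression_table()] from per-condition
#' mean RPKM values alone (no replicate counts, hence no p-values). Used for
#' deterministic fixtures and for ingesting published per-gene RPKM tables.
#'
#' @param gene_id Character vector.
#' @param rpkm_24h,rpkm_48h Condition-mean RPKM values.
#' @return Expression-record data.frame; `p_value` is `NA` and `significant`
#'   `FALSE` throughout.
#' @export
records_from_rpkm <- function(gene_id, rpkm_24h, rpkm_48h) {
  l24 <- log2(rpkm_24h); l48 <- log2(rpkm_48h)
  e24 <- expressed_call(l24); e48 <- expressed_call(l48)
  lfc <- log2((rpkm_48h + 0.25) / (rpkm_24h + 0.25))
  data.frame(
    gene_id = gene_id,
    rpkm_24h = rpkm_24h, rpkm_48h = rpkm_48h,
    rpkm_reported_24h = ifelse(e24, rpkm_24h, 0),
    rpkm_reported_48h = ifelse(e48, rpkm_48h, 0),
    log2rpkm_24h = l24, log2rpkm_48h = l48,
    expressed_24h = e24, expressed_48h = e48,
    category = categorize(e24, e48),
    log2fc = lfc,
    p_value = NA_real_,
    significant = FALSE,
    strong = abs(lfc) >= 1,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
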