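# Cluster assembly and candidate BGC selection.

TRANSFERASE_CODES <- c("OAT", "cAT")

#' Group genes into clusters
#'
#' Either passes through an upstream cluster assignment (a `cluster_id`
#' column, e.g. from a dedicated cluster-prediction tool) or groups genes by
#' intergenic distance: maximal runs of consecutive genes on one scaffold
#' whose intergenic gap is at most `max_gap_bp`.
#'
#' @param genes Gene-model data.frame sorted by (scaffold, start).
#' @param max_gap_bp Maximum intergenic distance (bp) within a cluster;
#'   default 10000.
#' @param use_given Use an existing `cluster_id` column when present
#'   (default `TRUE`).
#' @return `genes` with a `cluster_id` column and an attribute
#'   `cluster_source` (`"given"` or `"distance_grouping"`). Genes without an
#'   upstream assignment (NA/empty `cluster_id`) keep `NA` in pass-through
#'   mode.
#' @export
group_clusters <- function(genes, max_gap_bp = 10000, use_given = TRUE) {
  ord <- order(genes$scaffold, genes$start)
  if (!identical(ord, seq_len(nrow(genes))))
    stop("gene table must be sorted by (scaffold, start)")
  if (use_given && "cluster_id" %in% names(genes)) {
    genes$cluster_id[!is.na(genes$cluster_id) & genes$cluster_id == ""] <- NA
    attr(genes, "cluster_source") <- "given"
    return(genes)
  }
  if (max_gap_bp <= 0) stop("max_gap_bp must be positive")
  new_cluster <- c(TRUE, genes$scaffold[-1] != genes$scaffold[-nrow(genes)] |
                     (genes$start[-1] - genes$end[-nrow(genes)]) > max_gap_bp)
  genes$cluster_id <- paste0("CL", cumsum(new_cluster))
  attr(genes, "cluster_source") <- "distance_grouping"
  genes
}

#' Find candidate BGCs by architecture co-localization
#'
#' A cluster is a candidate when at least two of its genes carry the full
#' required domain architecture (the two-synthase signature of a two-chain
#' polyketide) and, optionally, a transferase-annotated gene (domain code
#' `OAT` or `cAT`) is present to join the chains. Candidates are returned in
#' deterministic order by (scaffold, start).
#'
#' @param genes Gene table with a `cluster_id` column (see
#'   [group_clusters()]).
#' @param required Required domain codes, e.g.
#'   `c("KS","AT","DH","MT","ER","KR","ACP")`.
#' @param require_transferase Demand a transferase gene in the cluster
#'   (default `TRUE`).
#' @return A data.frame of candidates: `cluster_id`, `scaffold`, `start`,
#'   `end`, `n_genes`, `matching_pks` (comma-separated gene ids),
#'   `n_matching`, `has_transferase`, `verdict` (initially `"unscreened"`),
#'   `rank` (NA until the expression filter runs). Zero rows when nothing
#'   qualifies.
#' @export
find_candidates <- function(genes, required, require_transferase = TRUE) {
  if (!"cluster_id" %in% names(genes))
    stop("genes must carry a cluster_id column; run group_clusters() first")
  hit <- scan_architecture(genes, required)
  archs <- parse_domains(genes$domains)
  is_transferase <- vapply(archs, function(a) any(TRANSFERASE_CODES %in% a),
                           logical(1))
  keep <- !is.na(genes$cluster_id)
  rows <- lapply(split(which(keep), genes$cluster_id[keep]), function(idx) {
    m <- idx[hit[idx]]
    if (length(m) < 2L) return(NULL)
    if (require_transferase && !any(is_transferase[idx])) return(NULL)
    data.frame(
      cluster_id = genes$cluster_id[idx[1]],
      scaffold = genes$scaffold[idx[1]],
      start = min(genes$start[idx]), end = max(genes$end[idx]),
      n_genes = length(idx),
      matching_pks = paste(genes$gene_id[m], collapse = ","),
      n_matching = length(m),
      has_transferase = any(is_transferase[idx]),
      verdict = "unscreened", rank = NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(cluster_id = character(0), scaffold = character(0),
                      start = integer(0), end = integer(0), n_genes = integer(0),
                      matching_pks = character(0), n_matching = integer(0),
                      has_transferase = logical(0), verdict = character(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  out <- out[order(out$scaffold, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen candidates by the producing-condition expression pattern
#'
#' A candidate shows the producing pattern when all of its matching synthase
#' genes are expressed (log2 RPKM >= 1) at the producing condition; a
#' candidate whose synthases are silent there is kept with verdict
#' `"silent"`. Producing-pattern candidates rank first; ties break by
#' (scaffold, start).
#'
#' @param candidates Candidate data.frame from [find_candidates()].
#' @param records Expression records (see [expression_table()]).
#' @param producing Producing condition label, `"48h"` (default) or `"24h"`.
#' @return `candidates` with `verdict` filled in and `rank` assigned.
#' @export
apply_expression_filter <- function(candidates, records, producing = "48h") {
  if (nrow(candidates) == 0L) return(candidates)
  producing <- match.arg(producing, c("48h", "24h"))
  col <- paste0("expressed_", producing)
  verdicts <- vapply(seq_len(nrow(candidates)), function(i) {
    ids <- strsplit(candidates$matching_pks[i], ",", fixed = TRUE)[[1]]
    j <- match(ids, records$gene_id)
    if (anyNA(j))
      stop("missing expression record(s) for: ",
           paste(ids[is.na(j)], collapse = ", "))
    expressed <- records[[col]][j]
    if (all(expressed)) "producing_pattern"
    else if (!any(expressed)) "silent"
    else "other"
  }, character(1))
  candidates$verdict <- verdicts
  ord <- order(verdicts != "producing_pattern", candidates$scaffold,
               candidates$start)
  candidates <- candidates[ord, , drop = FALSE]
  candidates$rank <- seq_len(nrow(candidates))
  rownames(candidates) <- NULL
  candidates
}

#' The rasfonin (rsf) cluster gene roles
#'
#' The nine genes of the rasfonin biosynthetic gene cluster of Chalara
#' gorgonifer, DNG_02774 through DNG_02782: two flanking HR-PKSs (rsf1 =
#' CgPKS4, rsf9 = CgPKS5), three cytochrome P450s (rsf2, rsf6, rsf8), an
#' O-acyltransferase (rsf3), an MFS transporter (rsf4), a standalone
#' FSH-family thioesterase (rsf5) and one uncharacterised gene (rsf7).
#'
#' @return A data.frame: `rsf`, `gene_id`, `role`, `domains`.
#' @export
rsf_genes <- function() {
  data.frame(
    rsf = paste0("rsf", 1:9),
    gene_id = sprintf("DNG_%05d", 2774:2782),
    role = c("HR-PKS (CgPKS4)", "cytochrome P450", "O-acyltransferase",
             "MFS transporter", "trans-acting thioesterase (FSH family)",
             "cytochrome P450", "uncharacterised", "cytochrome P450",
             "HR-PKS (CgPKS5)"),
    domains = c("KS;AT;DH;MT;ER;KR;ACP", "P450", "OAT", "MFS", "TE_FSH",
                "P450", "UNK", "P450", "KS;AT;DH;MT;ER;KR;ACP"),
    stringsAsFactors = FALSE
  )
}
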