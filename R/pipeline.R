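# End-to-end orchestration: retro-biosynthesis -> architecture scan ->
# co-localization -> expression filter -> border calling -> report.

#' Run the full cluster-inference pipeline
#'
#' Derives the required synthase architecture from the compound
#' specification, groups genes into clusters (honouring a given `cluster_id`
#' column when present), selects candidate clusters with a co-localized
#' matching synthase pair plus transferase, screens them by the
#' producing-condition expression pattern, and calls borders around the
#' top-ranked producing candidate by coregulation.
#'
#' @param genes Gene-model data.frame (see [read_gene_table()]).
#' @param records Expression records (see [expression_table()] /
#'   [records_from_rpkm()]).
#' @param compound A [compound_spec()]; default [rasfonin_compound()].
#' @param producing Producing condition label (default `"48h"`).
#' @param max_gap_bp Intergenic distance for cluster grouping when no
#'   assignment column is present.
#' @param require_transferase Demand a transferase in candidate clusters.
#' @return A `bgc_prediction` list: `retro` (the retro-biosynthetic report),
#'   `required` (domain set), `candidates` (ranked candidate table),
#'   `border` (a `border_call`, or `NULL` when no producing-pattern
#'   candidate exists), `n_producing`.
#' @export
predict_bgc <- function(genes, records, compound = rasfonin_compound(),
                        producing = "48h", max_gap_bp = 10000,
                        require_transferase = TRUE) {
  retro <- retro_compound(compound)
  required <- Reduce(union, lapply(retro$chains, required_domains))
  missing_ids <- setdiff(genes$gene_id, records$gene_id)
  if (length(missing_ids))
    stop("gene id(s) without expression records: ",
         paste(utils::head(missing_ids, 5), collapse = ", "),
         if (length(missing_ids) > 5) ", ...")
  grouped <- group_clusters(genes, max_gap_bp = max_gap_bp)
  candidates <- find_candidates(grouped, required, require_transferase)
  candidates <- apply_expression_filter(candidates, records, producing)
  border <- NULL
  n_producing <- sum(candidates$verdict == "producing_pattern")
  if (n_producing >= 1L) {
    top <- candidates[1L, ]
    pks <- strsplit(top$matching_pks, ",", fixed = TRUE)[[1]]
    j <- match(pks, genes$gene_id)
    anchors <- pks[order(genes$start[j])][c(1L, length(pks))]
    border <- call_borders(genes, records, anchors)
  }
  structure(list(retro = retro, required = required, candidates = candidates,
                 border = border, n_producing = n_producing),
            class = "bgc_prediction")
}

#' The proposed biosynthetic route for the rasfonin cluster
#'
#' Static pathway model annotating the winning cluster's genes with their
#' proposed catalytic steps: chain assembly by the two HR-PKSs, thioesterase
#' release with pyrone formation, C4 hydroxylation by a cluster P450,
#' transacylation by the O-acyltransferase, and C8'/C10' hydroxylation by
#' the remaining P450s.
#'
#' @return A data.frame: `step`, `event`, `catalysts` (rsf names).
#' @export
pathway_model <- function() {
  data.frame(
    step = 1:6,
    event = c(
      "assembly of the hexaketide and tetraketide chains",
      "chain release / alpha-pyrone formation by the trans-acting thioesterase",
      "C4 hydroxylation (cytochrome P450)",
      "capture of the tetraketide and transacylation (ester link)",
      "C8' and C10' hydroxylation (cytochrome P450)",
      "rasfonin"
    ),
    catalysts = c("rsf1, rsf9", "rsf5", "rsf2/rsf6/rsf8", "rsf3",
                  "rsf2/rsf6/rsf8", "-"),
    stringsAsFactors = FALSE
  )
}

#' Human-readable prediction report
#'
#' Summarizes the retro-biosynthetic requirements, the candidate table, the
#' per-category counts of backbone-gene expression (when backbone ids are
#' supplied), the border call, and — when the winning span matches the rsf
#' locus layout — the role annotation of its genes.
#'
#' @param prediction A `bgc_prediction` from [predict_bgc()].
#' @param records Expression records used in the run.
#' @param backbone_ids Optional ids of backbone genes for the category
#'   summary.
#' @return Character vector of report lines (also works with
#'   `writeLines()`).
#' @export
bgc_report <- function(prediction, records, backbone_ids = NULL) {
  p <- prediction
  lines <- c("# BGC prediction report", "")
  for (r in p$retro$chains)
    lines <- c(lines, sprintf(
      "retro: %s — %d ketide units, %d malonyl extensions, %d methyls, domains {%s}",
      r$name, r$units, r$extensions, r$methyls,
      paste(r$required_domains, collapse = ",")))
  if (length(p$retro$post_pks_enzymes))
    lines <- c(lines, paste0(
      "retro: post-assembly demands: ",
      paste(sprintf("%s x%d", names(p$retro$post_pks_enzymes),
                    p$retro$post_pks_enzymes), collapse = ", ")))
  lines <- c(lines, "",
             sprintf("required architecture: {%s}", paste(p$required, collapse = ",")),
             sprintf("candidate clusters: %d (%d with the producing pattern)",
                     nrow(p$candidates), p$n_producing), "")
  if (nrow(p$candidates)) {
    lines <- c(lines, "rank\tcluster\tscaffold\tmatching synthases\ttransferase\tverdict")
    lines <- c(lines, sprintf("%d\t%s\t%s\t%s\t%s\t%s",
                              p$candidates$rank, p$candidates$cluster_id,
                              p$candidates$scaffold, p$candidates$matching_pks,
                              ifelse(p$candidates$has_transferase, "yes", "no"),
                              p$candidates$verdict))
  }
  if (!is.null(backbone_ids)) {
    cat_counts <- table(factor(records$category[records$gene_id %in% backbone_ids],
                               levels = c("Cat1", "Cat2", "Cat3")))
    lines <- c(lines, "", sprintf(
      "backbone expression categories: Cat1 %d, Cat2 %d, Cat3 %d (total %d)",
      cat_counts["Cat1"], cat_counts["Cat2"], cat_counts["Cat3"], sum(cat_counts)))
  }
  if (is.null(p$border)) {
    lines <- c(lines, "", "no producing-pattern candidate: no border call")
  } else {
    b <- p$border
    lines <- c(lines, "", sprintf(
      "border call: %s, %d genes, %s..%s (%d-%d bp)",
      b$scaffold, b$n_genes, b$first_gene_id, b$last_gene_id, b$start, b$end))
    rsf <- rsf_genes()
    if (identical(b$gene_ids, rsf$gene_id)) {
      lines <- c(lines, "", "rsf locus role annotation:")
      lines <- c(lines, sprintf("  %s\t%s\t%s", rsf$rsf, rsf$gene_id, rsf$role))
      pw <- pathway_model()
      lines <- c(lines, "", "proposed route:")
      lines <- c(lines, sprintf("  %d. %s [%s]", pw$step, pw$event, pw$catalysts))
    }
  }
  lines
}

#' Write the candidate table as TSV
#'
#' @param prediction A `bgc_prediction`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(prediction, path) {
  utils::write.table(prediction$candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
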