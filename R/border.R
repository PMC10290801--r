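# Coregulation-based cluster border calling.

#' The producing expression pattern
#'
#' TRUE for genes silent during active growth (24 h) and expressed in the
#' producing stationary phase (48 h) — the categorical coregulation signature
#' used to walk cluster borders.
#'
#' @param records Expression-record data.frame (or one row).
#' @param require_significant Additionally demand `significant == TRUE`
#'   (default `FALSE`; the categorical pattern alone reproduces the reference
#'   locus).
#' @return Logical vector along the rows of `records`.
#' @export
producing_pattern <- function(records, require_significant = FALSE) {
  p <- !records$expressed_24h & records$expressed_48h
  if (require_significant) p <- p & records$significant
  p
}

#' Call cluster borders by expression coregulation
#'
#' Starting from the inclusive interval between two anchor genes (the
#' candidate synthase pair), verifies that both anchors and every interior
#' gene show the producing pattern, then extends the span outward one gene at
#' a time in each direction while the next gene still matches, stopping at
#' the first violation or the scaffold end. Gap tolerance is zero: a single
#' non-matching gene terminates extension.
#'
#' @param genes Gene table restricted to (or containing) the anchors'
#'   scaffold; coordinate order defines gene order.
#' @param records Expression records covering the scaffold's genes.
#' @param anchors Character vector of two anchor gene ids.
#' @param require_significant Passed to [producing_pattern()].
#' @return A `border_call` list: `scaffold`, `first_gene_id`, `last_gene_id`,
#'   `gene_ids` (ordered span), `anchor_ids`, `n_genes`.
#' @export
call_borders <- function(genes, records, anchors, require_significant = FALSE) {
  if (length(anchors) != 2L) stop("exactly two anchor gene ids are required")
  ai <- match(anchors, genes$gene_id)
  if (anyNA(ai))
    stop("anchor gene(s) not found: ", paste(anchors[is.na(ai)], collapse = ", "))
  scf <- unique(genes$scaffold[ai])
  if (length(scf) != 1L) stop("anchors lie on different scaffolds")
  g <- genes[genes$scaffold == scf, , drop = FALSE]
  g <- g[order(g$start), , drop = FALSE]
  j <- match(g$gene_id, records$gene_id)
  if (anyNA(j))
    stop("missing expression record(s) for scaffold genes: ",
         paste(g$gene_id[is.na(j)], collapse = ", "))
  pat <- producing_pattern(records[j, , drop = FALSE], require_significant)
  ai <- sort(match(anchors, g$gene_id))
  lo <- ai[1]; hi <- ai[2]
  if (!all(pat[c(lo, hi)])) {
    bad <- g$gene_id[c(lo, hi)][!pat[c(lo, hi)]]
    stop("anchor fails the producing pattern: ", paste(bad, collapse = ", "))
  }
  interior <- setdiff(seq(lo, hi), c(lo, hi))
  if (length(interior) && !all(pat[interior]))
    stop("cluster interrupted: interior gene fails the producing pattern: ",
         paste(g$gene_id[interior[!pat[interior]]], collapse = ", "))
  while (lo > 1L && pat[lo - 1L]) lo <- lo - 1L
  while (hi < nrow(g) && pat[hi + 1L]) hi <- hi + 1L
  if (lo == 1L && hi == nrow(g))
    warning("every gene on scaffold ", scf,
            " matches the pattern; span covers the whole scaffold",
            call. = FALSE)
  span <- g[lo:hi, , drop = FALSE]
  structure(list(
    scaffold = scf,
    first_gene_id = span$gene_id[1],
    last_gene_id = span$gene_id[nrow(span)],
    gene_ids = span$gene_id,
    anchor_ids = anchors,
    n_genes = nrow(span),
    start = min(span$start), end = max(span$end)
  ), class = "border_call")
}

#' @export
print.border_call <- function(x, ...) {
  cat(sprintf("<border_call> %s: %d genes, %s..%s (%d-%d bp)\n",
              x$scaffold, x$n_genes, x$first_gene_id, x$last_gene_id,
              x$start, x$end))
  invisible(x)
}

#' Write a border call as a GFF3 feature
#'
#' Emits one `biosynthetic_gene_cluster` feature covering the called span.
#'
#' @param call A `border_call` from [call_borders()].
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_border_gff <- function(call, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = call$scaffold,
    ranges = IRanges::IRanges(call$start, call$end),
    type = "biosynthetic_gene_cluster",
    ID = paste0("BGC_", call$first_gene_id, "_", call$last_gene_id),
    first_gene = call$first_gene_id,
    last_gene = call$last_gene_id
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
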