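# Gene/domain data model, table I/O, backbone classification and
# architecture matching.

#' Recognised domain codes
#'
#' Closed enumeration of the domain and protein-family codes used in gene
#' annotations: the PKS module domains (KS, AT, DH, MT, ER, KR, ACP), the
#' NRPS core (C, A, PCP), chalcone/stilbene synthase halves (CHS_N, CHS_C,
#' marking type III PKSs), terpene synthase (TPS), and the tailoring/transport
#' families used in cluster annotation: cytochrome P450 (P450), major
#' facilitator superfamily transporter (MFS), FSH-family serine hydrolase /
#' thioesterase (TE_FSH), O-acyltransferase (OAT), carnitine acyltransferase
#' (cAT), and UNK for anything unrecognised.
#'
#' @export
DOMAIN_CODES <- c("KS", "AT", "DH", "MT", "ER", "KR", "ACP",
                  "cAT", "C", "A", "PCP", "TPS", "CHS_N", "CHS_C",
                  "P450", "MFS", "TE_FSH", "OAT", "UNK")

#' Parse a semicolon-separated domain annotation string
#'
#' Unknown codes are mapped to `UNK` with a warning rather than rejected, so
#' heterogeneous upstream annotations do not break ingestion.
#'
#' @param x Character vector of `;`-separated domain strings (may be empty).
#' @return A list of character vectors of validated domain codes.
#' @export
parse_domains <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(character(0))
    codes <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    codes <- codes[nzchar(codes)]
    bad <- !(codes %in% DOMAIN_CODES)
    if (any(bad)) {
      warning("unknown domain code(s) mapped to UNK: ",
              paste(unique(codes[bad]), collapse = ", "), call. = FALSE)
      codes[bad] <- "UNK"
    }
    codes
  })
}

GENE_TABLE_COLS <- c("gene_id", "scaffold", "start", "end", "strand", "product", "domains")

validate_gene_table <- function(genes) {
  missing <- setdiff(GENE_TABLE_COLS, names(genes))
  if (length(missing))
    stop("gene table is missing column(s): ", paste(missing, collapse = ", "))
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (any(is.na(genes$start)) || any(is.na(genes$end)))
    stop("malformed coordinates in gene table")
  if (any(genes$end < genes$start))
    stop("gene(s) with end < start: ",
         paste(genes$gene_id[genes$end < genes$start], collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id(s): ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  genes[order(genes$scaffold, genes$start), , drop = FALSE]
}

#' Read a gene table with domain annotations
#'
#' Two dialects are supported. The flat TSV dialect has columns `gene_id`,
#' `scaffold`, `start`, `end`, `strand`, `product`, `domains`
#' (semicolon-separated codes), plus an optional `cluster_id` column carrying
#' an upstream cluster assignment. The GFF3 dialect uses features of any type
#' with `ID`, and optional `product`, `domains` and `cluster_id` attributes.
#' Coordinates are 1-based inclusive; output rows are sorted by
#' (scaffold, start).
#'
#' @param path File path.
#' @param format `"tsv"` or `"gff3"` (default guessed from the extension).
#' @return A data.frame of gene models in coordinate order. Row order and
#'   domain strings are validated; unknown domain codes become `UNK` with a
#'   warning.
#' @export
read_gene_table <- function(path, format = c("auto", "tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  if (format == "tsv") {
    genes <- utils::read.delim(path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE, colClasses = "character")
    genes$start <- as.integer(genes$start)
    genes$end <- as.integer(genes$end)
  } else {
    g <- rtracklayer::readGFF(path)
    # GFF3 reserves ';' for attribute separation, so the domains attribute is
    # comma-separated there; normalize to the ';' convention of the TSV dialect
    doms <- if ("domains" %in% names(g)) g$domains else rep("", nrow(g))
    if (!is.character(doms))
      doms <- vapply(as.list(doms), paste, character(1), collapse = ";")
    genes <- data.frame(
      gene_id = as.character(g$ID),
      scaffold = as.character(g$seqid),
      start = as.integer(g$start),
      end = as.integer(g$end),
      strand = as.character(g$strand),
      product = if ("product" %in% names(g)) as.character(g$product) else NA_character_,
      domains = gsub(",", ";", as.character(doms), fixed = TRUE),
      stringsAsFactors = FALSE
    )
    if ("cluster_id" %in% names(g)) genes$cluster_id <- as.character(g$cluster_id)
    genes$domains[is.na(genes$domains)] <- ""
  }
  genes <- validate_gene_table(genes)
  invisible(parse_domains(genes$domains))  # validates codes, warns on unknowns
  rownames(genes) <- NULL
  genes
}

#' Write a gene table in the flat TSV dialect
#'
#' @param genes Gene-model data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  cols <- c(GENE_TABLE_COLS, intersect("cluster_id", names(genes)))
  utils::write.table(genes[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Classify a gene's backbone-enzyme type from its domain architecture
#'
#' Rule table: KS and AT present marks a PKS; the C-A-PCP triad marks an
#' NRPS; both together a PKS-NRPS hybrid; an adenylation (A) domain without a
#' condensation (C) domain an NRPS-like protein; chalcone/stilbene synthase
#' halves a type III PKS; a TPS domain a terpene synthase; anything else is
#' not a backbone enzyme. For (non-hybrid) PKSs the reduction level is `HR`
#' (highly reducing) when KR, DH and ER are all present, `PR` (partially
#' reducing) when some but not all are, and `NR` otherwise.
#'
#' @param architecture Character vector of domain codes (one gene), or a
#'   `;`-separated string.
#' @return A list with `class` (one of `PKS`, `type3_PKS`, `NRPS`,
#'   `NRPS_like`, `PKS_NRPS_hybrid`, `TPS`, `none`) and `reduction` (`HR`,
#'   `PR`, `NR`, or `NA`).
#' @export
classify_backbone <- function(architecture) {
  if (is.character(architecture) && length(architecture) == 1L &&
      grepl(";", architecture))
    architecture <- parse_domains(architecture)[[1]]
  a <- architecture
  has <- function(...) all(c(...) %in% a)
  pks_core <- has("KS", "AT")
  nrps_core <- has("C", "A", "PCP")
  cls <- if (pks_core && nrps_core) "PKS_NRPS_hybrid"
    else if (pks_core) "PKS"
    else if (nrps_core) "NRPS"
    else if (has("CHS_N") || has("CHS_C")) "type3_PKS"
    else if (has("TPS")) "TPS"
    else if (has("A") && !has("C")) "NRPS_like"
    else "none"
  red <- NA_character_
  if (cls == "PKS") {
    nred <- sum(c("KR", "DH", "ER") %in% a)
    red <- if (nred == 3L) "HR" else if (nred > 0L) "PR" else "NR"
  }
  list(class = cls, reduction = red)
}

#' Does an architecture satisfy a required domain set?
#'
#' Set containment: every required code must be present; domain order is not
#' enforced, because the inference argues from domain presence, and iterative
#' fungal PKSs vary in annotated order.
#'
#' @param architecture Character vector of domain codes, or `;`-separated
#'   string.
#' @param required Character vector of required domain codes.
#' @return Logical scalar.
#' @export
matches_required <- function(architecture, required) {
  if (is.character(architecture) && length(architecture) == 1L &&
      grepl(";", architecture))
    architecture <- parse_domains(architecture)[[1]]
  all(required %in% architecture)
}

#' Which genes of a table match a required architecture
#'
#' @param genes Gene-model data.frame.
#' @param required Character vector of required domain codes.
#' @return Logical vector along the rows of `genes`.
#' @export
scan_architecture <- function(genes, required) {
  archs <- parse_domains(genes$domains)
  vapply(archs, matches_required, logical(1), required = required)
}
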