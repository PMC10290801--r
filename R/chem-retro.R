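# Retro-biosynthetic decomposition of polyketide chain specifications into
# the PKS domain inventory and post-assembly enzyme demands they imply.

BETA_STATES <- c("starter", "ketone", "hydroxyl", "enoyl", "reduced")
CORE_PKS_DOMAINS <- c("KS", "AT", "ACP")

#' Ketide unit of a polyketide chain specification
#'
#' One two-carbon chain segment, indexed from the starter unit, annotated with
#' its alpha-methylation and the processing state of its beta carbon.
#'
#' @param index 1-based position from the starter unit.
#' @param alpha_methyl Logical; does the unit carry an alpha (SAM-derived)
#'   methyl branch?
#' @param beta_state One of `"starter"`, `"ketone"`, `"hydroxyl"`, `"enoyl"`,
#'   `"reduced"`. The starter unit (index 1) must have state `"starter"`.
#' @return A `ketide_unit` list.
#' @export
ketide_unit <- function(index, alpha_methyl = FALSE, beta_state = "ketone") {
  index <- as.integer(index)
  if (is.na(index) || index < 1L) stop("unit index must be a positive integer")
  beta_state <- match.arg(beta_state, BETA_STATES)
  if ((index == 1L) != (beta_state == "starter"))
    stop("beta_state 'starter' is required for, and restricted to, unit index 1")
  structure(list(index = index, alpha_methyl = isTRUE(alpha_methyl),
                 beta_state = beta_state),
            class = "ketide_unit")
}

#' Polyketide chain specification
#'
#' An ordered sequence of ketide units plus the release mechanism of the
#' assembled chain. This is the substrate of retro-biosynthetic decomposition:
#' the chain as drawn from the compound structure, before any post-assembly
#' tailoring.
#'
#' @param name Chain label.
#' @param units List of [ketide_unit()] objects with contiguous indices from 1.
#' @param release One of `"pyrone_cyclization"`, `"hydrolysis"`,
#'   `"ester_transfer"` — how the chain leaves the synthase.
#' @return A `chain_spec` list.
#' @export
chain_spec <- function(name, units,
                       release = c("pyrone_cyclization", "hydrolysis", "ester_transfer")) {
  release <- match.arg(release)
  if (length(units) < 1L) stop("a chain needs at least one ketide unit")
  idx <- vapply(units, function(u) u$index, integer(1))
  if (!identical(idx, seq_along(units)))
    stop("unit indices must be contiguous from 1 in order")
  structure(list(name = name, units = units, release = release),
            class = "chain_spec")
}

#' Tailoring domains implied by one ketide unit
#'
#' The beta-carbon state fixes which reductive domains must have acted in that
#' iteration: a retained ketone needs none, a hydroxyl needs the ketoreductase
#' (KR), an enoyl additionally the dehydratase (DH), and a fully reduced
#' methylene the enoylreductase (ER) on top. An alpha methyl adds the
#' C-methyltransferase (MT).
#'
#' @param beta_state Beta-carbon state (not `"starter"`).
#' @param alpha_methyl Logical.
#' @return Character vector of domain codes (possibly empty).
#' @export
module_tailoring <- function(beta_state, alpha_methyl = FALSE) {
  beta_state <- match.arg(beta_state, BETA_STATES)
  if (beta_state == "starter")
    stop("starter units undergo no extension and have no tailoring domains")
  doms <- switch(beta_state,
                 ketone   = character(0),
                 hydroxyl = "KR",
                 enoyl    = c("KR", "DH"),
                 reduced  = c("KR", "DH", "ER"))
  if (isTRUE(alpha_methyl)) doms <- c(doms, "MT")
  doms
}

#' Decompose a chain specification into synthase requirements
#'
#' Counts the ketide units, the malonyl-CoA extension condensations (units
#' minus one: every unit beyond the starter is one extension), and the alpha
#' methyls, and derives the full domain set the iterative synthase must carry:
#' the condensation core (KS, AT, ACP) plus the union of per-iteration
#' tailoring domains.
#'
#' @param spec A [chain_spec()].
#' @return A `chain_requirements` list with fields `units`, `extensions`,
#'   `methyls`, `required_domains`, `per_module_tailoring`.
#' @export
decompose_chain <- function(spec) {
  stopifnot(inherits(spec, "chain_spec"))
  n <- length(spec$units)
  ext <- lapply(spec$units[-1], function(u) module_tailoring(u$beta_state, u$alpha_methyl))
  methyls <- sum(vapply(spec$units, function(u) u$alpha_methyl, logical(1)))
  structure(list(
    name = spec$name,
    units = n,
    extensions = n - 1L,
    methyls = as.integer(methyls),
    required_domains = required_domains_from_tailoring(ext),
    per_module_tailoring = ext
  ), class = "chain_requirements")
}

required_domains_from_tailoring <- function(tailoring_sets) {
  extra <- unique(unlist(tailoring_sets))
  # canonical N- to C-terminal domain order of an iterative HR-PKS
  canon <- c("KS", "AT", "DH", "MT", "ER", "KR", "ACP")
  intersect(canon, union(CORE_PKS_DOMAINS, extra))
}

#' Required domain set of a decomposed chain
#'
#' @param req A `chain_requirements` object from [decompose_chain()].
#' @return Character vector of domain codes in canonical HR-PKS order.
#' @export
required_domains <- function(req) {
  stopifnot(inherits(req, "chain_requirements"))
  req$required_domains
}

#' Compound specification
#'
#' A multi-chain polyketide compound: its chains, inter-chain ester links,
#' post-assembly hydroxylation positions, and molecular formula. Construction
#' enforces the carbon bookkeeping identity: each ketide unit contributes two
#' backbone carbons and each alpha methyl one, so
#' `sum(2 * units + methyls)` over chains must equal the formula's carbon
#' count.
#'
#' @param name Compound name.
#' @param chains List of [chain_spec()] objects.
#' @param ester_links List of `(chain_name, position)` pairs (may be empty).
#' @param post_pks_hydroxylations Character vector of carbon positions
#'   hydroxylated after chain assembly (tailoring P450 demand).
#' @param formula Molecular formula (string or `molecular_formula`).
#' @return A `compound_spec` list.
#' @export
compound_spec <- function(name, chains, ester_links = list(),
                          post_pks_hydroxylations = character(0), formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(all(vapply(chains, inherits, logical(1), "chain_spec")))
  carbons <- sum(vapply(chains, function(ch) {
    2L * length(ch$units) +
      sum(vapply(ch$units, function(u) u$alpha_methyl, logical(1)))
  }, numeric(1)))
  fc <- unclass(formula)[["C"]]
  if (is.na(fc) || carbons != fc)
    stop(sprintf(
      "carbon bookkeeping violation: chains account for %d backbone+methyl carbons but formula %s has %d",
      carbons, format_formula(formula), fc))
  structure(list(name = name, chains = chains, ester_links = ester_links,
                 post_pks_hydroxylations = post_pks_hydroxylations,
                 formula = formula),
            class = "compound_spec")
}

#' Retro-biosynthetic report for a compound
#'
#' Decomposes every chain and derives the post-assembly enzyme demands:
#' an O-acyltransferase whenever chains are joined by an ester link, a
#' standalone (trans) thioesterase whenever a chain is released by hydrolysis
#' or pyrone cyclization without an intrinsic release domain, and one
#' cytochrome P450 demand per post-assembly hydroxylation (reported as a
#' merged count, since a single P450 may act at several positions).
#'
#' @param spec A [compound_spec()].
#' @return A `retro_report` list: `chains` (list of `chain_requirements`) and
#'   `post_pks_enzymes` (named integer vector of demand counts).
#' @export
retro_compound <- function(spec) {
  stopifnot(inherits(spec, "compound_spec"))
  reqs <- lapply(spec$chains, decompose_chain)
  demands <- integer(0)
  if (length(spec$ester_links) > 0)
    demands["O_acyltransferase"] <- 1L
  releases <- vapply(spec$chains, function(ch) ch$release, character(1))
  if (any(releases %in% c("hydrolysis", "pyrone_cyclization")))
    demands["trans_thioesterase"] <- 1L
  if (length(spec$post_pks_hydroxylations) > 0)
    demands["cytochrome_p450"] <- length(spec$post_pks_hydroxylations)
  structure(list(compound = spec$name, chains = reqs, post_pks_enzymes = demands),
            class = "retro_report")
}

#' @export
print.retro_report <- function(x, ...) {
  cat("<retro_report>", x$compound, "\n")
  for (r in x$chains)
    cat(sprintf("  %s: %d units, %d malonyl extensions, %d methyls; domains {%s}\n",
                r$name, r$units, r$extensions, r$methyls,
                paste(r$required_domains, collapse = ",")))
  if (length(x$post_pks_enzymes))
    cat("  post-assembly demands:",
        paste(sprintf("%s x%d", names(x$post_pks_enzymes), x$post_pks_enzymes),
              collapse = ", "), "\n")
  invisible(x)
}

#' The rasfonin compound specification
#'
#' Rasfonin is an alpha-pyrone natural product built from two acetate-derived
#' polyketide chains joined by an ester bond: a 6,8,10-trimethylated,
#' partially reduced hexaketide carrying the pyrone head, and a
#' 4',6'-dimethylated tetraketide. The hexaketide leaves its synthase by
#' thioesterase-mediated pyrone formation (no intrinsic release domain); the
#' tetraketide is captured by an O-acyltransferase and transferred onto the
#' hexaketide. Hydroxylations at C4, C8' and C10' happen after chain assembly
#' (cytochrome P450 tailoring). Unit indices count from the starter unit, so
#' the methyl positions C10/C8/C6 of the hexaketide sit on units 2-4 and
#' C6'/C4' of the tetraketide on units 2-3. The beta-carbon states are chosen
#' to match the reduction pattern of the final chains; unit and methyl counts
#' are fixed by the structure.
#'
#' @return A [compound_spec()] for rasfonin (C25H38O6).
#' @export
rasfonin_compound <- function() {
  hexa <- chain_spec(
    "hexaketide",
    list(
      ketide_unit(1, FALSE, "starter"),
      ketide_unit(2, TRUE,  "reduced"),
      ketide_unit(3, TRUE,  "reduced"),
      ketide_unit(4, TRUE,  "enoyl"),
      ketide_unit(5, FALSE, "hydroxyl"),
      ketide_unit(6, FALSE, "ketone")
    ),
    release = "pyrone_cyclization"
  )
  tetra <- chain_spec(
    "tetraketide",
    list(
      ketide_unit(1, FALSE, "starter"),
      ketide_unit(2, TRUE,  "reduced"),
      ketide_unit(3, TRUE,  "enoyl"),
      ketide_unit(4, FALSE, "reduced")
    ),
    release = "ester_transfer"
  )
  compound_spec(
    "rasfonin",
    chains = list(hexa, tetra),
    ester_links = list(list(chain = "tetraketide", position = "C4")),
    post_pks_hydroxylations = c("C4", "C8'", "C10'"),
    formula = "C25H38O6"
  )
}

#' Read a compound specification from a YAML file
#'
#' Expected keys: `name`, `formula`, `chains` (each with `name`, `release`,
#' and `units`, a list of `{alpha_methyl, beta_state}` entries in order),
#' optional `ester_links` (`{chain, position}`) and
#' `post_pks_hydroxylations`.
#'
#' @param path Path to a YAML compound file.
#' @return A [compound_spec()].
#' @export
read_compound_spec <- function(path) {
  y <- yaml::read_yaml(path)
  for (k in c("name", "formula", "chains"))
    if (is.null(y[[k]])) stop("compound file is missing key: ", k)
  chains <- lapply(y$chains, function(ch) {
    units <- lapply(seq_along(ch$units), function(i) {
      u <- ch$units[[i]]
      ketide_unit(i, isTRUE(u$alpha_methyl), u$beta_state)
    })
    chain_spec(ch$name, units, release = ch$release)
  })
  compound_spec(
    y$name, chains,
    ester_links = if (is.null(y$ester_links)) list() else y$ester_links,
    post_pks_hydroxylations = as.character(y$post_pks_hydroxylations %||% character(0)),
    formula = y$formula
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
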