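# Synthetic genomes, domain annotations and negative binomial count data
# with the statistical structure the inference assumes: one planted
# rasfonin-like cluster (silent at 24 h, expressed at 48 h), decoy clusters,
# and condition-invariant background genes.

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline targets: a planted
#' 9-gene rasfonin-like cluster whose genes are silent during active growth
#' (true mean RPKM 0.5) and expressed in stationary phase (true mean RPKM
#' 16), three replicates per condition, negative binomial counts with
#' dispersion 0.1, and decoys that exercise every filtering rule (a silent
#' two-HR-PKS cluster with a transferase, single-PKS clusters, an NRPS
#' cluster). Gene lengths are log-normal (median 1.5 kb) and intergenic gaps
#' uniform on 0.5-5 kb, so the default 10 kb grouping distance keeps clusters
#' intact.
#'
#' @param seed Integer RNG seed; every downstream draw is reproducible from
#'   it.
#' @param n_scaffolds,n_genes Genome layout.
#' @param planted_cluster Plant the rasfonin-like 9-gene cluster?
#' @param decoys Named counts:
#'   `c(silent_two_pks = , single_pks = , nrps = )`.
#' @param nb_dispersion Negative binomial dispersion (variance = mu +
#'   dispersion * mu^2); values below 1e-8 fall back to Poisson draws.
#' @param expressed_mean_rpkm,silent_mean_rpkm True mean RPKM of planted
#'   genes in the expressed / silent condition.
#' @param replicates_per_condition Samples per time point.
#' @param read_depth Library size (reads per sample).
#' @param background_silent_frac Fraction of background genes that are
#'   constitutively silent.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_scaffolds = 3L, n_genes = 120L,
                       planted_cluster = TRUE,
                       decoys = c(silent_two_pks = 1L, single_pks = 2L, nrps = 1L),
                       nb_dispersion = 0.1,
                       expressed_mean_rpkm = 16, silent_mean_rpkm = 0.5,
                       replicates_per_condition = 3L, read_depth = 5e6,
                       background_silent_frac = 0.25) {
  stopifnot(expressed_mean_rpkm >= 2, silent_mean_rpkm < 2,
            nb_dispersion >= 0, all(decoys >= 0))
  structure(list(seed = as.integer(seed), n_scaffolds = as.integer(n_scaffolds),
                 n_genes = as.integer(n_genes),
                 planted_cluster = isTRUE(planted_cluster),
                 decoys = decoys, nb_dispersion = nb_dispersion,
                 expressed_mean_rpkm = expressed_mean_rpkm,
                 silent_mean_rpkm = silent_mean_rpkm,
                 replicates_per_condition = as.integer(replicates_per_condition),
                 read_depth = read_depth,
                 background_silent_frac = background_silent_frac),
            class = "sim_config")
}

# Domain strings for the planted cluster, in rsf role order.
planted_cluster_domains <- function() rsf_genes()$domains

decoy_domains <- list(
  silent_two_pks = c("KS;AT;DH;MT;ER;KR;ACP", "P450", "cAT", "UNK",
                     "KS;AT;DH;MT;ER;KR;ACP"),
  single_pks = c("KS;AT;DH;MT;ER;KR;ACP", "P450", "MFS"),
  nrps = c("C;A;PCP", "P450", "MFS")
)

#' Generate a synthetic annotated genome
#'
#' Lays out `n_genes` genes over `n_scaffolds` scaffolds, plants the 9-gene
#' rasfonin-like cluster (two full-architecture HR-PKSs flanking an
#' O-acyltransferase, three P450s, an MFS transporter, a thioesterase and one
#' unknown) and the configured decoy clusters at random non-overlapping
#' positions, and assigns every gene a true mean RPKM per condition: planted
#' genes are silent at 24 h and expressed at 48 h; all other genes
#' (background and decoys) are condition-invariant, a configured fraction of
#' them constitutively silent.
#'
#' @param config A [sim_config()].
#' @return A list: `genes` (gene-model data.frame) and `truth` (planted gene
#'   ids and span, decoy gene ids by type, per-gene true RPKM matrix,
#'   per-gene lengths).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  planted_n <- if (config$planted_cluster) 9L else 0L
  decoy_sizes <- vapply(names(config$decoys), function(d)
    length(decoy_domains[[d]]) * config$decoys[[d]], integer(1))
  if (planted_n + sum(decoy_sizes) > n)
    stop("config infeasible: cluster genes exceed n_genes")

  scaffold <- sort(sample(paste0("scf_", seq_len(config$n_scaffolds)), n,
                          replace = TRUE))
  len <- pmax(300L, as.integer(round(stats::rlnorm(n, log(1500), 0.35))))
  genes <- data.frame(
    gene_id = sprintf("SYN_%05d", seq_len(n)),
    scaffold = scaffold, start = NA_integer_, end = NA_integer_,
    strand = sample(c("+", "-"), n, replace = TRUE),
    product = "hypothetical protein",
    domains = "",
    stringsAsFactors = FALSE
  )

  # choose non-overlapping index blocks for planted + decoy clusters,
  # confined to single scaffolds
  blocks <- list()
  used <- rep(FALSE, n)
  place_block <- function(size) {
    ok <- which(vapply(seq_len(n - size + 1L), function(i) {
      idx <- i:(i + size - 1L)
      !any(used[idx]) && length(unique(scaffold[idx])) == 1L
    }, logical(1)))
    if (!length(ok)) stop("config infeasible: no room to place a cluster block")
    i <- if (length(ok) == 1L) ok else sample(ok, 1L)
    used[i:(i + size - 1L)] <<- TRUE
    i:(i + size - 1L)
  }
  planted_idx <- integer(0)
  if (config$planted_cluster) {
    planted_idx <- place_block(9L)
    genes$domains[planted_idx] <- planted_cluster_domains()
    genes$product[planted_idx] <- rsf_genes()$role
  }
  decoy_idx <- list()
  for (d in names(config$decoys)) {
    reps <- config$decoys[[d]]
    decoy_idx[[d]] <- lapply(seq_len(reps), function(k) {
      idx <- place_block(length(decoy_domains[[d]]))
      genes$domains[idx] <<- decoy_domains[[d]]
      genes$product[idx] <<- paste0(d, " decoy gene")
      idx
    })
  }

  # lay out coordinates: tight gaps (0.5-5 kb) inside cluster blocks, wide
  # gaps (15-30 kb) everywhere else, so a 10 kb grouping distance keeps
  # planted and decoy clusters intact and isolated from background genes
  in_block_gap <- rep(FALSE, n)
  all_blocks <- c(if (length(planted_idx)) list(planted_idx) else list(),
                  unlist(decoy_idx, recursive = FALSE))
  for (blk in all_blocks)
    if (length(blk) > 1L) in_block_gap[blk[-1]] <- TRUE
  gap <- ifelse(in_block_gap,
                as.integer(round(stats::runif(n, 500, 5000))),
                as.integer(round(stats::runif(n, 15000, 30000))))
  pos <- 1L
  for (i in seq_len(n)) {
    if (i > 1L && scaffold[i] != scaffold[i - 1L]) pos <- 1L
    genes$start[i] <- pos + gap[i]
    genes$end[i] <- genes$start[i] + len[i] - 1L
    pos <- genes$end[i]
  }

  # true expression: planted genes switch conditions; everything else is
  # condition-invariant
  silent_bg <- stats::runif(n) < config$background_silent_frac
  bg_level <- ifelse(silent_bg, 0.4, stats::rlnorm(n, log(20), 0.8))
  true_rpkm <- cbind(`24h` = bg_level, `48h` = bg_level)
  if (config$planted_cluster) {
    true_rpkm[planted_idx, "24h"] <- config$silent_mean_rpkm
    true_rpkm[planted_idx, "48h"] <- config$expressed_mean_rpkm
  }
  for (k in seq_along(decoy_idx$silent_two_pks)) {
    idx <- decoy_idx$silent_two_pks[[k]]
    true_rpkm[idx, ] <- config$silent_mean_rpkm
  }
  rownames(true_rpkm) <- genes$gene_id

  truth <- list(
    planted_gene_ids = genes$gene_id[planted_idx],
    planted_scaffold = if (length(planted_idx)) scaffold[planted_idx[1]] else NA,
    decoy_gene_ids = lapply(decoy_idx, function(l)
      lapply(l, function(idx) genes$gene_id[idx])),
    true_rpkm = true_rpkm,
    lengths_bp = stats::setNames(len, genes$gene_id)
  )
  list(genes = genes, truth = truth)
}

#' Generate negative binomial counts for a simulated genome
#'
#' Per gene and sample, the expected count is
#' `true RPKM * length_bp * read_depth / 1e9`; counts are drawn negative
#' binomial with the configured dispersion (Poisson in the zero-dispersion
#' limit). Planted cluster genes use the silent mean at 24 h and the
#' expressed mean at 48 h; all other genes are condition-invariant.
#'
#' The simulated gene set is a window of a full transcriptome: its counts
#' sum to far less than the library size. The returned `lib_sizes` therefore
#' carry the configured read depth (the full-library denominator for RPKM),
#' not the column sums, and must be passed on to [expression_table()].
#'
#' @param config A [sim_config()].
#' @param truth Truth object from [generate_genome()].
#' @return A list: `counts` (genes x samples integer matrix), `conditions`
#'   (per-sample labels), `lengths_bp`, `lib_sizes`.
#' @export
generate_counts <- function(config, truth) {
  set.seed(config$seed + 10000L)
  reps <- config$replicates_per_condition
  conditions <- rep(c("24h", "48h"), each = reps)
  mu <- truth$true_rpkm[, conditions, drop = FALSE] *
    truth$lengths_bp * config$read_depth / 1e9
  draw <- function(m) {
    if (config$nb_dispersion < 1e-8) stats::rpois(length(m), m)
    else stats::rnbinom(length(m), mu = m, size = 1 / config$nb_dispersion)
  }
  counts <- matrix(draw(mu), nrow = nrow(mu),
                   dimnames = list(rownames(truth$true_rpkm),
                                   paste0("S", conditions, "_", rep(seq_len(reps), 2))))
  list(counts = counts, conditions = conditions, lengths_bp = truth$lengths_bp,
       lib_sizes = rep(config$read_depth, length(conditions)))
}

#' Random scaffold sequences for a simulated gene table
#'
#' Emits one random DNA sequence per scaffold, long enough to contain its
#' genes; useful when a FASTA companion to the simulated annotation is
#' needed.
#'
#' @param genes Simulated gene table.
#' @param seed RNG seed.
#' @param gc Target GC fraction (default 0.55, a fungal genome-wide value).
#' @return A `Biostrings::DNAStringSet`, one entry per scaffold.
#' @export
sim_genome_fasta <- function(genes, seed = 1L, gc = 0.55) {
  set.seed(seed)
  scfs <- unique(genes$scaffold)
  seqs <- vapply(scfs, function(s) {
    L <- max(genes$end[genes$scaffold == s]) + 1000L
    paste(sample(c("A", "T", "G", "C"), L, replace = TRUE,
                 prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
          collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(stats::setNames(seqs, scfs))
}
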