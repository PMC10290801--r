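# Deterministic reference dataset: the Chalara gorgonifer backbone-gene
# inventory, cluster assignments, PKS domain architectures and rsf-locus
# expression states used to validate the inference chain end to end.
#
# Encoded facts: 24 predicted clusters holding 308 genes and 29 backbone
# genes (ten PKSs, three PKS-NRPS hybrids, one type III PKS, NRPSs,
# NRPS-like proteins, three terpene synthases); 14 PKS-class genes of which
# seven carry the full reducing architecture {KS,AT,DH,MT,ER,KR,ACP}; two
# clusters with a co-localized matching pair plus transferase (the rsf locus
# with CgPKS4/CgPKS5 and DNG_02776, and the silent CgPKS10/CgPKS11 cluster
# with DNG_07106); the rsf pair expressed at 48 h only, the CgPKS10/11 pair
# silent at both time points; and backbone expression categories totalling
# 14 Cat1, 3 Cat2 and 12 Cat3. Coordinates and filler genes are synthetic.

#' Deterministic reference genome-mining dataset
#'
#' Builds, entirely in code, the annotated gene table, cluster assignments
#' and per-gene condition-mean RPKM values of the reference genome-mining
#' scenario: the rasfonin (rsf) locus DNG_02774-DNG_02782 inside cluster 6
#' with non-coregulated flanking genes, the silent two-HR-PKS decoy cluster
#' 12, 22 further clusters carrying the remaining backbone genes, and filler
#' tailoring genes bringing the clustered gene total to 308.
#'
#' @return A list:
#'   \describe{
#'     \item{genes}{gene-model data.frame with `cluster_id` (NA for
#'       unclustered flanks).}
#'     \item{expression}{expression records built with
#'       [records_from_rpkm()].}
#'     \item{pks_gene_ids}{ids of the 14 PKS-class genes (CgPKS1-CgPKS14).}
#'     \item{backbone_gene_ids}{ids of the 29 in-cluster backbone genes.}
#'     \item{required_domains}{the full reducing PKS architecture.}
#'   }
#' @export
reference_fixture <- function() {
  full <- "KS;AT;DH;MT;ER;KR;ACP"
  hybrid <- "KS;AT;KR;ACP;C;A;PCP"
  rsf <- rsf_genes()

  # backbone gene placement: cluster -> (slot within cluster, id, domains,
  # CgPKS label where applicable, rpkm at 24h/48h)
  bb <- list(
    list(cl = 1, slot = 4, domains = "C;A;PCP", label = "NRPS", rpkm = c(0.3, 0.5)),
    list(cl = 1, slot = 9, domains = "A", label = "NRPS-like", rpkm = c(15, 16)),
    list(cl = 2, slot = 4, domains = "C;A;PCP", label = "NRPS", rpkm = c(5, 25)),
    list(cl = 2, slot = 9, domains = "A", label = "NRPS-like", rpkm = c(15, 16)),
    list(cl = 3, slot = 4, domains = "C;A;PCP", label = "NRPS", rpkm = c(5, 25)),
    list(cl = 3, slot = 9, domains = "A", label = "NRPS-like", rpkm = c(15, 16)),
    list(cl = 4, slot = 7, domains = "KS;AT;DH;ER;KR;ACP", label = "CgPKS1", rpkm = c(0.3, 0.5)),
    list(cl = 5, slot = 7, domains = full, label = "CgPKS2", rpkm = c(5, 25)),
    # cluster 6 backbone genes (CgPKS4/CgPKS5) are laid down with the locus
    list(cl = 7, slot = 7, domains = "KS;AT;DH;MT;KR;ACP", label = "CgPKS3", rpkm = c(0.4, 0.6)),
    list(cl = 8, slot = 7, domains = "KS;AT;KR;ACP", label = "CgPKS6", rpkm = c(0.2, 0.3)),
    list(cl = 9, slot = 7, domains = full, label = "CgPKS7", rpkm = c(5, 25)),
    list(cl = 10, slot = 7, domains = hybrid, label = "CgPKS8", rpkm = c(0.5, 0.8)),
    list(cl = 11, slot = 7, domains = hybrid, label = "CgPKS9", rpkm = c(5, 25)),
    # cluster 12: CgPKS10 / transferase / CgPKS11, all silent
    list(cl = 12, slot = 6, domains = full, label = "CgPKS10", rpkm = c(0.3, 0.4)),
    list(cl = 12, slot = 8, domains = full, label = "CgPKS11", rpkm = c(0.3, 0.4)),
    list(cl = 13, slot = 7, domains = hybrid, label = "CgPKS12", rpkm = c(5, 25)),
    list(cl = 14, slot = 7, domains = full, label = "CgPKS13", rpkm = c(15, 16)),
    list(cl = 15, slot = 7, domains = "CHS_N;CHS_C", label = "CgPKS14", rpkm = c(0.4, 0.5)),
    list(cl = 16, slot = 7, domains = "C;A;PCP", label = "NRPS", rpkm = c(10, 0.4)),
    list(cl = 17, slot = 7, domains = "C;A;PCP", label = "NRPS", rpkm = c(0.3, 0.4)),
    list(cl = 18, slot = 7, domains = "C;A;PCP", label = "NRPS", rpkm = c(5, 25)),
    list(cl = 19, slot = 7, domains = "A", label = "NRPS-like", rpkm = c(0.3, 0.4)),
    list(cl = 20, slot = 7, domains = "A", label = "NRPS-like", rpkm = c(0.5, 0.6)),
    list(cl = 21, slot = 7, domains = "A", label = "NRPS-like", rpkm = c(15, 16)),
    list(cl = 22, slot = 7, domains = "TPS", label = "TPS", rpkm = c(0.3, 0.4)),
    list(cl = 23, slot = 7, domains = "TPS", label = "TPS", rpkm = c(0.4, 0.5)),
    list(cl = 24, slot = 7, domains = "TPS", label = "TPS", rpkm = c(0.2, 0.3))
  )

  rows <- list()
  rpkms <- list()
  add_gene <- function(gene_id, scaffold, slot, domains, product, cluster_id,
                       rpkm24, rpkm48, length_bp = 1500L) {
    start <- 2000L + (slot - 1L) * 9000L
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = gene_id, scaffold = scaffold, start = start,
      end = start + length_bp - 1L,
      strand = if (slot %% 2L == 0L) "-" else "+",
      product = product, domains = domains, cluster_id = cluster_id,
      stringsAsFactors = FALSE)
    rpkms[[length(rpkms) + 1L]] <<- data.frame(
      gene_id = gene_id, rpkm_24h = rpkm24, rpkm_48h = rpkm48,
      stringsAsFactors = FALSE)
  }

  for (cl in setdiff(1:24, 6L)) {
    scf <- sprintf("scf_%02d", cl)
    bb_here <- Filter(function(b) b$cl == cl, bb)
    bb_slots <- vapply(bb_here, `[[`, numeric(1), "slot")
    for (slot in 1:13) {
      hit <- which(bb_slots == slot)
      if (cl == 12L) {
        gid <- sprintf("DNG_%05d", 7099L + slot)
      } else {
        gid <- sprintf("DNG_%05d", 10000L + cl * 100L + slot)
      }
      if (length(hit) == 1L) {
        b <- bb_here[[hit]]
        add_gene(gid, scf, slot, b$domains, paste0("backbone ", b$label),
                 as.character(cl), b$rpkm[1], b$rpkm[2],
                 length_bp = if (grepl("KS", b$domains)) 7500L else 1500L)
      } else if (cl == 12L && slot == 7L) {
        # DNG_07106, the transferase between CgPKS10 and CgPKS11
        add_gene(gid, scf, slot, "cAT", "putative carnitine acyltransferase",
                 "12", 0.3, 0.4)
      } else {
        add_gene(gid, scf, slot, "", "hypothetical protein", as.character(cl),
                 15, 15)
      }
    }
  }

  # cluster 6: three non-coregulated flanks, the nine rsf genes, three
  # non-coregulated flanks; flanks are outside the predicted cluster
  scf <- "scf_06"
  flank_left <- list(c(20, 22), c(15, 16), c(18, 19))   # Cat3: expressed at both
  for (i in 1:3)
    add_gene(sprintf("DNG_%05d", 2770L + i), scf, i, "", "hypothetical protein",
             NA_character_, flank_left[[i]][1], flank_left[[i]][2])
  for (i in 1:9)
    add_gene(rsf$gene_id[i], scf, 3L + i, rsf$domains[i], rsf$role[i], "6",
             0.5, 24,
             length_bp = if (grepl("KS", rsf$domains[i])) 7500L else 1500L)
  flank_right <- list(c(0.3, 0.4), c(12, 13), c(0.2, 0.3))  # Cat1 / Cat3 mix
  for (i in 1:3)
    add_gene(sprintf("DNG_%05d", 2782L + i), scf, 12L + i, "",
             "hypothetical protein", NA_character_,
             flank_right[[i]][1], flank_right[[i]][2])

  genes <- do.call(rbind, rows)
  genes <- genes[order(genes$scaffold, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  rp <- do.call(rbind, rpkms)
  expression <- records_from_rpkm(rp$gene_id, rp$rpkm_24h, rp$rpkm_48h)

  labels <- vapply(bb, `[[`, character(1), "label")
  pks_ids <- c(
    genes$gene_id[match(paste0("backbone ",
                               labels[grepl("^CgPKS", labels)]),
                        genes$product)],
    rsf$gene_id[c(1, 9)]  # CgPKS4, CgPKS5
  )
  backbone_ids <- c(genes$gene_id[grepl("^backbone ", genes$product)],
                    rsf$gene_id[c(1, 9)])
  list(
    genes = genes,
    expression = expression,
    pks_gene_ids = sort(pks_ids),
    backbone_gene_ids = sort(backbone_ids),
    required_domains = c("KS", "AT", "DH", "MT", "ER", "KR", "ACP")
  )
}
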