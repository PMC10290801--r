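two_gene_table <- function(gap) {
  data.frame(
    gene_id = c("a", "b"), scaffold = "s1",
    start = c(1000L, 3000L + gap), end = c(3000L, 5000L + gap),
    strand = "+", product = "x", domains = "",
    stringsAsFactors = FALSE
  )
}

full_arch <- "KS;AT;DH;MT;ER;KR;ACP"
req <- c("KS", "AT", "DH", "MT", "ER", "KR", "ACP")

candidate_cluster <- function(with_transferase = TRUE, cluster = "c1",
                              scaffold = "s1", offset = 0L) {
  doms <- c(full_arch, "P450", if (with_transferase) "OAT" else "MFS",
            full_arch)
  data.frame(
    gene_id = paste0(cluster, "_g", seq_along(doms)),
    scaffold = scaffold,
    start = offset + seq_along(doms) * 5000L,
    end = offset + seq_along(doms) * 5000L + 2000L,
    strand = "+", product = "x", domains = doms, cluster_id = cluster,
    stringsAsFactors = FALSE
  )
}

test_that("distance grouping splits at the gap threshold", {
  near <- group_clusters(two_gene_table(5000L), max_gap_bp = 10000)
  expect_equal(length(unique(near$cluster_id)), 1L)
  far <- group_clusters(two_gene_table(15000L), max_gap_bp = 10000)
  expect_equal(length(unique(far$cluster_id)), 2L)
  expect_equal(attr(far, "cluster_source"), "distance_grouping")
})

test_that("grouping partitions genes and rejects unsorted input", {
  set.seed(41)
  g <- generate_genome(sim_config(seed = 41))$genes
  grouped <- group_clusters(g)
  expect_equal(nrow(grouped), nrow(g))
  expect_false(anyNA(grouped$cluster_id))
  expect_equal(sum(table(grouped$cluster_id)), nrow(g))
  # clusters are scaffold-confined runs
  expect_true(all(tapply(grouped$scaffold, grouped$cluster_id,
                         function(s) length(unique(s))) == 1L))
  expect_error(group_clusters(g[rev(seq_len(nrow(g))), ]), "sorted")
})

test_that("a given cluster assignment passes through untouched", {
  g <- candidate_cluster()
  grouped <- group_clusters(g, max_gap_bp = 1)
  expect_equal(attr(grouped, "cluster_source"), "given")
  expect_equal(unique(grouped$cluster_id), "c1")
})

test_that("candidate selection needs two matching synthases and a transferase", {
  g <- candidate_cluster()
  cands <- find_candidates(g, req)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$n_matching, 2L)
  expect_true(cands$has_transferase)

  # no transferase: excluded under the default, kept when the rule is lifted
  g2 <- candidate_cluster(with_transferase = FALSE)
  expect_equal(nrow(find_candidates(g2, req)), 0L)
  expect_equal(nrow(find_candidates(g2, req, require_transferase = FALSE)), 1L)

  # a single matching synthase is never enough
  g3 <- g[1:3, ]
  expect_equal(nrow(find_candidates(g3, req)), 0L)

  # zero PKS genes: empty result with stable columns
  g4 <- g; g4$domains <- "P450"
  empty <- find_candidates(g4, req)
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("cluster_id", "matching_pks", "verdict") %in% names(empty)))
})

test_that("shrinking the required set never removes a candidate", {
  fx <- reference_fixture()
  grouped <- group_clusters(fx$genes)
  full_cands <- find_candidates(grouped, req)$cluster_id
  for (drop in req) {
    smaller <- setdiff(req, drop)
    expect_true(all(full_cands %in% find_candidates(grouped, smaller)$cluster_id))
  }
})

test_that("the expression filter ranks producing candidates first and keeps silent ones", {
  g <- rbind(candidate_cluster(cluster = "c1", scaffold = "s1"),
             candidate_cluster(cluster = "c2", scaffold = "s2"))
  rec <- records_from_rpkm(
    g$gene_id,
    rpkm_24h = rep(0.5, nrow(g)),
    rpkm_48h = ifelse(g$cluster_id == "c2", 0.5, 20)  # c2 silent throughout
  )
  cands <- apply_expression_filter(find_candidates(g, req), rec)
  expect_equal(cands$verdict, c("producing_pattern", "silent"))
  expect_equal(cands$cluster_id, c("c1", "c2"))
  expect_equal(cands$rank, 1:2)

  # all candidates silent: zero producing-pattern verdicts
  rec_all_silent <- records_from_rpkm(g$gene_id, rep(0.5, nrow(g)),
                                      rep(0.5, nrow(g)))
  cands2 <- apply_expression_filter(find_candidates(g, req), rec_all_silent)
  expect_equal(sum(cands2$verdict == "producing_pattern"), 0L)

  # a missing record is an error, not a silent mis-rank
  expect_error(apply_expression_filter(find_candidates(g, req), rec[-1, ]),
               "missing expression record")
})

test_that("the rsf knowledge table is complete and internally consistent", {
  rsf <- rsf_genes()
  expect_equal(nrow(rsf), 9L)
  expect_equal(rsf$gene_id, sprintf("DNG_%05d", 2774:2782))
  expect_equal(sum(grepl("HR-PKS", rsf$role)), 2L)
  expect_equal(sum(rsf$domains == "P450"), 3L)
  cls <- classify_backbone(parse_domains(rsf$domains[1])[[1]])
  expect_equal(cls, list(class = "PKS", reduction = "HR"))
})
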