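# Independent oracles and small generators used across tests.

# All integer partitions of n (as length vectors), brute force.
partitions_of <- function(n) {
  rec <- function(n, max_part) {
    if (n == 0) return(list(integer(0)))
    out <- list()
    for (k in seq_len(min(n, max_part)))
      out <- c(out, lapply(rec(n - k, k), function(p) c(k, p)))
    out
  }
  rec(n, n)
}

# N50 straight from the definition: the largest length L present such that
# scaffolds of length >= L cover at least half the total.
n50_oracle <- function(lengths) {
  total <- sum(lengths)
  ok <- Filter(function(L) sum(lengths[lengths >= L]) >= total / 2,
               unique(lengths))
  max(unlist(ok))
}

# Random chain specification for property tests.
random_chain <- function(n_units) {
  units <- lapply(seq_len(n_units), function(i) {
    if (i == 1) ketide_unit(1, sample(c(TRUE, FALSE), 1), "starter")
    else ketide_unit(i, sample(c(TRUE, FALSE), 1),
                     sample(c("ketone", "hydroxyl", "enoyl", "reduced"), 1))
  })
  chain_spec(paste0("chain", n_units), units,
             release = sample(c("pyrone_cyclization", "hydrolysis",
                                "ester_transfer"), 1))
}

# One full simulated run at the default study conditions.
run_sim_pipeline <- function(seed) {
  cfg <- sim_config(seed = seed)
  g <- generate_genome(cfg)
  cm <- generate_counts(cfg, g$truth)
  rec <- expression_table(cm$counts, cm$lengths_bp, cm$conditions, cm$lib_sizes)
  list(config = cfg, genome = g, counts = cm, records = rec,
       prediction = predict_bgc(g$genes, rec))
}
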