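# small configurations shared across tests; sizes chosen so each file runs in
# seconds while keeping every structural feature of the full design

small_cfg <- function(..., rng_seed = 42) {
  sim_config(n_genes = 800,
             seeds_per_timepoint = 48,
             program_sizes = c(group1 = 60, group2 = 30),
             rng_seed = rng_seed, ...)
}

fastq_cfg <- function(rng_seed = 7, n_genes = 60) {
  sim_config(n_genes = n_genes,
             program_sizes = c(group1 = 8, group2 = 4),
             rng_seed = rng_seed)
}

# brute-force global minimum edge cut by enumerating all bipartitions;
# independent oracle for the min-cut step used inside HCS
brute_min_cut <- function(edges, vertices) {
  n <- length(vertices)
  stopifnot(n <= 12)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    side <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    names(side) <- vertices
    cut <- sum(xor(side[edges[, 1]], side[edges[, 2]]))
    if (cut < best) best <- cut
  }
  best
}

# brute-force two-sided rank-sum p-value by enumerating all assignments of
# the pooled ranks to group A
brute_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  na <- length(a)
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(length(pooled), na)
  ws <- apply(combs, 2, function(i) sum(r[i])) - na * (na + 1) / 2
  mu <- na * length(b) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

random_edge_graph <- function(n, p = 0.5) {
  vertices <- letters[seq_len(n)]
  pairs <- t(utils::combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample.int(nrow(pairs), 1)] <- TRUE
  data.frame(gene1 = vertices[pairs[keep, 1]],
             gene2 = vertices[pairs[keep, 2]],
             rho = 1, stringsAsFactors = FALSE)
}

col_vars_test <- function(x) setNames(apply(x, 2, stats::var), colnames(x))
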