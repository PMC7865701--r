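# Independent oracles and tiny fixture builders shared across test files.

# Brute-force one-sided ("x stochastically smaller") rank-sum p-value by
# enumerating every assignment of the combined ranks to the x positions.
# Valid for tie-free data only.
brute_force_ranksum_p <- function(x, y, alternative = "less") {
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  sets <- utils::combn(n, nx)
  w_all <- colSums(matrix(seq_len(n)[sets], nrow = nx))
  switch(alternative,
         less = mean(w_all <= w_obs),
         greater = mean(w_all >= w_obs),
         stop("unsupported alternative"))
}

# Kruskal-Wallis H from the textbook rank formula (no tie correction;
# callers must supply tie-free data).
brute_force_kw_h <- function(groups) {
  all_v <- unlist(groups)
  n <- length(all_v)
  r <- rank(all_v)
  idx <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(r, idx, mean)
  12 / (n * (n + 1)) * sum(lengths(groups) * (rbar - (n + 1) / 2)^2)
}

# Hand product-limit estimator over event times (right-censoring,
# censored-at-t subjects remain at risk at t).
brute_force_km <- function(time, event) {
  ev <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ev))
  for (k in seq_along(ev)) {
    n_k <- sum(time >= ev[k])
    d_k <- sum(time == ev[k] & event == 1)
    s <- s * (1 - d_k / n_k)
    out[k] <- s
  }
  data.frame(time = ev, survival = out)
}

# A tiny two-sample, two-gene disruption matrix built from raw records.
tiny_matrix <- function() {
  v <- data.frame(sample_id = "s1", gene = "gA",
                  consequence = "stop_gained",
                  sift_score = NA_real_, esp_af = NA_real_, kg_af = NA_real_,
                  stringsAsFactors = FALSE)
  build_disruption_matrix(v, NULL, samples = c("s1", "s2"),
                          genes = c("gA", "gB"))
}

# Deterministic graph with given node and edge counts: a ring plus chords.
ring_plus_chords <- function(n_nodes, n_edges) {
  stopifnot(n_edges >= n_nodes, n_edges <= n_nodes * (n_nodes - 1) / 2)
  nodes <- sprintf("N%03d", seq_len(n_nodes))
  ring <- cbind(nodes, nodes[c(2:n_nodes, 1)])
  extra <- n_edges - n_nodes
  chords <- cbind(nodes[seq_len(extra)],
                  nodes[((seq_len(extra) + 1) %% n_nodes) + 1])
  df <- data.frame(gene_a = c(ring[, 1], chords[, 1]),
                   gene_b = c(ring[, 2], chords[, 2]),
                   stringsAsFactors = FALSE)
  build_sc_network(df)
}
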