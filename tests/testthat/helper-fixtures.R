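# Shared fixtures: everything is built in code at test time.

tiny_annotation <- function() {
  data.frame(gene_id = c("gA", "gB"),
             start = c(11L, 61L), end = c(40L, 100L),
             strand = c("+", "-"), stringsAsFactors = FALSE)
}

# one focal insert with known W among many neutral intergenic inserts;
# returns the grown insertion table plus its realized expansion factor
grow_focal_insert <- function(W, G, n0_count = 100, n_neutral = 100,
                              noise = "none", seed = 1) {
  ann <- data.frame(gene_id = "gA", start = 1L, end = 100L, strand = "+",
                    stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = "gA", class = "set", true_W = W,
                      essential = FALSE, stringsAsFactors = FALSE)
  ins <- data.frame(site = c(50L, seq(200L, by = 3L, length.out = n_neutral)),
                    count_t0 = rep(n0_count, n_neutral + 1),
                    count_tf = NA_real_, library_id = "L",
                    stringsAsFactors = FALSE)
  grown <- simulate_outgrowth(ins, ann, truth, generations = G,
                              noise = noise, seed = seed)
  list(inserts = grown, ann = ann, d = attr(grown, "realized_d"))
}

# brute-force TA scan: the independent oracle for enumerate_ta_sites
ta_scan_oracle <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  out <- integer(0)
  i <- 1L
  while (i < length(chars)) {
    if (chars[i] == "T" && chars[i + 1L] == "A") out <- c(out, i)
    i <- i + 1L
  }
  out
}

# brute-force BH step-up: q_(i) = min_{j>=i} p_(j) m / j on the sorted scale
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  run_min <- Inf
  for (i in m:1) {
    run_min <- min(run_min, p[o[i]] * m / i)
    q_sorted[i] <- min(run_min, 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# rank-then-Pearson Spearman with average-rank ties
spearman_oracle <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
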