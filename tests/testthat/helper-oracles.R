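# Independent oracles used to cross-check the implementation. These are
# deliberately naive (sliding windows, exhaustive enumeration) and share no
# code with the package internals.

# O(n*m) sliding-window motif scan on both strands
naive_scan <- function(seq_str, motif) {
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(motif, "")[[1]]), collapse = ""))
  n <- nchar(seq_str); m <- nchar(motif)
  hits <- integer(0)
  if (n >= m) {
    for (i in seq_len(n - m + 1)) {
      w <- substr(seq_str, i, i + m - 1)
      if (w == motif || w == rc) hits <- c(hits, i)
    }
  }
  sort(unique(hits))
}

# Recursive left-to-right merge of sub-resolution label positions: an
# accumulating cluster absorbs the next label while it is within `limit` of
# the cluster's running (half-up rounded) mean.
merge_oracle <- function(pos, limit) {
  if (length(pos) == 0) return(numeric(0))
  out <- numeric(0)
  members <- pos[1]
  cur <- pos[1]
  for (p in pos[-1]) {
    if (p - cur <= limit) {
      members <- c(members, p)
      cur <- floor(mean(members) + 0.5)
    } else {
      out <- c(out, cur)
      members <- p
      cur <- p
    }
  }
  c(out, cur)
}

# Score of one explicit monotone pairing under the aligner's objective
# (free ends; interior skips penalised; locus interval size-cost free).
pairing_score <- function(ref, qry, ri, qi, p) {
  s <- length(ri) * p$match_score
  if (length(ri) > 1) {
    for (k in 2:length(ri)) {
      s <- s - p$miss_ref * (ri[k] - ri[k - 1] - 1) -
        p$miss_qry * (qi[k] - qi[k - 1] - 1)
      free <- !is.null(p$free_gap) &&
        ref[ri[k - 1]] <= p$free_gap[1] && ref[ri[k]] >= p$free_gap[2]
      if (!free)
        s <- s - p$size_cost *
          ((ref[ri[k]] - ref[ri[k - 1]]) - (qry[qi[k]] - qry[qi[k - 1]]))^2
    }
  }
  s
}

# Exhaustive search over all non-empty monotone pairings (feasible for
# <= 8 labels a side); returns the maximal score.
best_pairing_score <- function(ref, qry, p) {
  best <- -Inf
  recurse <- function(i, j, ri, qi) {
    if (length(ri) > 0) {
      s <- pairing_score(ref, qry, ri, qi, p)
      if (s > best) best <<- s
    }
    if (i > length(ref) || j > length(qry)) return()
    for (ii in i:length(ref))
      for (jj in j:length(qry))
        recurse(ii + 1, jj + 1, c(ri, ii), c(qi, jj))
  }
  recurse(1, 1, integer(0), integer(0))
  best
}

# Exact two-sided Mann-Whitney p by enumerating all group labelings,
# mirroring the tail-doubling convention of the test statistic U.
mw_enum_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pool <- c(a, b)
  r <- rank(pool)
  combs <- utils::combn(na + nb, na)
  U_all <- apply(combs, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  U_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (U_obs > mu) p <- 2 * mean(U_all >= U_obs) else p <- 2 * mean(U_all <= U_obs)
  min(1, p)
}

# Exact two-sided paired Wilcoxon p by enumerating all 2^n sign flips of
# the non-zero differences (midranks of |d|).
wilcox_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  if (W_obs > mu) p <- 2 * mean(W_all >= W_obs) else p <- 2 * mean(W_all <= W_obs)
  min(1, p)
}

# Naive per-element histogram binning
naive_bins <- function(sizes, w) {
  k <- vapply(sizes, function(s) floor(s / w), numeric(1))
  table(factor(k, levels = seq(min(k), max(k))))
}

# Shared simulation fixtures (built once per test run)
.fixtures <- new.env()

shared_region <- function() {
  if (is.null(.fixtures$region)) .fixtures$region <- simulate_region()
  .fixtures$region
}

shared_noiseless_f35t <- function() {
  if (is.null(.fixtures$nl_f35t)) {
    sim <- simulate_molecules(f35t_profile(), shared_region(), 400,
                              noise = noise_model_off(), seed = 5)
    .fixtures$nl_f35t <- list(sim = sim, res = size_pipeline(sim))
  }
  .fixtures$nl_f35t
}

random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
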