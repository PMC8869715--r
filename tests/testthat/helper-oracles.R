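# Independent reference implementations used as oracles. These are literal,
# loop-based transcriptions of the definitions, kept deliberately naive and
# separate from the package's vectorized code paths.

# Full weighted-KS running sum, one step per ranked gene.
oracle_running_sum <- function(scores, hits, p = 1) {
  N <- length(scores)
  k <- sum(hits)
  stopifnot(k >= 1)
  nr <- sum(abs(scores[hits])^p)
  rs <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    if (hits[i]) {
      cur <- cur + if (nr > 0) abs(scores[i])^p / nr else 1 / k
    } else {
      cur <- cur - 1 / (N - k)
    }
    rs[i] <- cur
  }
  rs
}

# Signed maximum deviation, positive extremum wins magnitude ties.
oracle_es <- function(scores, hits, p = 1) {
  if (all(hits)) return(1)
  rs <- oracle_running_sum(scores, hits, p)
  mx <- max(rs)
  mn <- min(c(rs, 0))
  if (mx >= -mn - 1e-12) mx else mn # magnitude ties resolve positive
}

# Single-sample enrichment: weighted in-set ECDF (rank^alpha) minus
# unweighted out-of-set ECDF, summed over the descending-expression walk.
oracle_ssgsea <- function(values, set, alpha = 0.25) {
  genes <- names(values)
  N <- length(values)
  r <- rank(values, ties.method = "average")
  ord <- order(-values, genes)
  in_set <- genes %in% set
  k <- sum(in_set)
  total_in <- sum(r[ord][in_set[ord]]^alpha)
  cin <- 0; cout <- 0; s <- 0
  for (idx in ord) {
    if (in_set[idx]) cin <- cin + r[idx]^alpha else cout <- cout + 1
    s <- s + (cin / total_in - if (N > k) cout / (N - k) else 0)
  }
  unname(s)
}

# Ordinary pooled-variance two-sample t statistic, per gene.
oracle_pooled_t <- function(m1, m2) {
  n1 <- ncol(m1); n2 <- ncol(m2)
  mu1 <- rowMeans(m1); mu2 <- rowMeans(m2)
  s2 <- (rowSums((m1 - mu1)^2) + rowSums((m2 - mu2)^2)) / (n1 + n2 - 2)
  (mu1 - mu2) / sqrt(s2 * (1 / n1 + 1 / n2))
}

# Moments estimators of the scaled-F prior and the shrunken t, written as a
# direct transcription of the closed forms (root-finding by uniroot, not
# Newton, so the numerical path differs from the package's).
oracle_moderated_t <- function(m1, m2) {
  n1 <- ncol(m1); n2 <- ncol(m2)
  dg <- n1 + n2 - 2
  mu1 <- rowMeans(m1); mu2 <- rowMeans(m2)
  s2 <- (rowSums((m1 - mu1)^2) + rowSums((m2 - mu2)^2)) / dg
  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  evar <- stats::var(e) - trigamma(dg / 2)
  if (evar > 0) {
    half_d0 <- stats::uniroot(function(x) trigamma(x) - evar,
                              lower = 1e-8, upper = 1e8,
                              tol = .Machine$double.eps^0.8)$root
    d0 <- 2 * half_d0
  } else {
    d0 <- 1e6
  }
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  s2_post <- (d0 * s02 + dg * s2) / (d0 + dg)
  tstat <- (mu1 - mu2) / sqrt(s2_post * (1 / n1 + 1 / n2))
  list(d0 = d0, s02 = s02, t = tstat,
       p = 2 * stats::pt(-abs(tstat), df = d0 + dg))
}

# Exhaustive hypergeometric upper-tail sum (one-sided Fisher enrichment p).
oracle_hyper_tail <- function(a, K, n, N) {
  x <- a:min(K, n)
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

# Hand step-up BH adjustment.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# Naive O(n^3) agglomerative clustering; returns the cophenetic distance
# matrix implied by merging the closest cluster pair at each step, with the
# cluster-pair distance taken as mean (average linkage) or max (complete)
# over original pairwise distances.
oracle_agglomerate_cophenetic <- function(m, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  D <- as.matrix(dist(m))
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        pair_d <- D[clusters[[i]], clusters[[j]], drop = FALSE]
        d <- if (linkage == "average") mean(pair_d) else max(pair_d)
        if (d < bestd) { bestd <- d; best <- c(i, j) }
      }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- bestd; coph[b, a] <- bestd
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# Small paired dataset used by several integration tests.
tiny_sim <- function(seed = 42, ...) {
  simulate_paired_omics(n_genes = 300, n_de_up = 20, n_de_down = 15,
                        seed = seed, ...)
}

# Build an expression tibble from a matrix-like specification.
expr_fixture <- function(values, genes, samples) {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  as_expr_tbl(m)
}

meta_fixture <- function(samples, groups) {
  tibble::tibble(sample = samples, group = groups)
}
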