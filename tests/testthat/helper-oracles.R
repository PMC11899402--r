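# Brute-force reference implementations, kept deliberately independent of
# the package's code paths.

oracle_entropy <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) <= 1) return(0)
  p <- counts / sum(counts)
  h <- 0
  for (pi in p) h <- h - pi * log(pi)
  h
}

# AUC as the fraction of positive/negative pairs ranked correctly,
# ties counted half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive Youden scan over every candidate cut (all midpoints plus
# extremes), prediction rule score >= t.
oracle_youden <- function(scores, labels) {
  u <- sort(unique(scores))
  cands <- if (length(u) < 2) u else (u[-length(u)] + u[-1]) / 2
  best_j <- -Inf
  best_t <- cands[1]
  for (t in cands) {
    sens <- sum(scores >= t & labels == 1) / sum(labels == 1)
    spec <- sum(scores < t & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_t <- t
    }
  }
  list(threshold = best_t, j = best_j)
}

# Exact two-sided Mann-Whitney p-value by enumerating every assignment of
# the pooled values into the two groups.
oracle_mwu <- function(x, y) {
  u_stat <- function(a, b) {
    r <- rank(c(a, b))
    sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  }
  obs <- u_stat(x, y)
  pooled <- c(x, y)
  n <- length(pooled)
  k <- length(x)
  mu <- length(x) * length(y) / 2
  combos <- utils::combn(n, k)
  stats <- apply(combos, 2L, function(idx) {
    u_stat(pooled[idx], pooled[-idx])
  })
  p <- mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
  list(u = obs, p = min(1, p))
}

oracle_quantile90 <- function(x) {
  # type-7 linear interpolation done longhand
  x <- sort(x)
  h <- (length(x) - 1) * 0.9 + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[lo + 1 - (h == lo)] - x[lo]) * (h != lo)
}

make_variant <- function(sample_id = "S1", chrom = "chr1", pos = 100,
                         ref = "A", alt = "T", gene = "GENE1",
                         consequence = "missense", protein_change = "",
                         tumor_depth = 100, normal_depth = 60,
                         tumor_vaf = 0.3, normal_vaf = 0, alt_reads = 30) {
  data.frame(sample_id = sample_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, gene = gene, consequence = consequence,
             protein_change = protein_change, tumor_depth = tumor_depth,
             normal_depth = normal_depth, tumor_vaf = tumor_vaf,
             normal_vaf = normal_vaf, alt_reads = alt_reads,
             stringsAsFactors = FALSE)
}

make_variants <- function(consequences, ...) {
  if (length(consequences) == 0) return(make_variant()[0, , drop = FALSE])
  do.call(rbind, lapply(seq_along(consequences), function(i) {
    make_variant(pos = 100 * i, consequence = consequences[i], ...)
  }))
}

no_segments <- function() {
  data.frame(sample_id = character(), chrom = character(), start = numeric(),
             end = numeric(), copy_number = numeric(), loglik = numeric(),
             stringsAsFactors = FALSE)
}

make_segment <- function(sample_id = "S1", chrom = "chr1", start = 0,
                         end = 1000, copy_number = 1, loglik = 200) {
  data.frame(sample_id = sample_id, chrom = chrom, start = start, end = end,
             copy_number = copy_number, loglik = loglik,
             stringsAsFactors = FALSE)
}

no_neoantigens <- function() {
  data.frame(sample_id = character(), mut_peptide = character(),
             wt_peptide = character(), mut_affinity_nM = numeric(),
             wt_affinity_nM = numeric(), recognition_potential = numeric(),
             hex_score = numeric(), dissimilarity = numeric(),
             stringsAsFactors = FALSE)
}

make_neo <- function(sample_id = "S1", wt = 500, mut = 50, rp = 1,
                     hex = 5, dis = 0.5, wt_peptide = "AAAAAAAAA") {
  data.frame(sample_id = sample_id, mut_peptide = "AAAAAAAAL",
             wt_peptide = wt_peptide, mut_affinity_nM = mut,
             wt_affinity_nM = wt, recognition_potential = rp,
             hex_score = hex, dissimilarity = dis, stringsAsFactors = FALSE)
}

# A separable toy modelling problem: one predictive feature among decoys.
toy_model_data <- function(n = 60, p = 4, seed = 99) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("T%02d", 1:n), paste0("f", 1:p)))
  y <- as.numeric(X[, 1] + rnorm(n, 0, 0.3) > 0)
  list(X = X, y = y)
}
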