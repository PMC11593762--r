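# Independent brute-force oracles: enumerate voxels one at a time and apply
# the textbook definitions directly, never touching the package's vectorized
# confusion-count path.

oracle_counts <- function(pred, truth) {
  p <- as.vector(pred); t <- as.vector(truth)
  cc <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (i in seq_along(p)) {
    if (p[i] == 1 && t[i] == 1) cc["tp"] <- cc["tp"] + 1
    else if (p[i] == 1 && t[i] == 0) cc["fp"] <- cc["fp"] + 1
    else if (p[i] == 0 && t[i] == 1) cc["fn"] <- cc["fn"] + 1
    else cc["tn"] <- cc["tn"] + 1
  }
  cc
}

oracle_metrics <- function(cc) {
  total <- sum(cc)
  r <- function(num, den) if (den == 0) 1 else num / den
  jf <- r(cc["tp"], cc["tp"] + cc["fp"] + cc["fn"])
  jb <- r(cc["tn"], cc["tn"] + cc["fp"] + cc["fn"])
  c(JI_F = unname(jf), JI_B = unname(jb), m_IoU = unname((jf + jb) / 2),
    DSC = unname(r(2 * cc["tp"], 2 * cc["tp"] + cc["fp"] + cc["fn"])),
    accuracy = unname((cc["tp"] + cc["tn"]) / total),
    error_rate = unname((cc["fp"] + cc["fn"]) / total),
    precision = unname(r(cc["tp"], cc["tp"] + cc["fp"])),
    recall = unname(r(cc["tp"], cc["tp"] + cc["fn"])),
    TNR = unname(r(cc["tn"], cc["tn"] + cc["fp"])))
}

# All-pairs Mann-Whitney AUROC: compare every (positive, negative) pair.
oracle_auroc <- function(scores, truth) {
  s <- as.vector(scores); t <- as.vector(truth)
  pos <- s[t == 1]; neg <- s[t == 0]
  wins <- 0
  for (a in pos) for (b in neg)
    wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(pos) * length(neg))
}

random_mask <- function(shape, p = 0.3) {
  array((stats::runif(prod(shape)) < p) + 0, shape)
}

random_shape <- function(max_side = 16) {
  c(sample(max_side, 1), sample(max_side, 1), sample(max_side, 1))
}
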