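# independent brute-force implementation (direct scans + explicit Mahalanobis)
exdet_brute <- function(ref, tar) {
  p <- ncol(ref)
  mins <- apply(ref, 2, min); maxs <- apply(ref, 2, max); rng <- maxs - mins
  mu <- colMeans(ref); S <- stats::cov(ref)
  Si <- solve(S)
  d2 <- function(x) drop(t(x - mu) %*% Si %*% (x - mu))
  d2max <- max(apply(ref, 1, d2))
  out <- data.frame(NT1 = numeric(nrow(tar)), NT2 = NA_real_,
                    class = NA_character_, mic = NA_character_)
  for (i in seq_len(nrow(tar))) {
    x <- as.numeric(tar[i, ])
    terms <- sapply(seq_len(p), function(j)
      min(0, min(x[j] - mins[j], maxs[j] - x[j])) / rng[j])
    nt1 <- sum(terms)
    if (nt1 < 0) {
      out$NT1[i] <- nt1
      out$class[i] <- "univariate"
      out$mic[i] <- colnames(ref)[which.min(terms)]
    } else {
      nt2 <- d2(x) / d2max
      out$NT1[i] <- 0; out$NT2[i] <- nt2
      if (nt2 > 1) {
        out$class[i] <- "combinatorial"
        red <- sapply(seq_len(p), function(j) {
          keep <- setdiff(seq_len(p), j)
          mu_j <- colMeans(ref[, keep, drop = FALSE])
          S_j <- stats::cov(ref[, keep, drop = FALSE])
          d2(x) - drop(t(x[keep] - mu_j) %*% solve(S_j) %*% (x[keep] - mu_j))
        })
        out$mic[i] <- colnames(ref)[which.max(red)]
      } else out$class[i] <- "analogue"
    }
  }
  out
}
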