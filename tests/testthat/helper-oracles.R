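# Independent brute-force oracles used to validate the package's
# implementations. These deliberately avoid the code paths they check.

# pixel-set Dice: build explicit coordinate sets and intersect them
oracle_dice <- function(a, b) {
  sa <- which(as.logical(a)); sb <- which(as.logical(b))
  if (length(sa) + length(sb) == 0) return(1.0)
  2 * length(intersect(sa, sb)) / (length(sa) + length(sb))
}

# iterative flood fill component count with explicit stack
oracle_count_components <- function(mask, connectivity = 8, min_area = 0) {
  mask <- mask > 0
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  nb <- if (connectivity == 4)
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  count <- 0L
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE; area <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      area <- area + 1L
      for (d in seq_len(nrow(nb))) {
        r <- p[1] + nb[d, 1]; c <- p[2] + nb[d, 2]
        if (r < 1 || r > H || c < 1 || c > W) next
        if (mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
    if (area >= min_area) count <- count + 1L
  }
  count
}

# exhaustive-search Otsu: minimise within-class weighted variance over all
# 256-bin histogram cut points of the normalised image. Thresholds inside an
# empty inter-mode gap tie exactly; like the standard convention, the
# midpoint of the tying plateau is returned (in bin-centre coordinates).
oracle_otsu <- function(x, levels = 256) {
  rng <- range(x)
  v <- (x - rng[1]) / diff(rng)
  bin <- pmin(floor(v * levels), levels - 1)   # 0 .. levels-1
  h <- tabulate(bin + 1L, nbins = levels)
  mids <- (seq_len(levels) - 0.5) / levels
  wcv <- rep(Inf, levels - 1)
  for (t in seq_len(levels - 1)) {             # cut after bin t
    lo <- h[seq_len(t)]; hi <- h[(t + 1):levels]
    wlo <- sum(lo); whi <- sum(hi)
    if (wlo == 0 || whi == 0) next
    mlo <- sum(lo * mids[seq_len(t)]) / wlo
    mhi <- sum(hi * mids[(t + 1):levels]) / whi
    vlo <- sum(lo * (mids[seq_len(t)] - mlo)^2) / wlo
    vhi <- sum(hi * (mids[(t + 1):levels] - mhi)^2) / whi
    wcv[t] <- (wlo * vlo + whi * vhi) / (wlo + whi)
  }
  tie <- which(wcv <= min(wcv) * (1 + 1e-12))
  t_norm <- (mids[tie[1]] + mids[tie[length(tie)]]) / 2
  t_norm * diff(rng) + rng[1]
}

# pairwise-enumeration ROC AUC (ties count one half)
oracle_roc_auc <- function(scores, labels, positive = "malignant") {
  pos <- scores[as.character(labels) == positive]
  neg <- scores[as.character(labels) != positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# direct numeric gradient of a scalar function of an array
oracle_num_grad <- function(arr, f, eps = 1e-6) {
  out <- arr * 0
  for (i in seq_along(arr)) {
    a1 <- arr; a1[i] <- a1[i] + eps
    a2 <- arr; a2[i] <- a2[i] - eps
    out[i] <- (f(a1) - f(a2)) / (2 * eps)
  }
  out
}
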