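# Independent brute-force oracles. Everything here is written as naive
# scalar double loops, sharing no code with the package implementation.

oracle_glcm <- function(img, drow, dcol, n, symmetric = TRUE) {
  counts <- matrix(0, n, n)
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    r2 <- r + drow; c2 <- c + dcol
    if (r2 >= 1 && r2 <= nrow(img) && c2 >= 1 && c2 <= ncol(img)) {
      counts[img[r, c], img[r2, c2]] <- counts[img[r, c], img[r2, c2]] + 1
      if (symmetric)
        counts[img[r2, c2], img[r, c]] <- counts[img[r2, c2], img[r, c]] + 1
    }
  }
  counts / sum(counts)
}

# All 19 descriptors from a normalized GLCM by explicit summation.
oracle_features <- function(p, dialect = "as_printed", logf = log) {
  n <- nrow(p)
  px <- numeric(n); py <- numeric(n)
  for (i in 1:n) for (j in 1:n) {
    px[i] <- px[i] + p[i, j]
    py[j] <- py[j] + p[i, j]
  }
  mu_x <- 0; mu_y <- 0
  for (i in 1:n) { mu_x <- mu_x + i * px[i]; mu_y <- mu_y + i * py[i] }
  var_x <- 0; var_y <- 0
  for (i in 1:n) {
    var_x <- var_x + (i - mu_x)^2 * px[i]
    var_y <- var_y + (i - mu_y)^2 * py[i]
  }
  p_sum <- numeric(2 * n); p_dif <- numeric(n)  # k and |k|+1 indexed
  for (i in 1:n) for (j in 1:n) {
    p_sum[i + j] <- p_sum[i + j] + p[i, j]
    p_dif[abs(i - j) + 1] <- p_dif[abs(i - j) + 1] + p[i, j]
  }
  mu_sum <- 0
  for (k in 2:(2 * n)) mu_sum <- mu_sum + k * p_sum[k]
  mu_dif <- 0
  for (k in 0:(n - 1)) mu_dif <- mu_dif + k * p_dif[k + 1]
  ent <- function(q) { s <- 0; for (v in q) if (v > 0) s <- s - v * logf(v); s }
  hx <- ent(px); hy <- ent(py); hxy <- ent(as.vector(p))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:n) for (j in 1:n) {
    q <- px[i] * py[j]
    if (q > 0) {
      if (p[i, j] > 0) hxy1 <- hxy1 - p[i, j] * logf(q)
      hxy2 <- hxy2 - q * logf(q)
    }
  }

  out <- c(autocorrelation = 0, contrast = 0, correlation = 0,
           cluster_prominence = 0, cluster_shade = 0, dissimilarity = 0,
           energy = 0, entropy = hxy, homogeneity = 0,
           maximum_probability = max(p), sum_of_squares_variance = 0,
           sum_average = mu_sum, sum_variance = 0, sum_entropy = 0,
           difference_variance = 0, difference_entropy = 0,
           imc1 = 0, imc2 = 0, inverse_difference = 0)
  e_prom <- if (dialect == "as_printed") 3 else 4
  e_shade <- if (dialect == "as_printed") 4 else 3
  for (i in 1:n) for (j in 1:n) {
    v <- p[i, j]
    out["autocorrelation"] <- out["autocorrelation"] + i * j * v
    out["contrast"] <- out["contrast"] + (i - j)^2 * v
    out["cluster_prominence"] <- out["cluster_prominence"] +
      (i + j - 2 * mu_x)^e_prom * v
    out["cluster_shade"] <- out["cluster_shade"] +
      (i + j - 2 * mu_x)^e_shade * v
    out["dissimilarity"] <- out["dissimilarity"] + abs(i - j) * v
    out["energy"] <- out["energy"] + v^2
    out["homogeneity"] <- out["homogeneity"] + v / (1 + (i - j)^2)
    out["sum_of_squares_variance"] <- out["sum_of_squares_variance"] +
      (i - mu_x)^2 * v
    out["inverse_difference"] <- out["inverse_difference"] +
      v / (1 + abs(i - j))
  }
  if (var_x > 0 && var_y > 0) {
    s <- 0
    for (i in 1:n) for (j in 1:n)
      s <- s + (i - mu_x) * (j - mu_y) * p[i, j]
    out["correlation"] <- s / sqrt(var_x * var_y)
  }
  for (k in 2:(2 * n)) {
    out["sum_variance"] <- out["sum_variance"] + (k - mu_sum)^2 * p_sum[k]
    if (p_sum[k] > 0)
      out["sum_entropy"] <- out["sum_entropy"] - p_sum[k] * logf(p_sum[k])
  }
  for (k in 0:(n - 1)) {
    out["difference_variance"] <- out["difference_variance"] +
      (k - mu_dif)^2 * p_dif[k + 1]
    if (p_dif[k + 1] > 0)
      out["difference_entropy"] <- out["difference_entropy"] -
        p_dif[k + 1] * logf(p_dif[k + 1])
  }
  if (max(hx, hy) > 0) out["imc1"] <- (hxy - hxy1) / max(hx, hy)
  arg <- max(0, 1 - exp(-2 * (hxy2 - hxy)))
  out["imc2"] <- if (dialect == "as_printed") arg else sqrt(arg)
  out
}

# AUC as pairwise concordance probability, ties counted one half.
oracle_auc <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Small random level raster for oracle sweeps.
random_levels <- function(nr, nc, n_levels) {
  matrix(sample.int(n_levels, nr * nc, replace = TRUE), nr, nc)
}

tiny_cohort_spec <- function(seed = 42, n = c(4, 4, 4)) {
  cohort_spec(counts = c(normal = n[1], mild_moderate = n[2], severe = n[3]),
              image_dims = c(160, 160), seed = seed)
}
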