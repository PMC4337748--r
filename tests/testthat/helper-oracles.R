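# Independent brute-force oracles used across tests. These deliberately use
# naive enumeration (loops, table()) so they share no code path with the
# package implementations they check.

# per-block class counts of a categorical matrix, as percentages
bf_block_fractions <- function(codes, factor, n_classes) {
  nr <- nrow(codes) / factor
  nc <- ncol(codes) / factor
  out <- array(0, dim = c(nr, nc, n_classes))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    block <- codes[((i - 1) * factor + 1):(i * factor),
                   ((j - 1) * factor + 1):(j * factor)]
    for (k in seq_len(n_classes))
      out[i, j, k] <- sum(block == k) * 100 / factor^2
  }
  out
}

# GLCM of one 3x3 patch by explicit enumeration of every cell pair at the
# four distance-1 offsets, accumulated in both directions
bf_glcm <- function(patch, n_levels) {
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  p <- matrix(0, n_levels, n_levels)
  for (r in 1:3) for (c in 1:3) for (o in offs) {
    r2 <- r + o[1]; c2 <- c + o[2]
    if (r2 < 1 || r2 > 3 || c2 < 1 || c2 > 3) next
    a <- patch[r, c]; b <- patch[r2, c2]
    if (is.na(a) || is.na(b)) next
    p[a + 1, b + 1] <- p[a + 1, b + 1] + 1
    p[b + 1, a + 1] <- p[b + 1, a + 1] + 1
  }
  if (sum(p) == 0) return(NULL)
  p / sum(p)
}

bf_metric <- function(p, metric) {
  n <- nrow(p)
  val <- 0
  mu_i <- 0; mu_j <- 0
  for (i in 1:n) for (j in 1:n) {
    mu_i <- mu_i + (i - 1) * p[i, j]
    mu_j <- mu_j + (j - 1) * p[i, j]
  }
  s_i <- 0; s_j <- 0
  for (i in 1:n) for (j in 1:n) {
    s_i <- s_i + (i - 1 - mu_i)^2 * p[i, j]
    s_j <- s_j + (j - 1 - mu_j)^2 * p[i, j]
  }
  for (i in 1:n) for (j in 1:n) {
    q <- p[i, j]
    d <- (i - 1) - (j - 1)
    val <- val + switch(metric,
      contrast = d^2 * q,
      dissimilarity = abs(d) * q,
      homogeneity = q / (1 + d^2),
      entropy = if (q > 0) -q * log(q) else 0,
      angular_second_moment = q^2,
      correlation = if (s_i > 0 && s_j > 0)
        ((i - 1) - mu_i) * ((j - 1) - mu_j) * q / sqrt(s_i * s_j) else 0)
  }
  val
}

bf_texture_map <- function(lv, n_levels, metric) {
  nr <- nrow(lv); nc <- ncol(lv)
  out <- matrix(NA_real_, nr, nc)
  if (nr < 3 || nc < 3) return(out)
  for (r in 2:(nr - 1)) for (c in 2:(nc - 1)) {
    p <- bf_glcm(lv[(r - 1):(r + 1), (c - 1):(c + 1)], n_levels)
    if (!is.null(p)) out[r, c] <- bf_metric(p, metric)
  }
  out
}

# relocation table on a fixed schedule for thinning tests
make_relocs <- function(times, x = NULL, y = NULL, id = "A1") {
  n <- length(times)
  data.frame(animal_id = id, sex = "F", year = 2006L,
             timestamp = times,
             x = if (is.null(x)) seq_len(n) * 10 else x,
             y = if (is.null(y)) rep(0, n) else y)
}

utc <- function(s) as.POSIXct(s, tz = "UTC")
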