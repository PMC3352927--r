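# Independent oracles, implemented without any package internals.

# Explicit-stack flood fill over the background of a logical mask
# (4-connectivity): counts regions not reaching the matrix border and their
# summed area.
floodFillHoles <- function(mask, minArea = 1L) {
  H <- nrow(mask)
  W <- ncol(mask)
  visited <- mask
  nRegions <- 0L
  area <- 0L
  stack <- integer(H * W)
  for (start in which(!mask)) {
    if (visited[start]) next
    sp <- 1L
    stack[1] <- start
    visited[start] <- TRUE
    cells <- 0L
    touches <- FALSE
    while (sp > 0L) {
      i <- stack[sp]
      sp <- sp - 1L
      cells <- cells + 1L
      r <- (i - 1L) %% H + 1L
      cc <- (i - 1L) %/% H + 1L
      if (r == 1L || r == H || cc == 1L || cc == W) touches <- TRUE
      nb <- c(if (r > 1L) i - 1L, if (r < H) i + 1L,
              if (cc > 1L) i - H, if (cc < W) i + H)
      for (j in nb) {
        if (!visited[j]) {
          visited[j] <- TRUE
          sp <- sp + 1L
          stack[sp] <- j
        }
      }
    }
    if (!touches && cells >= minArea) {
      nRegions <- nRegions + 1L
      area <- area + cells
    }
  }
  list(nRegions = nRegions, areaPx = area)
}

# Exact two-sided Mann-Whitney p by full enumeration of all C(n1+n2, n1)
# group labelings (continuous data, no ties).
mwEnumerate <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  uObs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  subsets <- utils::combn(n1 + n2, n1)
  us <- apply(subsets, 2, function(s) sum(rk[s]) - n1 * (n1 + 1) / 2)
  pl <- mean(us <= uObs)
  pu <- mean(us >= uObs)
  list(u = uObs, p = min(1, 2 * min(pl, pu)))
}

# Welch t test from the textbook formulas.
welchOracle <- function(a, b) {
  v1 <- stats::var(a) / length(a)
  v2 <- stats::var(b) / length(b)
  tStat <- (mean(a) - mean(b)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(a) - 1) + v2^2 / (length(b) - 1))
  list(t = tStat, df = df, p = 2 * stats::pt(-abs(tStat), df))
}

# Brute-force ROC sweep over a fixed threshold grid.
rocSweepOracle <- function(control, treated) {
  cand <- sort(unique(c(control, treated)))
  cand <- c(cand[1] - 1, (cand[-1] + cand[-length(cand)]) / 2,
            cand[length(cand)] + 1)
  best <- NULL
  for (th in cand) {
    sens <- mean(treated < th)
    spec <- mean(control >= th)
    if (is.null(best) || sens + spec > best$sens + best$spec)
      best <- list(threshold = th, sens = sens, spec = spec)
  }
  best
}
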