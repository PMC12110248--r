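# Independent brute-force oracles, deliberately written by definition and
# without reusing the package's scanning logic.

# All local maxima of a vector, plateaus resolved to their midpoint.
bf_local_maxima <- function(x) {
  n <- length(x)
  out <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i - 1] >= x[i]) next
    e <- i
    while (e < n && x[e + 1] == x[i]) e <- e + 1
    if (e < n && x[e + 1] < x[i]) out <- c(out, (i + e) %/% 2)
  }
  out
}

# Prominence by definition: lowest point on the way to the nearest strictly
# higher ground (or edge), on each side; prominence over the higher of the two.
bf_prominence <- function(x, i) {
  h <- x[i]
  left <- i; lmin <- h
  j <- i
  while (j > 1 && x[j - 1] <= h) {
    j <- j - 1
    if (x[j] < lmin) { lmin <- x[j]; left <- j }
  }
  right <- i; rmin <- h
  j <- i
  while (j < length(x) && x[j + 1] <= h) {
    j <- j + 1
    if (x[j] < rmin) { rmin <- x[j]; right <- j }
  }
  list(prom = h - max(lmin, rmin), lb = left, rb = right)
}

# Interpolated width at the given evaluation height, confined to the bases.
bf_width <- function(x, i, lb, rb, h) {
  a <- i
  while (a > lb && x[a] > h) a <- a - 1
  li <- if (x[a] > h) a else a + (h - x[a]) / (x[a + 1] - x[a])
  b <- i
  while (b < rb && x[b] > h) b <- b + 1
  ri <- if (x[b] > h) b else b - (h - x[b]) / (x[b - 1] - x[b])
  ri - li
}

# Full brute-force peak list on a normalized signal.
bf_peaks <- function(x, prominence = 0.1, min_width = 2) {
  rows <- list()
  for (i in bf_local_maxima(x)) {
    p <- bf_prominence(x, i)
    if (p$prom < prominence) next
    w <- bf_width(x, i, p$lb, p$rb, x[i] - 0.5 * p$prom)
    if (w < min_width) next
    rows[[length(rows) + 1]] <- data.frame(index = i, prominence = p$prom,
                                           width = w)
  }
  if (!length(rows)) return(data.frame(index = integer(0),
                                       prominence = numeric(0),
                                       width = numeric(0)))
  do.call(rbind, rows)
}

# Wrap a numeric vector as a normalized profile object.
as_profile <- function(v, layer = 1L, normalized = TRUE) {
  structure(list(layer = layer, xs = seq_along(v), ys = rep(1L, length(v)),
                 values = v, normalized = normalized),
            class = "gray_profile")
}

# Exhaustive enumeration of all source-to-sink paths of a layered node table:
# one node per layer, consecutive layers only. Returns the minimal total
# Euclidean length (Inf when a layer is empty).
bf_min_path <- function(layers) {
  sizes <- vapply(layers, nrow, integer(1))
  if (any(sizes == 0)) return(Inf)
  combos <- do.call(expand.grid, lapply(sizes, seq_len))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    len <- 0
    for (k in seq_len(length(layers) - 1)) {
      a <- layers[[k]][combos[r, k], ]
      b <- layers[[k + 1]][combos[r, k + 1], ]
      len <- len + sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
    }
    if (len < best) best <- len
  }
  best
}

# Reference gland extraction: greedy repeated minimum via enumeration, same
# thresholds and phase structure as the traced algorithm.
bf_trace <- function(peak_layers, full_max_len = 100, pair_max_len = 60) {
  layers <- lapply(peak_layers, function(p)
    if (nrow(p)) p[, c("x", "y")] else p[, c("x", "y")])
  total <- length(layers)
  out <- list()
  for (top in seq_len(max(total - 2, 0))) {
    span <- top:total
    repeat {
      sizes <- vapply(layers[span], nrow, integer(1))
      if (any(sizes == 0)) break
      combos <- do.call(expand.grid, lapply(sizes, seq_len))
      lens <- apply(combos, 1, function(cmb) {
        len <- 0
        for (k in seq_len(length(span) - 1)) {
          a <- layers[[span[k]]][cmb[k], ]
          b <- layers[[span[k + 1]]][cmb[k + 1], ]
          len <- len + sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
        }
        len
      })
      if (!length(lens) || min(lens) > full_max_len) break
      pick <- combos[which.min(lens), ]
      out[[length(out) + 1]] <- list(n_layers = length(span),
                                     length = min(lens))
      for (k in seq_along(span))
        layers[[span[k]]] <- layers[[span[k]]][-as.integer(pick[k]), , drop = FALSE]
    }
  }
  if (total >= 2) {
    a <- layers[[total - 1]]; b <- layers[[total]]
    repeat {
      if (!nrow(a) || !nrow(b)) break
      d <- outer(seq_len(nrow(a)), seq_len(nrow(b)), Vectorize(function(i, j)
        sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2)))
      if (min(d) >= pair_max_len) break
      ij <- which(d == min(d), arr.ind = TRUE)[1, ]
      out[[length(out) + 1]] <- list(n_layers = 2L, length = min(d))
      a <- a[-ij[1], , drop = FALSE]; b <- b[-ij[2], , drop = FALSE]
    }
  }
  out
}

# Random peak layer tables for graph tests.
# Default rows mirror the four depth fractions of a 140 px band starting at
# row 106 (gaps 49, 14, 28; full span 91 px, under the 100 px threshold).
random_peak_layers <- function(n_layers = 4, max_nodes = 5,
                               rows = c(120, 169, 183, 211)) {
  lapply(seq_len(n_layers), function(l) {
    n <- sample(0:max_nodes, 1)
    if (n == 0)
      return(data.frame(layer = integer(0), x = numeric(0), y = numeric(0),
                        index = integer(0), height = numeric(0),
                        prominence = numeric(0), width = numeric(0)))
    data.frame(layer = l, x = sort(runif(n, 0, 300)), y = rows[l],
               index = seq_len(n), height = 1, prominence = 0.5, width = 10)
  })
}

# Hand-built peak layer tables from a matrix of x positions (one column per
# gland column, NA = absent on that layer).
peaks_from_columns <- function(xcols, rows = c(120, 169, 183, 211)) {
  lapply(seq_along(rows), function(l) {
    xs <- xcols[l, ]
    xs <- xs[!is.na(xs)]
    if (!length(xs))
      return(data.frame(layer = integer(0), x = numeric(0), y = numeric(0),
                        index = integer(0), height = numeric(0),
                        prominence = numeric(0), width = numeric(0)))
    data.frame(layer = l, x = sort(xs), y = rows[l], index = seq_along(xs),
               height = 1, prominence = 0.5, width = 10)
  })
}
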