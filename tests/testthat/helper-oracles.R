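# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Dijkstra shortest-path cost on the weighted pixel graph via igraph.
# mask: logical matrix; p, q: 0-based (row, col).
oracle_geodesic_igraph <- function(mask, p, q, sy = 1, sx = 1) {
  stopifnot(requireNamespace("igraph", quietly = TRUE))
  idx <- which(mask)
  vid <- integer(length(mask))
  vid[idx] <- seq_along(idx)
  nr <- nrow(mask)
  nc <- ncol(mask)
  edges <- NULL
  wts <- NULL
  offs <- list(c(1, 0, sy), c(0, 1, sx), c(1, 1, sqrt(sy^2 + sx^2)),
               c(1, -1, sqrt(sy^2 + sx^2)))
  rc <- arrayInd(idx, dim(mask))
  for (o in offs) {
    rr <- rc[, 1] + o[1]; cc <- rc[, 2] + o[2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    jdx <- (cc - 1L) * nr + rr
    ok[ok] <- mask[jdx[ok]]
    if (any(ok)) {
      edges <- rbind(edges, cbind(vid[idx[ok]], vid[jdx[ok]]))
      wts <- c(wts, rep(o[3], sum(ok)))
    }
  }
  g <- igraph::make_graph(t(edges), n = length(idx), directed = FALSE)
  from <- vid[(p[2]) * nr + p[1] + 1L]
  to <- vid[(q[2]) * nr + q[1] + 1L]
  as.numeric(igraph::distances(g, v = from, to = to, weights = wts,
                               algorithm = "dijkstra"))
}

# random connected 8-neighbour pixel curve (random walk without revisits)
random_pixel_curve <- function(n_steps, nr, nc) {
  occupied <- matrix(FALSE, nr, nc)
  r <- sample.int(nr, 1); c <- sample.int(nc, 1)
  occupied[r, c] <- TRUE
  pts <- matrix(c(r, c), ncol = 2)
  moves <- expand.grid(dr = -1:1, dc = -1:1)
  moves <- moves[!(moves$dr == 0 & moves$dc == 0), ]
  for (i in seq_len(n_steps)) {
    ord <- sample.int(8)
    moved <- FALSE
    for (j in ord) {
      rr <- r + moves$dr[j]; cc <- c + moves$dc[j]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && !occupied[rr, cc]) {
        occupied[rr, cc] <- TRUE
        pts <- rbind(pts, c(rr, cc))
        r <- rr; c <- cc
        moved <- TRUE
        break
      }
    }
    if (!moved) break
  }
  list(mask = occupied, start = pts[1, ] - 1L, end = pts[nrow(pts), ] - 1L)
}

# exhaustive 2-means over all 255 cut points: minimizes within-class squared
# deviation of the histogram; returns the best integer cut (levels <= cut in
# the lower class)
oracle_best_cut <- function(h) {
  lv <- 0:255
  best <- NULL; best_ss <- Inf
  for (cut in 0:254) {
    lo <- lv <= cut
    w1 <- sum(h[lo]); w2 <- sum(h[!lo])
    if (w1 == 0 || w2 == 0) next
    m1 <- sum(h[lo] * lv[lo]) / w1
    m2 <- sum(h[!lo] * lv[!lo]) / w2
    ss <- sum(h[lo] * (lv[lo] - m1)^2) + sum(h[!lo] * (lv[!lo] - m2)^2)
    if (ss < best_ss) { best_ss <- ss; best <- cut }
  }
  best
}

# direct CDF-table inversion for histogram matching
oracle_match_level <- function(p, ref_hist) {
  cdf <- cumsum(ref_hist) / sum(ref_hist)
  which(cdf >= p - 1e-12)[1] - 1L
}

# brute-force nearest border pixel (physical distance, row-then-col ties)
oracle_nearest_border <- function(point, mask, sy = 1, sx = 1) {
  idx <- which(mask, arr.ind = TRUE)
  d2 <- ((idx[, 1] - 1 - point[1]) * sy)^2 + ((idx[, 2] - 1 - point[2]) * sx)^2
  best <- order(d2, idx[, 1], idx[, 2])[1]
  c(idx[best, 1] - 1L, idx[best, 2] - 1L)
}

# plain-R 8-connected flood-fill labeller (independent of the package's C++)
oracle_label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(r, c))
    lab[r, c] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# small flat-bordered phantom for fast pipeline tests, plus the matching
# preprocessing config (histogram reference rendered at the same geometry)
quick_geom <- list(width = 400L, height = 200L, side_span = 150L,
                   baseline_row = 80L, iris_thickness = 30L, pupil_gap = 60L)

quick_flat_spec <- function(seed = 1L, ...) {
  do.call(synthetic_iris_spec,
          utils::modifyList(c(quick_geom,
                              list(crypt_amplitude = 0, speckle_sigma = 0.05,
                                   blur_sigma = 1, seed = seed)),
                            list(...)))
}

.helper_cache <- new.env(parent = emptyenv())
pre_cfg_for <- function(geom) {
  key <- paste(deparse(geom), collapse = "")
  if (is.null(.helper_cache[[key]]))
    .helper_cache[[key]] <- preprocess_config(
      reference = reference_histogram_for(geom))
  .helper_cache[[key]]
}
quick_pre_cfg <- function() pre_cfg_for(quick_geom)
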