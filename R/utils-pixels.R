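# Shared pixel-level helpers: connected-component labeling, windowed local
# statistics with mirror padding, point-in-polygon, region-boundary tracing,
# polygon simplification and scanline rasterization.

#' 8-connected component labeling
#'
#' EBImage's `bwlabel()` is 4-connected; ImageJ's particle analysis uses
#' 8-connectivity. This labels 4-connected first, then merges label pairs that
#' touch diagonally via union-find, relabeling compactly in first-pixel order.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return Integer matrix of labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  if (connectivity == 4 || max(lab) <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs: (i, j) vs (i + 1, j + 1) and (i + 1, j - 1)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  # compact relabel, keeping raster-scan order of first occurrence
  newid <- integer(n)
  newid[sort(unique(root))] <- seq_along(unique(root))
  out <- lab
  out[out > 0] <- newid[root[out[out > 0]]]
  out
}

# local mean and sd in a (2 radius + 1)^2 window with mirror (symmetric)
# padding, via integral images; sd is the population sd of the window
local_mean_sd <- function(x, radius) {
  nr <- nrow(x); nc <- ncol(x)
  if (radius >= nr || radius >= nc) {
    stop("window radius exceeds image size", call. = FALSE)
  }
  ri <- c(radius:1, 1:nr, nr:(nr - radius + 1))
  ci <- c(radius:1, 1:nc, nc:(nc - radius + 1))
  p <- x[ri, ci, drop = FALSE]
  w <- 2L * radius + 1L
  box <- function(z) {
    s <- matrix(0, nrow(z) + 1L, ncol(z) + 1L)
    s[-1, -1] <- t(apply(apply(z, 2, cumsum), 1, cumsum))
    # window sum over padded rows i..i+w-1, cols j..j+w-1
    s[(1:nr) + w, (1:nc) + w, drop = FALSE] -
      s[1:nr, (1:nc) + w, drop = FALSE] -
      s[(1:nr) + w, 1:nc, drop = FALSE] + s[1:nr, 1:nc, drop = FALSE]
  }
  sm <- box(p); sq <- box(p * p)
  mean_ <- sm / (w * w)
  var_ <- pmax(sq / (w * w) - mean_^2, 0)
  list(mean = mean_, sd = sqrt(var_))
}

# even-odd point-in-polygon for pixel-centre points; poly is a matrix with
# columns (row, col); points exactly on a horizontal edge follow the
# half-open crossing rule
points_in_polygon <- function(pr, pc, poly) {
  n <- nrow(poly)
  inside <- logical(length(pr))
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    cross <- ((yi > pr) != (yj > pr)) &
      (pc < (xj - xi) * (pr - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# trace the outer boundary of each labeled region as a closed polygon in
# pixel-corner coordinates (pixel (r, c) spans [r - .5, r + .5] x [c - .5,
# c + .5]); holes are ignored (fill before calling when they matter).
# Returns a list of matrices (row, col). The shoelace area of the polygon of
# a hole-free region equals its pixel count exactly.
trace_region_boundary <- function(lab, id) {
  pix <- which(lab == id, arr.ind = TRUE)
  if (nrow(pix) == 0) return(NULL)
  nr <- nrow(lab); nc <- ncol(lab)
  inreg <- function(r, c) r >= 1 & r <= nr & c >= 1 & c <= nc &
    lab[cbind(pmax(pmin(r, nr), 1), pmax(pmin(c, nc), 1))] == id
  r <- pix[, 1]; c <- pix[, 2]
  segs <- list()
  # directed edges with the region on the left (y = row downward, x = col):
  up <- !inreg(r - 1, c)
  segs$up <- cbind(r[up] - 0.5, c[up] - 0.5, r[up] - 0.5, c[up] + 0.5)
  dn <- !inreg(r + 1, c)
  segs$dn <- cbind(r[dn] + 0.5, c[dn] + 0.5, r[dn] + 0.5, c[dn] - 0.5)
  lf <- !inreg(r, c - 1)
  segs$lf <- cbind(r[lf] + 0.5, c[lf] - 0.5, r[lf] - 0.5, c[lf] - 0.5)
  rt <- !inreg(r, c + 1)
  segs$rt <- cbind(r[rt] - 0.5, c[rt] + 0.5, r[rt] + 0.5, c[rt] + 0.5)
  E <- do.call(rbind, segs)
  key <- function(y, x) paste(round(y * 2), round(x * 2))
  from <- key(E[, 1], E[, 2])
  lookup <- split(seq_len(nrow(E)), from)
  used <- logical(nrow(E))
  loops <- list()
  for (start in seq_len(nrow(E))) {
    if (used[start]) next
    cur <- start
    verts <- list()
    repeat {
      used[cur] <- TRUE
      verts[[length(verts) + 1]] <- E[cur, 1:2]
      nxt_key <- key(E[cur, 3], E[cur, 4])
      cand <- lookup[[nxt_key]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      if (length(cand) > 1) {
        # degree-4 corner (diagonal contact): prefer the left turn so the
        # traced loop stays on one side
        dy <- E[cur, 3] - E[cur, 1]; dx <- E[cur, 4] - E[cur, 2]
        turn <- (E[cand, 3] - E[cand, 1]) * dx - (E[cand, 4] - E[cand, 2]) * dy
        cand <- cand[order(turn)][1]
      } else cand <- cand[1]
      cur <- cand
    }
    loops[[length(loops) + 1]] <- do.call(rbind, verts)
  }
  # keep the loop with the largest |area| as the outer boundary
  areas <- vapply(loops, function(p) abs(shoelace_area(p)), numeric(1))
  loops[[which.max(areas)]]
}

# signed shoelace area of polygon (row, col)
shoelace_area <- function(poly) {
  y <- poly[, 1]; x <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1)
  sum(x * y[j] - x[j] * y) / 2
}

# Visvalingam-Whyatt simplification: iteratively drop the vertex whose
# triangle with its neighbours has area < tol (px^2); keeps >= 4 vertices
simplify_polygon <- function(poly, tol) {
  if (tol <= 0) return(poly)
  repeat {
    n <- nrow(poly)
    if (n <= 4) break
    prv <- c(n, seq_len(n - 1)); nxt <- c(seq_len(n)[-1], 1)
    tri <- abs((poly[nxt, 2] - poly[prv, 2]) * (poly[, 1] - poly[prv, 1]) -
               (poly[, 2] - poly[prv, 2]) * (poly[nxt, 1] - poly[prv, 1])) / 2
    i <- which.min(tri)
    if (tri[i] >= tol) break
    poly <- poly[-i, , drop = FALSE]
  }
  poly
}

# count pixel centres (integer lattice points) inside a polygon given in
# pixel-corner coordinates, by horizontal scanlines with the even-odd rule
rasterized_pixel_count <- function(poly, nrow_img = NULL, ncol_img = NULL) {
  ymin <- ceiling(min(poly[, 1])); ymax <- floor(max(poly[, 1]))
  total <- 0L
  n <- nrow(poly)
  j <- c(seq_len(n)[-1], 1)
  y1 <- poly[, 1]; x1 <- poly[, 2]; y2 <- poly[j, 1]; x2 <- poly[j, 2]
  keep <- y1 != y2
  y1 <- y1[keep]; x1 <- x1[keep]; y2 <- y2[keep]; x2 <- x2[keep]
  for (r in seq(ymin, ymax)) {
    crosses <- (pmin(y1, y2) <= r) & (pmax(y1, y2) > r)
    if (!any(crosses)) next
    xs <- sort(x1[crosses] + (r - y1[crosses]) *
                 (x2[crosses] - x1[crosses]) / (y2[crosses] - y1[crosses]))
    for (k in seq(1, length(xs) - 1, by = 2)) {
      lo <- ceiling(xs[k]); hi <- floor(xs[k + 1])
      if (xs[k] == floor(xs[k])) lo <- xs[k]          # inclusive left edge
      if (hi >= lo) {
        if (!is.null(ncol_img)) { lo <- max(lo, 1); hi <- min(hi, ncol_img) }
        total <- total + max(0, floor(hi) - ceiling(lo) + 1)
      }
    }
  }
  total
}

# per-label summaries on a label matrix: pixel count, centroid, border flag
label_table <- function(lab) {
  idx <- which(lab > 0)
  if (length(idx) == 0) {
    return(tibble::tibble(id = integer(), area_px = integer(),
                          centroid_row = numeric(), centroid_col = numeric(),
                          touches_edge = logical()))
  }
  nr <- nrow(lab)
  ids <- lab[idx]
  rr <- (idx - 1) %% nr + 1
  cc <- (idx - 1) %/% nr + 1
  onb <- rr == 1 | rr == nr | cc == 1 | cc == ncol(lab)
  tibble::tibble(id = ids, r = rr, c = cc, onb = onb) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(area_px = dplyr::n(),
                     centroid_row = mean(.data$r),
                     centroid_col = mean(.data$c),
                     touches_edge = any(.data$onb), .groups = "drop")
}

# mean of `values` matrix over each label
label_means <- function(lab, values) {
  idx <- which(lab > 0)
  if (length(idx) == 0) return(numeric(0))
  as.numeric(tapply(values[idx], lab[idx], mean))
}

# solidity: pixel count / area of the convex hull of the pixel squares
label_solidity <- function(lab, ids) {
  nr <- nrow(lab)
  vapply(ids, function(i) {
    idx <- which(lab == i)
    rr <- (idx - 1) %% nr + 1
    cc <- (idx - 1) %/% nr + 1
    # corners of every pixel square (cheap enough for our object sizes)
    py <- c(rr - 0.5, rr - 0.5, rr + 0.5, rr + 0.5)
    px <- c(cc - 0.5, cc + 0.5, cc - 0.5, cc + 0.5)
    h <- grDevices::chull(px, py)
    hull <- cbind(py[h], px[h])
    ha <- abs(shoelace_area(hull))
    if (ha <= 0) return(1)
    min(length(idx) / ha, 1)
  }, numeric(1))
}

# rasterize a filled ellipse on the pixel-centre lattice; returns arr.ind
ellipse_pixels <- function(cy, cx, a, b, theta, nr, nc) {
  rmax <- max(a, b)
  r0 <- max(1L, floor(cy - rmax)); r1 <- min(nr, ceiling(cy + rmax))
  c0 <- max(1L, floor(cx - rmax)); c1 <- min(nc, ceiling(cx + rmax))
  if (r1 < r0 || c1 < c0) return(cbind(row = integer(), col = integer()))
  rr <- seq(r0, r1); cc <- seq(c0, c1)
  g <- expand.grid(row = rr, col = cc)
  dy <- g$row - cy; dx <- g$col - cx
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  cbind(row = g$row[keep], col = g$col[keep])
}
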