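# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from its definition (explicit loops, no shared code
# with the implementation).

# Phansalkar threshold by per-pixel double loop over an explicitly
# mirror-padded matrix
oracle_phansalkar <- function(img, radius, k = 0.25, r = 0.5, p = 2, q = 10,
                              polarity = "dark_objects") {
  x <- img / 255
  nr <- nrow(x); nc <- ncol(x)
  ri <- c(radius:1, 1:nr, nr:(nr - radius + 1))
  ci <- c(radius:1, 1:nc, nc:(nc - radius + 1))
  pad <- x[ri, ci]
  out <- matrix(NA, nr, nc)
  for (i in 1:nr) {
    for (j in 1:nc) {
      w <- pad[i:(i + 2 * radius), j:(j + 2 * radius)]
      m <- mean(w)
      s <- sqrt(mean(w^2) - m^2)
      t <- m * (1 + p * exp(-q * m) + k * (s / r - 1))
      out[i, j] <- if (polarity == "dark_objects") x[i, j] < t else x[i, j] > t
    }
  }
  out
}

# Benjamini-Hochberg step-up from the definition: sort ascending, take
# cumulative minima of p * m / rank from the largest rank down
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# repeated-measures one-way ANOVA sums of squares from the definition
oracle_rm_anova <- function(y, subject, condition) {
  subject <- as.factor(subject); condition <- as.factor(condition)
  n <- nlevels(subject); k <- nlevels(condition)
  grand <- mean(y)
  ss_cond <- 0
  for (cl in levels(condition)) {
    ss_cond <- ss_cond + n * (mean(y[condition == cl]) - grand)^2
  }
  ss_subj <- 0
  for (sl in levels(subject)) {
    ss_subj <- ss_subj + k * (mean(y[subject == sl]) - grand)^2
  }
  ss_err <- sum((y - grand)^2) - ss_cond - ss_subj
  f <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  list(F = f, df1 = k - 1, df2 = (k - 1) * (n - 1),
       p = pf(f, k - 1, (k - 1) * (n - 1), lower.tail = FALSE))
}

# match recovered particles to planted truth by nearest centroid; returns
# the truth-row index of each particle
match_to_truth <- function(particles, truth) {
  vapply(seq_len(nrow(particles)), function(i) {
    which.min((truth$centroid_row - particles$centroid_row[i])^2 +
              (truth$centroid_col - particles$centroid_col[i])^2)
  }, integer(1))
}

# polygon area by the shoelace formula (column order row, col)
oracle_polygon_area <- function(poly) {
  y <- poly[, 1]; x <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1)
  abs(sum(x * y[j] - x[j] * y) / 2)
}
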