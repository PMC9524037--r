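# Independent brute-force oracles used across the suite.  These are
# deliberately naive implementations that share no code with the package
# internals they check.

# exact Euclidean distance (pixels) from every pixel to the nearest
# foreground pixel, by exhaustive minimisation
brute_force_edt <- function(mask) {
  fg <- which(mask != 0, arr.ind = TRUE)
  out <- matrix(Inf, nrow(mask), ncol(mask))
  if (!nrow(fg)) return(out)
  for (i in seq_len(nrow(mask)))
    for (j in seq_len(ncol(mask)))
      out[i, j] <- sqrt(min((fg[, 1] - i)^2 + (fg[, 2] - j)^2))
  out
}

# morphological dilation of a binary mask by an exact Euclidean disk of
# radius r_px, by stamping the offset set on every foreground pixel
disk_stamp_dilate <- function(mask, r_px) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask != 0, arr.ind = TRUE)
  out <- matrix(FALSE, nr, nc)
  if (!nrow(fg)) return(out)
  r_int <- floor(r_px)
  off <- expand.grid(di = -r_int:r_int, dj = -r_int:r_int)
  off <- off[off$di^2 + off$dj^2 <= r_px^2, ]
  ii <- rep(fg[, 1], each = nrow(off)) + off$di
  jj <- rep(fg[, 2], each = nrow(off)) + off$dj
  keep <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
  out[cbind(ii[keep], jj[keep])] <- TRUE
  out
}

# 8-connected component labelling by explicit flood fill (BFS)
flood_fill_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  nbr <- expand.grid(di = -1:1, dj = -1:1)
  nbr <- nbr[!(nbr$di == 0 & nbr$dj == 0), ]
  for (start in which(mask != 0)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      pi <- (p - 1L) %% nr + 1L; pj <- (p - 1L) %/% nr + 1L
      for (k in seq_len(nrow(nbr))) {
        qi <- pi + nbr$di[k]; qj <- pj + nbr$dj[k]
        if (qi >= 1 && qi <= nr && qj >= 1 && qj <= nc &&
            mask[qi, qj] != 0 && lab[qi, qj] == 0L) {
          lab[qi, qj] <- cur
          queue <- c(queue, (qj - 1L) * nr + qi)
        }
      }
    }
  }
  lab
}

# two labelings agree up to renumbering iff the pixel partitions match
same_partition <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  fg <- a > 0
  key <- paste(a[fg], b[fg])
  length(unique(key)) == length(unique(a[fg])) &&
    length(unique(key)) == length(unique(b[fg]))
}

# one-way ANOVA F and p from first principles
anova_oracle <- function(values, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups); n <- length(values)
  gm <- tapply(values, groups, mean)
  ni <- tabulate(groups)
  ssb <- sum(ni * (gm - mean(values))^2)
  ssw <- sum((values - gm[as.integer(groups)])^2)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = f, p = pf(f, k - 1, n - k, lower.tail = FALSE),
       msw = ssw / (n - k), df = n - k, means = gm, ni = ni)
}

# Tukey HSD adjusted p for one pair from the studentized range distribution
tukey_oracle_p <- function(values, groups, a, b) {
  o <- anova_oracle(values, groups)
  ia <- which(names(o$means) == a); ib <- which(names(o$means) == b)
  se <- sqrt(o$msw / 2 * (1 / o$ni[ia] + 1 / o$ni[ib]))
  q <- abs(o$means[ia] - o$means[ib]) / se
  unname(ptukey(q, nlevels(as.factor(groups)), o$df, lower.tail = FALSE))
}

# small deterministic random label mask: a few disk-shaped objects
random_label_mask <- function(seed, shape = c(128L, 128L), pixel_size = 0.63,
                              n_obj = 4L, r_px = c(2, 5)) {
  set.seed(seed)
  m <- matrix(0, shape[1], shape[2])
  for (k in seq_len(n_obj)) {
    r <- runif(1, r_px[1], r_px[2])
    ci <- runif(1, 1 + r, shape[1] - r)
    cj <- runif(1, 1 + r, shape[2] - r)
    d2 <- outer((seq_len(shape[1]) - ci)^2, (seq_len(shape[2]) - cj)^2, `+`)
    m[d2 <= r^2] <- 1
  }
  m
}
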