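# Independent brute-force oracles for the texture matrices, plus small
# constructors for discretised regions built directly from label arrays.

# wrap a label matrix (one slice) as a discretised ROI
roi_from_matrix <- function(m, n_bins = 16L) {
  structure(list(labels = array(m, c(dim(m), 1L)), n_bins = n_bins,
                 retained = 1L),
            class = "discretised_roi")
}

# wrap a 3D label array (all slices retained)
roi_from_array <- function(a, n_bins = 16L) {
  structure(list(labels = a, n_bins = n_bins,
                 retained = seq_len(dim(a)[3])),
            class = "discretised_roi")
}

# exhaustive pair enumeration: every ordered pair of labelled cells at
# offset +d or -d (i.e. the symmetric co-occurrence count)
oracle_glcm <- function(lab, d, n_bins = 16L) {
  dims <- dim(lab)
  cnt <- matrix(0, n_bins, n_bins)
  cells <- which(!is.na(lab), arr.ind = TRUE)
  for (r in seq_len(nrow(cells))) {
    p <- cells[r, ]
    a <- lab[matrix(p, 1L)]
    for (s in c(1L, -1L)) {
      q <- p + s * d
      if (any(q < 1L) || any(q > dims)) next
      b <- lab[matrix(q, 1L)]
      if (is.na(b)) next
      cnt[a, b] <- cnt[a, b] + 1
    }
  }
  cnt
}

# exhaustive run scanner: walks every lattice line in direction d, restarting
# runs at unlabelled cells and label changes; works for 2D and 3D arrays
oracle_glrlm <- function(lab, d, n_bins = 16L) {
  dims <- dim(lab)
  runs_lab <- integer(0)
  runs_len <- integer(0)
  cells <- which(!is.na(lab) | is.na(lab), arr.ind = TRUE)  # all cells
  is_start <- function(p) {
    q <- p - d
    any(q < 1L) || any(q > dims)
  }
  for (r in seq_len(nrow(cells))) {
    p <- cells[r, ]
    if (!is_start(p)) next
    cur_lab <- NA_integer_
    cur_len <- 0L
    q <- p
    while (all(q >= 1L) && all(q <= dims)) {
      v <- lab[matrix(q, 1L)]
      if (is.na(v)) {
        if (cur_len > 0L) { runs_lab <- c(runs_lab, cur_lab)
                            runs_len <- c(runs_len, cur_len) }
        cur_len <- 0L; cur_lab <- NA_integer_
      } else if (!is.na(cur_lab) && v == cur_lab) {
        cur_len <- cur_len + 1L
      } else {
        if (cur_len > 0L) { runs_lab <- c(runs_lab, cur_lab)
                            runs_len <- c(runs_len, cur_len) }
        cur_lab <- v; cur_len <- 1L
      }
      q <- q + d
    }
    if (cur_len > 0L) { runs_lab <- c(runs_lab, cur_lab)
                        runs_len <- c(runs_len, cur_len) }
  }
  if (length(runs_len) == 0L) return(matrix(0, n_bins, 1L))
  cnt <- matrix(0, n_bins, max(runs_len))
  for (k in seq_along(runs_len))
    cnt[runs_lab[k], runs_len[k]] <- cnt[runs_lab[k], runs_len[k]] + 1
  cnt
}

# direct double-sum features from raw count matrices
oracle_sre <- function(cnt) {
  nr <- sum(cnt)
  if (nr == 0) return(NA_real_)
  s <- 0
  for (i in seq_len(nrow(cnt))) for (j in seq_len(ncol(cnt)))
    s <- s + cnt[i, j] / j^2
  s / nr
}

oracle_idm <- function(cnt) {
  tot <- sum(cnt)
  if (tot == 0) return(NA_real_)
  s <- 0
  for (i in seq_len(nrow(cnt))) for (j in seq_len(ncol(cnt)))
    s <- s + (cnt[i, j] / tot) / (1 + (i - j)^2)
  s
}

# pad two count matrices to a common number of run-length columns
pad_cols <- function(m, ncols) {
  if (ncol(m) >= ncols) return(m)
  cbind(m, matrix(0, nrow(m), ncols - ncol(m)))
}

expect_same_counts <- function(got, want) {
  nc <- max(ncol(got), ncol(want))
  expect_equal(unname(pad_cols(got, nc)), unname(pad_cols(want, nc)))
}

# random masked label slice
random_masked_slice <- function(n = 8L, p_mask = 0.75, n_levels = 4L) {
  lab <- matrix(sample.int(n_levels, n * n, replace = TRUE), n, n)
  lab[stats::runif(n * n) > p_mask] <- NA_integer_
  lab
}
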