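# Shared fixture builders: everything is generated in code at test time.

# Small single-lesion phantom; center chosen inside white matter.
tiny_phantom <- function(seed = 1, area_cm2 = 4, z_extent = 5,
                         contrast = c(2.0, 1.7), deform = 0,
                         grid = c(64, 64, 24), spacing = c(1, 1, 3),
                         noise_sd = 0.005) {
  ctr <- grid * spacing / 2 + c(4, 2, 0)
  generate_phantom(phantom_spec(
    grid_shape = grid, spacing_mm = spacing,
    lesion_specs = list(lesion_spec(ctr, area_cm2, z_extent,
                                    contrast = contrast)),
    deform_amplitude_mm = deform, noise_sd = noise_sd, seed = seed))
}

# Synthetic slice record with an optional bright square; separable by
# construction.
toy_record <- function(patient_id, positive, seed, n = 32, split = "train") {
  px <- withr::with_seed(seed, matrix(stats::rnorm(n * n, 0, 0.1), n, n))
  if (positive) px[10:18, 10:18] <- px[10:18, 10:18] + 3
  structure(list(patient_id = patient_id, slice_index = 0L, pixels = px,
                 mask = matrix(TRUE, n, n), spacing_mm = c(1, 1, 5),
                 label = as.integer(positive),
                 lesion_area_cm2 = if (positive) 0.81 else 0,
                 lesion_contrast = if (positive) 3 else 0,
                 arm = "HF", split = split),
            class = "slice_record")
}

toy_record_set <- function(n_pos = 15, n_neg = 15, seed = 1, split = "train") {
  c(lapply(seq_len(n_pos), function(i)
      toy_record(sprintf("pos%02d", i), TRUE, seed * 1000 + i, split = split)),
    lapply(seq_len(n_neg), function(i)
      toy_record(sprintf("neg%02d", i), FALSE, seed * 1000 + 500 + i,
                 split = split)))
}

# Independent brute-force gradient entropy: literal [1 -1] valid
# convolution along the horizontal (column) axis, explicit loops.
brute_gradient_entropy <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  if (nc < 2) return(0)
  g <- matrix(0, nr, nc - 1)
  for (i in seq_len(nr)) for (j in seq_len(nc - 1))
    g[i, j] <- abs(img[i, j + 1] - img[i, j])
  s <- sum(g)
  if (s == 0) return(0)
  f <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc - 1)) {
    h <- g[i, j] / s
    if (h > 0) f <- f - h * log2(h)
  }
  f
}

# Independent O(n^2) DeLong structural components (no ranks).
brute_delong <- function(labels, sa, sb) {
  psi <- function(x, y) ifelse(x > y, 1, ifelse(x == y, 0.5, 0))
  comp <- function(s) {
    pos <- s[labels == 1]; neg <- s[labels == 0]
    m <- length(pos); n <- length(neg)
    auc <- mean(outer(pos, neg, psi))
    v10 <- vapply(seq_len(m), function(i) mean(psi(pos[i], neg)), numeric(1))
    v01 <- vapply(seq_len(n), function(j) mean(psi(pos, neg[j])), numeric(1))
    list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
  }
  a <- comp(sa); b <- comp(sb)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / a$m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / a$n
  (a$auc - b$auc) / sqrt(v)
}
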