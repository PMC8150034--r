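# Shared fixtures: all synthetic, generated in code at test time.

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# compact long-bone spec used across segmentation/fabric tests; thicker
# struts (80 µm = 6.4 voxels) so segmentation accuracy is limited by the
# method, not strut resolvability
small_bone_spec <- function(seed, model = "aligned_rods", ...) {
  args <- modifyList(list(
    length_um = 3500, outer_radius_um = 900, cortical_thickness_um = 250,
    trabecular_model = model, scatter_deg = 10, rod_radius_um = 80,
    target_fill = 0.3, spacing_um = 25, seed = seed
  ), list(...))
  do.call(phantom_spec, args)
}

# segmentation as the pipeline runs it: median filter then segment
segment_phantom <- function(ph, ...) {
  segment_volume(median_filter(ph$volume, 3L), ...)
}

# brute-force maximal-inscribed-sphere local thickness (oracle); same
# convention as the production code: sphere radius at q is d(q), the
# centre-to-centre distance to the nearest background voxel
brute_local_thickness <- function(mask) {
  d <- dim(mask)
  co_all <- arrayInd(seq_along(mask), d)
  bg <- co_all[!mask, , drop = FALSE]
  fg <- which(mask)
  co <- co_all[fg, , drop = FALSE]
  th <- numeric(length(fg))
  r <- numeric(length(fg))
  for (i in seq_along(fg)) {
    if (nrow(bg)) {
      dd <- sqrt(min(rowSums(sweep(bg, 2, co[i, ])^2)))
    } else {
      dd <- Inf
    }
    r[i] <- dd
  }
  for (i in seq_along(fg)) {
    covers <- rowSums(sweep(co, 2, co[i, ])^2) <= r^2 + 1e-12
    th[i] <- 2 * max(r[covers])
  }
  out <- array(0, d)
  out[fg] <- th
  out
}

# exhaustive Otsu oracle: maximize between-class variance over all 256
# bin boundaries of the full-range histogram
brute_otsu <- function(x) {
  lo <- min(x); hi <- max(x)
  nb <- 256L
  bin <- pmin(nb - 1L, as.integer((as.numeric(x) - lo) / (hi - lo) * nb))
  h <- tabulate(bin + 1L, nbins = nb)
  centres <- lo + (seq_len(nb) - 0.5) / nb * (hi - lo)
  best <- -Inf; bestk <- 1L
  n <- sum(h)
  for (k in seq_len(nb - 1L)) {
    w0 <- sum(h[1:k]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:k] * centres[1:k]) / sum(h[1:k])
    mu1 <- sum(h[(k + 1):nb] * centres[(k + 1):nb]) / sum(h[(k + 1):nb])
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) { best <- v; bestk <- k }
  }
  lo + bestk / nb * (hi - lo)
}

# minimal defined anisotropy field for IO tests
toy_field <- function(da = c(0.9, 0.3), z = c(100, 600)) {
  n <- length(da)
  s <- data.frame(x = seq_len(n) * 100, y = 0, z = z, da = da,
                  ax = 0, ay = 0, az = 1, n_normals = 100L,
                  degenerate = FALSE, defined = da > 0)
  structure(list(samples = s,
                 lattice = list(spacing = 500, radius = 500)),
            class = "anisotropy_field")
}
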