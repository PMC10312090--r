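## Exact anisotropic (scaled) squared Euclidean distance transform by the
## separable lower-envelope algorithm: per axis, the 1D transform
## g(i) = min_j f(j) + w (i - j)^2 is computed from the lower envelope of
## the parabolas rooted at the finite f(j). Applying it along the three
## axes with per-axis weights w = (h / r)^2 gives, exactly,
## min over target voxels of sum_k ((Delta_k h_k) / r_k)^2.

.dt1dSq <- function(f, w) {
  n <- length(f)
  idx <- which(is.finite(f))
  if (!length(idx)) return(f)
  if (w == 0) return(rep(min(f[idx]), n))
  k <- 0L
  v <- integer(length(idx))
  z <- numeric(length(idx) + 1L)
  s <- 0
  for (q in idx) {
    fq <- f[q]
    repeat {
      if (k == 0L) break
      p <- v[k]
      s <- ((fq + w * q * q) - (f[p] + w * p * p)) / (2 * w * (q - p))
      if (s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- if (k == 1L) -Inf else s
    z[k + 1L] <- Inf
  }
  out <- numeric(n)
  j <- 1L
  for (q in seq_len(n)) {
    while (z[j + 1L] < q) j <- j + 1L
    p <- v[j]
    out[q] <- w * (q - p)^2 + f[p]
  }
  out
}

#' Scaled squared distance to a voxel set
#'
#' For every voxel, the minimum over target voxels of
#' sum_k ((Delta_k * h_k) / r_k)^2, where Delta_k is the center-to-center
#' voxel index offset, h_k the voxel spacing (mm) and r_k a per-axis
#' scaling radius (mm). With r = (1, 1, 1) this is the plain squared
#' Euclidean distance in mm^2; with r = (rip, rip, rtp) it is the
#' ellipsoidal norm used by the CSF-distance erosion criterion. Exact
#' (separable lower-envelope distance transform), Inf where the target set
#' is empty.
#'
#' @param target 3D logical array of target voxels.
#' @param voxelSize numeric(3) spacing in mm.
#' @param radii numeric(3) per-axis scaling radii in mm.
#' @return 3D numeric array of scaled squared distances.
#' @export
scaledSquaredDistance <- function(target, voxelSize, radii = c(1, 1, 1)) {
  stopifnot(length(dim(target)) == 3L, length(voxelSize) == 3L,
            length(radii) == 3L, all(radii > 0))  # Inf allowed: axis ignored
  d <- dim(target)
  w <- (voxelSize / radii)^2
  f <- array(Inf, d)
  f[target] <- 0
  for (ax in 1:3) {
    others <- setdiff(1:3, ax)
    f <- apply(f, others, .dt1dSq, w = w[ax])
    ## apply() returns the transformed axis first; permute back
    f <- aperm(array(f, dim = c(d[ax], d[others])), order(c(ax, others)))
  }
  f
}
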