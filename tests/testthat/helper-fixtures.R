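## Shared fixture builders. Everything is generated in code at test time.

TE6 <- c(0, 7.5, 17.5, 67.5, 147.5, 307.5)

## Noiseless three-pool decay evaluated by direct scalar arithmetic
## (independent of the package's forward model).
threePoolOracle <- function(a, t2, te) {
  vapply(te, function(x) sum(a * exp(-x / t2)), numeric(1))
}

## A uniform EchoVolume with the same signal in every voxel.
uniformEchoVolume <- function(signal, dims = c(6, 6, 4),
                              voxelSize = c(1.3, 1.3, 5), te = TE6) {
  EchoVolume(array(rep(signal, each = prod(dims)), c(dims, length(te))),
             voxelSize, te)
}

## Central chi mean factor sqrt(2) Gamma(n + 1/2) / Gamma(n), computed
## directly (oracle for the A = 0 identities).
chiMeanFactor <- function(n) sqrt(2) * exp(lgamma(n + 0.5) - lgamma(n))

## Brute-force scaled squared distance to a target set (oracle for the
## distance transform and the erosion criterion).
bruteScaledDistSq <- function(target, voxelSize, radii) {
  d <- dim(target)
  idx <- which(target, arr.ind = TRUE)
  out <- array(Inf, d)
  for (v in seq_len(prod(d))) {
    vi <- arrayInd(v, d)
    delta <- sweep(idx, 2, as.vector(vi), `-`)
    out[v] <- min(rowSums(sweep(sweep(delta, 2, voxelSize, `*`),
                                2, radii, `/`)^2))
  }
  out
}

## Brute-force Benjamini-Hochberg step-up adjusted p-values.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}
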