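## Three-pool box-constrained non-linear least-squares fitting.
##
## Model per voxel: S(TE) = A_MW e^{-TE/T2_MW} + A_IEW e^{-TE/T2_IEW} +
## A_CSF e^{-TE/T2_CSF}, with amplitudes >= 0 and each T2 confined to its
## pool's interval. T2s are optimized in log-space for conditioning;
## optimization uses L-BFGS-B.

#' Pool T2 bounds
#'
#' Lower and upper T2 limits (ms) for the myelin water, intra/extra-cellular
#' water and CSF pools.
#'
#' @param mw,iew,csf numeric(2) (lower, upper) per pool.
#' @return 3 x 2 matrix with rows mw, iew, csf.
#' @export
poolBounds <- function(mw = c(5, 20), iew = c(20, 200), csf = c(200, 2000)) {
  b <- rbind(mw = mw, iew = iew, csf = csf)
  colnames(b) <- c("lower", "upper")
  if (any(b[, 1L] >= b[, 2L])) stop("each lower bound must be < upper")
  if (b[1L, 2L] > b[2L, 1L] || b[2L, 2L] > b[3L, 1L])
    stop("pools may overlap only at shared endpoints")
  b
}

#' Fitting configuration
#'
#' @param lambda Laplacian spatial smoothness weight (>= 0; 0 = independent
#'   per-voxel fits). The penalty acts on the optimizer's parameter scale
#'   (amplitudes normalized by the volume's mean first-echo signal, T2s in
#'   log ms) so lambda is dimensionless.
#' @param maxit maximum L-BFGS-B iterations per voxel.
#' @param factr,pgtol L-BFGS-B convergence tolerances.
#' @param nStarts number of deterministic initializations per voxel (the
#'   standard initialization plus fixed alternates); the best final
#'   objective wins, ties resolved in initialization order. No random
#'   restarts.
#' @param nSweeps Gauss-Seidel sweeps over the volume when lambda > 0.
#' @param penalized character vector naming the parameter maps the
#'   Laplacian penalty applies to (default all six).
#' @return a list of class \code{fitConfig}.
#' @export
fitConfig <- function(lambda = 0, maxit = 500L, factr = 1e2, pgtol = 1e-10,
                      nStarts = 3L, nSweeps = 1L,
                      penalized = c("aMW", "aIEW", "aCSF",
                                    "t2MW", "t2IEW", "t2CSF")) {
  if (lambda < 0) stop("lambda must be >= 0")
  structure(list(lambda = lambda, maxit = as.integer(maxit), factr = factr,
                 pgtol = pgtol, nStarts = as.integer(nStarts),
                 nSweeps = as.integer(nSweeps), penalized = penalized),
            class = "fitConfig")
}

#' Log-linear T2 initializer
#'
#' Ordinary least-squares slope b of ln(S) against TE over the first four
#' echoes; T2 = -1/b clamped into [20, 200] ms. Degenerate inputs take
#' documented total-function fallbacks: any nonpositive signal or a rising
#' signal (b > 0) returns 70 ms; a flat signal (b = 0, formally T2 = +Inf)
#' clamps to the 200 ms upper bound.
#'
#' @param signal magnitudes at the first four echoes.
#' @param teMs matching echo times (ms).
#' @return T2 estimate in ms.
#' @export
loglinearInitT2 <- function(signal, teMs) {
  stopifnot(length(signal) == 4L, length(teMs) == 4L)
  if (any(signal <= 0)) return(70)
  b <- stats::cov(teMs, log(signal)) / stats::var(teMs)
  if (b == 0) return(200)
  if (b > 0) return(70)
  min(max(-1 / b, 20), 200)
}

#' Initialize three-pool parameters for one voxel
#'
#' Myelin-water and CSF T2 start at 10 and 2000 ms; the intra/extra-cellular
#' T2 comes from \code{\link{loglinearInitT2}} on the first four echoes.
#' Myelin-water and intra/extra-cellular amplitudes start at 10\% and 90\%
#' of the first-echo signal; the CSF amplitude starts at the last-echo
#' signal. All values are projected into their bounds.
#'
#' @param signal all-echo magnitudes (>= 5 echoes).
#' @param teMs matching echo times (ms).
#' @param bounds pool T2 bounds from \code{\link{poolBounds}}.
#' @return list with elements \code{a} (numeric(3) amplitudes), \code{t2}
#'   (numeric(3) ms) and \code{unfittable} (TRUE for an all-zero voxel,
#'   which is excluded from maps).
#' @export
initPools <- function(signal, teMs, bounds = poolBounds()) {
  stopifnot(length(signal) >= 5L, length(signal) == length(teMs))
  if (all(signal == 0))
    return(list(a = c(0, 0, 0), t2 = c(10, 70, 2000), unfittable = TRUE))
  s1 <- signal[1L]
  a <- pmax(c(0.10 * s1, 0.90 * s1, signal[length(signal)]), 0)
  t2 <- c(10, loglinearInitT2(signal[1:4], teMs[1:4]), 2000)
  t2 <- pmin(pmax(t2, bounds[, 1L]), bounds[, 2L])
  list(a = a, t2 = t2, unfittable = FALSE)
}

## Objective and analytic gradient in theta = (a1, a2, a3, log t2_1..3).
## Optional quadratic penalty pen = list(lambda, w, center, scale):
## lambda * sum_p ((w * theta_p - center_p) / scale_p)^2 with neighbor
## aggregates frozen (Gauss-Seidel linearization of the Laplacian penalty).
.fitObjective <- function(theta, signal, teMs, pen = NULL) {
  a <- theta[1:3]; t2 <- exp(theta[4:6])
  E <- exp(-outer(1 / t2, teMs))
  r <- signal - colSums(a * E)
  val <- sum(r * r)
  if (!is.null(pen)) {
    d <- (pen$w * theta - pen$center) / pen$scale
    val <- val + pen$lambda * sum(d * d)
  }
  val
}

.fitGradient <- function(theta, signal, teMs, pen = NULL) {
  a <- theta[1:3]; t2 <- exp(theta[4:6])
  E <- exp(-outer(1 / t2, teMs))
  r <- signal - colSums(a * E)
  ga <- -2 * as.vector(E %*% r)
  gt <- -2 * a * as.vector((E * outer(1 / t2, teMs)) %*% r)
  g <- c(ga, gt)
  if (!is.null(pen)) {
    d <- (pen$w * theta - pen$center) / pen$scale
    g <- g + 2 * pen$lambda * pen$w * d / pen$scale
  }
  g
}

## Deterministic alternate initializations: fixed multiplicative tweaks of
## the standard init's T2 values (projected into bounds).
.altInits <- function(init, bounds, nStarts) {
  inits <- list(init)
  if (nStarts >= 2L) {
    i2 <- init
    i2$t2 <- pmin(pmax(c(7, 0.7 * init$t2[2L], 1000), bounds[, 1L]),
                  bounds[, 2L])
    inits <- c(inits, list(i2))
  }
  if (nStarts >= 3L) {
    i3 <- init
    i3$t2 <- pmin(pmax(c(15, 1.3 * init$t2[2L], 2000), bounds[, 1L]),
                  bounds[, 2L])
    inits <- c(inits, list(i3))
  }
  inits
}

#' Fit the three-pool model to one voxel
#'
#' Box-constrained non-linear least squares by L-BFGS-B: amplitudes >= 0,
#' T2s inside their pool bounds (optimized in log space). Deterministic
#' given the initialization; with \code{nStarts > 1} a fixed set of
#' alternate initializations is tried and the best final objective kept.
#'
#' @param signal all-echo magnitudes (>= 6 echoes for the 6 parameters).
#' @param teMs matching echo times (ms).
#' @param bounds pool T2 bounds.
#' @param init initialization from \code{\link{initPools}}.
#' @param config a \code{\link{fitConfig}}.
#' @param penalty internal: frozen-neighbor quadratic penalty for the
#'   spatially regularized volume fit.
#' @return list with \code{a}, \code{t2}, \code{residual} (final residual
#'   norm), \code{objective}, \code{converged}, \code{atBound} (number of
#'   T2 parameters at a bound), \code{unfittable}.
#' @export
fitVoxel <- function(signal, teMs, bounds = poolBounds(),
                     init = initPools(signal, teMs, bounds),
                     config = fitConfig(), penalty = NULL) {
  stopifnot(length(signal) >= 6L, length(signal) == length(teMs))
  if (any(!is.finite(signal))) stop("non-finite signal")
  if (isTRUE(init$unfittable))
    return(list(a = c(NA_real_, NA_real_, NA_real_), t2 = init$t2,
                residual = NA_real_, objective = NA_real_,
                converged = FALSE, atBound = 0L, unfittable = TRUE))
  lo <- c(0, 0, 0, log(bounds[, 1L]))
  hi <- c(Inf, Inf, Inf, log(bounds[, 2L]))
  best <- NULL
  for (ini in .altInits(init, bounds, if (is.null(penalty)) config$nStarts
                                      else 1L)) {
    th0 <- c(ini$a, log(ini$t2))
    o <- stats::optim(th0, .fitObjective, .fitGradient, signal = signal,
                      teMs = teMs, pen = penalty, method = "L-BFGS-B",
                      lower = lo, upper = hi,
                      control = list(maxit = config$maxit,
                                     factr = config$factr,
                                     pgtol = config$pgtol))
    if (is.null(best) || o$value < best$value) best <- o
  }
  ## L-BFGS-B can land a few ulp below the zero bound
  a <- pmax(best$par[1:3], 0)
  t2 <- exp(best$par[4:6])
  resid <- sqrt(.fitObjective(best$par, signal, teMs))
  atB <- sum(abs(t2 - bounds[, 1L]) < 1e-9 | abs(t2 - bounds[, 2L]) < 1e-9)
  ## L-BFGS-B line searches can stall once the residual reaches machine
  ## precision; a fit at the numerical floor counts as converged
  conv <- best$convergence == 0L ||
    best$value < 1e-12 * max(1, sum(signal^2))
  list(a = a, t2 = t2, residual = resid, objective = best$value,
       converged = conv, atBound = as.integer(atB),
       unfittable = FALSE)
}

#' Water fractions from pool amplitudes
#'
#' Each fraction is the pool amplitude divided by the total amplitude; the
#' three fractions sum to exactly 1. A zero total is flagged undefined
#' (all-NA), never silently 0.
#'
#' @param pools either a numeric(3) of amplitudes (MW, IEW, CSF) or a fit
#'   result with an \code{a} element.
#' @return named numeric(3) (mwf, iewf, csff), all NA when undefined.
#' @export
computeWF <- function(pools) {
  a <- if (is.list(pools)) pools$a else pools
  stopifnot(length(a) == 3L)
  if (anyNA(a) || any(a < 0))
    if (anyNA(a)) return(c(mwf = NA_real_, iewf = NA_real_, csff = NA_real_))
    else stop("amplitudes must be nonnegative")
  tot <- sum(a)
  if (tot == 0) return(c(mwf = NA_real_, iewf = NA_real_, csff = NA_real_))
  f <- a / tot
  c(mwf = f[1L], iewf = f[2L], csff = f[3L])
}

#' Fit the three-pool model over a masked volume
#'
#' With \code{lambda = 0} this is the independent per-voxel fit. With
#' \code{lambda > 0} the per-voxel objectives are coupled by a discrete
#' Laplacian smoothness penalty on the parameter maps (6-neighborhood,
#' weights 1/h^2 from the physical voxel spacing, parameter maps taken on
#' the optimizer scale), minimized by Gauss-Seidel sweeps that refit each
#' voxel with its neighbors' current parameters frozen.
#'
#' @param volume an \linkS4class{EchoVolume} (bias-corrected magnitudes).
#' @param mask 3D logical array of voxels to fit.
#' @param bounds pool T2 bounds.
#' @param config a \code{\link{fitConfig}}.
#' @return list with \code{params} (named list of six 3D parameter maps),
#'   \code{wf} (a \linkS4class{WFMaps}), \code{quality} (integer array:
#'   0 fitted, 1 unfittable, 2 optimizer not converged, 3 outside mask)
#'   and \code{nAtBound} (count of fitted voxels with a T2 at a bound).
#' @export
fitVolume <- function(volume, mask, bounds = poolBounds(),
                      config = fitConfig()) {
  stopifnot(is(volume, "EchoVolume"))
  d <- dim(volume@data)
  if (!identical(dim(mask), d[1:3]))
    stop("mask dimensions must match the volume")
  if (!any(mask)) stop("empty mask")
  if (any(!is.finite(volume@data))) {
    bad <- which(!is.finite(volume@data), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite input at voxel (%d, %d, %d), echo %d",
                 bad[1L], bad[2L], bad[3L], bad[4L]))
  }
  te <- volume@teMs
  idx <- which(mask)
  arrInd <- arrayInd(idx, d[1:3])
  nv <- length(idx)

  pnames <- c("aMW", "aIEW", "aCSF", "t2MW", "t2IEW", "t2CSF")
  theta <- matrix(NA_real_, nv, 6L)     # optimizer-scale parameters
  quality <- array(3L, d[1:3])
  atBound <- 0L
  sigMat <- matrix(volume@data, prod(d[1:3]), d[4L])[idx, , drop = FALSE]

  fits <- vector("list", nv)
  for (v in seq_len(nv)) {
    s <- sigMat[v, ]
    ini <- initPools(s, te, bounds)
    f <- fitVoxel(s, te, bounds, ini, config)
    fits[[v]] <- f
    quality[idx[v]] <- if (f$unfittable) 1L else if (!f$converged) 2L else 0L
    if (!f$unfittable) {
      theta[v, ] <- c(f$a, log(f$t2))
      atBound <- atBound + (f$atBound > 0L)
    }
  }

  if (config$lambda > 0 && nv > 1L) {
    sRef <- mean(sigMat[, 1L])
    if (sRef <= 0) sRef <- 1
    scale <- c(rep(sRef, 3L), rep(1, 3L))   # amplitudes normalized by sRef
    penMask <- pnames %in% config$penalized
    effScale <- ifelse(penMask, scale, Inf) # Inf scale = unpenalized map
    w <- 1 / volume@voxelSize^2             # mm^-2 per axis
    ## linear index offsets of the 6-neighborhood
    offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                  c(0, 0, -1), c(0, 0, 1))
    offW <- w[c(1, 1, 2, 2, 3, 3)]
    pos <- array(NA_integer_, d[1:3]); pos[idx] <- seq_len(nv)
    lambdaEff <- config$lambda * sRef^2
    for (sweep in seq_len(config$nSweeps)) {
      for (v in seq_len(nv)) {
        if (quality[idx[v]] == 1L) next
        W <- 0; B <- numeric(6L)
        for (o in seq_len(6L)) {
          nb <- arrInd[v, ] + offs[o, ]
          if (any(nb < 1L) || any(nb > d[1:3])) next
          u <- pos[nb[1L], nb[2L], nb[3L]]
          if (is.na(u) || anyNA(theta[u, ])) next
          W <- W + offW[o]
          B <- B + offW[o] * theta[u, ]
        }
        if (W == 0) next
        s <- sigMat[v, ]
        pen <- list(lambda = lambdaEff, w = W, center = B, scale = effScale)
        ini <- list(a = theta[v, 1:3], t2 = exp(theta[v, 4:6]),
                    unfittable = FALSE)
        f <- fitVoxel(s, te, bounds, ini, config, penalty = pen)
        fits[[v]] <- f
        theta[v, ] <- c(f$a, log(f$t2))
        quality[idx[v]] <- if (!f$converged) 2L else 0L
      }
    }
  }

  params <- stats::setNames(lapply(seq_len(6L), function(p) {
    m <- array(NA_real_, d[1:3])
    vals <- theta[, p]
    if (p >= 4L) vals <- exp(vals)
    m[idx] <- vals
    m
  }), pnames)

  mwf <- array(NA_real_, d[1:3]); iewf <- mwf; csff <- mwf
  defined <- array(FALSE, d[1:3])
  for (v in seq_len(nv)) {
    f <- fits[[v]]
    wf <- computeWF(f)
    if (!anyNA(wf)) {
      mwf[idx[v]] <- wf[1L]; iewf[idx[v]] <- wf[2L]; csff[idx[v]] <- wf[3L]
      defined[idx[v]] <- TRUE
    }
  }
  wfMaps <- new("WFMaps", mwf = mwf, iewf = iewf, csff = csff,
                defined = defined, voxelSize = volume@voxelSize)
  list(params = params, wf = wfMaps, quality = quality,
       nAtBound = atBound)
}
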