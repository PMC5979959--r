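# SAXS curve analysis: Guinier fit with a curvature-aware window search,
# dimensionless Kratky transform, Porod invariant/volume with low- and
# high-q extrapolation, regularized P(r) inversion with Dmax scanning, and
# the volume -> mass -> subunit-count arithmetic for oligomer sizing.

#' Construct a SAXS curve
#'
#' @param q momentum transfer grid (strictly increasing, positive)
#' @param I intensities
#' @param sigma per-point uncertainties (NULL for unknown)
#' @param qUnit "A^-1" or "nm^-1"
#' @return a [SAXSCurve-class]
#' @export
saxsCurve <- function(q, I, sigma = NULL, qUnit = "A^-1") {
  if (is.null(sigma)) sigma <- rep(0, length(q))
  new("SAXSCurve", q = as.numeric(q), I = as.numeric(I),
      sigma = as.numeric(sigma), qUnit = qUnit)
}

#' Convert a SAXS curve between q units
#'
#' @param curve a [SAXSCurve-class]
#' @param qUnit target unit ("A^-1" or "nm^-1")
#' @return the converted [SAXSCurve-class]
#' @export
convertQUnit <- function(curve, qUnit) {
  if (curve@qUnit == qUnit) return(curve)
  f <- if (qUnit == "nm^-1") 10 else 0.1
  saxsCurve(curve@q * f, curve@I, curve@sigma, qUnit)
}

#' Guinier fit of the low-q region
#'
#' Fits ln I = ln I0 - (Rg^2/3) q^2 on a low-q window. The window is grown
#' from the lowest q until qmax * Rg exceeds `qRgLimit` (iterated to
#' self-consistency with the fitted Rg), then shrunk while the curvature of
#' the data (quadratic term in q^2) contributes more than three times the
#' noise scale at the window edge, so that systematic deviation from the
#' Guinier law never dominates the fit. Leading points whose studentized
#' residuals exceed +2.5 flag (and are dropped as) a low-q upturn,
#' reported as possible aggregation.
#'
#' @param curve a [SAXSCurve-class]
#' @param qRgLimit upper limit for qmax * Rg (1.3, the conventional
#'   validity bound of the Guinier approximation)
#' @param minPoints minimum number of low-q points in the fit
#' @return a [GuinierResult-class]; Rg is in the reciprocal of the curve's
#'   q unit
#' @export
guinierFit <- function(curve, qRgLimit = 1.3, minPoints = 10L) {
  ok <- curve@I > 0
  q <- curve@q[ok]
  I <- curve@I[ok]
  sg <- curve@sigma[ok]
  stopIfNot(length(q) >= minPoints,
            sprintf("need at least %d positive low-q points", minPoints))
  x <- q^2
  y <- log(I)
  rgOf <- function(idx) {
    b <- coef(lm(y[idx] ~ x[idx]))[2]
    if (is.na(b) || b >= 0) return(NA_real_)
    sqrt(-3 * b)
  }
  # expand until the qRg limit is hit (self-consistently with the fitted
  # Rg; windows too small to pin the slope down keep growing)
  j <- minPoints
  while (j < length(q)) {
    rg <- rgOf(1:(j + 1L))
    if (!is.na(rg) && q[j + 1L] * rg > qRgLimit) break
    j <- j + 1L
  }
  if (is.na(rgOf(1:j)))
    stop("negative or zero Guinier slope: not a decaying low-q region",
         call. = FALSE)
  # shrink while systematic curvature at the window edge exceeds the noise
  noiseScale <- function(idx) {
    s <- if (any(sg[idx] > 0)) stats::median(sg[idx] / I[idx]) else 0
    max(s, 1e-12)
  }
  aggregated <- FALSE
  repeat {
    idx <- 1:j
    if (j <= minPoints) break
    fq <- lm(y[idx] ~ x[idx] + I(x[idx]^2))
    cc <- coef(fq)[3]
    dev <- abs(cc) * (x[j] - x[1])^2 / 4
    s <- max(noiseScale(idx), sqrt(mean(stats::resid(fq)^2)))
    if (dev <= 3 * s) break
    # a significant *positive* curvature is a steep low-q rise on top of
    # the Guinier decay: the signature of aggregation
    if (cc > 0) aggregated <- TRUE
    j <- j - 1L
  }
  # leading-upturn check: fit the upper 80% of the window and test whether
  # the lowest-q points rise above the extrapolated Guinier line
  k0 <- max(3L, ceiling(0.2 * j))
  if (j - k0 >= 5L) {
    refIdx <- (k0 + 1L):j
    refFit <- lm(y[refIdx] ~ x[refIdx])
    pred <- coef(refFit)[1] + coef(refFit)[2] * x[1:3]
    excess <- mean(y[1:3] - pred)
    s <- max(noiseScale(refIdx),
             sqrt(mean(stats::resid(refFit)^2)), 3e-4)
    if (excess > 3 * s) aggregated <- TRUE
  }
  # final fit; drop leading points with studentized residuals > 2.5
  # (these are the points of a low-q upturn)
  drop0 <- 0L
  repeat {
    idx <- (drop0 + 1L):j
    fit <- lm(y[idx] ~ x[idx])
    r <- stats::resid(fit)
    sr <- r / max(stats::sd(r), 1e-12)
    if (sr[1] > 2.5 && length(idx) > minPoints) {
      drop0 <- drop0 + 1L
      aggregated <- TRUE
    } else break
  }
  b <- coef(fit)[2]
  stopIfNot(!is.na(b) && b < 0,
            "negative or zero Guinier slope after outlier removal")
  rg <- sqrt(-3 * b)
  i0 <- exp(coef(fit)[1])
  new("GuinierResult", rg = unname(rg), i0 = unname(i0),
      qRange = c(q[drop0 + 1L], q[j]), qmaxRg = unname(q[j] * rg),
      npts = length(idx), aggregated = aggregated,
      residualSd = stats::sd(stats::resid(fit)))
}

#' Dimensionless Kratky transform
#'
#' Computes (q Rg)^2 I(q)/I(0) against q Rg. A compact globular particle
#' peaks at (sqrt(3), 3/e ~ 1.104); flexible chains rise to a plateau
#' without returning to the baseline. The peak is located by cubic-spline
#' interpolation of the transformed series.
#'
#' @param curve a [SAXSCurve-class]
#' @param guinier a [GuinierResult-class] for the same curve
#' @return list with `series` (data.frame qRg, kratky), `peakX`, `peakY`
#' @export
kratkyDimensionless <- function(curve, guinier) {
  stopIfNot(guinier@i0 > 0, "I(0) must be positive")
  xr <- curve@q * guinier@rg
  yr <- xr^2 * curve@I / guinier@i0
  sf <- splinefun(xr, yr, method = "fmm")
  # bracket the global grid maximum, then refine by spline interpolation
  i <- which.max(yr)
  lo <- xr[max(i - 1L, 1L)]
  hi <- xr[min(i + 1L, length(xr))]
  opt <- optimize(sf, c(lo, hi), maximum = TRUE,
                  tol = .Machine$double.eps^0.5)
  list(series = data.frame(qRg = xr, kratky = yr),
       peakX = opt$maximum, peakY = opt$objective)
}

#' Porod invariant and Porod volume
#'
#' Q = integral of q^2 [I(q) - background] dq, with the data range
#' complemented by a Guinier extrapolation from q = 0 to the first data
#' point and a q^-4 Porod tail beyond the last. The flat background and
#' the Porod constant K are estimated from a linear fit of I q^4 versus
#' q^4 over the high-q tail. The Porod volume is Vp = 2 pi^2 I(0) / Q.
#'
#' The Porod constant K and the flat background B are estimated jointly
#' over the high-q tail window by alternating the moment conditions
#' K = mean((I - B) q^4) and B = mean(I - K q^-4), which averages over the
#' form-factor oscillations of globular particles instead of fitting a
#' slope to them.
#'
#' @param curve a [SAXSCurve-class]
#' @param guinier a [GuinierResult-class] for the same curve
#' @param tailFraction fraction of the q range (from the high-q end) used
#'   for the background/Porod-constant estimate
#' @param subtractBackground estimate and subtract a flat background
#' @return a [PorodResult-class]; volume in the cube of the reciprocal q
#'   unit
#' @export
porodVolume <- function(curve, guinier, tailFraction = 0.35,
                        subtractBackground = TRUE) {
  q <- curve@q
  I <- curve@I
  rg <- guinier@rg
  i0 <- guinier@i0
  tail <- q >= q[length(q)] * (1 - tailFraction) |
    seq_along(q) > length(q) - 10L
  meanTailI <- mean(I[tail])
  B <- 0
  if (subtractBackground) {
    # joint moment solution of I = B + K q^-4 over the tail window:
    #   K + B mean(q^4)  = mean(I q^4)
    #   K mean(q^-4) + B = mean(I)
    m4 <- mean(q[tail]^4)
    mm4 <- mean(q[tail]^-4)
    det <- 1 - m4 * mm4
    Braw <- if (abs(det) > 1e-12)
      (meanTailI - mean(I[tail] * q[tail]^4) * mm4) / det else 0
    stopIfNot(!(Braw < 0 && abs(Braw) > meanTailI),
              "background estimate is negative and exceeds the tail intensity")
    # a flat background cannot exceed the smallest observed high-q intensity
    B <- min(max(Braw, 0), min(I[q >= q[length(q)] / 2]))
  }
  K <- mean((I[tail] - B) * q[tail]^4)
  if (K < 0) K <- 0
  Isub <- pmax(I - B, 0)
  # low-q: analytic Guinier piece 0..q[1]
  lowQ <- integrate(function(qq) qq^2 * i0 * exp(-qq^2 * rg^2 / 3), 0,
                    q[1])$value
  core <- trapz(q, q^2 * Isub)
  tailQ <- K / q[length(q)]  # integral of K q^-2 from qmax to infinity
  Q <- lowQ + core + tailQ
  stopIfNot(Q > 0, "non-positive Porod invariant")
  new("PorodResult", invariant = Q, volume = 2 * pi^2 * i0 / Q,
      settings = list(background = B, porodConstant = K,
                      tailFraction = tailFraction,
                      qmax = q[length(q)]))
}

# design matrix of the indirect transform: I(q) = 4*pi*sum_j w_j P_j sinc(q r_j)
prDesign <- function(q, r) {
  dr <- r[2] - r[1]
  w <- rep(dr, length(r))
  w[c(1, length(r))] <- dr / 2
  A <- outer(q, r, function(qq, rr) {
    x <- qq * rr
    s <- ifelse(x == 0, 1, sin(x) / ifelse(x == 0, 1, x))
    s
  })
  sweep(A, 2, 4 * pi * w, `*`)
}

# non-negative, smoothness-regularized LS solve by iterated clipping of an
# equality-free active set (deterministic)
prSolve <- function(A, b, wts, alpha, L) {
  AtA <- crossprod(A * wts)
  Atb <- crossprod(A * wts, b * wts)
  P <- alpha * crossprod(L)
  free <- rep(TRUE, ncol(A))
  for (it in 1:50) {
    p <- rep(0, ncol(A))
    M <- AtA[free, free, drop = FALSE] + P[free, free, drop = FALSE]
    p[free] <- solve(M + 1e-12 * mean(diag(M)) * diag(sum(free)),
                     Atb[free])
    neg <- p < -1e-10 * max(abs(p))
    if (!any(neg)) return(pmax(p, 0))
    free <- free & !neg
    if (!any(free)) return(rep(0, ncol(A)))
  }
  pmax(p, 0)
}

#' Pair-distance distribution P(r) and maximum dimension Dmax
#'
#' Estimates P(r) by a regularized indirect transform on a fixed r grid
#' with the boundary conditions P(0) = P(Dmax) = 0 and non-negativity,
#' scanning a grid of trial Dmax values. For each trial the misfit
#' (reduced chi-square against the data) and a roughness measure of the
#' solution are combined into a perceptual score; the chosen Dmax is the
#' smallest trial whose misfit is within 5 percent of the best achievable,
#' favouring compact supports. The regularization weight is picked from a
#' fixed grid by an L-curve-style heuristic (largest alpha that does not
#' degrade the misfit by more than 10 percent); everything is seedless and
#' deterministic.
#'
#' @param curve a [SAXSCurve-class]
#' @param dmaxGrid trial Dmax values; default `seq(2.2, 4.2, 0.1) * Rg`
#'   from the Guinier fit
#' @param guinier optional [GuinierResult-class] (fitted on the fly when
#'   missing; used only to build the default trial grid)
#' @param nr number of r-grid intervals
#' @return a [PrResult-class]
#' @export
prEstimate <- function(curve, dmaxGrid = NULL, guinier = NULL, nr = 60L) {
  q <- curve@q
  I <- curve@I
  stopIfNot(any(I != 0), "all-zero intensity")
  if (is.null(dmaxGrid)) {
    if (is.null(guinier)) guinier <- guinierFit(curve)
    dmaxGrid <- seq(2.2, 4.2, by = 0.1) * guinier@rg
  }
  dmaxGrid <- sort(dmaxGrid)
  dq <- max(diff(q))
  stopIfNot(dq < pi / max(dmaxGrid),
            "curve too coarsely sampled for the requested Dmax (need dq < pi/Dmax)")
  sg <- curve@sigma
  # effective uncertainties: supplied sigma (floored so that form-factor
  # minima with sigma ~ 0 cannot dominate), or 0.1% relative for
  # noise-free synthetic curves
  floorS <- 1e-6 * max(abs(I))
  wts <- ifelse(sg > 0, 1 / pmax(sg, floorS),
                1 / pmax(1e-3 * abs(I), floorS))
  alphas <- 10^seq(-8, 0, by = 1)
  fits <- lapply(dmaxGrid, function(dmax) {
    r <- seq(0, dmax, length.out = nr + 1L)
    A <- prDesign(q, r[-c(1, nr + 1L)])
    L <- diff(diag(nr - 1L), differences = 2L)
    # alpha scan: L-curve heuristic
    best <- NULL
    chis <- numeric(length(alphas))
    sols <- vector("list", length(alphas))
    for (k in seq_along(alphas)) {
      scaleA <- mean(diag(crossprod(A * wts)))
      p <- prSolve(A, I, wts, alphas[k] * scaleA, L)
      sols[[k]] <- p
      chis[k] <- mean(((I - A %*% p) * wts)^2)
    }
    kBest <- max(which(chis <= 1.1 * min(chis)))
    p <- sols[[kBest]]
    rough <- sum(diff(p, differences = 2L)^2) / max(sum(p^2), 1e-300)
    list(dmax = dmax, r = r, p = p, chi = chis[kBest],
         alpha = alphas[kBest], rough = rough,
         edge = p[length(p)] / max(max(p), 1e-300))
  })
  chiAll <- vapply(fits, `[[`, numeric(1), "chi")
  edgeAll <- vapply(fits, `[[`, numeric(1), "edge")
  # the misfit drops off a cliff at the true Dmax and then sits in a flat
  # basin; take the basin level from the upper half of the trial grid and
  # admit the smallest Dmax that reaches it without an abrupt P(r) edge
  basin <- stats::median(chiAll[seq_len(length(chiAll)) >
                                  length(chiAll) / 2])
  admissible <- which(chiAll <= 3 * basin & edgeAll <= 0.1)
  if (!length(admissible)) admissible <- which.min(chiAll)
  stopIfNot(length(admissible) > 0, "no admissible Dmax in the trial grid")
  pick <- fits[[min(admissible)]]
  pr <- c(0, pick$p, 0)
  r <- pick$r
  norm <- trapz(r, pr)
  stopIfNot(norm > 0, "degenerate P(r) solution")
  rgP <- sqrt(trapz(r, r^2 * pr) / (2 * norm))
  new("PrResult", r = r, pr = pr, dmax = pick$dmax, rg = rgP,
      i0 = 4 * pi * norm,
      score = pick$chi / min(chiAll) + pick$rough, alpha = pick$alpha)
}

#' Mass estimates from particle volumes
#'
#' Empirical volume-to-mass conversions for globular protein particles:
#' the Porod volume in nm^3 divided by 1.6 gives the mass in kDa
#' (`massFromPorod`), and an ab initio bead-model excluded volume in nm^3
#' divided by 2 gives the mass in kDa (`massFromExcludedVolume`). Values
#' are returned unrounded; printed reports conventionally round to whole
#' kDa.
#'
#' @param vp Porod volume (nm^3)
#' @param va excluded volume of a bead model (nm^3)
#' @param factor the empirical divisor
#' @return mass in kDa
#' @examples
#' massFromPorod(2368)   # 1480 kDa
#' massFromPorod(1470)   # 918.75 -> prints as 919 kDa
#' @export
massFromPorod <- function(vp, factor = 1.6) {
  stopIfNot(all(vp > 0), "volume must be positive")
  vp / factor
}

#' @rdname massFromPorod
#' @export
massFromExcludedVolume <- function(va, factor = 2) {
  stopIfNot(all(va > 0), "volume must be positive")
  va / factor
}

#' Number of subunits from an oligomer mass
#'
#' Nearest integer of MW / monomer, ties rounding away from zero.
#'
#' @param mw oligomer mass (kDa)
#' @param monomer subunit mass (kDa); 26.9 is the DNAJB6 monomer
#' @return integer subunit count
#' @examples
#' subunitCount(1480)  # 55
#' subunitCount(540)   # 20
#' @export
subunitCount <- function(mw, monomer = 26.9) {
  stopIfNot(all(mw > 0) && monomer > 0, "masses must be positive")
  as.integer(roundAway(mw / monomer))
}

#' Oligomer size estimate from volumes
#'
#' Chains the volume-to-mass rules and the subunit count into one result:
#' MWp = Vp/1.6 (kDa), optionally MWa = Va/2 (kDa), and
#' subunits = round(MWp / monomer).
#'
#' @param vp Porod volume (nm^3)
#' @param va optional excluded volume (nm^3)
#' @param monomer monomer mass (kDa)
#' @return a [SizeEstimate-class]
#' @examples
#' sizeEstimate(2368)  # 1480 kDa, 55 subunits
#' @export
sizeEstimate <- function(vp, va = NA_real_, monomer = 26.9) {
  mwP <- massFromPorod(vp)
  mwA <- if (is.na(va)) NA_real_ else massFromExcludedVolume(va)
  new("SizeEstimate", mwP = mwP, mwA = mwA, monomer = monomer,
      subunits = as.numeric(subunitCount(mwP, monomer)))
}
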