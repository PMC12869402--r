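# Geometric trajectory-bundle generators used to validate the tubularity
# metrics against planted structure.

#' Default bundle-geometry configuration
#'
#' @return list of parameters; see \code{\link{makeTrajectoryBundles}}.
#' @export
defaultBundleConfig <- function() {
  list(
    nBundles     = 2L,
    nPerBundle   = 5L,
    T            = 20L,
    D            = 3L,
    family       = "straight",   # straight | arc | loop
    arrangement  = "parallel",   # parallel | cross
    sigma        = 0.1,          # within-bundle dispersion scale
    separation   = 5,            # center spacing (parallel) / span (cross)
    length       = 10            # center-curve extent
  )
}

# Center curve of bundle k (of K) at normalized times s in [0,1]:
# a T x D matrix. First two dims carry the geometry, the rest are 0.
bundleCenter <- function(k, K, s, cfg) {
  T <- length(s); D <- cfg$D
  m <- matrix(0, T, D)
  if (cfg$family == "straight") {
    if (cfg$arrangement == "cross") {
      # lines through the origin at mid-curve, fanned over half the circle
      ang <- (k - 1) * pi / K + pi / (2 * K)
      m[, 1] <- (s - 0.5) * cfg$length * cos(ang)
      m[, 2] <- (s - 0.5) * cfg$length * sin(ang)
    } else {
      m[, 1] <- s * cfg$length
      m[, 2] <- (k - 1) * cfg$separation
    }
  } else if (cfg$family == "arc") {
    r <- cfg$length / pi + (k - 1) * cfg$separation
    m[, 1] <- r * cos(pi * s)
    m[, 2] <- r * sin(pi * s)
  } else if (cfg$family == "loop") {
    r <- cfg$length / (2 * pi) + (k - 1) * cfg$separation
    m[, 1] <- r * cos(2 * pi * s)
    m[, 2] <- r * sin(2 * pi * s)
  } else {
    stop(sprintf("config error: unknown center-curve family '%s'", cfg$family),
         call. = FALSE)
  }
  m
}

# Count intersections between two 2-D polylines by exhaustive segment
# pairs (proper crossings; shared endpoints of consecutive segments are
# not double-counted).
polylineIntersections <- function(P, Q) {
  orient <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    sign(v)
  }
  count <- 0L
  for (i in seq_len(nrow(P) - 1L)) {
    for (j in seq_len(nrow(Q) - 1L)) {
      a <- P[i, ]; b <- P[i + 1L, ]; c <- Q[j, ]; d <- Q[j + 1L, ]
      o1 <- orient(a, b, c); o2 <- orient(a, b, d)
      o3 <- orient(c, d, a); o4 <- orient(c, d, b)
      if (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
        count <- count + 1L
    }
  }
  count
}

#' Generate labeled trajectory bundles with planted geometry
#'
#' Each bundle is a center curve (straight line, arc, or closed loop)
#' plus a smooth per-trajectory offset: a random affine curve
#' \code{a + b s} with \code{a, b ~ N(0, sigma^2)} per dimension, so the
#' mean distance of trajectory points to the bundle center scales
#' linearly with \code{sigma}, and \code{sigma = 0} collapses every
#' trajectory onto its center. The \code{cross} arrangement fans straight
#' center lines through a common midpoint, planting one center-curve
#' intersection per bundle pair. Planted crossings are counted on the
#' center curves (projected to the first two dimensions) by exhaustive
#' segment intersection and scaled by trajectories-per-bundle squared,
#' i.e. the number of cross-bundle trajectory-pair crossing events the
#' construction implies.
#'
#' @param geomConfig list of parameters merged over
#'   \code{\link{defaultBundleConfig}}.
#' @param seed integer.
#' @return list with \code{trajectories} (a \linkS4class{TrajectorySet},
#'   one class per bundle) and \code{plantedCrossings} (integer).
#' @export
makeTrajectoryBundles <- function(geomConfig = list(), seed = 1L) {
  cfg <- modifyList(defaultBundleConfig(), geomConfig)
  if (cfg$sigma < 0)
    stop("config error: sigma must be nonnegative", call. = FALSE)
  stopIfNot(cfg$nBundles >= 1 && cfg$nPerBundle >= 1 && cfg$T >= 2 &&
              cfg$D >= 2, "config error: need >=1 bundle, >=1 trajectory, T >= 2, D >= 2")
  K <- cfg$nBundles; n <- cfg$nPerBundle; T <- cfg$T; D <- cfg$D
  s <- seq(0, 1, length.out = T)
  centers <- lapply(seq_len(K), function(k) bundleCenter(k, K, s, cfg))

  tr <- array(0, dim = c(K * n, T, D))
  withSeed(seed, {
    idx <- 0L
    for (k in seq_len(K)) {
      for (j in seq_len(n)) {
        idx <- idx + 1L
        a <- rnorm(D, 0, cfg$sigma)
        b <- rnorm(D, 0, cfg$sigma)
        off <- outer(rep(1, T), a) + outer(s, b)
        tr[idx, , ] <- centers[[k]] + off
      }
    }
  })

  planted <- 0L
  if (K >= 2L) {
    for (k in seq_len(K - 1L)) {
      for (l in (k + 1L):K) {
        planted <- planted +
          polylineIntersections(centers[[k]][, 1:2, drop = FALSE],
                                centers[[l]][, 1:2, drop = FALSE])
      }
    }
  }
  labels <- data.frame(
    base_class = rep(sprintf("bundle%02d", seq_len(K)), each = n),
    stringsAsFactors = FALSE
  )
  ts <- new("TrajectorySet", trajectories = tr, labels = labels,
            timeAxis = s, projection = list())
  list(trajectories = ts, plantedCrossings = planted * n * n)
}

#' Simulate trajectories from a discrete linear dynamical system
#'
#' Iterates \code{x(t+1) = A x(t) + noise} from isotropic Gaussian
#' initial states; a validation source for dynamical similarity analysis.
#'
#' @param A square D x D transition matrix.
#' @param nTraj number of trajectories.
#' @param T number of time steps (including the initial state).
#' @param noiseSd standard deviation of isotropic process noise.
#' @param seed integer.
#' @param label class label stored on every trajectory.
#' @return a \linkS4class{TrajectorySet}; the spectral radius of \code{A}
#'   is reported in \code{projection(x)$spectralRadius}.
#' @export
simulateLinearDynamics <- function(A, nTraj, T, noiseSd = 0, seed = 1L,
                                   label = "dyn") {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A))
    stop("shape error: A must be square", call. = FALSE)
  stopIfNot(T >= 2, "T must be at least 2")
  stopIfNot(noiseSd >= 0, "config error: noiseSd must be nonnegative")
  D <- nrow(A)
  tr <- array(0, dim = c(nTraj, T, D))
  withSeed(seed, {
    for (i in seq_len(nTraj)) {
      x <- rnorm(D)
      tr[i, 1, ] <- x
      for (t in 2:T) {
        x <- as.vector(A %*% x)
        if (noiseSd > 0) x <- x + rnorm(D, 0, noiseSd)
        tr[i, t, ] <- x
      }
    }
  })
  rho <- max(Mod(eigen(A, only.values = TRUE)$values))
  new("TrajectorySet", trajectories = tr,
      labels = data.frame(base_class = rep(label, nTraj),
                          stringsAsFactors = FALSE),
      timeAxis = seq_len(T) - 1,
      projection = list(spectralRadius = rho))
}
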