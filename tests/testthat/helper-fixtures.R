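# Shared test helpers: small geometric toys and cached fixtures.

# role-index lookup for a built conformer
rix <- function(conf) stats::setNames(seq_len(nrow(conf$atoms)),
                                      conf$atoms$role)

# a rigid rotation + translation applied to all coordinates
rigid_motion <- function(conf, seed = 1) {
  set.seed(seed)
  ang <- stats::runif(3, -pi, pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  Rz <- rbind(c(cos(ang[2]), -sin(ang[2]), 0),
              c(sin(ang[2]), cos(ang[2]), 0), c(0, 0, 1))
  tr <- stats::runif(3, -5, 5)
  xyz <- as.matrix(conf$atoms[, c("x", "y", "z")]) %*% t(Rx %*% Rz)
  conf$atoms$x <- xyz[, 1] + tr[1]
  conf$atoms$y <- xyz[, 2] + tr[2]
  conf$atoms$z <- xyz[, 3] + tr[3]
  conf
}

beta_spec <- function(...) build_spec("Sem", phi1 = -60, psi1 = -30,
                                      phi2 = -90, psi2 = 0, chi1 = 65,
                                      chi2 = -91, chi3 = 180,
                                      chi1_phe = 40, chi2_phe = 70, ...)

extended_spec <- function(...) build_spec("Sem", phi1 = -160, psi1 = 160,
                                          phi2 = -160, psi2 = 160,
                                          chi1 = 180, chi2 = 60,
                                          chi3 = 180, chi1_phe = 170,
                                          chi2_phe = 90, ...)

# brute-force minimal-cost pairing oracle: enumerates every injective
# monotone-free assignment of the shorter band list into the longer one
brute_force_pairing <- function(ex, th) {
  if (length(ex) > length(th)) {
    res <- brute_force_pairing(th, ex)
    return(list(cost = res$cost,
                pairs = res$pairs[, 2:1, drop = FALSE]))
  }
  m <- length(ex); n <- length(th)
  best <- list(cost = Inf, pairs = NULL)
  idx <- utils::combn(n, m)
  for (k in seq_len(ncol(idx))) {
    for (perm in asplit(perms(idx[, k]), 1)) {
      cost <- sum((ex - th[perm])^2)
      if (cost < best$cost)
        best <- list(cost = cost, pairs = cbind(seq_len(m), perm))
    }
  }
  best
}

perms <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], perms(v[-i])))
  out
}

DELTA <- "\u03b4"
PI_S <- "\u03c0"
lbl <- function(...) paste0(...)
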