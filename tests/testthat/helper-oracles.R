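# Naive, loop-based reference implementations. Deliberately written in the
# most literal style possible (explicit double loops, scalar arithmetic) so
# they stay independent of the vectorised / compiled code paths they check.

oracle_modified_distance <- function(cc) {
  cc <- min(max(cc, -1 + 1e-6), 1)
  if (cc == 0) return(1)
  s <- sqrt(abs(cc))
  (s - cc) / (s + cc)
}

oracle_hyperbolic_distance <- function(cc) {
  cc <- min(max(cc, -1 + 1e-6), 1)
  (1 - cc) / (1 + cc)
}

# one full FCM update cycle (centroids -> distances -> memberships), loops only
oracle_fcm_cycle <- function(X, U, m) {
  n <- nrow(X); c <- ncol(U); p <- ncol(X)
  V <- matrix(0, c, p)
  for (j in 1:c) {
    w <- U[, j]^m
    for (t in 1:p) V[j, t] <- sum(w * X[, t]) / sum(w)
  }
  D <- matrix(0, n, c)
  for (i in 1:n) for (j in 1:c)
    D[i, j] <- oracle_modified_distance(cor(X[i, ], V[j, ]))
  U2 <- matrix(0, n, c)
  for (i in 1:n) for (j in 1:c)
    U2[i, j] <- 1 / sum((D[i, j] / D[i, ])^(2 / (m - 1)))
  J <- 0
  for (i in 1:n) for (j in 1:c) J <- J + U2[i, j]^m * D[i, j]^2
  list(V = V, D = D, U = U2, J = J)
}

# every compactness/separation measure from raw U, D, V, X, loops only
oracle_measures <- function(U, D, V, X, m) {
  n <- nrow(U); c <- ncol(U)
  n1 <- nm <- s1 <- sm <- numeric(c)
  for (j in 1:c) {
    n1[j] <- sum(U[, j])
    nm[j] <- sum(U[, j]^m)
    s1[j] <- sum(U[, j] * D[, j]^2)
    sm[j] <- sum(U[, j]^m * D[, j]^2)
  }
  piM1 <- sum(sm / n1)
  piMM <- sum(sm / nm)
  mx <- apply(U, 1, max)
  FC <- sum(mx^2) / sum(mx)
  gm <- mean(X)   # scalar grand mean over all voxels and time points
  d2 <- numeric(c)
  for (j in 1:c) d2[j] <- sum((V[j, ] - gm)^2)
  Km <- sum(nm * d2); K1 <- sum(n1 * d2); S <- mean(d2)
  pd <- matrix(0, c, c)
  for (j in 1:c) for (k in 1:c) pd[j, k] <- sqrt(sum((V[j, ] - V[k, ])^2))
  SS <- sum(1 / rowSums(pd))
  FS <- 0
  for (j in 1:(c - 1)) for (k in (j + 1):c) {
    mn <- pmin(U[, j], U[, k])
    FS <- FS + sum(mn^2) / sum(mn)
  }
  offdiag <- pd; diag(offdiag) <- Inf
  Vdmin <- min(offdiag); Vdmax <- max(pd)
  Vdminj <- apply(offdiag, 1, min)
  IDintra <- max(sapply(1:c, function(j)
    (n - n1[j]) / n1[j] * s1[j] / sum(s1[-j])))
  IDinter <- min(sapply(1:c, function(j) min(s1[-j]) / s1[j]))
  list(n1 = n1, nm = nm, s1 = s1, sm = sm, piM1 = piM1, piMM = piMM,
       FC = FC, Km = Km, K1 = K1, FS = FS, S = S, SS = SS, FO = FS / FC,
       Vdmin = Vdmin, Vdmax = Vdmax, Vdminj = Vdminj,
       IDintra = IDintra, IDinter = IDinter, J1 = sum(s1), Jm = sum(sm))
}

# the eight indices from an oracle measure list (alphas supplied)
oracle_indices <- function(om, X, c, m, n, alphas) {
  sigmaX <- apply(X, 2, var)
  pi11 <- sum(om$s1 / om$n1)
  list(
    cv_rlr = sum(om$s1) / (c * sqrt(sum(sigmaX^2))) +
      (1 / alphas[["cv_rlr"]]) * om$Vdmax * om$SS / om$Vdmin,
    cv_zle = alphas[["cv_zle"]] * om$S / om$piM1 - om$FS / om$FC,
    cv_gv = om$K1 / (c^2 * om$J1),
    cv_kp = pi11 / c + (1 / alphas[["cv_kp"]]) * c / om$Vdmin,
    cv_pbm = (n / c) * om$Vdmax / om$Jm,
    cv_wy = sum(om$n1 / max(om$n1) - exp(-om$Vdminj^2 / om$S)),
    cv_bws = om$Km / om$piMM,
    cv_new = om$Km * (om$IDinter / om$IDintra) * (om$FC / om$J1))
}

# breadth-first flood fill, one queue, for connected-component checking
oracle_components <- function(vol, connectivity) {
  dims <- dim(vol)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  nn <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[nn > 0 & nn <= switch(as.character(connectivity),
                                     "6" = 1, "18" = 2, "26" = 3), ]
  comp <- array(0L, dims)
  nextId <- 0L
  for (start in which(vol != 0)) {
    if (comp[start] != 0) next
    nextId <- nextId + 1L
    lab <- vol[start]
    queue <- start
    comp[start] <- nextId
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      pos <- arrayInd(cur, dims)
      for (r in seq_len(nrow(offs))) {
        nb <- pos + as.integer(offs[r, ])
        if (any(nb < 1) || any(nb > dims)) next
        idx <- nb[1] + dims[1] * (nb[2] - 1 + dims[2] * (nb[3] - 1))
        if (vol[idx] == lab && comp[idx] == 0) {
          comp[idx] <- nextId
          queue <- c(queue, idx)
        }
      }
    }
  }
  comp
}

# region-size multiset per cluster label from an oracle component map
oracle_region_sizes <- function(vol, connectivity) {
  comp <- oracle_components(vol, connectivity)
  inside <- comp > 0
  if (!any(inside)) return(list())
  split(tapply(comp[inside], comp[inside], length),
        tapply(vol[inside], comp[inside], function(x) x[1]))
}

# a small, cleanly separable fixture: two antiphase sinusoid blocks + jitter
separable_fixture <- function(n = 40, p = 30, seed = 99, jitter = 0.05) {
  set.seed(seed)
  tt <- seq(0, 4 * pi, length.out = p)
  X <- rbind(matrix(rep(sin(tt), n / 2), ncol = p, byrow = TRUE),
             matrix(rep(-sin(tt), n / 2), ncol = p, byrow = TRUE))
  X + matrix(rnorm(n * p, sd = jitter), n, p)
}
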