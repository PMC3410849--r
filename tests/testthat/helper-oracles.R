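# Independent oracles used to cross-check the implementation. These are
# deliberately naive re-derivations (brute force / closed form / alternative
# algorithm) and share no code with the package internals they test.

# brute-force residue-by-residue minimal distance matrix in pure R
oracle_res_min_dist <- function(chainA, chainB) {
  nA <- nchar(chainA$seqres)
  nB <- nchar(chainB$seqres)
  out <- matrix(Inf, nA, nB)
  xa <- as.matrix(chainA$atoms[, c("x", "y", "z")])
  xb <- as.matrix(chainB$atoms[, c("x", "y", "z")])
  ra <- chainA$atoms$res_idx
  rb <- chainB$atoms$res_idx
  for (i in seq_len(nrow(xa))) {
    d <- sqrt(colSums((t(xb) - xa[i, ])^2))
    for (j in seq_len(nrow(xb))) {
      if (d[j] < out[ra[i], rb[j]]) out[ra[i], rb[j]] <- d[j]
    }
  }
  out
}

# full two-rule interface annotation re-derived literally from the residue
# distance matrix and per-residue dASA values
oracle_annotation_pairs <- function(dimer, cutoff = 6, use_dasa = TRUE,
                                    dasa = NULL) {
  dm <- oracle_res_min_dist(dimer$chainX, dimer$chainY)
  pairs <- which(dm < cutoff, arr.ind = TRUE)
  out <- data.frame(posX = pairs[, 1], posY = pairs[, 2])
  if (use_dasa) {
    dX <- rep(0, nrow(dm)); dY <- rep(0, ncol(dm))
    dX[as.integer(names(dasa$X))] <- dasa$X
    dY[as.integer(names(dasa$Y))] <- dasa$Y
    add <- function(transposed) {
      m <- if (transposed) t(dm) else dm
      dA <- if (transposed) dY else dX
      dB <- if (transposed) dX else dY
      res <- NULL
      for (rx in which(dA > 0)) {
        if (min(m[rx, ]) < cutoff) next        # has a partner within cutoff
        cand <- which(dB > 0)
        if (length(cand) == 0) next
        ry <- cand[which.min(m[rx, cand])]
        if (!is.finite(m[rx, ry])) next
        res <- rbind(res, if (transposed) c(ry, rx) else c(rx, ry))
      }
      res
    }
    extra <- rbind(add(FALSE), add(TRUE))
    if (!is.null(extra))
      out <- unique(rbind(out, data.frame(posX = extra[, 1],
                                          posY = extra[, 2])))
  }
  out <- out[order(out$posX, out$posY), ]
  rownames(out) <- NULL
  out
}

# quaternion (Horn) superposition: minimized RMSD from the largest
# eigenvalue of the 4x4 key matrix; no SVD involved
oracle_quaternion_rmsd <- function(A, B) {
  n <- nrow(A)
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  S <- t(Bc) %*% Ac
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Ac^2) + sum(Bc^2) - 2 * lam) / n
  sqrt(max(0, msd))
}

# random rigid transform (proper rotation + translation)
random_rigid <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x),
                1 - 2 * (x^2 + y^2)), 3, 3)
  list(R = R, t = rnorm(3, sd = 20))
}

apply_rigid_chain <- function(chain, rigid) {
  xyz <- as.matrix(chain$atoms[, c("x", "y", "z")]) %*% t(rigid$R)
  a <- chain$atoms
  a$x <- xyz[, 1] + rigid$t[1]
  a$y <- xyz[, 2] + rigid$t[2]
  a$z <- xyz[, 3] + rigid$t[3]
  new_chain(chain$chain_id, chain$seqres, a, author_ids = chain$author_ids)
}

apply_rigid_dimer <- function(dimer, rigid) {
  dimer$chainX <- apply_rigid_chain(dimer$chainX, rigid)
  dimer$chainY <- apply_rigid_chain(dimer$chainY, rigid)
  dimer
}
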