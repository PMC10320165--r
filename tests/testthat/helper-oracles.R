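# Independent brute-force oracles used to cross-check the package's
# vectorised implementations. Deliberately naive: explicit loops, no code
# shared with the implementation path.

# pTM by direct double-loop summation over allowed pairs
oracle_ptm <- function(pae, mask = NULL) {
  n <- nrow(pae)
  if (is.null(mask)) mask <- matrix(TRUE, n, n)
  part <- logical(n)
  for (i in 1:n) for (j in 1:n) if (mask[i, j]) part[i] <- part[j] <- TRUE
  nres <- sum(part)
  d0 <- if (nres > 26) 1.24 * (nres - 15)^(1 / 3) - 1.8 else 1.0
  best <- -Inf
  for (i in 1:n) {
    tot <- 0; cnt <- 0
    for (j in 1:n) {
      if (mask[i, j]) {
        tot <- tot + 1 / (1 + (pae[i, j] / d0)^2)
        cnt <- cnt + 1
      }
    }
    if (cnt > 0 && tot / cnt > best) best <- tot / cnt
  }
  best
}

# minimum heavy-atom distance between every cross-partner residue pair,
# by an explicit residue-pair scan
oracle_min_residue_dist <- function(model, receptor_chains, ligand_chains) {
  at <- model$atoms
  rec <- at[at$chain %in% receptor_chains, ]
  lig <- at[at$chain %in% ligand_chains, ]
  rres <- unique(paste(rec$chain, rec$resno))
  lres <- unique(paste(lig$chain, lig$resno))
  out <- matrix(Inf, length(rres), length(lres),
                dimnames = list(rres, lres))
  rblocks <- lapply(rres, function(k)
    as.matrix(rec[paste(rec$chain, rec$resno) == k, c("x", "y", "z")]))
  lblocks <- lapply(lres, function(k)
    as.matrix(lig[paste(lig$chain, lig$resno) == k, c("x", "y", "z")]))
  for (ri in seq_along(rres)) {
    ra <- rblocks[[ri]]; na <- nrow(ra)
    for (li in seq_along(lres)) {
      la <- lblocks[[li]]
      d <- as.matrix(stats::dist(rbind(ra, la)))
      out[ri, li] <- min(d[seq_len(na), na + seq_len(nrow(la))])
    }
  }
  out
}

oracle_fnat <- function(native, model, receptor_chains, ligand_chains,
                        cutoff = 5) {
  dn <- oracle_min_residue_dist(native, receptor_chains, ligand_chains)
  dm <- oracle_min_residue_dist(model, receptor_chains, ligand_chains)
  nat <- which(dn <= cutoff, arr.ind = TRUE)
  stopifnot(nrow(nat) > 0)
  kept <- 0
  for (k in seq_len(nrow(nat)))
    if (dm[nat[k, 1], nat[k, 2]] <= cutoff) kept <- kept + 1
  kept / nrow(nat)
}

# optimal-superposition RMSD by Horn's quaternion eigenvalue method --
# a closed form independent of the SVD/Kabsch implementation path
oracle_fit_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  M <- t(bc) %*% ac
  K <- matrix(c(
    M[1,1]+M[2,2]+M[3,3], M[2,3]-M[3,2],        M[3,1]-M[1,3],        M[1,2]-M[2,1],
    M[2,3]-M[3,2],        M[1,1]-M[2,2]-M[3,3], M[1,2]+M[2,1],        M[3,1]+M[1,3],
    M[3,1]-M[1,3],        M[1,2]+M[2,1],       -M[1,1]+M[2,2]-M[3,3], M[2,3]+M[3,2],
    M[1,2]-M[2,1],        M[3,1]+M[1,3],        M[2,3]+M[3,2],       -M[1,1]-M[2,2]+M[3,3]),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(ac^2) + sum(bc^2) - 2 * lambda) / nrow(a)
  sqrt(max(msd, 0))
}

# brute-force rotation search: many random proper rotations followed by
# local refinement over Euler angles
oracle_rotation_search_rmsd <- function(a, b, n_starts = 200, seed = 99) {
  a <- as.matrix(a); b <- as.matrix(b)
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  rot_euler <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  }
  obj <- function(ang) {
    R <- rot_euler(ang)
    sqrt(mean(rowSums((bc %*% t(R) - ac)^2)))
  }
  set.seed(seed)
  best <- Inf
  for (s in seq_len(n_starts)) {
    ang0 <- stats::runif(3, -pi, pi)
    fit <- stats::optim(ang0, obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-12))
    if (fit$value < best) best <- fit$value
  }
  best
}

# reference complexes for docking-metric oracle comparisons
oracle_lrmsd <- function(native, model, receptor_chains, ligand_chains) {
  bb <- c("N", "CA", "C", "O")
  sel <- function(m, chains) {
    at <- m$atoms
    at <- at[at$chain %in% chains & at$elety %in% bb, ]
    at[order(at$chain, at$resno, match(at$elety, bb)), ]
  }
  rn <- sel(native, receptor_chains); rm_ <- sel(model, receptor_chains)
  stopifnot(identical(paste(rn$chain, rn$resno, rn$elety),
                      paste(rm_$chain, rm_$resno, rm_$elety)))
  # fit receptor by Horn's quaternion method, rotation from the principal
  # eigenvector (independent of the SVD/Kabsch implementation path)
  a <- as.matrix(rn[, c("x", "y", "z")]); b <- as.matrix(rm_[, c("x", "y", "z")])
  ca <- colMeans(a); cb <- colMeans(b)
  M <- t(sweep(b, 2, cb)) %*% sweep(a, 2, ca)
  K <- matrix(c(
    M[1,1]+M[2,2]+M[3,3], M[2,3]-M[3,2],        M[3,1]-M[1,3],        M[1,2]-M[2,1],
    M[2,3]-M[3,2],        M[1,1]-M[2,2]-M[3,3], M[1,2]+M[2,1],        M[3,1]+M[1,3],
    M[3,1]-M[1,3],        M[1,2]+M[2,1],       -M[1,1]+M[2,2]-M[3,3], M[2,3]+M[3,2],
    M[1,2]-M[2,1],        M[3,1]+M[1,3],        M[2,3]+M[3,2],       -M[1,1]-M[2,2]+M[3,3]),
    4, 4, byrow = TRUE)
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2+x^2-y^2-z^2, 2*(x*y - w*z),   2*(x*z + w*y),
    2*(x*y + w*z),   w^2-x^2+y^2-z^2, 2*(y*z - w*x),
    2*(x*z - w*y),   2*(y*z + w*x),   w^2-x^2-y^2+z^2), 3, byrow = TRUE)
  ln <- sel(native, ligand_chains); lm <- sel(model, ligand_chains)
  la <- as.matrix(ln[, c("x", "y", "z")]); lb <- as.matrix(lm[, c("x", "y", "z")])
  lb <- sweep(sweep(lb, 2, cb) %*% t(R), 2, ca, `+`)
  sqrt(mean(rowSums((la - lb)^2)))
}
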