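# shared fixtures, built in code; cached per test session
kB <- 0.001987204259

default_sys <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- make_pocket_system(default_system_config(), seed = 1)
    val
  }
})

default_pair <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- make_ligand_pair(default_system_config(), seed = 1)
    val
  }
})

# brute-force double-loop oracle for the energy decomposition; written
# independently of the vectorized implementation
oracle_energy <- function(system, coords) {
  rec <- system$receptor
  lig <- system$ligand
  ele <- vdw <- 0
  per_ele <- per_hyd <- numeric(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    for (j in seq_len(nrow(lig))) {
      dx <- coords[j, ] - c(rec$x[i], rec$y[i], rec$z[i])
      r <- sqrt(sum(dx^2))
      if (r >= 9.0) next
      s <- if (r <= 7.5) 1 else {
        u <- (r - 7.5) / 1.5
        1 - u^2 * (3 - 2 * u)
      }
      e <- 332.0636 * rec$charge[i] * lig$charge[j] / r * s
      sg <- (rec$sigma[i] + lig$sigma[j]) / 2
      ep <- sqrt(rec$epsilon[i] * lig$epsilon[j])
      v <- 4 * ep * ((sg / r)^12 - (sg / r)^6) * s
      ele <- ele + e
      vdw <- vdw + v
      per_ele[i] <- per_ele[i] + e
      if (rec$type[i] == "hydrophobic" && lig$type[j] == "hydrophobic" &&
            r < 6.0) {
        w <- if (r <= 4.5) 1 else {
          u <- (r - 4.5) / 1.5
          1 - u^2 * (3 - 2 * u)
        }
        per_hyd[i] <- per_hyd[i] + w
      }
    }
  }
  list(ele = ele, vdw = vdw, hyd = sum(per_hyd),
       per_ele = per_ele, per_hyd = per_hyd)
}

# brute-force interaction-fingerprint oracle
oracle_ifp <- function(system, coords) {
  rec <- system$receptor
  lig <- system$ligand
  cut <- c(hydrophobic = 4.5, hbond = 3.5, ionic = 4.0, aromatic = 4.5)
  channels <- c("hydrophobic", "hbond_don", "hbond_acc", "ionic", "aromatic")
  bits <- matrix(0L, nrow(rec), 5)
  for (i in seq_len(nrow(rec))) {
    for (j in seq_len(nrow(lig))) {
      r <- sqrt(sum((coords[j, ] - c(rec$x[i], rec$y[i], rec$z[i]))^2))
      ti <- rec$type[i]; tj <- lig$type[j]
      if (ti == "hydrophobic" && tj == "hydrophobic" && r <= cut["hydrophobic"])
        bits[i, 1] <- 1L
      if (ti == "hbond_donor" && tj == "hbond_acceptor" && r <= cut["hbond"])
        bits[i, 2] <- 1L
      if (ti == "hbond_acceptor" && tj == "hbond_donor" && r <= cut["hbond"])
        bits[i, 3] <- 1L
      if (((ti == "cation" && tj == "anion") ||
             (ti == "anion" && tj == "cation")) && r <= cut["ionic"])
        bits[i, 4] <- 1L
      if (ti == "aromatic" && tj == "aromatic" && r <= cut["aromatic"])
        bits[i, 5] <- 1L
    }
  }
  v <- as.integer(bits)
  names(v) <- as.vector(outer(rec$label, channels, paste, sep = ":"))
  v
}

# random ligand placements spanning bound, rim and unbound regions
random_configs <- function(system, n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    shift <- rnorm(3, 0, 4)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, 0, 2 * pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    Rm <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    com <- colMeans(system$native_pose)
    sweep(sweep(system$native_pose, 2, com) %*% t(Rm), 2, com + shift, "+")
  })
}
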