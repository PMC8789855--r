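# Shared fixtures and independent oracles, all built in code at test time.

random_frame <- function(n = 50, seed = 1, box = NULL) {
  set.seed(seed)
  elements <- c("C", "N", "O", "S", "P", "K")
  atoms <- data.frame(
    serial = seq_len(n),
    name = sprintf("A%d", seq_len(n)),
    resname = sample(c("ALA", "LEU", "HOH"), n, replace = TRUE),
    resid = sample(1:20, n, replace = TRUE),
    chain = sample(LETTERS[1:4], n, replace = TRUE),
    element = sample(elements, n, replace = TRUE),
    x = runif(n, -10, 10), y = runif(n, -10, 10), z = runif(n, -10, 10),
    stringsAsFactors = FALSE
  )
  new_frame(atoms, box = box)
}

# four-subunit collar frame with midpoints at given radii (azimuths 0, 90,
# 180, 270 degrees), Cd1/Cd2 straddling each midpoint tangentially
collar_frame <- function(radii = rep(2.5, 4), z = 0, half_sep = 0.8) {
  phi <- (0:3) * pi / 2
  rows <- list()
  for (s in 1:4) {
    mid <- c(radii[s] * cos(phi[s]), radii[s] * sin(phi[s]), z)
    tang <- c(-sin(phi[s]), cos(phi[s]), 0)
    for (j in 1:2) {
      p <- mid + (if (j == 1) half_sep else -half_sep) * tang
      rows[[length(rows) + 1]] <- data.frame(
        serial = 2 * (s - 1) + j,
        name = c("CD1", "CD2")[j], resname = "LEU", resid = 124L,
        chain = LETTERS[s], element = "C",
        x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
    }
  }
  new_frame(do.call(rbind, rows))
}

# independent quaternion-method (Horn) superposition oracle
quaternion_rmsd <- function(P, Q) {
  # P, Q: n x 3 matched coordinates; returns least-squares rmsd of Q onto P
  cp <- colMeans(P); cq <- colMeans(Q)
  X <- sweep(Q, 2, cq); Y <- sweep(P, 2, cp)
  S <- t(X) %*% Y
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
  lam <- max(eigen(N, symmetric = TRUE)$values)
  e2 <- (sum(X^2) + sum(Y^2) - 2 * lam) / nrow(P)
  sqrt(max(e2, 0))
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

transform_frame <- function(frame, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(frame$atoms[, c("x", "y", "z")]) %*% t(R)
  frame$atoms$x <- xyz[, 1] + t[1]
  frame$atoms$y <- xyz[, 2] + t[2]
  frame$atoms$z <- xyz[, 3] + t[3]
  frame
}

# brute-force O(N^2) minimum tail-collar distances
brute_engaged <- function(frame, tail_atoms, collar_idx, cutoff, box = NULL) {
  xyz <- as.matrix(frame$atoms[, c("x", "y", "z")])
  mi <- function(d, L) if (is.null(L)) d else d - L * round(d / L)
  vapply(tail_atoms, function(ta) {
    dmin <- Inf
    for (i in ta) for (j in collar_idx) {
      dx <- mi(xyz[i, 1] - xyz[j, 1], box[1])
      dy <- mi(xyz[i, 2] - xyz[j, 2], box[2])
      dz <- mi(xyz[i, 3] - xyz[j, 3], box[3])
      dmin <- min(dmin, sqrt(dx^2 + dy^2 + dz^2))
    }
    dmin <= cutoff
  }, logical(1))
}

# state-machine replay oracle for plane crossings (explicit transcription)
replay_crossings <- function(z, plane, h) {
  events <- 0L
  dirs <- character(0)
  state <- "none"
  for (v in z) {
    pos <- if (v < plane - h) "below" else if (v > plane + h) "above" else "band"
    if (pos == "band") next
    if (state != "none" && pos != state) {
      events <- events + 1L
      dirs <- c(dirs, if (pos == "above") "+z" else "-z")
    }
    state <- pos
  }
  list(n = events, dirs = dirs)
}

shoelace <- function(pts) {
  # pts: k x 2 ordered polygon vertices
  n <- nrow(pts)
  j <- c(2:n, 1)
  abs(sum(pts[, 1] * pts[j, 2] - pts[j, 1] * pts[, 2])) / 2
}
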