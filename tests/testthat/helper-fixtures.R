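# Shared fixtures: small deterministic scenes and brute-force metric oracles
# written independently of the implementation paths they check.

smallScene <- function(seed = 1, size = 48L) {
  generateScene(sceneParams(imageSize = c(size, size),
                            bodyRadiusRange = c(6, 15), seed = seed))
}

# brute-force mean SSIM: explicit double loop over windows
bruteSSIM <- function(x, y, k = 7L, dataRange = 1) {
  N <- k * k
  cn <- N / (N - 1)
  c1 <- (0.01 * dataRange)^2
  c2 <- (0.03 * dataRange)^2
  vals <- c()
  for (i in 1:(nrow(x) - k + 1)) {
    for (j in 1:(ncol(x) - k + 1)) {
      wx <- as.vector(x[i:(i + k - 1), j:(j + k - 1)])
      wy <- as.vector(y[i:(i + k - 1), j:(j + k - 1)])
      ux <- mean(wx); uy <- mean(wy)
      vx <- cn * (mean(wx^2) - ux^2)
      vy <- cn * (mean(wy^2) - uy^2)
      vxy <- cn * (mean(wx * wy) - ux * uy)
      vals <- c(vals, ((2 * ux * uy + c1) * (2 * vxy + c2)) /
                  ((ux^2 + uy^2 + c1) * (vx + vy + c2)))
    }
  }
  mean(vals)
}

# brute-force MSE via explicit double loop
bruteMSE <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) s <- s + (a[i, j] - b[i, j])^2
  s / (nrow(a) * ncol(a))
}

# textbook Pearson correlation
brutePearson <- function(a, b) {
  x <- as.vector(a); y <- as.vector(b)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
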