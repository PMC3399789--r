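# shared fixture builders (everything generated in code at test time)

paperBValues <- function() c(0, 50, 100, 150, 200, 250, 300, 500, 750, 1000)

# compact phantom on a coarse grid: fast, all regions above the 10-voxel floor
smallGeometry <- function(spacing = c(1, 1, 2.2), radii = c(8, 8, 8),
                          rim = 2, shape = c(48, 48, 14)) {
  makeGeometry(shape = shape, spacing = spacing,
               tumorRadii = radii, rimThickness = rim)
}

smallTruth <- function(masks, noiseSigma = 0, seed = 1L)
  makePhantomTruth(masks, noiseSigma = noiseSigma, seed = seed)

smallMeta <- function() acquisitionMeta(inPlaneSpacing = c(1, 1))

# DCE/DSC frame-midpoint grids of the emulated protocol
dceTimes <- function() (seq_len(80) - 0.5) * 3.7
dscTimes <- function() (seq_len(80) - 0.5) * 2

# brute-force Kruskal-Wallis H with mid-ranks and tie correction: the
# independent oracle against the kruskal.test-backed implementation
bruteForceH <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (N + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr == 0) 0 else H / corr
}

# cohort profiles with every effect factor forced to 1 (pure null)
nullProfiles <- function(cv = 0.15) {
  prof <- defaultGroupProfiles(cv = cv)
  for (g in names(prof)) prof[[g]]$factors[, -1] <- 1
  prof
}
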