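# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-seed derivation: a master seed plus string tags map to
# an integer < 2^31 so every stage/subject gets an independent, reproducible
# RNG stream. Plain modular hash; products stay below 2^53 so the double
# arithmetic is exact.
deriveSeed <- function(master, ...) {
  tags <- paste(c(...), collapse = "/")
  h <- as.numeric(master) %% 2147483647
  if (nzchar(tags)) {
    for (code in utf8ToInt(tags)) {
      h <- (h * 31 + code) %% 2147483647
    }
  }
  as.integer(h %% 2147483629 + 1)
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Rician corruption of a magnitude image: Gaussian noise of scale sigma on
# two quadrature channels, magnitude taken afterwards.
riceCorrupt <- function(a, sigma) {
  if (sigma < 0) stop("noise sigma must be >= 0")
  if (sigma == 0) return(a)
  n <- length(a)
  sqrt((a + stats::rnorm(n, sd = sigma))^2 + stats::rnorm(n, sd = sigma)^2)
}

stopifnotFinite <- function(x, what) {
  if (any(!is.finite(x)))
    stop(sprintf("%s must be finite (found NA/NaN/Inf)", what))
  invisible(x)
}

# series/mask pairing check used everywhere a mask is consumed
checkGridMatch <- function(series, masks) {
  ds <- dim(seriesData(series))[1:3]
  dm <- dim(maskLabels(masks))
  if (!identical(as.integer(ds), as.integer(dm)))
    stop(sprintf(
      "mask grid (%s) does not match the series spatial grid (%s); no silent resampling",
      paste(dm, collapse = "x"), paste(ds, collapse = "x")))
  invisible(TRUE)
}

# uniform frame-midpoint time grid, seconds
frameTimes <- function(nFrames, frameDuration) {
  (seq_len(nFrames) - 0.5) * frameDuration
}
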