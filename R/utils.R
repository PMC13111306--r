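#' Derive a child seed from a run seed and a stage label
#'
#' Every random operation in the package draws its seed deterministically
#' from a single run seed plus a short label naming the stage, so that whole
#' pipelines are reproducible from one integer while stages stay decoupled.
#'
#' @param seed integer run seed.
#' @param label character stage label.
#' @return an integer seed in [1, 2^31 - 2].
#' @export
deriveSeed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 31 + ch) %% m
  s <- ((abs(seed) %% m) * 48271 + h) %% m
  as.integer(max(1, s))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards (no hidden global randomness).
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clampProb <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

logit <- function(p) log(p / (1 - p))

`%||%` <- function(a, b) if (is.null(a)) b else a

num1 <- function(x) is.numeric(x) && length(x) == 1L

# scan-level measurement columns, in canonical order
scanParamCols <- function() {
  c("k1_D", "k2_D", "kmax_D", "cct_um", "axial_length_mm", "acd_mm")
}

recordParamCols <- function() c(scanParamCols(), "astigmatism_D")

writeJSONCanonical <- function(x, path) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                          null = "null", na = "null")
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}
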