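#' @useDynLib glossprobe, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom cor sd optim plogis qlogis
NULL

# Highlight floor: one display-quantization step of an 8-bit image. A pixel
# "contains a highlight" when its ground-truth specular value exceeds this.
GLOSS_EPSILON <- 1 / 255

#' Highlight binarization floor
#'
#' The intensity below which a ground-truth specular value is treated as
#' "no highlight". Fixed at 1/255 (one 8-bit quantization step) so that a
#' single binarization convention is shared by the stimulus generator, the
#' probe categorizer and every downstream analysis.
#'
#' @return A scalar.
#' @export
gloss_epsilon <- function() GLOSS_EPSILON

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All stochastic operations in the package
# funnel through this so that identical seeds give identical results.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from (seed, stream tag); keeps every component on an
# independent, reproducible stream while staying inside 32-bit range.
derive_seed <- function(seed, ...) {
  tags <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(tags)) h <- (h * 31 + ch) %% 2147483647L
  as.integer(h)
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
}

#' Read or write a plain-text PGM image
#'
#' Lossless 16-bit grayscale interchange using the ASCII `P2` NetPBM format.
#' Values in `[0, 1]` are quantized to 16 bits on write and mapped back on
#' read.
#'
#' @param x Numeric matrix with values in `[0, 1]`.
#' @param path File path.
#' @return `read_pgm()` returns a numeric matrix in `[0, 1]`.
#' @export
write_pgm <- function(x, path) {
  stopifnot(is.matrix(x))
  q <- round(clamp01(x) * 65535)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(x), nrow(x)), "65535"), con)
  # one image row per line
  writeLines(apply(q, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stop("only ASCII P2 PGM files are supported")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxv <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxv
}

# Pearson correlation that tolerates but flags degenerate input; used by the
# GA fitness path where fully severed networks produce constant predictions.
safe_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) {
    structure(0, degenerate = TRUE)
  } else {
    structure(cor(x, y), degenerate = FALSE)
  }
}
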