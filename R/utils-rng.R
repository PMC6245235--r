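# Named, reproducible substreams: a (master seed, label) pair maps to a fixed
# 32-bit seed, so every stochastic step in a pipeline draws from its own
# stream and pipelines can share streams by sharing labels.

#' Derive a deterministic substream seed
#'
#' Same master seed and label always give the same derived seed; distinct
#' labels give (with overwhelming probability) distinct streams.
#'
#' @param master integer master seed.
#' @param label character substream label.
#' @return an integer seed below 2^31.
#' @export
#' @examples
#' substreamSeed(1L, "resample") == substreamSeed(1L, "resample")
substreamSeed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  h <- master %% 2147483647
  for (byte in utf8ToInt(label)) {
    # doubles stay below 2^53, so the modular arithmetic is exact
    h <- (h * 31 + byte) %% 2147483647
  }
  h <- (h * 69069 + 12345) %% 2147483647
  as.integer(h)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

# shared input checks
assertCount <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x))
    stop(sprintf("%s must be a positive integer", nm), call. = FALSE)
  as.integer(x)
}
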