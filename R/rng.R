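#' Derive a reproducible child seed from a master seed
#'
#' Every stochastic operation in the package takes an explicit seed. When an
#' operation runs per-sample (or per-replicate) streams, the child seeds are a
#' deterministic function of the master seed and the stream index, so that
#' adding samples never perturbs earlier streams.
#'
#' @param seed integer master seed.
#' @param index non-negative integer stream index.
#' @return An integer seed in `[0, 2^31)`.
#' @export
#' @examples
#' derive_seed(1L, 0:3)
derive_seed <- function(seed, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  # exact in double precision: |values| < 2^53
  s <- (abs(as.double(seed)) %% 2147483647) * 48271 + as.double(index) * 7919
  as.integer(s %% 2147483629)
}

# run code under a temporary RNG state
with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
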