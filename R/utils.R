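#' @importFrom rlang abort warn .data
#' @importFrom stats fft mvfft cor cov sd var lm.fit pt pf qf rnorm rnbinom runif
#' @importFrom stats median quantile complete.cases coef setNames
#' @keywords internal
"_PACKAGE"

N_REGIONS <- 86L
N_CORTICAL <- 68L

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministically derive a child seed (< 2^31) from a master seed and
# arbitrary label strings; used to give each subject/session/modality an
# independent, reproducible random stream.
derive_seed <- function(master, ...) {
  lbl <- paste(c(master, ...), collapse = "/")
  h <- 5381
  for (v in utf8ToInt(lbl)) h <- (h * 33 + v) %% 2147483629
  as.integer(h + 1)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
}
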