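#' @importFrom stats rbinom rnorm runif plogis qlogis pchisq lm coef vcov
#' @importFrom stats binomial glm.fit predict sd
#' @importFrom utils read.delim write.table
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had_seed <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation; keeps results < 2^31 for set.seed().
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (i in seq_along(idx)) {
    s <- (s * 69069 + as.double(idx[i]) * 7919 + 1) %% 2147483647
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be TRUE or FALSE", name), call. = FALSE)
  }
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x) && x > 0
}

assert_binary_matrix <- function(m, what) {
  if (!is.matrix(m) || length(m) == 0L) {
    stop(sprintf("%s must be a non-empty matrix", what), call. = FALSE)
  }
  bad <- !(m %in% c(0, 1))
  if (any(bad)) {
    stop(sprintf("%s contains non-binary entries (e.g. %s)",
                 what, paste(utils::head(unique(m[bad]), 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(m)
}
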