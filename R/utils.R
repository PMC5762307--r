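## Internal helpers: classed conditions, seed fan-out, small checks.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(msg, class) {
  stop(structure(
    class = c(paste0("iplscreen_", class), "iplscreen_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

config_error <- function(msg) abort(msg, "config_error")
input_error <- function(msg) abort(msg, "input_error")
layout_error <- function(msg) abort(msg, "layout_error")
size_error <- function(msg) abort(msg, "size_error")

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    config_error(sprintf("'%s' must be an integer >= %d", field, min))
  as.integer(x)
}

check_proportion <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    config_error(sprintf("'%s' must be a proportion in [0, 1]", field))
  as.numeric(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    config_error(sprintf("'%s' must be a non-negative number", field))
  as.numeric(x)
}

## One RNG stream per data modality, all derived from the master seed, so
## that e.g. changing plate parameters never perturbs the expression draws.
seed_streams <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 6L)
  names(s) <- c("expression", "copynumber", "pathway", "screen",
                "segmentation", "pipeline")
  s
}

## Lognormal multiplicative noise factors with unit mean and given CV.
cv_noise_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
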