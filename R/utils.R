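#' Logit and inverse-logit
#'
#' Convenience wrappers around [stats::qlogis()] and [stats::plogis()], used
#' throughout the package to move prevalences between the probability and
#' log-odds scales.
#'
#' @param p Probabilities strictly inside (0, 1) for `logit`.
#' @param x Real values for `expit`.
#' @return Numeric vector.
#' @export
logit <- function(p) stats::qlogis(p)

#' @rdname logit
#' @export
expit <- function(x) stats::plogis(x)

# log(1 + exp(x)) without overflow for large x
log1pexp <- function(x) {
  out <- x
  small <- x < 30
  out[small] <- log1p(exp(x[small]))
  out
}

#' Derive a stage seed from a master seed
#'
#' Maps a master seed and a stage label to a reproducible 31-bit integer seed,
#' so that every stochastic stage of a pipeline draws from its own stream and
#' adding a stage never perturbs the streams of earlier stages.
#'
#' @param master Integer master seed.
#' @param stage Character stage label, e.g. `"sample"` or `"bootstrap"`.
#' @return A single integer in `[0, 2^31 - 1)`.
#' @examples
#' derive_seed(1, "sample")
#' derive_seed(1, "bootstrap")
#' @export
derive_seed <- function(master, stage) {
  stopifnot(length(master) == 1, is.finite(master), is.character(stage),
            length(stage) == 1)
  mod <- 2147483647
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% mod
  as.integer((abs(master) %% mod * 48271 + h) %% mod)
}

# validate a single positive count
check_count <- function(x, name, min = 1L) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != round(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  as.integer(x)
}

# columns required in a data.frame, with a helpful error
check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}
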