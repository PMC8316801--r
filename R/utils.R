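#' @keywords internal
"_PACKAGE"

## Condition constructors. Validation/config/io errors map to CLI exit code 1,
## anything else to 2.

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("img2net_validation", "img2net_error")))
}

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("img2net_config", "img2net_validation",
                                "img2net_error")))
}

stop_io <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("img2net_io", "img2net_validation",
                                "img2net_error")))
}

stop_singular <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("img2net_singular", "img2net_error")))
}

## Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## One global seed feeds per-stage independent generators. Stage names are
## hashed into an offset so stages can be re-run in isolation.
derive_seed <- function(seed, stage, index = 0L) {
  code <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  s <- (as.double(seed) %% 2147483647) * 31 + code * 97561 + index * 104729
  as.integer(s %% 2147483646) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == round(x)
}
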