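# internal helpers shared across modules

# Run `code` under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(structure(class = c("bimansem_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_validation(name, " must be a probability in [0, 1], got ",
                    deparse(substitute(x)))
}

MODES <- c("in_phase", "anti_phase")
HANDS <- c("L", "R")
FINGERS <- c("index", "middle")
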