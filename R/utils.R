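# internal helpers

abort_da <- function(message, class) {
  rlang::abort(message, class = c(class, "darkadaptr_error"))
}

# Scoped seeding: restores the caller's RNG state on exit so package functions
# are deterministic under `seed` without clobbering the session RNG.
local_seed_if <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::local_seed(as.integer(seed), .local_envir = env)
  }
  invisible(NULL)
}

# trapezoidal integral of y over x (used for the adjusted AUC)
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
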