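# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
# All stochastic operations in the package take an explicit seed and go
# through this, so results never depend on the session RNG state.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Log-spaced sequence, used for default diffusion-time grids.
lseq <- function(from, to, length.out) {
  exp(seq(log(from), log(to), length.out = length.out))
}

stop_axonwalk <- function(message, class) {
  abort(message, class = c(class, "axonwalk_error"))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (allow_inf || is.finite(x)) && x >= lower && x <= upper
  if (!ok) {
    stop_axonwalk(
      sprintf("`%s` must be a single number in [%s, %s].", name, lower, upper),
      "axonwalk_error_invalid_spec"
    )
  }
  invisible(x)
}

# Gaussian smoothing of a regularly sampled series with reflective padding.
# `sigma` in the same units as the grid spacing `dx`; sigma = 0 is a no-op.
gaussian_smooth <- function(x, sigma, dx) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma / dx))
  u <- (-half:half) * dx
  kern <- exp(-u^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  n <- length(x)
  pad <- c(x[pmin(half:1, n)], x, x[pmax(n - (1:half) + 1L, 1L)])
  as.numeric(stats::filter(pad, kern, sides = 2))[(half + 1L):(half + n)]
}
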