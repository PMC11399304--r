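# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  All stochastic operations in the package
# route through this so identical configs give byte-identical output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    stop_invalid("'%s' must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

check_prob <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- length(x) == 1L && is.numeric(x) && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    stop_invalid("'%s' must be in %s%g, %g%s", name,
                 if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]")
  }
  as.numeric(x)
}

is_x_chrom <- function(chrom) {
  chrom == 23L | toupper(as.character(chrom)) == "X"
}

# Symmetrize a numeric matrix (guards against sub-eps asymmetry from BLAS).
symmetrize <- function(m) (m + t(m)) / 2
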