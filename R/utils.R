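# internal validation and seeding helpers

stop_invalid <- function(...) {
  stop(structure(class = c("episel_invalid_parameter", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stop_invalid(name, " must be a single integer >= ", min)
  as.integer(x)
}

check_positive <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x <= 0)
    stop_invalid(name, " must be a single positive number")
  as.numeric(x)
}

check_prob <- function(x, name, open_lo = FALSE, open_hi = FALSE) {
  if (length(x) != 1L || !is.finite(x) ||
      (open_lo && x <= 0) || (!open_lo && x < 0) ||
      (open_hi && x >= 1) || (!open_hi && x > 1))
    stop_invalid(name, " must lie in ", if (open_lo) "(" else "[", "0, 1",
                 if (open_hi) ")" else "]")
  as.numeric(x)
}

# Derive reproducible child seeds from one root seed.  Used so that each
# replicate / module-level rerun consumes its own stream regardless of
# the order in which other components are run.
child_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(check_count(seed, "seed", min = 0L))
  invisible(NULL)
}
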