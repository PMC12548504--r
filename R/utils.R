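# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hw <- function(..., class) {
  stop(structure(
    class = c(class, "hw_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_hw(name, " must be a single finite number", class = "hw_domain_error")
  if (x < lower || x > upper || (!allow_zero && x == 0))
    stop_hw(name, " = ", format(x), " is outside [", lower, ", ", upper, "]",
            class = "hw_domain_error")
  as.numeric(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x))
    stop_hw(name, " must be a single integer", class = "hw_domain_error")
  if (x < lower)
    stop_hw(name, " must be >= ", lower, class = "hw_domain_error")
  as.integer(x)
}

# full-precision text encoding of doubles; round trips bitwise through
# as.numeric (17 significant digits suffice for IEEE double)
num_to_chr <- function(x) sprintf("%.17g", x)
chr_to_num <- function(x) as.numeric(x)

# split a user seed into independent substreams, keeping each < 2^31
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647
}

# centred frequency axis after an fftshift, length n, dwell dt (s) -> Hz
freq_axis <- function(n, dt) {
  (seq_len(n) - 1L - n %/% 2L) / (n * dt)
}

# reorder an fft output so frequency runs from -SW/2 to +SW/2
fftshift_idx <- function(n) {
  c(seq.int(n %/% 2L + 1L, n), seq_len(n %/% 2L))
}
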