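# Internal helpers shared across modules.

# Deterministic 32-bit FNV-1a hash of a string; used to key fold assignment
# by subject id so fold membership survives row reordering.
fnv1a32 <- function(x) {
  # arithmetic on 16-bit halves: R integers are 32-bit signed and doubles
  # lose exactness past 2^53, so neither bitwXor nor plain multiplication
  # can act on full 32-bit words here
  prime <- 16777619
  vapply(x, function(s) {
    h <- 2166136261
    for (b in utf8ToInt(s)) {
      lo <- bitwXor(as.integer(h %% 65536), b) + (h %/% 65536) * 65536
      h <- (lo %% 65536 * prime + ((lo %/% 65536 * prime) %% 65536) * 65536) %%
        4294967296
    }
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# round half away from zero (base round() is banker's)
round_half_up <- function(x) floor(x + 0.5)

z_quartile <- qnorm(0.75)

# sd of a normal with the given IQR
normal_sd_from_iqr <- function(iqr) iqr / (2 * z_quartile)

# log-sd of a lognormal with the given median and IQR:
# IQR = 2 * median * sinh(z * sigma) with z = qnorm(0.75)
lognormal_sdlog_from_iqr <- function(median, iqr) {
  asinh(iqr / (2 * median)) / z_quartile
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)),
          class = "uhrisk_config_error")
  }
  invisible(x)
}
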