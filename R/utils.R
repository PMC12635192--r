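# internal helpers shared across modules

# run code under a local RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# derive a child seed (< 2^31) from a parent seed and a text salt, so that
# independent generators (per GCM id, per species, ...) get distinct but
# reproducible streams
derive_seed <- function(seed, salt) {
  h <- sum(utf8ToInt(as.character(salt)) * seq_along(utf8ToInt(as.character(salt))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pn <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == floor(x)
}

# numerically stable log(sum(exp(x)))
log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
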